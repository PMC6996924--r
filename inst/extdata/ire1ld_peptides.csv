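start_res,end_res,mz,z,sequence
24,36,631.345,2,STSTVTLPETLL
37,45,938.478,1,FVSTLDGSL
46,59,396.730,4,HAVSKRTGSIKWTL
77,85,927.435,1,LPDPNDGSL
86,106,779.087,3,YTLGSKNNEGLTKLPFTIPEL
96,106,636.380,2,LTKLPFTIPEL
107,119,1316.680,1,VQASPSRSSDGIL
120,128,390.199,3,YMGKKQDIW
130,134,735.424,1,YVIDLL
134,145,631.832,2,LTGEKQQTLSSA
147,157,1090.563,1,ADSLSPSTSLL
157,168,730.874,2,LYLGRTEYTITM
168,175,522.242,2,MYDTKTRE
176,183,535.772,2,LRWNATYF
186,195,1031.447,1,AASLPEDDVD
196,208,727.837,2,YKMSHFVSNGDGL
209,221,703.343,2,VVTVDSESGDVLW
221,232,697.856,2,WIQNYASPVVAF
233,240,1050.537,1,YVWQREGL
241,248,332.864,3,RKVMHINV
253,258,406.735,2,LRYLTF
280,287,444.28,2,KSKLTPTL
288,296,1017.525,1,YVGKYSTSL
297,302,655.273,1,YASPSM
303,316,474.268,3,VHEGVAVVPRGSTL
317,335,956.978,2,PLLEGPQTDGVTIGDKGES
343,360,534.307,4,VKFDPGLKSKNKLNYLRN
365,378,503.588,3,IGHHETPLSASTKM
379,404,516.606,6,LERFPNNLPKHRENVIPADSEKKSFE
410,424,810.376,2,VDQTSENAPTTVSRD
410,443,727.149,5,VDQTSENAPTTVSRDVEEKPAHAPARPEAPVDSM
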