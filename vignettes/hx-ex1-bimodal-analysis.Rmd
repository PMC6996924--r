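---
title: "Deuterium uptake and EX1 bimodal analysis of HX-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deuterium uptake and EX1 bimodal analysis of HX-MS data}
  %\VignetteEncoding{UTF-8}
---

## Scope

`hxtools` implements a peptide-level analysis chain for hydrogen/deuterium
exchange mass spectrometry (HX-MS) of a protein whose activity is governed
by a monomer–dimer equilibrium — the ER stress sensor IRE1's luminal
domain, whose dimer is actively disassembled by the Hsp70 chaperone BiP
with its J-domain co-chaperone. The chain runs from peptic-peptide
chemistry (monoisotopic m/z, exchangeable-amide counts, isotope envelopes,
coverage maps) through centroid-based uptake quantification with
back-exchange correction, to the core computation: deconvolution of
bimodal (EX1-regime) isotope clusters into low- and high-exchanging
subpopulations by a global two-Gaussian fit, and extraction of the
transition rate constant `k_trans` of the low-to-high conversion from a
one-phase association fit. Ancillary fits used alongside such a study —
anisotropy/Hill binding, FRET association kinetics with initial
velocities, biexponential BLI dissociation, DSF melting temperatures —
are included, as is a synthetic-data generator with known ground truth.

## The exchange model

A backbone amide exchanges its hydrogen for a solvent deuteron only while
the structure-specific H-bond protecting it is open:

    F(H)  <--k_op / k_cl-->  U(H)  --k_ch-->  U(D)  <-->  F(D)

with opening rate `k_op`, closing rate `k_cl` and intrinsic chemical rate
`k_ch`. Two limits matter:

* **EX1** (`k_cl << k_ch`): every opening event exchanges all amides of the
  element at once; the observed rate is essentially `k_op` and spectra are
  **bimodal** — a mixture of an undeuterated-like and a near-fully
  deuterated envelope whose weights evolve as `1 - exp(-k_op t)`.
* **EX2** (`k_cl >> k_ch`): many opening cycles are needed; the envelope
  shifts **gradually and unimodally** with per-amide rate
  `(k_op / k_cl) k_ch`.

`hx_exchanged_fraction_exact()` provides the closed-form solution of the
full three-state scheme (used as a cross-check and for mixed-regime
simulation); `hx_fraction_opened()` is the EX1 limit.

Hydrogen exchange is quasi-irreversible on the experimental timescale:
once a molecule has transited the high-exchanging conformation it keeps
that signature. Two consequences are wired into the code: fraction-high
time courses are fitted with a plateau that can never fall below the
intercept (the plateau is parameterised as `f0 + d`, `d >= 0`), and `f0`
is a free parameter — samples pre-incubated with chaperones enter D2O
already partially converted, so the intercept must not be pinned to zero.

## Bimodal deconvolution

For one cluster (one peptide / timepoint / condition / replicate) the
isotope peak maxima versus m/z are fitted with the sum of two Gaussians,

I(µ) = A1/(σ√2π) · exp(−(µ−µ1)²/2σ²) + A2/(σ√2π) · exp(−(µ−µ2)²/2σ²),

with one shared σ and the means fitted globally across the peaks of the
timepoint. Replicates are fitted independently. From the fitted
parameters, per-peak subpopulation fractions are computed as the density
ratio A2·G(µ;µ2,σ) / [A1·G(µ;µ1,σ) + A2·G(µ;µ2,σ)] at each peak position.

Numerical choices, all surfaced as arguments:

* **Initialisation from controls.** µ1 starts at the unexchanged-control
  centroid, µ2 at the fully-deuterated-control centroid, σ at the
  intensity-weighted width of the unexchanged control, and the areas at
  half the observed peak area each. The two mandated control samples pin
  the two modes, which is why the pipeline requires them.
* **Bounds.** µ1 and µ2 are each confined to ±2 Th of their initialiser
  and σ to [0.3, 5] times its initialiser, preventing label switching and
  mode collapse. Tolerances: 1e-8 relative on parameters and cost, 1024
  iterations of bounded Levenberg–Marquardt (minpack.lm), preceded by a
  four-point deterministic multi-start (area splits 50/50, 80/20, 20/80
  and a doubled σ) so the reported optimum is the global one within the
  box.
* **Minimum data.** A five-parameter model is only fitted to clusters
  with at least five peak points; smaller clusters are rejected with an
  instruction to route them to unimodal analysis. A stalled optimiser
  returns `converged = FALSE` instead of throwing.
* **Peak grids.** Natural isotope peaks are spaced 1.00335/z (the
  C13–C12 mass difference over charge); deuteron incorporation shifts
  mass by 1.006277/z. The simulator keeps both ladders exact;
  `hx_peak_maxima()` merges near-degenerate positions onto the isotope
  grid anchored at the most intense peak and flags anything further than
  20% of a spacing off-grid as spurious.

### Regime classification

Two notions are computed and kept separate:

* **Fit degeneracy** (`unimodal` flag): minor-component area below 1% of
  the total, or mean separation below one peak spacing.
* **Modality of the data** (`hx_classify_modality()`): a valley test on
  the grid-merged peak list — the cluster is bimodal when some interior
  grid position dips below half the smaller of its flanking maxima. This
  is the operational meaning of "bimodal isotope distribution" and is the
  primary classifier: a mid-exchange EX2 envelope sits far from both
  control anchors, where the µ-bounded two-Gaussian fit cannot collapse
  by the area rule alone, but the valley test identifies it as unimodal
  directly. The default valley depth (0.5) is deliberately conservative;
  it is exact on noise-free data and robust to the few-percent intensity
  noise used here, but is not a dip test for heavily noised spectra.

### Two definitions of the high-mass fraction

The aggregate fraction-high is reported both as the area ratio
`A2/(A1+A2)` and as the intensity-weighted mean of the per-peak fractions
(`fraction_high_weighted`). Real isotope envelopes of short peptides are
skewed, and a shared-σ Gaussian pair is a mildly misspecified model for
them: at the least-squares optimum the area ratio can misstate the true
mixture weight by up to about 0.01–0.02 (and the fitted areas can miss
the summed peak area by more than 5%), with the weighted per-peak
aggregate usually closer to the truth for well-separated subpopulations.
Both are therefore emitted, and the k_trans stage uses the area ratio, the
convention this kind of analysis reports. The package's tests quantify this bias on
simulated data; the area-balance property is asserted only where the
Gaussian model actually describes the envelope.

## k_trans extraction and comparison

Fraction-high time courses are fitted per replicate with
`f(t) = f0 + (plateau − f0)(1 − exp(−k_trans t))` under
`0 ≤ f0, plateau ≤ 1` and `k_trans > 0`; flat series are reported as
non-identifiable rather than fitted. `hx_compare_ktrans()` summarises
replicate k_trans values per condition (mean ± sd) with plain two-sample
comparisons. Absolute k_trans values inherit the small-subpopulation bias
discussed above (they are compressed by roughly the same factor in every
condition), so condition *ratios* are the robust readout — matching the
interpretation that differences in k_trans between conditions, not its
absolute value, report on dimer dissociation.

## What the simulator emulates — and what it does not

`hx_simulate_dataset()` emulates: triplicate isotope clusters for the
packaged 31-peptide peptic map at D2O times {0, 30, 300} s (denser series
on request), untreated versus chaperone-treated conditions differing only
in opening rate, per-peptide unexchanged (`time_s = -1`) and fully
deuterated (`time_s = -2`) controls generated under the same
back-exchange, and multiplicative-plus-additive Gaussian intensity noise
(`I·(1+ε_rel) + ε_abs`). Defaults: `k_op` 0.002 (untreated) and 0.006 1/s
(treated; the three-fold acceleration mirrors the chaperone effect),
`k_cl` 0.05 1/s, `k_ch` 5 1/s (EX1 conditions at 30 °C-like chemistry),
back-exchange 0.15, relative noise 0.02 — no measured values exist for
spectral noise or back-exchange in the emulated design, so these are
stated, realistic choices, reported with every run, not measured facts.
Randomness derives from one master seed through per-(peptide, condition,
replicate) substreams, so any subset is reproducible independently.

Not emulated: chromatographic co-elution, cross-peptide envelope overlap,
charge-state interference, partial-protection EX1 (the high-exchanging
subpopulation is modelled at full deuteration of the observable amides,
with the N-terminal residue and prolines excluded), pH/temperature
dependence of `k_ch`, and vendor raw formats (spectra arrive as tabular
peak lists). Passing recovery tests on these simulations therefore shows
the estimator chain is correct under the stated noise model; it does not
certify performance on spectra whose dominant artefacts are the ones not
modelled.

## Ancillary fits

All nonlinear fits share one backend contract: bounded
Levenberg–Marquardt, convergence at 1e-8 or tighter, deterministic given
data and initialiser.

* **Anisotropy/Hill**: `A = (I∥ − I⊥)/(I∥ + 2 I⊥)`;
  `r(X) = r_free + (r_max − r_free)·Xʰ/(Xʰ + Kʰ)` with minimal
  constraints (positivity of K and h, `r_max > r_free`). The fitted
  half-maximal concentration K_1/2max is an operational half-saturation
  point; because the model ignores the binding partner's own
  dimer/oligomer equilibria it does **not** reflect the dissociation
  constant.
* **FRET association**: one-phase association; the initial velocity is
  the slope of the fitted curve at time zero, `k·(plateau − y0)`.
* **BLI dissociation**: `y0·[p·e^(−k_fast t) + (1−p)·e^(−k_slow t)]` on
  traces normalised to their value at the first post-wash timepoint, with
  `k_fast ≥ k_slow` enforced to resolve label switching. Whether such
  fits should carry a free plateau is a modelling choice; the default
  fixes it at zero (traces decay toward baseline) with a free-plateau
  variant behind a flag.
* **DSF**: Savitzky–Golay smoothing (window 5, order 2 — a derivative of
  raw noisy fluorescence is unusable), central-difference derivative, Tm
  at the global minimum of −dF/dT refined by local quadratic
  interpolation; curves with no interior extremum are rejected.

## Problem sizes and verification

The test-suite and analysis scripts run at desk scale: the full 31-peptide
map for coverage/uptake (triplicates, two conditions, two-to-three
timepoints), the two bimodal exemplar peptides (655.273¹⁺, residues
297–302, and 636.380²⁺, residues 96–106) for the k_trans chain over five
timepoints, twenty-seed noise replicates for ratio-recovery properties,
and one hundred seeds for the Hill-K recovery property. Oracles are kept
independent of the fitting route: exhaustive isotopologue enumeration for
envelopes, per-residue boolean set union for coverage, RK4 integration
for the three-state kinetics, and grid-search-plus-polish optimisers for
the two-Gaussian, Hill and biexponential fits.

## Known limitations

* The two-Gaussian area ratio under-resolves very small subpopulations
  (below ~5% of total intensity) on skewed envelopes; use the weighted
  per-peak aggregate and condition ratios there.
* The valley classifier assumes baseline-dominated valleys; at high
  noise-to-signal it will under-call bimodality.
* No residue-level exchange-rate fitting from overlapping peptides, no
  three-component mixtures, no fitting of raw profile spectra (peak
  maxima only), and no Bayesian uncertainty on k_trans.
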