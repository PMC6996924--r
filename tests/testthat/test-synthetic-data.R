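test_that("fraction opened follows first-order opening kinetics", {
  par <- hx_regime_params(0.01, 0.001, 10)
  expect_identical(par$regime, "EX1")
  expect_equal(hx_fraction_opened(par, 0), 0)
  expect_equal(hx_fraction_opened(par, log(2) / 0.01), 0.5, tolerance = 1e-12)
  t <- seq(0, 2000, by = 50)
  f <- hx_fraction_opened(par, t)
  expect_true(all(diff(f) > 0))
  expect_equal(hx_fraction_opened(par, 1e7), 1, tolerance = 1e-12)
  expect_error(hx_fraction_opened(par, -1), ">= 0")
  expect_error(hx_regime_params(0, 1, 1), "> 0")
})

test_that("exact three-state closed form matches numerical integration and the EX1 limit", {
  cases <- list(c(0.005, 0.05, 5), c(0.01, 1, 0.5), c(0.002, 10, 0.01))
  for (k in cases) {
    for (t_end in c(30, 300)) {
      expect_equal(hx_exchanged_fraction_exact(k[1], k[2], k[3], t_end),
                   exchange_rk4(k[1], k[2], k[3], t_end),
                   tolerance = 1e-7)
    }
  }
  # EX1 limit: k_cl << k_ch makes the exact solution track 1 - exp(-k_op t)
  ex1 <- hx_regime_params(0.005, 0.005, 50)
  t <- c(10, 100, 500)
  expect_equal(hx_exchanged_fraction_exact(0.005, 0.005, 50, t),
               hx_fraction_opened(ex1, t), tolerance = 1e-3)
})

test_that("simulated clusters honour the unexchanged and fully-deuterated endpoints", {
  pep <- hx_peptide("YASPSM", 297, 302, 1)
  par <- hx_regime_params(0.005, 0.05, 5)
  env <- hx_isotope_envelope("YASPSM", 1, 8)

  cl0 <- hx_simulate_cluster(pep, par, 0)
  expect_equal(cl0$mz, env$monoisotopic_mz + (0:7) * env$spacing, tolerance = 1e-9)
  expect_equal(cl0$intensity, as.numeric(env$abundances), tolerance = 1e-12)

  # endpoint: centroid of a long-time EX1 cluster equals the fully
  # deuterated control centroid (same back-exchange)
  b <- 0.15
  n_ex <- hx_exchangeable_amides("YASPSM")
  fd <- hxtools:::.cross_envelope(env, stats::dbinom(0:n_ex, n_ex, 1 - b), 1)
  cl_inf <- hx_simulate_cluster(pep, par, 1e7, back_exchange = b)
  expect_equal(hx_centroid(cl_inf, 0), hx_centroid(fd, 0), tolerance = 1e-9)
})

test_that("EX1 mixture weight at the opening half-life is exactly one half", {
  pep <- hx_peptide("YASPSM", 297, 302, 1)
  par <- hx_regime_params(0.005, 0.05, 5)
  t_half <- log(2) / 0.005  # 138.6 s
  cl <- hx_simulate_cluster(pep, par, t_half)
  # direct two-component decomposition: rows on the deuterated ladder
  env <- hx_isotope_envelope("YASPSM", 1, 8)
  low_mz <- env$monoisotopic_mz + (0:7) * env$spacing
  is_low <- cl$mz %in% low_mz
  expect_equal(sum(cl$intensity[!is_low]) / sum(cl$intensity), 0.5,
               tolerance = 1e-9)
})

test_that("total cluster intensity is conserved across timepoints at zero noise", {
  pep <- hx_peptide("LTKLPFTIPEL", 96, 106, 2)
  par <- hx_regime_params(0.005, 0.05, 5)
  totals <- vapply(c(0, 30, 300, 3000), function(t) {
    sum(hx_simulate_cluster(pep, par, t, back_exchange = 0.15)$intensity)
  }, numeric(1))
  expect_equal(totals, rep(totals[1], 4), tolerance = 1e-9)
})

test_that("dataset simulation yields the expected design counts and determinism", {
  peps <- suppressMessages(hx_read_peptides(peptide_fixture_path()))
  cfg <- hx_sim_config(peps, timepoints = c(30, 300), replicates = 3, seed = 7)
  ds <- hx_simulate_dataset(cfg)
  samples <- ds[ds$time_s >= 0, ]
  groups <- unique(samples[, c("peptide_id", "condition", "replicate", "time_s")])
  expect_identical(nrow(groups), 31L * 2L * 3L * 2L)  # 372 clusters
  ctrls <- unique(ds[ds$time_s < 0, c("peptide_id", "time_s")])
  expect_identical(nrow(ctrls), 62L)                  # 2 controls per peptide

  ds2 <- hx_simulate_dataset(cfg)
  expect_identical(ds, ds2)

  expect_error(hx_sim_config(peps, conditions = list(a = cfg$conditions[[1]],
                                                     a = cfg$conditions[[2]])),
               "uniquely named")
})

test_that("raising the opening rate raises every peptide's early uptake", {
  peps <- suppressMessages(hx_read_peptides(peptide_fixture_path()))[c(6, 24)]
  condA <- hx_regime_params(0.002, 0.02, 2)
  condB <- hx_regime_params(0.004, 0.02, 2)
  cfg <- hx_sim_config(peps, timepoints = c(30), replicates = 1,
                       conditions = list(A = condA, B = condB),
                       back_exchange = 0.1, noise_sd_rel = 0, noise_sd_abs = 0)
  ds <- hx_simulate_dataset(cfg)
  for (pid in unique(ds$peptide_id[ds$time_s >= 0])) {
    cA <- hx_centroid(ds[ds$peptide_id == pid & ds$condition == "A", ], 0)
    cB <- hx_centroid(ds[ds$peptide_id == pid & ds$condition == "B", ], 0)
    expect_gt(cB, cA)
  }
})

test_that("trace simulator anchors match the closed-form models", {
  fr <- hx_simulate_trace("fret_association",
                          list(y0 = 1000, plateau = 1400, k = 0.002,
                               times = c(0, 100, 500, 2000)))
  expect_equal(fr$y[1], 1000)
  expect_equal(fr$y[4], 1000 + 400 * (1 - exp(-0.002 * 2000)))

  # degenerate single-phase mixture equals the closed form at all t
  t <- seq(0, 500, by = 25)
  bli <- hx_simulate_trace("bli_dissociation",
                           list(y0 = 2, p = 1, k_fast = 0.02, k_slow = 0.001,
                                times = t))
  expect_equal(bli$y, 2 * exp(-0.02 * t), tolerance = 1e-12)
  expect_error(hx_simulate_trace("bli_dissociation",
                                 list(y0 = 1, p = 1.4, k_fast = 1, k_slow = 0.1,
                                      times = t)), "p must be")

  # Hill midpoint at X = K regardless of h
  for (h in c(0.5, 1, 3)) {
    an <- hx_simulate_trace("anisotropy_titration",
                            list(r_free = 0.05, r_max = 0.25, K = 2, h = h,
                                 conc = c(0.1, 2, 50)))
    expect_equal(an$r[2], (0.05 + 0.25) / 2, tolerance = 1e-12)
    expect_equal(hx_anisotropy(an$I_para, an$I_perp), an$r, tolerance = 1e-12)
  }

  expect_error(hx_simulate_trace("melt_curve", list(F0 = 1, dF = 2)), "missing")
})
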