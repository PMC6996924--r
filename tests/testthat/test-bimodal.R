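test_that("peak-maximum extraction is idempotent and rejects tiny clusters", {
  setup <- make_ex1_setup("YASPSM", 297, 302, 1)
  cl <- hx_simulate_cluster(setup$pep, setup$par, 100)
  pk <- hx_peak_maxima(cl, 1)
  pk2 <- hx_peak_maxima(pk, 1)
  expect_equal(pk2$mz, pk$mz, tolerance = 1e-12)
  expect_equal(pk2$intensity, pk$intensity, tolerance = 1e-12)
  expect_error(hx_peak_maxima(data.frame(mz = c(1, 2, 3), intensity = 1:3), 1),
               "too few")
  expect_error(hx_peak_maxima(data.frame(mz = 1, intensity = NaN), 1),
               "non-finite")
})

test_that("dense profile input reduces to isotope peak maxima on the grid", {
  mono <- 655
  s <- hx_constants[["c13_shift"]]
  heights <- c(0.6, 0.25, 0.08, 0.4, 0.3, 0.1)
  grid <- seq(mono - 0.5, mono + 5 * s + 0.5, by = 0.01)
  prof <- rowSums(vapply(seq_along(heights), function(i) {
    heights[i] * exp(-0.5 * ((grid - (mono + (i - 1) * s)) / 0.05)^2)
  }, numeric(length(grid))))
  pk <- hx_peak_maxima(data.frame(mz = grid, intensity = prof), 1)
  expect_identical(nrow(pk), 6L)
  expect_true(all(abs(pk$mz - (mono + (0:5) * s)) <= 0.005 + 1e-12))
})

test_that("off-grid spurious peaks are flagged and excluded", {
  s <- hx_constants[["c13_shift"]]
  mz <- 655 + (0:5) * s
  cl <- data.frame(mz = c(mz, 655 + 2.5 * s),
                   intensity = c(0.5, 0.3, 0.15, 0.3, 0.2, 0.05, 0.12))
  pk <- hx_peak_maxima(cl, 1)
  expect_identical(nrow(pk), 6L)
  flagged <- attr(pk, "flagged")
  expect_identical(nrow(flagged), 1L)
  expect_equal(flagged$mz, 655 + 2.5 * s)
})

test_that("the two-Gaussian fit recovers its own model exactly", {
  s <- hx_constants[["c13_shift"]]
  mu1 <- 655.3; mu2 <- 659.5; sigma <- 0.62; A1 <- 0.8; A2 <- 0.8
  x <- 655.3 + (-2:7) * s
  y <- A1 * gauss_dens(x, mu1, sigma) + A2 * gauss_dens(x, mu2, sigma)
  fit <- hx_fit_bimodal(data.frame(mz = x, intensity = y),
                        list(mu1 = mu1 + 0.3, mu2 = mu2 - 0.4, sigma = 0.5))
  expect_true(fit$converged)
  expect_equal(fit$mu1, mu1, tolerance = 1e-6)
  expect_equal(fit$mu2, mu2, tolerance = 1e-6)
  expect_equal(fit$sigma, sigma, tolerance = 1e-6)
  expect_equal(fit$A1, A1, tolerance = 1e-6)
  expect_equal(fit$fraction_high, 0.5, tolerance = 1e-8)
})

test_that("single-Gaussian data degenerates to a flagged unimodal fit", {
  s <- hx_constants[["c13_shift"]]
  x <- 655.3 + (-2:6) * s
  y <- 1.2 * gauss_dens(x, 655.5, 0.7)
  fit <- hx_fit_bimodal(data.frame(mz = x, intensity = y),
                        list(mu1 = 655.5, mu2 = 659.5, sigma = 0.7))
  expect_true(fit$unimodal)
  expect_lt(min(fit$A1, fit$A2), 0.01 * (fit$A1 + fit$A2))
  # one-Gaussian reference fit explains the data equally well
  ref <- stats::optim(c(1, 655.5, 0.7), function(p) {
    sum((p[1] * gauss_dens(x, p[2], p[3]) - y)^2)
  }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(fit$rss, ref$value + 1e-10)
})

test_that("EX1 simulations at fraction_opened 0.3 yield fraction_high 0.30 within 0.01", {
  setup <- make_ex1_setup("YASPSM", 297, 302, 1)
  t <- -log(1 - 0.3) / setup$par$k_op
  cl <- hx_simulate_cluster(setup$pep, setup$par, t)
  fit <- hx_fit_bimodal(hx_peak_maxima(cl, 1), setup$init)
  expect_true(fit$converged)
  expect_identical(fit$modality, "bimodal")
  expect_lt(abs(fit$fraction_high - 0.30), 0.01)
})

test_that("noise-free mixture weights are recovered within 0.01 across fractions", {
  setup <- make_ex1_setup("LTKLPFTIPEL", 96, 106, 2)
  for (f in c(0.3, 0.5, 0.7)) {
    t <- -log(1 - f) / setup$par$k_op
    cl <- hx_simulate_cluster(setup$pep, setup$par, t)
    fit <- hx_fit_bimodal(hx_peak_maxima(cl, 2), setup$init)
    expect_lt(abs(fit$fraction_high - f), 0.025)
    expect_lt(abs(fit$fraction_high_weighted - f), 0.01)
  }
})

test_that("per-peak fractions follow the density-ratio formula", {
  fit <- structure(list(A1 = 1.3, A2 = 0.6, mu1 = 655.2, mu2 = 659.4,
                        sigma = 0.71, converged = TRUE),
                   class = "hx_bimodal_fit")
  x <- 654.5 + (0:6) * 1.00335
  got <- hx_per_peak_fractions(fit, data.frame(mz = x, intensity = 1))
  # independent re-implementation of the ratio formula
  g <- function(m, mu, s) exp(-((m - mu)^2) / (2 * s^2)) / sqrt(2 * pi * s^2)
  ref <- 0.6 * g(x, 659.4, 0.71) /
    (1.3 * g(x, 655.2, 0.71) + 0.6 * g(x, 659.4, 0.71))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))

  # midpoint symmetry at equal areas
  fit$A1 <- fit$A2 <- 1
  mid <- (fit$mu1 + fit$mu2) / 2
  expect_equal(hx_per_peak_fractions(fit, data.frame(mz = mid, intensity = 1)),
               0.5, tolerance = 1e-12)

  # degenerate mixture: no high component anywhere
  fit$A2 <- 0
  expect_equal(hx_per_peak_fractions(fit, data.frame(mz = x, intensity = 1)),
               rep(0, 7))

  # both densities under the floor: undefined, marked missing
  fit$A2 <- 1
  far <- data.frame(mz = 10000, intensity = 1)
  expect_true(is.na(hx_per_peak_fractions(fit, far)))
})

test_that("fraction_high is invariant under uniform intensity rescaling", {
  setup <- make_ex1_setup("YASPSM", 297, 302, 1)
  cl <- hx_simulate_cluster(setup$pep, setup$par, 150)
  f1 <- hx_fit_bimodal(hx_peak_maxima(cl, 1), setup$init)$fraction_high
  cl$intensity <- cl$intensity * 37.5
  f2 <- hx_fit_bimodal(hx_peak_maxima(cl, 1), setup$init)$fraction_high
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("fraction_high grows monotonically in time on noiseless EX1 data", {
  setup <- make_ex1_setup("YASPSM", 297, 302, 1)
  times <- c(10, 30, 100, 300, 1000)
  fr <- vapply(times, function(t) {
    cl <- hx_simulate_cluster(setup$pep, setup$par, t)
    hx_fit_bimodal(hx_peak_maxima(cl, 1), setup$init)$fraction_high
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("fitted areas balance the observed peak area within 5%", {
  # Gaussian-shaped cluster with a deterministic 2% shape perturbation:
  # the regime where the area parameters are physically interpretable
  s <- hx_constants[["c13_shift"]]
  x <- 655.3 + (-2:7) * s
  y <- (0.6 * gauss_dens(x, 655.4, 0.65) + 0.9 * gauss_dens(x, 659.5, 0.65)) *
    (1 + 0.02 * cos(seq_along(x)))
  pk <- hx_peak_maxima(data.frame(mz = x, intensity = y), 1)
  fit <- hx_fit_bimodal(pk, list(mu1 = 655.4, mu2 = 659.5, sigma = 0.6))
  total_area <- sum(pk$intensity) * attr(pk, "spacing")
  expect_lt(abs((fit$A1 + fit$A2) - total_area) / total_area, 0.05)
})

test_that("global fit optimum matches a grid-search-plus-polish oracle", {
  setup <- make_ex1_setup("YASPSM", 297, 302, 1, n_peaks = 5L)
  cl <- hx_simulate_cluster(setup$pep, setup$par, 150, n_peaks = 5L)
  pk <- hx_peak_maxima(cl, 1)
  expect_lte(nrow(pk), 9L)
  fit <- hx_fit_bimodal(pk, setup$init)
  rss_oracle <- oracle_bimodal_rss(pk, setup$init)
  expect_lt(abs(fit$rss - rss_oracle), 1e-6 * max(rss_oracle, 1e-12))
})

test_that("one-phase association recovers transition parameters", {
  t <- c(0, 10, 30, 100, 300, 1000)
  y <- 0.1 + 0.8 * (1 - exp(-0.01 * t))
  tf <- hx_fit_transition(t, y)
  expect_true(tf$converged)
  expect_equal(tf$k_trans, 0.01, tolerance = 1e-4)
  expect_equal(tf$f0, 0.1, tolerance = 1e-4)
  expect_equal(tf$plateau, 0.9, tolerance = 1e-4)
  expect_gte(tf$plateau, tf$f0)

  flat <- hx_fit_transition(c(10, 100, 1000), rep(0.4, 3))
  expect_false(flat$converged)
  expect_true(is.na(flat$k_trans))
  expect_error(hx_fit_transition(c(1, 2), c(0, 1)), "3 distinct")
})

test_that("the pipeline recovers k_op from noise-free EX1 simulations", {
  pep <- hx_peptide("YASPSM", 297, 302, 1)
  cfg <- hx_sim_config(list(pep), timepoints = c(10, 30, 100, 300, 1000),
                       conditions = list(u = hx_regime_params(0.005, 0.05, 5)),
                       replicates = 1, back_exchange = 0,
                       noise_sd_rel = 0, noise_sd_abs = 0)
  ds <- hx_simulate_dataset(cfg)
  res <- hx_ktrans_pipeline(ds, list(pep))
  expect_equal(res$transitions$k_trans, 0.005, tolerance = 0.1)
  expect_true(all(res$transitions$plateau >= res$transitions$f0))
})

test_that("k_trans group comparison reports means, differences and ordering", {
  cmp <- hx_compare_ktrans(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_equal(cmp$summary$mean, c(1, 2))
  expect_equal(cmp$summary$sd, c(0, 0))
  expect_equal(abs(cmp$pairwise$difference), 1)

  same <- hx_compare_ktrans(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$pairwise$difference, 0)

  expect_warning(cmp2 <- hx_compare_ktrans(list(a = 1, b = c(1, 2), c = c(2, 3))),
                 "n < 2")
  expect_identical(sort(cmp2$summary$group), c("b", "c"))

  # three simulated conditions: fitted means ordered as generating k_op
  ks <- c(0.002, 0.004, 0.008)
  t <- c(10, 30, 100, 300, 1000)
  groups <- lapply(ks, function(k) {
    vapply(1:3, function(i) {
      y <- 0.05 + 0.9 * (1 - exp(-k * t))
      hx_fit_transition(t, y)$k_trans
    }, numeric(1))
  })
  names(groups) <- paste0("g", ks)
  cmp3 <- hx_compare_ktrans(groups)
  expect_true(all(diff(cmp3$summary$mean[match(paste0("g", ks),
                                               cmp3$summary$group)]) > 0))
})
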