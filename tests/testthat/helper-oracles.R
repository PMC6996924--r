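# Independent oracles and fixture builders shared across tests.

peptide_fixture_path <- function() {
  system.file("extdata", "ire1ld_peptides.csv", package = "hxtools")
}

# Brute-force isotope distribution by exhaustive enumeration over all
# isotopologue combinations of a small molecule. `composition` is a named
# count vector over C,H,N,O,S; returns abundances by extra-neutron count.
enumerate_isotopologues <- function(composition) {
  abund <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
  atoms <- unlist(mapply(function(el, n) rep(el, n),
                         names(composition), composition))
  choices <- lapply(atoms, function(el) seq_along(abund[[el]]) - 1L)
  grid <- do.call(expand.grid, choices)
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(mapply(function(el, k) abund[[el]][k + 1L], atoms,
                as.numeric(grid[i, ])))
  }, numeric(1))
  shifts <- rowSums(grid)
  out <- tapply(probs, shifts, sum)
  as.numeric(out[order(as.numeric(names(out)))])
}

# Per-residue boolean brute-force coverage
coverage_bruteforce <- function(starts, ends, span_start, span_end) {
  hit <- vapply(span_start:span_end, function(r) {
    any(starts <= r & r <= ends)
  }, logical(1))
  mean(hit)
}

# RK4 integration of the three-state exchange scheme F <-> U -> exchanged
exchange_rk4 <- function(k_op, k_cl, k_ch, t_end, n_steps = 20000) {
  h <- t_end / n_steps
  state <- c(F = 1, U = 0)
  deriv <- function(s) {
    c(-k_op * s[1] + k_cl * s[2],
      k_op * s[1] - (k_cl + k_ch) * s[2])
  }
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  1 - sum(state)
}

gauss_dens <- function(x, mu, sigma) {
  exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
}

# Two-stage grid search + local polish oracle for the two-Gaussian fit:
# dense grid over (mu1, mu2, sigma) inside the same box constraints with
# the areas solved linearly, then Nelder-Mead polish. Independent of the
# package's Levenberg-Marquardt route.
oracle_bimodal_rss <- function(peaks, init, mu_window = 2,
                               sigma_range = c(0.3, 5), n_mu = 25, n_sigma = 18) {
  x <- peaks$mz
  y <- peaks$intensity
  mu1s <- seq(init$mu1 - mu_window, init$mu1 + mu_window, length.out = n_mu)
  mu2s <- seq(init$mu2 - mu_window, init$mu2 + mu_window, length.out = n_mu)
  sigmas <- seq(init$sigma * sigma_range[1], init$sigma * sigma_range[2],
                length.out = n_sigma)
  solve_areas <- function(m1, m2, s) {
    X <- cbind(gauss_dens(x, m1, s), gauss_dens(x, m2, s))
    A <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
    if (anyNA(A)) return(NULL)
    A <- pmax(A, 0)
    r <- sum((X %*% A - y)^2)
    list(A = A, rss = r)
  }
  best <- list(rss = Inf)
  for (m1 in mu1s) for (m2 in mu2s) for (s in sigmas) {
    sol <- solve_areas(m1, m2, s)
    if (!is.null(sol) && sol$rss < best$rss) {
      best <- list(rss = sol$rss, par = c(sol$A, m1, m2, s))
    }
  }
  obj <- function(p) {
    p <- pmin(pmax(p, c(0, 0, init$mu1 - mu_window, init$mu2 - mu_window,
                        init$sigma * sigma_range[1])),
              c(Inf, Inf, init$mu1 + mu_window, init$mu2 + mu_window,
                init$sigma * sigma_range[2]))
    sum((p[1] * gauss_dens(x, p[3], p[5]) + p[2] * gauss_dens(x, p[4], p[5]) - y)^2)
  }
  pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  min(best$rss, pol$value)
}

# Grid search + polish oracle for the Hill fit: (K, h) grid with the linear
# parameters (r_free, amplitude) solved by least squares.
oracle_hill <- function(conc, r, K_range, h_range, n = 60) {
  Ks <- exp(seq(log(K_range[1]), log(K_range[2]), length.out = n))
  hs <- seq(h_range[1], h_range[2], length.out = n)
  rss_for <- function(K, h) {
    s <- conc^h / (conc^h + K^h)
    f <- stats::lm.fit(cbind(1, s), r)
    sum(f$residuals^2)
  }
  best <- list(rss = Inf)
  for (K in Ks) for (h in hs) {
    rv <- rss_for(K, h)
    if (rv < best$rss) best <- list(rss = rv, K = K, h = h)
  }
  pol <- stats::optim(c(best$K, best$h),
                      function(p) if (any(p <= 0)) Inf else rss_for(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(rss = min(best$rss, pol$value),
       K = if (pol$value < best$rss) pol$par[1] else best$K,
       h = if (pol$value < best$rss) pol$par[2] else best$h)
}

# Grid search + polish oracle for the two-phase dissociation at fixed y0 = 1
oracle_dissociation <- function(t, y, n = 25) {
  ps <- seq(0, 1, length.out = n)
  kfs <- exp(seq(log(1e-4), log(1), length.out = n))
  kss <- exp(seq(log(1e-5), log(0.1), length.out = n))
  rss_for <- function(p, kf, ks) {
    sum((p * exp(-kf * t) + (1 - p) * exp(-ks * t) - y)^2)
  }
  best <- list(rss = Inf)
  for (p in ps) for (kf in kfs) for (ks in kss) {
    if (kf < ks) next
    rv <- rss_for(p, kf, ks)
    if (rv < best$rss) best <- list(rss = rv, par = c(p, kf, ks))
  }
  pol <- stats::optim(best$par, function(q) {
    if (q[1] < 0 || q[1] > 1 || any(q[2:3] <= 0)) return(Inf)
    rss_for(q[1], q[2], q[3])
  }, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
  par <- if (pol$value < best$rss) pol$par else best$par
  list(rss = min(best$rss, pol$value), p = par[1],
       k_fast = max(par[2], par[3]), k_slow = min(par[2], par[3]))
}

# Noise-free EX1 cluster plus peak lists and fit initialiser for a peptide
make_ex1_setup <- function(sequence, start_res, end_res, charge,
                           k_op = 0.005, n_peaks = 8L) {
  pep <- hx_peptide(sequence, start_res, end_res, charge)
  par <- hx_regime_params(k_op, k_op * 10, k_op * 1000) # EX1: k_cl << k_ch
  env <- hx_isotope_envelope(sequence, charge, n_peaks)
  n_ex <- hx_exchangeable_amides(sequence)
  unex <- hxtools:::.cross_envelope(env, 1, charge)
  fd <- hxtools:::.cross_envelope(env, stats::dbinom(0:n_ex, n_ex, 1), charge)
  init <- hx_bimodal_init(hx_peak_maxima(unex, charge),
                          hx_peak_maxima(fd, charge))
  list(pep = pep, par = par, env = env, n_ex = n_ex,
       unex = unex, fd = fd, init = init)
}
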