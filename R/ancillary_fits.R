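# Ancillary biophysical fits: anisotropy + Hill binding, one-phase
# association with initial velocity, two-phase dissociation, DSF melting
# temperature.

#' Fluorescence anisotropy
#'
#' `A = (I_para - I_perp) / (I_para + 2 I_perp)`. Scale-invariant in the
#' intensities.
#'
#' @param I_para,I_perp Parallel and perpendicular fluorescence intensities.
#' @return Anisotropy (dimensionless), vectorised.
#' @export
hx_anisotropy <- function(I_para, I_perp) {
  den <- I_para + 2 * I_perp
  if (any(den <= 0)) stop("I_para + 2*I_perp must be > 0", call. = FALSE)
  (I_para - I_perp) / den
}

#' Hill fit of an anisotropy titration
#'
#' Least-squares fit of
#' `r(X) = r_free + (r_max - r_free) X^h / (X^h + K^h)` with minimal
#' constraints (K > 0, h > 0, r_max > r_free). `K` is the half-maximal
#' concentration K_1/2max; note that because the model ignores competing
#' dimer/oligomer equilibria of the binding partner, K_1/2max does not
#' reflect the dissociation constant — it is an operational half-saturation
#' point only.
#'
#' @param conc Positive concentrations (same unit as the returned `K`).
#' @param r Measured anisotropy values.
#' @return An `hx_hill_fit`: list with `r_free`, `r_max`, `K`, `h`, `rss`,
#'   `r_squared`, `converged`.
#' @export
hx_fit_hill <- function(conc, r) {
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(conc) < 5) stop("need >= 5 concentrations spanning K", call. = FALSE)
  model <- function(p, x) {
    p[["r_free"]] + p[["dr"]] * x^p[["h"]] / (x^p[["h"]] + p[["K"]]^p[["h"]])
  }
  par0 <- c(r_free = min(r), dr = max(1e-6, diff(range(r))),
            K = stats::median(conc), h = 1)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = c(-Inf, 1e-12, 1e-12, 1e-12),
    upper = c(Inf, Inf, Inf, Inf),
    fn = function(p) model(p, conc) - r,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 1024))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  structure(list(r_free = p[["r_free"]], r_max = p[["r_free"]] + p[["dr"]],
                 K = p[["K"]], h = p[["h"]], rss = rss,
                 r_squared = 1 - rss / sum((r - mean(r))^2),
                 converged = fit$info %in% 1:3),
            class = "hx_hill_fit")
}

#' One-phase association fit with initial velocity
#'
#' Fits `y(t) = y0 + (plateau - y0)(1 - exp(-k t))` and reports the initial
#' velocity, the slope of the fitted curve at time zero:
#' `initial_velocity = k (plateau - y0)`.
#'
#' @param t Times in seconds (>= 4 points).
#' @param y Signal.
#' @return An `hx_association_fit`: list with `k`, `y0`, `plateau`,
#'   `initial_velocity`, `rss`, `converged`. A trace whose fitted plateau
#'   falls below y0 (monotone-decreasing data) is reported with
#'   `converged = FALSE`.
#' @export
hx_fit_association <- function(t, y) {
  if (length(t) < 4) stop("need >= 4 points", call. = FALSE)
  span <- diff(range(t))
  par0 <- c(y0 = y[which.min(t)], plateau = y[which.max(t)],
            k = log(2) / max(span / 4, 1e-9))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = c(-Inf, -Inf, 1e-12), upper = c(Inf, Inf, Inf),
    fn = function(p) p[["y0"]] + (p[["plateau"]] - p[["y0"]]) *
      (1 - exp(-p[["k"]] * t)) - y,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 1024))
  p <- fit$par
  structure(list(k = p[["k"]], y0 = p[["y0"]], plateau = p[["plateau"]],
                 initial_velocity = p[["k"]] * (p[["plateau"]] - p[["y0"]]),
                 rss = sum(fit$fvec^2),
                 converged = fit$info %in% 1:3 && p[["plateau"]] >= p[["y0"]]),
            class = "hx_association_fit")
}

#' Two-phase dissociation fit
#'
#' Fits `y(t) = y0 (p exp(-k_fast t) + (1 - p) exp(-k_slow t))` to a
#' dissociation trace normalised so dissociation starts at t = 0 (the trace
#' is divided by its value at the first timepoint). Label switching is
#' resolved by enforcing `k_fast >= k_slow`. By default the plateau is
#' fixed at zero (traces decay toward baseline); `free_plateau = TRUE` adds
#' a fitted offset.
#'
#' @param t Times in seconds (>= 6 points).
#' @param y Signal; must be overall decaying.
#' @param free_plateau Fit an additive plateau term.
#' @return An `hx_dissociation_fit`: list with `y0`, `p`, `k_fast`,
#'   `k_slow`, `plateau`, `rss`, `converged`.
#' @export
hx_fit_dissociation <- function(t, y, free_plateau = FALSE) {
  if (length(t) < 6) stop("need >= 6 points", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (y[length(y)] > y[1]) stop("rising trace: not a dissociation", call. = FALSE)
  ynorm <- y / y[1]
  span <- diff(range(t))
  par0 <- c(y0 = 1, p = 0.5, k_fast = 5 * log(2) / span, k_slow = log(2) / span,
            plateau = 0)
  lower <- c(0, 0, 1e-12, 1e-12, if (free_plateau) -Inf else 0)
  upper <- c(Inf, 1, Inf, Inf, if (free_plateau) Inf else 0)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(pp) pp[["y0"]] * (pp[["p"]] * exp(-pp[["k_fast"]] * t) +
      (1 - pp[["p"]]) * exp(-pp[["k_slow"]] * t)) + pp[["plateau"]] - ynorm,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 1024))
  pp <- fit$par
  if (pp[["k_fast"]] < pp[["k_slow"]]) {
    kf <- pp[["k_slow"]]; pp[["k_slow"]] <- pp[["k_fast"]]; pp[["k_fast"]] <- kf
    pp[["p"]] <- 1 - pp[["p"]]
  }
  structure(list(y0 = pp[["y0"]], p = pp[["p"]], k_fast = pp[["k_fast"]],
                 k_slow = pp[["k_slow"]], plateau = pp[["plateau"]],
                 rss = sum(fit$fvec^2), converged = fit$info %in% 1:3),
            class = "hx_dissociation_fit")
}

#' Melting temperature from a DSF melt curve
#'
#' Smooths the fluorescence with a Savitzky-Golay filter (moving polynomial,
#' default window 5, order 2), differentiates by central differences, and
#' calls Tm at the global minimum of the negative first derivative
#' (-dF/dT), refined by quadratic interpolation around the grid minimum.
#' A raw-data derivative without smoothing would be unusable on noisy
#' curves. Curves with no interior extremum are rejected ("no transition").
#'
#' @param temperature Monotone increasing temperature grid (>= 20 points).
#' @param fluorescence Fluorescence signal.
#' @param window Odd smoothing window length in points.
#' @param order Polynomial order of the smoother.
#' @return An `hx_melt_fit`: list with `Tm` (same unit as the input grid)
#'   and `curve_deriv` (data.frame `temperature`, `neg_dFdT` used for the
#'   call).
#' @export
hx_dsf_tm <- function(temperature, fluorescence, window = 5L, order = 2L) {
  if (length(temperature) < 20) stop("need >= 20 temperature points", call. = FALSE)
  if (any(diff(temperature) <= 0)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  sm <- signal::sgolayfilt(fluorescence, p = order, n = window)
  n <- length(sm)
  h <- diff(temperature)
  # central differences on the interior points
  deriv <- (sm[3:n] - sm[1:(n - 2)]) / (temperature[3:n] - temperature[1:(n - 2)])
  tt <- temperature[2:(n - 1)]
  neg <- -deriv
  i <- which.min(neg)
  flat <- diff(range(neg)) <= 1e-10 * max(abs(neg), 1)
  if (flat || i == 1 || i == length(neg)) {
    stop("no interior transition in the melt curve", call. = FALSE)
  }
  # quadratic refinement around the grid minimum
  xs <- tt[(i - 1):(i + 1)]
  ys <- neg[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  tm <- if (co[[3]] > 0) -co[[2]] / (2 * co[[3]]) else tt[i]
  if (tm < min(xs) || tm > max(xs)) tm <- tt[i]
  structure(list(Tm = tm,
                 curve_deriv = data.frame(temperature = tt, neg_dFdT = neg)),
            class = "hx_melt_fit")
}
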