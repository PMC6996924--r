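# Bimodal (EX1) isotope-cluster deconvolution: peak-maximum extraction,
# global two-Gaussian fitting, per-peak subpopulation fractions,
# fraction-high time courses and transition-rate (k_trans) extraction.

.gauss <- function(x, mu, sigma) {
  exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
}

#' Extract isotope peak maxima from a cluster
#'
#' Produces the peak-maximum versus m/z list that the two-Gaussian model is
#' fitted to. Dense profile input (many points at sub-isotope spacing) is
#' reduced to local maxima first; peak-list input is validated. Peaks are
#' then snapped to the isotope grid anchored at the most intense peak
#' (spacing 1.00335/z): near-degenerate entries on the same grid position
#' are merged (intensity-weighted position, summed intensity) and peaks
#' further than `tol_frac` of a spacing from the grid are flagged as
#' spurious and excluded.
#'
#' @param cluster data.frame with columns `mz`, `intensity`.
#' @param charge Charge state (used for the expected spacing).
#' @param tol_frac Grid tolerance as a fraction of the spacing.
#' @return An `hx_peaklist`: data.frame `mz`, `intensity` ordered by m/z,
#'   with attributes `spacing`, `grid_index` and `flagged` (the excluded
#'   off-grid peaks, possibly empty).
#' @export
hx_peak_maxima <- function(cluster, charge, tol_frac = 0.2) {
  if (nrow(cluster) == 0) stop("cluster is empty", call. = FALSE)
  if (any(!is.finite(cluster$intensity))) {
    stop("non-finite intensities", call. = FALSE)
  }
  s <- hx_constants[["c13_shift"]] / charge
  d <- cluster[order(cluster$mz), , drop = FALSE]
  gaps <- diff(d$mz)
  if (nrow(d) >= 50 && length(gaps) && stats::median(gaps) < 0.3 * s) {
    # dense profile: keep strict local maxima
    y <- d$intensity
    i <- which(diff(sign(diff(y))) == -2) + 1L
    d <- d[i, , drop = FALSE]
  }
  anchor <- d$mz[which.max(d$intensity)]
  k <- round((d$mz - anchor) / s)
  resid <- d$mz - (anchor + k * s)
  off <- abs(resid) > tol_frac * s
  flagged <- d[off, , drop = FALSE]
  d <- d[!off, , drop = FALSE]
  k <- k[!off]
  mz <- vapply(split(seq_len(nrow(d)), k), function(i) {
    stats::weighted.mean(d$mz[i], d$intensity[i])
  }, numeric(1))
  intensity <- vapply(split(d$intensity, k), sum, numeric(1))
  out <- data.frame(mz = unname(mz), intensity = unname(intensity))
  ord <- order(out$mz)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 4) {
    stop(sprintf("only %d isotope peaks: too few for bimodal analysis", nrow(out)),
         call. = FALSE)
  }
  structure(out, class = c("hx_peaklist", "data.frame"), spacing = s,
            grid_index = sort(unique(k)), flagged = flagged)
}

#' Classify an isotope cluster as unimodal or bimodal
#'
#' Valley test on the grid-merged peak list: the cluster is called bimodal
#' when some interior grid position (including gaps, counted as zero
#' intensity) dips below `valley_frac` times the smaller of the flanking
#' maxima. Noise-free unimodal envelopes never trigger this; EX1 mixtures
#' with separated subpopulations always do.
#'
#' @param peaks An [hx_peak_maxima()] output.
#' @param valley_frac Depth a valley must reach, as a fraction of the
#'   smaller flanking maximum.
#' @return `"bimodal"` or `"unimodal"`.
#' @export
hx_classify_modality <- function(peaks, valley_frac = 0.5) {
  k <- attr(peaks, "grid_index")
  full <- seq(min(k), max(k))
  v <- numeric(length(full))
  v[match(k, full)] <- peaks$intensity
  n <- length(v)
  if (n < 3) return("unimodal")
  for (m in 2:(n - 1)) {
    flank <- min(max(v[1:(m - 1)]), max(v[(m + 1):n]))
    if (v[m] < valley_frac * flank) return("bimodal")
  }
  "unimodal"
}

#' Initialise the two-Gaussian fit from control samples
#'
#' The unexchanged and fully deuterated controls pin the two modes: mu1 from
#' the unexchanged-control centroid, mu2 from the fully-deuterated-control
#' centroid, sigma from the intensity-weighted width of the unexchanged
#' control.
#'
#' @param unexchanged,fully_deuterated data.frames (`mz`, `intensity`) of
#'   the two control clusters.
#' @return List with `mu1`, `mu2`, `sigma`.
#' @export
hx_bimodal_init <- function(unexchanged, fully_deuterated) {
  mu1 <- hx_centroid(unexchanged)
  mu2 <- hx_centroid(fully_deuterated)
  w <- unexchanged$intensity
  sigma <- sqrt(sum(w * (unexchanged$mz - mu1)^2) / sum(w))
  if (!(sigma > 0)) sigma <- 0.1
  list(mu1 = mu1, mu2 = mu2, sigma = sigma)
}

#' Global two-Gaussian fit of an isotope cluster
#'
#' Least-squares fit of
#' `I(mu) = A1/(sigma sqrt(2 pi)) exp(-((mu - mu1)/sigma)^2 / 2) +
#'          A2/(sigma sqrt(2 pi)) exp(-((mu - mu2)/sigma)^2 / 2)`
#' to the isotope peak maxima of one cluster, with a shared sigma and the
#' two means fitted globally across all peaks of the timepoint; replicates
#' are fitted separately. Bounds prevent label switching and mode collapse:
#' each mean is constrained to `mu_window` Th of its control-derived
#' initialiser and sigma to `sigma_range` times its initialiser. A stalled
#' optimiser returns `converged = FALSE` rather than throwing.
#'
#' @param peaks An [hx_peak_maxima()] output (or data.frame `mz`,
#'   `intensity` with at least 5 rows).
#' @param init List with `mu1`, `mu2`, `sigma` (see [hx_bimodal_init()]).
#' @param mu_window Half-width (Th) of the box around each initial mean.
#' @param sigma_range Length-2 multiplier range for sigma.
#' @param ftol,ptol Convergence tolerances on cost and parameters.
#' @param maxiter Maximum optimiser iterations.
#' @return An `hx_bimodal_fit`: list with areas `A1`, `A2`, means `mu1 <=
#'   mu2`, `sigma`, aggregate `fraction_high = A2/(A1+A2)`, the
#'   intensity-weighted per-peak aggregate `fraction_high_weighted`,
#'   `per_peak_fraction_high`, `rss`, `converged`, `unimodal` (fit
#'   degeneracy: minor area < 1% of total or mean separation below one peak
#'   spacing) and `modality` from the valley test where available.
#' @export
hx_fit_bimodal <- function(peaks, init, mu_window = 2,
                           sigma_range = c(0.3, 5),
                           ftol = 1e-8, ptol = 1e-8, maxiter = 1024L) {
  if (any(!is.finite(peaks$intensity)) || any(!is.finite(peaks$mz))) {
    stop("non-finite peak data", call. = FALSE)
  }
  if (nrow(peaks) < 5) {
    stop("two-Gaussian fit needs at least 5 peak points; route this cluster to unimodal analysis",
         call. = FALSE)
  }
  if (!(init$mu1 < init$mu2)) stop("init must satisfy mu1 < mu2", call. = FALSE)
  x <- peaks$mz
  y <- peaks$intensity
  spacing <- attr(peaks, "spacing")
  if (is.null(spacing)) spacing <- stats::median(diff(sort(x)))
  area0 <- sum(y) * spacing / 2
  par0 <- c(A1 = area0, A2 = area0, mu1 = init$mu1, mu2 = init$mu2,
            sigma = init$sigma)
  lower <- c(0, 0, init$mu1 - mu_window, init$mu2 - mu_window,
             init$sigma * sigma_range[1])
  upper <- c(Inf, Inf, init$mu1 + mu_window, init$mu2 + mu_window,
             init$sigma * sigma_range[2])
  resid_fn <- function(p) {
    p["A1"] * .gauss(x, p["mu1"], p["sigma"]) +
      p["A2"] * .gauss(x, p["mu2"], p["sigma"]) - y
  }
  # deterministic multi-start: area splits and sigma scalings guard against
  # local minima of the shared-sigma objective
  starts <- list(par0,
                 replace(par0, c("A1", "A2"), c(1.6 * area0, 0.4 * area0)),
                 replace(par0, c("A1", "A2"), c(0.4 * area0, 1.6 * area0)),
                 replace(par0, "sigma", min(upper[5], 2 * init$sigma)))
  fit <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                               fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 ftol = ftol, ptol = ptol, maxiter = maxiter))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  p <- fit$par
  if (p[["mu1"]] > p[["mu2"]]) {
    p[c("mu1", "mu2")] <- p[c("mu2", "mu1")]
    p[c("A1", "A2")] <- p[c("A2", "A1")]
  }
  total <- p[["A1"]] + p[["A2"]]
  res <- structure(list(
    A1 = p[["A1"]], A2 = p[["A2"]], mu1 = p[["mu1"]], mu2 = p[["mu2"]],
    sigma = p[["sigma"]],
    fraction_high = if (total > 0) p[["A2"]] / total else NA_real_,
    rss = sum(fit$fvec^2),
    converged = fit$info %in% 1:3,
    unimodal = (total > 0 && min(p[["A1"]], p[["A2"]]) < 0.01 * total) ||
      (p[["mu2"]] - p[["mu1"]]) < spacing,
    spacing = spacing, n_peaks = length(x)
  ), class = "hx_bimodal_fit")
  res$per_peak_fraction_high <- hx_per_peak_fractions(res, peaks)
  w_ok <- !is.na(res$per_peak_fraction_high)
  res$fraction_high_weighted <- if (any(w_ok)) {
    sum(y[w_ok] * res$per_peak_fraction_high[w_ok]) / sum(y[w_ok])
  } else NA_real_
  res$modality <- if (inherits(peaks, "hx_peaklist")) {
    hx_classify_modality(peaks)
  } else NA_character_
  res
}

#' @export
print.hx_bimodal_fit <- function(x, ...) {
  cat(sprintf("<hx_bimodal_fit> mu1=%.3f mu2=%.3f sigma=%.3f fraction_high=%.3f%s%s\n",
              x$mu1, x$mu2, x$sigma, x$fraction_high,
              if (isTRUE(x$unimodal)) " [degenerate/unimodal]" else "",
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Per-peak subpopulation fractions
#'
#' At each isotope peak position mu, the proportion of intensity assigned to
#' the high-mass subpopulation:
#' `f_high(mu) = A2 G(mu; mu2, sigma) / (A1 G(mu; mu1, sigma) + A2 G(mu; mu2, sigma))`.
#' Positions where both component densities fall below the machine floor
#' yield `NA` (fraction undefined there).
#'
#' @param fit An `hx_bimodal_fit`.
#' @param peaks Peak list whose `mz` positions are evaluated.
#' @return Numeric vector of fractions in \[0, 1\] (or `NA`).
#' @export
hx_per_peak_fractions <- function(fit, peaks) {
  if (!isTRUE(fit$converged)) {
    warning("per-peak fractions from a non-converged fit")
  }
  lo <- fit$A1 * .gauss(peaks$mz, fit$mu1, fit$sigma)
  hi <- fit$A2 * .gauss(peaks$mz, fit$mu2, fit$sigma)
  tot <- lo + hi
  out <- ifelse(tot > .Machine$double.xmin, hi / tot, NA_real_)
  as.numeric(out)
}

#' One-phase association fit of a fraction-high time course
#'
#' Fits `fraction_high(t) = f0 + (plateau - f0) (1 - exp(-k_trans t))` by
#' bounded least squares. Because samples can enter D2O already partially
#' converted (e.g. pre-incubated with chaperones), `f0` is a free parameter,
#' never pinned to 0. The plateau is parameterised as `f0 + d` with `d >= 0`
#' so the fit respects the quasi-irreversibility of hydrogen exchange
#' (plateau never below f0). A flat series is reported as non-identifiable
#' (`converged = FALSE`, `k_trans = NA`).
#'
#' @param t Times in seconds (>= 3 distinct values).
#' @param fraction_high Fraction-high observations in \[0, 1\].
#' @return An `hx_transition_fit`: list with `k_trans`, `f0`, `plateau`,
#'   `rss`, `converged`.
#' @export
hx_fit_transition <- function(t, fraction_high) {
  if (length(unique(t)) < 3) stop("need >= 3 distinct timepoints", call. = FALSE)
  y <- fraction_high
  if (stats::sd(y) < 1e-10) {
    return(structure(list(k_trans = NA_real_, f0 = mean(y), plateau = mean(y),
                          rss = sum((y - mean(y))^2), converged = FALSE),
                     class = "hx_transition_fit"))
  }
  f0_init <- max(0, min(1, y[which.min(t)]))
  d_init <- max(1e-3, min(1, max(y) - f0_init))
  k_init <- log(2) / max(stats::median(t), 1e-6)
  resid_fn <- function(p) {
    p[["f0"]] + p[["d"]] * (1 - exp(-p[["k"]] * t)) - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(f0 = f0_init, d = d_init, k = k_init),
    lower = c(0, 0, 1e-9), upper = c(1, 1, Inf), fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 1024))
  p <- fit$par
  structure(list(k_trans = p[["k"]], f0 = p[["f0"]],
                 plateau = p[["f0"]] + p[["d"]],
                 rss = sum(fit$fvec^2), converged = fit$info %in% 1:3),
            class = "hx_transition_fit")
}

#' @export
print.hx_transition_fit <- function(x, ...) {
  cat(sprintf("<hx_transition_fit> k_trans=%.4g 1/s  f0=%.3f  plateau=%.3f%s\n",
              x$k_trans, x$f0, x$plateau,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Compare k_trans between condition groups
#'
#' Per-group mean and sample standard deviation plus pairwise mean
#' differences with a plain two-sample (Welch) comparison. Groups with
#' fewer than two values are excluded with a warning.
#'
#' @param groups Named list of numeric k_trans vectors.
#' @return List with `summary` (group, mean, sd, n) and `pairwise` (group_A,
#'   group_B, difference, p_value).
#' @export
hx_compare_ktrans <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    groups <- groups[setdiff(names(groups), small)]
  }
  if (length(groups) < 2) stop("fewer than 2 usable groups", call. = FALSE)
  summ <- data.frame(
    group = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    n = vapply(groups, length, integer(1)),
    row.names = NULL
  )
  combs <- utils::combn(names(groups), 2)
  pw <- apply(combs, 2, function(g) {
    a <- groups[[g[1]]]; b <- groups[[g[2]]]
    pv <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
    data.frame(group_A = g[1], group_B = g[2],
               difference = mean(a) - mean(b), p_value = pv)
  })
  list(summary = summ, pairwise = do.call(rbind, pw))
}

#' Fraction-high time course for one peptide and condition
#'
#' Runs the bimodal stage of the pipeline for every replicate and timepoint
#' of one peptide under one condition: peak-maximum extraction, modality
#' classification, two-Gaussian fit initialised from that peptide's
#' controls, and both aggregate fraction-high definitions.
#'
#' @param dataset Long-format dataset (see [hx_simulate_dataset()]).
#' @param peptide The [hx_peptide()] analysed.
#' @param condition Condition name in the dataset.
#' @return data.frame with one row per replicate/timepoint: `fraction_high`,
#'   `fraction_high_weighted`, `mu1`, `mu2`, `sigma`, `A1`, `A2`, `rss`,
#'   `converged`, `unimodal`, `modality`.
#' @export
hx_fraction_high_course <- function(dataset, peptide, condition) {
  pid <- peptide$id
  z <- peptide$charge
  ctrl <- dataset[dataset$peptide_id == pid & dataset$time_s < 0, ]
  if (!nrow(ctrl)) stop("no controls for peptide ", pid, call. = FALSE)
  unex <- hx_peak_maxima(ctrl[ctrl$time_s == -1, c("mz", "intensity")], z)
  fd <- hx_peak_maxima(ctrl[ctrl$time_s == -2, c("mz", "intensity")], z)
  init <- hx_bimodal_init(unex, fd)
  d <- dataset[dataset$peptide_id == pid & dataset$condition == condition &
                 dataset$time_s >= 0, ]
  if (!nrow(d)) stop("no samples for peptide ", pid, " in condition ", condition,
                     call. = FALSE)
  key <- interaction(d$replicate, d$time_s, drop = TRUE)
  rows <- lapply(split(d, key), function(s) {
    pk <- hx_peak_maxima(s[, c("mz", "intensity")], z)
    fit <- hx_fit_bimodal(pk, init)
    data.frame(peptide_id = pid, condition = condition,
               replicate = s$replicate[1], time_s = s$time_s[1],
               A1 = fit$A1, A2 = fit$A2, mu1 = fit$mu1, mu2 = fit$mu2,
               sigma = fit$sigma, fraction_high = fit$fraction_high,
               fraction_high_weighted = fit$fraction_high_weighted,
               rss = fit$rss, converged = fit$converged,
               unimodal = fit$unimodal, modality = fit$modality)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$replicate, res$time_s), ]
  rownames(res) <- NULL
  res
}

#' Full k_trans extraction pipeline
#'
#' For each peptide and condition: fraction-high time course per replicate
#' (replicates treated independently), then a one-phase association fit per
#' replicate giving k_trans.
#'
#' @param dataset Long-format dataset with controls.
#' @param peptides List of [hx_peptide()] objects to analyse.
#' @param conditions Condition names; defaults to all non-control conditions
#'   present.
#' @return List with `courses` (row-bound fraction-high tables) and
#'   `transitions` (peptide_id, condition, replicate, k_trans, f0, plateau,
#'   rss, converged).
#' @export
hx_ktrans_pipeline <- function(dataset, peptides, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- setdiff(unique(dataset$condition), "control")
  }
  courses <- list()
  trans <- list()
  for (pep in peptides) {
    for (cond in conditions) {
      fc <- hx_fraction_high_course(dataset, pep, cond)
      courses[[length(courses) + 1L]] <- fc
      for (r in unique(fc$replicate)) {
        s <- fc[fc$replicate == r, ]
        tf <- hx_fit_transition(s$time_s, s$fraction_high)
        trans[[length(trans) + 1L]] <- data.frame(
          peptide_id = pep$id, condition = cond, replicate = r,
          k_trans = tf$k_trans, f0 = tf$f0, plateau = tf$plateau,
          rss = tf$rss, converged = tf$converged)
      }
    }
  }
  list(courses = do.call(rbind, courses),
       transitions = do.call(rbind, trans))
}
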