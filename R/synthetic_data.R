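# Synthetic-data generator: isotope clusters under EX1/EX2 exchange kinetics
# with back-exchange and noise, plus FRET/BLI/DSF/anisotropy traces with
# known ground truth.

#' Exchange-regime kinetic parameters
#'
#' Houses the rates of the structural opening/closing equilibrium and the
#' intrinsic chemical exchange step: a backbone amide exchanges only after a
#' structure-specific H-bond opens (folded F to unfolded U, opening rate
#' `k_op`, closing rate `k_cl`) and then reacts chemically at `k_ch`. In the
#' EX1 limit (`k_cl` << `k_ch`) every opening event exchanges all amides of
#' the element at once, so the observed rate approximates `k_op` and spectra
#' are bimodal; in the EX2 limit (`k_cl` >> `k_ch`) exchange is gradual and
#' unimodal with per-amide rate (k_op/k_cl)*k_ch.
#'
#' @param k_op,k_cl,k_ch Positive rates in 1/s.
#' @return An object of class `hx_regime` with a derived `regime` label
#'   (`"EX1"` when k_cl/k_ch <= 0.1, `"EX2"` when >= 10, else `"mixed"`).
#' @export
hx_regime_params <- function(k_op, k_cl, k_ch) {
  if (any(c(k_op, k_cl, k_ch) <= 0)) stop("all rates must be > 0", call. = FALSE)
  ratio <- k_cl / k_ch
  regime <- if (ratio <= 0.1) "EX1" else if (ratio >= 10) "EX2" else "mixed"
  structure(list(k_op = k_op, k_cl = k_cl, k_ch = k_ch, regime = regime),
            class = "hx_regime")
}

#' Fraction of molecules that have opened (EX1 limit)
#'
#' In the EX1 limit every opening event leads to complete exchange of the
#' structural element, so the exchanged ("high-mass") fraction follows the
#' first-order opening kinetics 1 - exp(-k_op * t).
#'
#' @param params An [hx_regime_params()] object.
#' @param t Time(s) in seconds, >= 0.
#' @return Probability in \[0, 1\], vectorised over `t`.
#' @seealso [hx_exchanged_fraction_exact()] for the general closed form of
#'   the three-state scheme.
#' @export
hx_fraction_opened <- function(params, t) {
  stopifnot(inherits(params, "hx_regime"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 - exp(-params$k_op * t)
}

#' Exact exchanged fraction of the three-state scheme
#'
#' Closed-form solution of F <-> U -> exchanged, starting folded: the
#' exchanged fraction at time t for opening rate `k_op`, closing rate
#' `k_cl` and chemical rate `k_ch`. Reduces to `1 - exp(-k_op t)` in the
#' EX1 limit and to per-amide rate (k_op/k_cl) k_ch in the EX2 limit.
#'
#' @param k_op,k_cl,k_ch Positive rates (1/s).
#' @param t Time(s) in seconds.
#' @return Exchanged fraction in \[0, 1\].
#' @export
hx_exchanged_fraction_exact <- function(k_op, k_cl, k_ch, t) {
  s <- k_op + k_cl + k_ch
  disc <- sqrt(s^2 - 4 * k_op * k_ch)
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  pre <- k_ch * k_op / (l1 - l2)
  pmin(1, pmax(0, pre * ((1 - exp(-l2 * t)) / l2 - (1 - exp(-l1 * t)) / l1)))
}

# deterministic substream seed from a base seed and a key string
.substream_seed <- function(seed, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((seed %% 2147483647 + h * 2654435) %% 2147483647)
}

#' Simulate one isotope cluster under EX1 or EX2 kinetics
#'
#' Builds the theoretical natural-abundance envelope of the peptide and
#' evolves it in D2O. Under EX1 kinetics the cluster is a two-component
#' mixture: an undeuterated-like envelope with weight `1 - f(t)` and a
#' near-fully-deuterated envelope with weight `f(t) = 1 - exp(-k_op t)`,
#' whose deuteron count is binomial over the exchangeable amides with
#' per-deuteron survival `1 - back_exchange`. Under EX2 kinetics the cluster
#' is a single envelope with per-amide deuteration probability
#' `(1 - exp(-(k_op/k_cl) k_ch t)) * (1 - back_exchange)`. Mixed-regime
#' parameters use the exact three-state exchanged fraction as the high-mass
#' weight. Deuterons shift mass by 1.006277/z; natural isotope structure
#' keeps its 1.00335/z spacing, so peak positions are exact cross-products
#' of the two ladders. Noise (multiplicative then additive Gaussian) is
#' applied last; with zero noise the output is deterministic.
#'
#' @param peptide An [hx_peptide()] object.
#' @param params An [hx_regime_params()] object.
#' @param t Incubation time in D2O (s), >= 0.
#' @param back_exchange Per-deuteron loss probability in \[0, 1).
#' @param noise_sd_rel,noise_sd_abs Gaussian noise magnitudes
#'   (`I*(1+eps_rel) + eps_abs`); absolute noise is on the scale of total
#'   cluster intensity 1.
#' @param seed Integer seed for the noise draws (ignored at zero noise).
#' @param n_peaks Number of natural-abundance isotope peaks carried.
#' @return An object of class `hx_cluster`: a data.frame with columns `mz`
#'   and `intensity`, with the peptide metadata in attributes.
#' @export
hx_simulate_cluster <- function(peptide, params, t, back_exchange = 0,
                                noise_sd_rel = 0, noise_sd_abs = 0,
                                seed = NULL, n_peaks = 8L) {
  stopifnot(inherits(peptide, "hx_peptide"), inherits(params, "hx_regime"))
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (back_exchange < 0 || back_exchange >= 1) {
    stop("back_exchange must be in [0, 1)", call. = FALSE)
  }
  env <- hx_isotope_envelope(peptide$sequence, peptide$charge, n_peaks)
  n_ex <- hx_exchangeable_amides(peptide$sequence)
  z <- peptide$charge
  if (params$regime == "EX2") {
    k_obs <- (params$k_op / params$k_cl) * params$k_ch
    p <- (1 - exp(-k_obs * t)) * (1 - back_exchange)
    deut <- stats::dbinom(0:n_ex, n_ex, p)
    comp <- .cross_envelope(env, deut, z)
  } else {
    f <- if (params$regime == "EX1") {
      hx_fraction_opened(params, t)
    } else {
      hx_exchanged_fraction_exact(params$k_op, params$k_cl, params$k_ch, t)
    }
    low <- .cross_envelope(env, 1, z)               # undeuterated-like
    deut <- stats::dbinom(0:n_ex, n_ex, 1 - back_exchange)
    high <- .cross_envelope(env, deut, z)           # near-fully-deuterated
    low$intensity <- low$intensity * (1 - f)
    high$intensity <- high$intensity * f
    comp <- rbind(low, high)
  }
  comp <- comp[comp$intensity > 0, , drop = FALSE]
  comp <- comp[order(comp$mz), , drop = FALSE]
  rownames(comp) <- NULL
  if (noise_sd_rel > 0 || noise_sd_abs > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(comp)
    comp$intensity <- comp$intensity * (1 + stats::rnorm(n, 0, noise_sd_rel)) +
      stats::rnorm(n, 0, noise_sd_abs)
  }
  structure(comp, class = c("hx_cluster", "data.frame"),
            peptide_id = peptide$id, charge = z, time_s = t)
}

# cross-product of the natural envelope ladder (spacing c13/z) with a
# deuteron-count distribution (spacing d/z)
.cross_envelope <- function(env, deut_dist, z) {
  i <- seq_along(env$abundances) - 1L
  j <- seq_along(deut_dist) - 1L
  grid <- expand.grid(i = i, j = j)
  mz <- env$monoisotopic_mz +
    (grid$i * hx_constants[["c13_shift"]] + grid$j * hx_constants[["d_shift"]]) / z
  intensity <- env$abundances[grid$i + 1L] * deut_dist[grid$j + 1L]
  data.frame(mz = mz, intensity = intensity)
}

#' Simulation configuration for an HX-MS dataset
#'
#' Bundles the study design: peptides, D2O incubation times, named
#' conditions (each an [hx_regime_params()]), replicates, back-exchange,
#' noise magnitudes and the seed. Defaults emulate the packaged study
#' design: triplicates at 30 and 300 s (plus the t = 0 anchor) with 15%
#' back-exchange.
#'
#' @param peptides List of [hx_peptide()] objects.
#' @param timepoints D2O incubation times in seconds.
#' @param conditions Named list of [hx_regime_params()] objects.
#' @param replicates Number of independent replicates (>= 1).
#' @param back_exchange Per-deuteron loss fraction in \[0, 1).
#' @param noise_sd_rel,noise_sd_abs Noise magnitudes (see
#'   [hx_simulate_cluster()]).
#' @param seed Integer master seed; every random draw in the dataset derives
#'   from it through per-(peptide, condition, replicate) substreams.
#' @return An object of class `hx_sim_config`.
#' @export
hx_sim_config <- function(peptides,
                          timepoints = c(0, 30, 300),
                          conditions = list(
                            untreated = hx_regime_params(0.002, 0.05, 5),
                            treated   = hx_regime_params(0.006, 0.05, 5)
                          ),
                          replicates = 3L,
                          back_exchange = 0.15,
                          noise_sd_rel = 0.02,
                          noise_sd_abs = 0.001,
                          seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (back_exchange < 0 || back_exchange >= 1) {
    stop("back_exchange must be in [0, 1)", call. = FALSE)
  }
  if (any(timepoints < 0)) stop("timepoints must be non-negative", call. = FALSE)
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must be uniquely named", call. = FALSE)
  }
  structure(list(peptides = peptides, timepoints = timepoints,
                 conditions = conditions, replicates = as.integer(replicates),
                 back_exchange = back_exchange, noise_sd_rel = noise_sd_rel,
                 noise_sd_abs = noise_sd_abs, seed = as.integer(seed)),
            class = "hx_sim_config")
}

#' Simulate a full HX-MS dataset with controls
#'
#' Emits one isotope cluster per peptide/condition/timepoint/replicate plus,
#' per peptide, one unexchanged control (`time_s = -1`) and one fully
#' deuterated control (`time_s = -2`, generated under the same back-exchange
#' as the samples, as in an experiment where the 100% control passes through
#' the same workup). Fully reproducible from the config seed.
#'
#' @param config An [hx_sim_config()] object.
#' @return Long-format data.frame with columns `peptide_id`, `condition`,
#'   `replicate`, `time_s`, `mz`, `intensity`.
#' @export
hx_simulate_dataset <- function(config) {
  stopifnot(inherits(config, "hx_sim_config"))
  out <- vector("list", 0L)
  for (pep in config$peptides) {
    for (cond in names(config$conditions)) {
      par <- config$conditions[[cond]]
      for (rep_i in seq_len(config$replicates)) {
        sseed <- .substream_seed(config$seed,
                                 paste(pep$id, cond, rep_i, sep = "|"))
        for (ti in seq_along(config$timepoints)) {
          t <- config$timepoints[ti]
          cl <- hx_simulate_cluster(pep, par, t, config$back_exchange,
                                    config$noise_sd_rel, config$noise_sd_abs,
                                    seed = sseed + ti)
          out[[length(out) + 1L]] <- data.frame(
            peptide_id = pep$id, condition = cond, replicate = rep_i,
            time_s = t, mz = cl$mz, intensity = cl$intensity
          )
        }
      }
    }
    # per-peptide controls (unexchanged, fully deuterated)
    ctrl_seed <- .substream_seed(config$seed, paste(pep$id, "control", sep = "|"))
    env <- hx_isotope_envelope(pep$sequence, pep$charge)
    unex <- .noisy_control(.cross_envelope(env, 1, pep$charge),
                           config, ctrl_seed)
    n_ex <- hx_exchangeable_amides(pep$sequence)
    fd <- .noisy_control(
      .cross_envelope(env, stats::dbinom(0:n_ex, n_ex, 1 - config$back_exchange),
                      pep$charge),
      config, ctrl_seed + 1L)
    out[[length(out) + 1L]] <- data.frame(
      peptide_id = pep$id, condition = "control", replicate = 1L,
      time_s = -1, mz = unex$mz, intensity = unex$intensity)
    out[[length(out) + 1L]] <- data.frame(
      peptide_id = pep$id, condition = "control", replicate = 1L,
      time_s = -2, mz = fd$mz, intensity = fd$intensity)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.noisy_control <- function(comp, config, seed) {
  comp <- comp[comp$intensity > 0, , drop = FALSE]
  comp <- comp[order(comp$mz), , drop = FALSE]
  if (config$noise_sd_rel > 0 || config$noise_sd_abs > 0) {
    set.seed(seed)
    n <- nrow(comp)
    comp$intensity <- comp$intensity * (1 + stats::rnorm(n, 0, config$noise_sd_rel)) +
      stats::rnorm(n, 0, config$noise_sd_abs)
  }
  comp
}

#' Simulate a plate-reader kinetic trace or titration table
#'
#' Forward models with known ground truth for the ancillary measurements:
#' \describe{
#'   \item{`fret_association`}{`y = y0 + (plateau - y0)(1 - exp(-k t))`;
#'     params `y0`, `plateau`, `k`, plus `times`.}
#'   \item{`bli_dissociation`}{`y = y0 (p exp(-k_fast t) + (1-p) exp(-k_slow t))`;
#'     params `y0`, `p`, `k_fast`, `k_slow`, plus `times`.}
#'   \item{`melt_curve`}{rising sigmoid `F0 + dF / (1 + exp(-(T - Tm)/w))`;
#'     params `F0`, `dF`, `Tm`, `w`, plus `temperatures`.}
#'   \item{`anisotropy_titration`}{Hill binding
#'     `r = r_free + (r_max - r_free) X^h / (X^h + K^h)`; params `r_free`,
#'     `r_max`, `K`, `h`, plus `conc`. Parallel/perpendicular intensities are
#'     synthesised as `I_para = 1 + 2r`, `I_perp = 1 - r`, consistent with
#'     the anisotropy definition.}
#' }
#'
#' @param kind One of `"fret_association"`, `"bli_dissociation"`,
#'   `"melt_curve"`, `"anisotropy_titration"`.
#' @param params Named list of ground-truth parameters (see Details).
#' @param noise_sd Additive Gaussian noise standard deviation on the signal.
#' @param seed Integer seed for noise.
#' @return For kinetic kinds, a data.frame `t`, `y`; for melt curves
#'   `temperature`, `fluorescence`; for titrations `conc`, `I_para`,
#'   `I_perp`, `r`.
#' @export
hx_simulate_trace <- function(kind = c("fret_association", "bli_dissociation",
                                       "melt_curve", "anisotropy_titration"),
                              params, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
    fret_association = c("y0", "plateau", "k", "times"),
    bli_dissociation = c("y0", "p", "k_fast", "k_slow", "times"),
    melt_curve = c("F0", "dF", "Tm", "w", "temperatures"),
    anisotropy_titration = c("r_free", "r_max", "K", "h", "conc"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop(sprintf("missing parameter(s) for %s: %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (kind == "fret_association") {
    t <- params$times
    y <- params$y0 + (params$plateau - params$y0) * (1 - exp(-params$k * t))
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    return(data.frame(t = t, y = y))
  }
  if (kind == "bli_dissociation") {
    if (params$p < 0 || params$p > 1) stop("p must be in [0, 1]", call. = FALSE)
    t <- params$times
    y <- params$y0 * (params$p * exp(-params$k_fast * t) +
                        (1 - params$p) * exp(-params$k_slow * t))
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    return(data.frame(t = t, y = y))
  }
  if (kind == "melt_curve") {
    tp <- params$temperatures
    f <- params$F0 + params$dF / (1 + exp(-(tp - params$Tm) / params$w))
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    return(data.frame(temperature = tp, fluorescence = f))
  }
  x <- params$conc
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  r <- params$r_free + (params$r_max - params$r_free) *
    x^params$h / (x^params$h + params$K^params$h)
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  data.frame(conc = x, I_para = 1 + 2 * r, I_perp = 1 - r, r = r)
}
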