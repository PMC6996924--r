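# Centroid-based deuterium uptake with back-exchange correction, replicate
# statistics and condition difference profiles.

#' Intensity-weighted centroid of an isotope cluster
#'
#' Peaks below a relative-intensity floor (default 1% of the cluster
#' maximum) are excluded before centroiding, so that baseline noise does not
#' drag the centroid.
#'
#' @param cluster A data.frame with columns `mz` and `intensity` (e.g. an
#'   [hx_simulate_cluster()] output).
#' @param min_rel_intensity Relative floor in \[0, 1).
#' @return Centroid m/z in Th.
#' @export
hx_centroid <- function(cluster, min_rel_intensity = 0.01) {
  if (!all(c("mz", "intensity") %in% names(cluster))) {
    stop("cluster must have columns mz and intensity", call. = FALSE)
  }
  keep <- cluster$intensity >= min_rel_intensity * max(cluster$intensity)
  y <- cluster$intensity[keep]
  x <- cluster$mz[keep]
  if (!any(y > 0)) stop("cluster has no positive intensity", call. = FALSE)
  sum(x * y) / sum(y)
}

#' Percentage of amide hydrogen exchange with back-exchange correction
#'
#' Anchors the observed centroid between the unexchanged control (0%) and
#' the fully deuterated control (100%): `100 (m - m_unex) / (m_full -
#' m_unex)`. Because the fully deuterated control passes through the same
#' workup, this corrects for back-exchange.
#'
#' @param m Observed centroid m/z (vectorised).
#' @param m_unexchanged Centroid of the unexchanged control.
#' @param m_full Centroid of the fully deuterated control.
#' @param peptide_id Optional label used in error messages.
#' @return Percent exchange (can exceed \[0, 100\] under noise).
#' @export
hx_percent_exchange <- function(m, m_unexchanged, m_full, peptide_id = NULL) {
  if (!(m_full > m_unexchanged)) {
    stop(sprintf("degenerate controls%s: fully deuterated centroid (%.4f) must exceed unexchanged centroid (%.4f)",
                 if (is.null(peptide_id)) "" else paste0(" for peptide ", peptide_id),
                 m_full, m_unexchanged), call. = FALSE)
  }
  100 * (m - m_unexchanged) / (m_full - m_unexchanged)
}

#' Deuterons incorporated from a centroid shift
#'
#' Raw (uncorrected) deuteron count: `(m - m_unexchanged) * z / 1.006277`.
#'
#' @param m Observed centroid m/z.
#' @param m_unexchanged Unexchanged-control centroid m/z.
#' @param charge Charge state.
#' @return Non-integer deuteron count.
#' @export
hx_deuterons <- function(m, m_unexchanged, charge) {
  (m - m_unexchanged) * charge / hx_constants[["d_shift"]]
}

#' Per-replicate uptake records from a long-format dataset
#'
#' Splits a simulated or imported long-format spectral table into clusters,
#' centroids each, and computes percent exchange (back-exchange corrected
#' against the per-peptide controls), raw deuterons and corrected deuterons
#' (`percent_ex/100 * exchangeable amides`).
#'
#' @param dataset Long-format data.frame with columns `peptide_id`,
#'   `condition`, `replicate`, `time_s`, `mz`, `intensity`; controls flagged
#'   by `time_s = -1` (unexchanged) and `-2` (fully deuterated).
#' @param peptides List of [hx_peptide()] objects covering every
#'   `peptide_id` in the dataset.
#' @param min_rel_intensity Centroid peak floor, see [hx_centroid()].
#' @return data.frame with one row per peptide/condition/time/replicate and
#'   columns `centroid_mz`, `percent_ex`, `deuterons_raw`, `deuterons`.
#' @export
hx_uptake_records <- function(dataset, peptides, min_rel_intensity = 0.01) {
  peps <- stats::setNames(peptides, vapply(peptides, `[[`, character(1), "id"))
  missing <- setdiff(unique(dataset$peptide_id), names(peps))
  if (length(missing)) {
    stop("dataset contains peptide_id(s) without peptide records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- dataset[dataset$time_s >= 0, , drop = FALSE]
  key <- interaction(samples$peptide_id, samples$condition, samples$replicate,
                     samples$time_s, drop = TRUE)
  rows <- lapply(split(samples, key), function(d) {
    pid <- d$peptide_id[1]
    pep <- peps[[pid]]
    ctrl <- dataset[dataset$peptide_id == pid & dataset$time_s < 0, ]
    m_unex <- hx_centroid(ctrl[ctrl$time_s == -1, ], min_rel_intensity)
    m_full <- hx_centroid(ctrl[ctrl$time_s == -2, ], min_rel_intensity)
    m <- hx_centroid(d, min_rel_intensity)
    pex <- hx_percent_exchange(m, m_unex, m_full, pid)
    data.frame(
      peptide_id = pid, condition = d$condition[1],
      replicate = d$replicate[1], time_s = d$time_s[1],
      centroid_mz = m, percent_ex = pex,
      deuterons_raw = hx_deuterons(m, m_unex, pep$charge),
      deuterons = pex / 100 * hx_exchangeable_amides(pep$sequence)
    )
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$peptide_id, res$condition, res$time_s, res$replicate), ]
  rownames(res) <- NULL
  res
}

#' Aggregate uptake records over replicates
#'
#' Mean and sample standard deviation per peptide/condition/timepoint for
#' each metric. Single-replicate groups yield `sd = 0` with a warning (a
#' policy, not a statistical claim).
#'
#' @param records Output of [hx_uptake_records()].
#' @param metric One of `"percent_ex"`, `"deuterons"`, `"deuterons_raw"`.
#' @return Long-format data.frame `peptide_id`, `condition`, `time_s`,
#'   `mean`, `sd`, `n`, `metric`.
#' @export
hx_uptake_summary <- function(records, metric = c("percent_ex", "deuterons",
                                                  "deuterons_raw")) {
  metric <- match.arg(metric)
  key <- interaction(records$peptide_id, records$condition, records$time_s,
                     drop = TRUE)
  warned <- FALSE
  rows <- lapply(split(records, key), function(d) {
    n <- nrow(d)
    if (n == 1L && !warned) warned <<- TRUE
    data.frame(peptide_id = d$peptide_id[1], condition = d$condition[1],
               time_s = d$time_s[1], mean = mean(d[[metric]]),
               sd = if (n > 1) stats::sd(d[[metric]]) else 0,
               n = n, metric = metric)
  })
  if (warned) warning("single-replicate group(s): sd reported as 0")
  res <- do.call(rbind, rows)
  res <- res[order(res$peptide_id, res$condition, res$time_s), ]
  rownames(res) <- NULL
  res
}

#' Difference profile between two conditions
#'
#' Per matched peptide and timepoint: `mean_A - mean_B` with independent
#' error propagation `sd = sqrt(sd_A^2 + sd_B^2)`. Peptides present in only
#' one input are reported in the `missing` attribute (and a warning), never
#' dropped silently.
#'
#' @param summary_A,summary_B Outputs of [hx_uptake_summary()] for the two
#'   conditions/states being compared (same metric).
#' @return data.frame `peptide_id`, `time_s`, `delta`, `sd`, `n_A`, `n_B`,
#'   `metric`, with attribute `missing`.
#' @export
hx_difference_profile <- function(summary_A, summary_B) {
  if (summary_A$metric[1] != summary_B$metric[1]) {
    stop("difference profile requires a common metric", call. = FALSE)
  }
  ka <- paste(summary_A$peptide_id, summary_A$time_s)
  kb <- paste(summary_B$peptide_id, summary_B$time_s)
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no overlapping peptides/timepoints", call. = FALSE)
  miss <- union(setdiff(ka, kb), setdiff(kb, ka))
  if (length(miss)) {
    warning("unmatched peptide/timepoint(s): ", paste(miss, collapse = "; "))
  }
  a <- summary_A[match(shared, ka), ]
  b <- summary_B[match(shared, kb), ]
  res <- data.frame(
    peptide_id = a$peptide_id, time_s = a$time_s,
    delta = a$mean - b$mean,
    sd = sqrt(a$sd^2 + b$sd^2),
    n_A = a$n, n_B = b$n, metric = a$metric
  )
  res <- res[order(res$peptide_id, res$time_s), ]
  rownames(res) <- NULL
  attr(res, "missing") <- miss
  res
}
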