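# Pipeline driver: configuration, stage execution, manifest.

# small deterministic hash of an R object (for manifests)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every stage's inputs and thresholds. All tolerances must be
#' positive and referenced files must exist; validation happens here,
#' before any stage runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim An [hx_sim_config()]; its seed is overridden by `seed` so a
#'   single seed governs the whole run.
#' @param peptide_table Optional path to a peptide table used for the
#'   coverage stage; defaults to the peptides in `sim`.
#' @param span Length-2 residue bounds of the construct for coverage.
#' @param stages Character subset of
#'   `c("simulate", "coverage", "uptake", "bimodal", "traces")`.
#' @param bimodal_ids Peptide ids for the bimodal stage (default: all).
#' @param min_rel_intensity Centroid peak floor (> 0).
#' @param tol_frac Peak-grid tolerance (> 0).
#' @param valley_frac Modality valley depth (> 0).
#' @param trace_truth Named list of ground-truth parameter lists for the
#'   traces stage (kinds as in [hx_simulate_trace()]).
#' @param trace_noise_sd Additive noise for simulated traces.
#' @param seed Master seed for the run.
#' @return An object of class `hx_pipeline_config`.
#' @export
hx_pipeline_config <- function(out_dir,
                               sim,
                               peptide_table = NULL,
                               span = c(24L, 444L),
                               stages = c("simulate", "coverage", "uptake",
                                          "bimodal", "traces"),
                               bimodal_ids = NULL,
                               min_rel_intensity = 0.01,
                               tol_frac = 0.2,
                               valley_frac = 0.5,
                               trace_truth = list(
                                 fret_association = list(y0 = 1000, plateau = 1400,
                                                         k = 0.002,
                                                         times = seq(0, 3000, by = 30)),
                                 bli_dissociation = list(y0 = 1, p = 0.6,
                                                         k_fast = 0.05, k_slow = 0.005,
                                                         times = seq(0, 600, by = 5)),
                                 melt_curve = list(F0 = 100, dF = 900, Tm = 52,
                                                   w = 2,
                                                   temperatures = seq(20, 95, by = 0.5)),
                                 anisotropy_titration = list(r_free = 0.05,
                                                             r_max = 0.25, K = 2,
                                                             h = 1.5,
                                                             conc = 10^seq(-2, 2, length.out = 12))
                               ),
                               trace_noise_sd = 0,
                               seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  tol <- c(min_rel_intensity = min_rel_intensity, tol_frac = tol_frac,
           valley_frac = valley_frac)
  bad <- names(tol)[tol <= 0]
  if (length(bad)) {
    stop("tolerance(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(peptide_table) && !file.exists(peptide_table)) {
    stop("peptide_table does not exist: ", peptide_table, call. = FALSE)
  }
  stopifnot(inherits(sim, "hx_sim_config"))
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, peptide_table = peptide_table,
                 span = as.integer(span), stages = stages,
                 bimodal_ids = bimodal_ids,
                 min_rel_intensity = min_rel_intensity, tol_frac = tol_frac,
                 valley_frac = valley_frac, trace_truth = trace_truth,
                 trace_noise_sd = trace_noise_sd, seed = as.integer(seed)),
            class = "hx_pipeline_config")
}

#' Run the HX-MS analysis pipeline
#'
#' Executes the enabled stages in order — simulate, coverage, uptake,
#' bimodal, traces — writing one canonical table per stage under
#' `config$out_dir`, plus a run manifest (`manifest.json`) recording the
#' config hash, seed, package version, per-stage row counts and warning
#' tallies. Warnings (flagged peptides, non-converged fits) never abort the
#' run. Re-running with an identical config and seed reproduces identical
#' tables.
#'
#' @param config An [hx_pipeline_config()].
#' @return Invisibly, a list with the stage tables and the manifest.
#' @export
hx_run_pipeline <- function(config) {
  stopifnot(inherits(config, "hx_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = .config_hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("hxtools")),
                   stages = list(), warnings = list())
  out <- list()
  note <- function(stage, msg) {
    manifest$warnings[[stage]] <<- c(manifest$warnings[[stage]], msg)
  }
  dataset <- NULL
  if ("simulate" %in% config$stages) {
    dataset <- hx_simulate_dataset(config$sim)
    hx_write_table(dataset, file.path(config$out_dir, "clusters.csv"))
    manifest$stages$simulate <- list(rows = nrow(dataset))
    out$dataset <- dataset
  }
  peptides <- config$sim$peptides
  if (!is.null(config$peptide_table)) {
    peptides <- withCallingHandlers(
      hx_read_peptides(config$peptide_table),
      message = function(m) {
        note("coverage", conditionMessage(m)); invokeRestart("muffleMessage")
      })
  }
  n_flagged <- sum(vapply(peptides, `[[`, logical(1), "flagged"))
  if (n_flagged) note("peptides", sprintf("%d flagged peptide record(s)", n_flagged))
  if ("coverage" %in% config$stages) {
    cov <- hx_coverage(peptides, config$span[1], config$span[2])
    tab <- data.frame(span_start = cov$span_start, span_end = cov$span_end,
                      n_peptides = length(peptides),
                      fraction = cov$fraction,
                      percent = round(100 * cov$fraction))
    hx_write_table(tab, file.path(config$out_dir, "coverage.csv"))
    manifest$stages$coverage <- list(rows = nrow(tab),
                                     percent = round(100 * cov$fraction))
    out$coverage <- cov
  }
  if ("uptake" %in% config$stages && !is.null(dataset)) {
    rec <- hx_uptake_records(dataset, config$sim$peptides,
                             config$min_rel_intensity)
    summ <- do.call(rbind, lapply(c("percent_ex", "deuterons", "deuterons_raw"),
                                  function(m) hx_uptake_summary(rec, m)))
    hx_write_table(rec, file.path(config$out_dir, "uptake_records.csv"))
    hx_write_table(summ, file.path(config$out_dir, "uptake_summary.csv"))
    conds <- setdiff(unique(dataset$condition), "control")
    if (length(conds) >= 2) {
      sd_metric <- summ[summ$metric == "deuterons", ]
      diffp <- hx_difference_profile(
        sd_metric[sd_metric$condition == conds[1], ],
        sd_metric[sd_metric$condition == conds[2], ])
      hx_write_table(diffp, file.path(config$out_dir, "difference_profile.csv"))
      out$difference <- diffp
    }
    manifest$stages$uptake <- list(rows = nrow(rec))
    out$uptake <- rec
    out$uptake_summary <- summ
  }
  if ("bimodal" %in% config$stages && !is.null(dataset)) {
    peps <- config$sim$peptides
    if (!is.null(config$bimodal_ids)) {
      peps <- Filter(function(p) p$id %in% config$bimodal_ids, peps)
    }
    bi <- hx_ktrans_pipeline(dataset, peps)
    hx_write_table(bi$courses, file.path(config$out_dir, "fraction_high.csv"))
    hx_write_table(bi$transitions, file.path(config$out_dir, "transitions.csv"))
    nc <- sum(!bi$transitions$converged)
    if (nc) note("bimodal", sprintf("%d non-converged transition fit(s)", nc))
    manifest$stages$bimodal <- list(rows = nrow(bi$courses),
                                    transitions = nrow(bi$transitions))
    out$bimodal <- bi
  }
  if ("traces" %in% config$stages) {
    rows <- list()
    for (kind in names(config$trace_truth)) {
      tr <- hx_simulate_trace(kind, config$trace_truth[[kind]],
                              noise_sd = config$trace_noise_sd,
                              seed = .substream_seed(config$seed, kind))
      fit <- switch(kind,
        fret_association = hx_fit_association(tr$t, tr$y),
        bli_dissociation = hx_fit_dissociation(tr$t, tr$y),
        melt_curve = hx_dsf_tm(tr$temperature, tr$fluorescence),
        anisotropy_titration = hx_fit_hill(tr$conc,
                                           hx_anisotropy(tr$I_para, tr$I_perp)))
      est <- unclass(fit)
      est <- est[vapply(est, function(v) is.numeric(v) && length(v) == 1L,
                        logical(1))]
      rows[[kind]] <- data.frame(kind = kind, parameter = names(est),
                                 estimate = unlist(est), row.names = NULL)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    hx_write_table(tab, file.path(config$out_dir, "trace_fits.csv"))
    manifest$stages$traces <- list(rows = nrow(tab))
    out$trace_fits <- tab
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
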