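# Peptide-level chemistry: monoisotopic m/z, exchangeable amides,
# theoretical isotope envelopes, coverage maps.

#' Construct a peptic peptide record
#'
#' Represents one row of a peptic-peptide table: sequence, residue interval
#' (1-based, inclusive), charge state and optionally the observed m/z. When
#' the sequence length disagrees with the residue interval the record is
#' flagged (`flagged = TRUE`) rather than silently corrected; downstream,
#' the sequence stays authoritative for mass computations and the interval
#' for coverage.
#'
#' @param sequence One-letter amino-acid string (canonical 20 letters).
#' @param start_res,end_res Residue interval, 1-based inclusive.
#' @param charge Positive integer charge state.
#' @param observed_mz Observed mass-to-charge (Th), or `NA`.
#' @param id Optional identifier; defaults to `"<start>-<end>_<sequence>"`.
#' @return An object of class `hx_peptide`.
#' @export
hx_peptide <- function(sequence, start_res, end_res, charge,
                       observed_mz = NA_real_, id = NULL) {
  letters <- .assert_sequence(sequence)
  if (!(start_res <= end_res)) stop("start_res must be <= end_res", call. = FALSE)
  if (charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  flagged <- length(letters) != (end_res - start_res + 1L)
  if (is.null(id)) id <- sprintf("%d-%d_%s", start_res, end_res, sequence)
  structure(list(
    id = id, sequence = sequence, start_res = as.integer(start_res),
    end_res = as.integer(end_res), charge = as.integer(charge),
    observed_mz = as.numeric(observed_mz), flagged = flagged
  ), class = "hx_peptide")
}

#' @export
print.hx_peptide <- function(x, ...) {
  cat(sprintf("<hx_peptide> %s  z=%d  residues %d-%d%s\n", x$sequence,
              x$charge, x$start_res, x$end_res,
              if (x$flagged) "  [flagged: sequence/interval mismatch]" else ""))
  invisible(x)
}

#' Theoretical monoisotopic m/z of a protonated peptide
#'
#' Computes (sum of residue monoisotopic masses + water + charge protons) /
#' charge, using water = 18.010565 Da and proton = 1.007276 Da.
#'
#' @param sequence One-letter amino-acid string.
#' @param charge Positive integer charge state.
#' @return Monoisotopic m/z in Thomson.
#' @examples
#' hx_peptide_mz("KSKLTPTL", 2) # ~444.282
#' @export
hx_peptide_mz <- function(sequence, charge) {
  letters <- .assert_sequence(sequence)
  if (charge < 1) stop("charge must be >= 1", call. = FALSE)
  (sum(.AA_MONO[letters]) + hx_constants[["water"]] +
     charge * hx_constants[["proton"]]) / charge
}

#' Number of exchangeable backbone amide hydrogens
#'
#' Counts the backbone amides whose exchange is observable by HX-MS:
#' sequence length minus one (the N-terminal amide back-exchanges too fast
#' to be detected, so the N-terminal residue is excluded) minus the number
#' of prolines beyond the first position (prolines have no amide hydrogen).
#'
#' @param sequence One-letter amino-acid string.
#' @return Non-negative integer count.
#' @examples
#' hx_exchangeable_amides("LPDPNDGSL") # 6
#' @export
hx_exchangeable_amides <- function(sequence) {
  letters <- .assert_sequence(sequence)
  n <- length(letters)
  max(0L, n - 1L - sum(letters[-1] == "P"))
}

#' Theoretical natural-abundance isotope envelope
#'
#' Assembles the elemental composition of the peptide (residue formulas plus
#' one water) and computes the aggregated isotope distribution by iterative
#' convolution of the per-element isotope-abundance polynomials. Peaks are
#' indexed by extra-neutron count; the first peak sits at the monoisotopic
#' m/z and successive peaks are spaced by the C13-C12 mass difference over
#' charge.
#'
#' @param sequence One-letter amino-acid string.
#' @param charge Positive integer charge state.
#' @param n_peaks Number of isotope peaks to retain (>= 2). The default
#'   matches the simulator's, so control and sample envelopes share one
#'   truncation.
#' @return An object of class `hx_envelope` with fields `monoisotopic_mz`,
#'   `spacing` (Th) and `abundances` (normalised to sum 1).
#' @export
hx_isotope_envelope <- function(sequence, charge, n_peaks = 8L) {
  letters <- .assert_sequence(sequence)
  if (n_peaks < 2) stop("n_peaks must be >= 2", call. = FALSE)
  comp <- colSums(.AA_FORMULA[letters, , drop = FALSE])
  comp["H"] <- comp["H"] + 2  # water
  comp["O"] <- comp["O"] + 1
  # maximum extra neutrons is bounded by heavy-isotope availability
  max_neutrons <- sum(comp * vapply(.ISO_ABUND[names(comp)],
                                    function(a) length(a) - 1L, integer(1)))
  if (n_peaks > max_neutrons + 1) {
    warning(sprintf("n_peaks = %d exceeds the %d isotopologue mass states; truncated",
                    n_peaks, max_neutrons + 1L))
    n_peaks <- max_neutrons + 1L
  }
  dist <- .convolve_composition(comp, keep = n_peaks)
  abund <- dist[seq_len(n_peaks)]
  abund <- abund / sum(abund)
  structure(list(
    monoisotopic_mz = hx_peptide_mz(sequence, charge),
    spacing = hx_constants[["c13_shift"]] / charge,
    abundances = abund
  ), class = "hx_envelope")
}

# Aggregated isotope distribution over extra-neutron counts for an elemental
# composition (named vector over C,H,N,O,S), by polynomial convolution.
.convolve_composition <- function(comp, keep = 12L) {
  dist <- 1
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    pol <- .ISO_ABUND[[el]]
    elem <- .poly_power(pol, n, keep)
    dist <- .poly_mult(dist, elem, keep)
  }
  length(dist) <- max(keep, length(dist))
  dist[is.na(dist)] <- 0
  dist
}

.poly_mult <- function(a, b, keep) {
  out <- numeric(min(length(a) + length(b) - 1L, keep))
  for (i in seq_along(a)) {
    jmax <- min(length(b), keep - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# power by repeated squaring, truncated to `keep` terms
.poly_power <- function(p, n, keep) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- .poly_mult(result, base, keep)
    n <- n %/% 2
    if (n > 0) base <- .poly_mult(base, base, keep)
  }
  result
}

#' Sequence coverage map from a set of peptic peptides
#'
#' Computes the per-residue union of the peptide residue intervals clipped
#' to a construct span. N-terminal residues are included for coverage even
#' though they are excluded from exchange analysis (the interval, not the
#' exchange-competent subsequence, defines what was identified).
#'
#' @param peptides List of [hx_peptide()] objects (or a data.frame with
#'   `start_res`/`end_res` columns).
#' @param span_start,span_end Integer residue bounds of the construct.
#' @return An object of class `hx_coverage` with fields `span_start`,
#'   `span_end`, `covered` (per-residue logical) and `fraction`.
#' @export
hx_coverage <- function(peptides, span_start, span_end) {
  if (span_start > span_end) stop("span_start must be <= span_end", call. = FALSE)
  if (is.data.frame(peptides)) {
    ivals <- peptides[, c("start_res", "end_res")]
  } else {
    ivals <- data.frame(
      start_res = vapply(peptides, `[[`, integer(1), "start_res"),
      end_res = vapply(peptides, `[[`, integer(1), "end_res")
    )
  }
  covered <- rep(FALSE, span_end - span_start + 1L)
  if (nrow(ivals) == 0L) {
    warning("empty peptide list: coverage fraction is 0")
  } else {
    for (i in seq_len(nrow(ivals))) {
      a <- max(ivals$start_res[i], span_start)
      b <- min(ivals$end_res[i], span_end)
      if (a <= b) covered[(a:b) - span_start + 1L] <- TRUE
    }
  }
  structure(list(span_start = as.integer(span_start),
                 span_end = as.integer(span_end),
                 covered = covered, fraction = mean(covered)),
            class = "hx_coverage")
}

#' @export
print.hx_coverage <- function(x, ...) {
  cat(sprintf("<hx_coverage> residues %d-%d: %.1f%% covered\n",
              x$span_start, x$span_end, 100 * x$fraction))
  invisible(x)
}
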