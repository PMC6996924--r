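# Tabular artifact I/O: one fixed dialect (comma, "." decimal, UTF-8, Unix
# newlines), shortest-round-trip numeric formatting, validating readers.

# shortest decimal string that parses back to exactly x
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 15:17) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Write a table in the package's canonical dialect
#'
#' Comma separator, "." decimal point, UTF-8, Unix newlines, no quoting, no
#' row names; doubles serialised with the shortest representation that
#' round-trips to the same value, so `write(read(x))` is byte-identical for
#' files produced by this writer.
#'
#' @param df data.frame to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
hx_write_table <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) .fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and validate a canonical table
#'
#' Rejects files with missing required columns (naming the column) and
#' non-numeric entries in numeric columns (naming file, row and column).
#'
#' @param path Input file path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as finite numbers.
#' @return data.frame.
#' @export
hx_read_table <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (cc in intersect(numeric_cols, names(df))) {
    val <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                   path, cc, bad[1]), call. = FALSE)
    }
    df[[cc]] <- val
  }
  df
}

#' Read a peptic-peptide table
#'
#' Expects the headered columns `start_res`, `end_res`, `mz`, `z`,
#' `sequence`. Records whose sequence length disagrees with the residue
#' interval are flagged (see [hx_peptide()]), with one message summarising
#' the flags.
#'
#' @param path Path to the peptide table (the packaged study table is at
#'   `system.file("extdata", "ire1ld_peptides.csv", package = "hxtools")`).
#' @return List of [hx_peptide()] objects; the parsed data.frame is attached
#'   as attribute `table`.
#' @export
hx_read_peptides <- function(path) {
  df <- hx_read_table(path,
                      required = c("start_res", "end_res", "mz", "z", "sequence"),
                      numeric_cols = c("start_res", "end_res", "mz", "z"))
  peps <- lapply(seq_len(nrow(df)), function(i) {
    hx_peptide(df$sequence[i], df$start_res[i], df$end_res[i], df$z[i],
               observed_mz = df$mz[i])
  })
  n_flag <- sum(vapply(peps, `[[`, logical(1), "flagged"))
  if (n_flag > 0) {
    message(sprintf("%d peptide record(s) flagged for sequence/interval mismatch",
                    n_flag))
  }
  attr(peps, "table") <- df
  peps
}
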