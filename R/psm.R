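## Peptide-spectrum-match filtering: E-value acceptance, per-spectrum best
## match across database partitions and search spaces, peptide-level
## aggregation, the spectral-count rule, and target-decoy FDR.

psm_required_cols <- c("spectrum_id", "peptide", "evalue", "engine",
                       "search_space", "partition_id", "is_decoy")

#' Read a PSM table from TSV
#'
#' Expects a header row with columns `spectrum_id`, `peptide`, `evalue`,
#' `engine`, `search_space`, `partition_id`, `is_decoy` (plus an optional
#' `tissue` column, defaulted to `"all"`). Rows violating the invariants
#' (non-positive or non-numeric E-value, empty peptide, '*' in the peptide)
#' are dropped with a warning naming their line numbers.
#'
#' @param path TSV file.
#' @return data frame of typed PSMs.
#' @export
read_psm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(psm_required_cols, names(df))
  if (length(missing))
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  if (!("tissue" %in% names(df))) df$tissue <- "all"
  ev <- suppressWarnings(as.numeric(df$evalue))
  dec <- tolower(df$is_decoy) %in% c("true", "t", "1", "yes")
  bad <- is.na(ev) | ev <= 0 | !nzchar(df$peptide) | grepl("*", df$peptide, fixed = TRUE)
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed PSM row(s) at line(s) ",
            paste(which(bad) + 1L, collapse = ", "),
            " (header is line 1)")
    df <- df[!bad, , drop = FALSE]
    ev <- ev[!bad]; dec <- dec[!bad]
  }
  df$evalue <- ev
  df$is_decoy <- dec
  rownames(df) <- NULL
  df[, c(psm_required_cols, "tissue")]
}

#' Accept PSMs by E-value and per-spectrum best match
#'
#' Removes PSMs with E-value above `evalue_max` (the threshold is
#' inclusive: an E-value exactly equal to `evalue_max` is accepted). When
#' the same spectrum was matched more than once — across database
#' partitions and across the protein and genome search spaces — only the
#' match with the lowest E-value survives. Ties are broken
#' deterministically: lexicographically smallest peptide, then smallest
#' partition id. Deduplication is performed within each (decoy flag,
#' engine, tissue, spectrum) group: each search engine keeps its own best
#' match per spectrum, and decoy searches are filtered as a separate stream
#' by the identical rules.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param evalue_max acceptance threshold (default 0.01).
#' @return filtered PSM data frame; idempotent and order-independent.
#' @export
accept_psms <- function(psms, evalue_max = 0.01) {
  keep <- psms$evalue <= evalue_max
  df <- psms[keep, , drop = FALSE]
  if (!nrow(df)) { rownames(df) <- NULL; return(df) }
  ord <- order(df$is_decoy, df$engine, df$tissue, df$spectrum_id,
               df$evalue, df$peptide, df$partition_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  grp <- .key(df$is_decoy, df$engine, df$tissue, df$spectrum_id)
  df <- df[!duplicated(grp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Aggregate accepted PSMs to peptide-level hits
#'
#' @param psms accepted PSM data frame.
#' @return data frame with one row per (decoy flag, tissue, peptide):
#'   spectrum and engine counts, id lists (comma-joined) and the best
#'   (minimum) E-value.
#' @export
aggregate_peptide_hits <- function(psms) {
  if (!nrow(psms))
    return(data.frame(peptide = character(), tissue = character(),
                      is_decoy = logical(), n_spectra = integer(),
                      n_engines = integer(), spectra = character(),
                      engines = character(), best_evalue = numeric()))
  grp <- .key(psms$is_decoy, psms$tissue, psms$peptide)
  sp <- split(seq_len(nrow(psms)), grp)
  rows <- lapply(sp, function(idx) {
    spectra <- sort(unique(psms$spectrum_id[idx]))
    engines <- sort(unique(psms$engine[idx]))
    data.frame(peptide = psms$peptide[idx[1]], tissue = psms$tissue[idx[1]],
               is_decoy = psms$is_decoy[idx[1]],
               n_spectra = length(spectra), n_engines = length(engines),
               spectra = paste(spectra, collapse = ","),
               engines = paste(engines, collapse = ","),
               best_evalue = min(psms$evalue[idx]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$is_decoy, out$tissue, out$peptide, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the spectral-count rule
#'
#' Single-spectrum identifications are rejected unless they were identified
#' by at least two distinct search engines: a hit is kept iff it has two or
#' more spectra, or exactly one spectrum confirmed by two or more engines.
#'
#' @param hits peptide hits from [aggregate_peptide_hits()].
#' @return kept hits.
#' @export
spectral_count_filter <- function(hits) {
  keep <- hits$n_spectra >= 2L | (hits$n_spectra == 1L & hits$n_engines >= 2L)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy false discovery rate
#'
#' `100 * accepted decoys / accepted targets`, as a percentage reported to
#' two decimals (half-up). Decoy counts must come through the identical
#' acceptance and spectral-count path as the targets.
#'
#' @param n_target_accepted accepted target count (must be >= 1).
#' @param n_decoy_accepted accepted decoy count.
#' @return FDR percentage.
#' @export
compute_fdr <- function(n_target_accepted, n_decoy_accepted) {
  if (n_target_accepted < 1L)
    stop("FDR undefined: zero accepted target identifications")
  round_half_up(100 * n_decoy_accepted / n_target_accepted, 2)
}

#' Per-tissue FDR report
#'
#' Runs the full acceptance path (E-value threshold, per-spectrum best
#' match, peptide aggregation, spectral-count rule) on targets and decoys
#' alike, then tabulates counts and FDR per tissue.
#'
#' @param psms raw PSM data frame.
#' @param evalue_max acceptance threshold.
#' @return data frame with `tissue`, `n_target`, `n_decoy`, `fdr_pct`
#'   (NA where no targets survive).
#' @export
fdr_report <- function(psms, evalue_max = 0.01) {
  hits <- spectral_count_filter(aggregate_peptide_hits(
    accept_psms(psms, evalue_max)))
  tissues <- sort(unique(psms$tissue))
  out <- do.call(rbind, lapply(tissues, function(ti) {
    h <- hits[hits$tissue == ti, , drop = FALSE]
    nt <- sum(!h$is_decoy); nd <- sum(h$is_decoy)
    data.frame(tissue = ti, n_target = nt, n_decoy = nd,
               fdr_pct = if (nt >= 1L) compute_fdr(nt, nd) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
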