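## Annotation-relative classification of novel single-locus peptides into
## ten categories, independently against each of two reference gene sets,
## and the cross-annotation count/percentage summary.

#' The ten peptide categories
#'
#' In display order: intergenic, intron, transcript_noncoding,
#' coding_out_of_frame, nter_extension, cter_extension, utr5, utr3,
#' exon5_extension, exon3_extension.
#'
#' @return character vector of category names.
#' @export
peptide_categories <- function() {
  c("intergenic", "intron", "transcript_noncoding", "coding_out_of_frame",
    "nter_extension", "cter_extension", "utr5", "utr3",
    "exon5_extension", "exon3_extension")
}

## Rule priority when several rules match (most CDS-proximal wins);
## intergenic only when no same-strand gene overlaps.
.category_priority <- c("coding_out_of_frame", "nter_extension",
                        "cter_extension", "utr5", "utr3",
                        "exon5_extension", "exon3_extension",
                        "transcript_noncoding", "intron", "intergenic")

## fraction of [p1,p2] covered by an IRanges set
.covered <- function(p1, p2, ir) {
  if (!length(ir)) return(FALSE)
  q <- IRanges::IRanges(p1, p2)
  sum(IRanges::width(IRanges::intersect(q, ir))) == (p2 - p1 + 1L)
}

## candidate categories of one locus against one same-strand transcript
.tx_candidates <- function(p1, p2, t) {
  cand <- character()
  sp <- tx_span(t)
  s <- t$strand
  pep_phase <- function(pos) if (s == "+") (pos - p1) %% 3L else (p2 - pos) %% 3L
  if (length(t$cds)) {
    cf <- t$cds_frames
    ov <- which(cf$start <= p2 & cf$end >= p1)
    if (length(ov)) {
      mism <- vapply(ov, function(i) {
        pos <- max(p1, cf$start[i])
        pep_phase(pos) != cds_phase_at(t, pos)
      }, logical(1))
      if (any(mism)) cand <- c(cand, "coding_out_of_frame")
    }
    cds_lo <- min(cf$start); cds_hi <- max(cf$end)
    if (s == "+") {
      if (p1 < cds_lo && p2 >= cds_lo - 1L && (cds_lo - p1) %% 3L == 0L)
        cand <- c(cand, "nter_extension")
      if (p2 > cds_hi && p1 <= cds_hi + 1L && (cds_hi + 1L - p1) %% 3L == 0L)
        cand <- c(cand, "cter_extension")
    } else {
      if (p2 > cds_hi && p1 <= cds_hi + 1L && (p2 - cds_hi) %% 3L == 0L)
        cand <- c(cand, "nter_extension")
      if (p1 < cds_lo && p2 >= cds_lo - 1L && (p2 - (cds_lo - 1L)) %% 3L == 0L)
        cand <- c(cand, "cter_extension")
    }
    if (.covered(p1, p2, t$utr5)) cand <- c(cand, "utr5")
    if (.covered(p1, p2, t$utr3)) cand <- c(cand, "utr3")
  }
  cross5 <- if (s == "+") (p1 < sp[1] && p2 >= sp[1]) else (p2 > sp[2] && p1 <= sp[2])
  cross3 <- if (s == "+") (p2 > sp[2] && p1 <= sp[2]) else (p1 < sp[1] && p2 >= sp[1])
  if (cross5) cand <- c(cand, "exon5_extension")
  if (cross3) cand <- c(cand, "exon3_extension")
  if (t$biotype == "noncoding" && .covered(p1, p2, t$exons))
    cand <- c(cand, "transcript_noncoding")
  if (length(t$introns) &&
      any(IRanges::start(t$introns) <= p2 & IRanges::end(t$introns) >= p1))
    cand <- c(cand, "intron")
  ## genic but matched by no specific rule (degenerate geometries only):
  ## fall back on the most generic genic category
  if (!length(cand)) cand <- "intron"
  cand
}

#' Classify one peptide locus against a gene set
#'
#' Rules are evaluated in a fixed priority order, most CDS-proximal first:
#' coding_out_of_frame, then in-frame N-/C-terminal extensions (frame
#' continuation abutting or overlapping the CDS terminus), UTRs (wholly
#' within UTR exonic intervals), 5'/3' exon extensions (crossing the
#' transcript terminus), noncoding-transcript exons, intron, and finally
#' intergenic when no same-strand gene overlaps the locus (antisense-only
#' overlap also classifies intergenic).
#'
#' @param locus list or one-row data frame with `chrom`, `strand`, `start`,
#'   `end`.
#' @param gs a `pg_geneset`.
#' @param idx optional prebuilt [build_interval_index()] of `gs`.
#' @return a single category name.
#' @export
classify_peptide <- function(locus, gs, idx = NULL) {
  if (is.null(idx)) idx <- build_interval_index(gs)
  p1 <- as.integer(locus$start); p2 <- as.integer(locus$end)
  hits <- query_index(idx, locus$chrom, p1, p2, strand = locus$strand,
                      mode = "same", what = "transcripts")
  if (!nrow(hits)) return("intergenic")
  cand <- unique(unlist(lapply(hits$tx_id, function(tid)
    .tx_candidates(p1, p2, gs$transcripts[[tid]]))))
  .category_priority[min(match(cand, .category_priority))]
}

#' Classify many peptide loci against a gene set
#'
#' @param loci data frame of single-locus peptides (see [map_peptides()]).
#' @param gs a `pg_geneset`.
#' @return character vector of categories, one per row of `loci`.
#' @export
classify_peptides <- function(loci, gs) {
  idx <- build_interval_index(gs)
  vapply(seq_len(nrow(loci)),
         function(i) classify_peptide(loci[i, ], gs, idx), character(1))
}

#' Classify peptide loci against two annotation sets independently
#'
#' @param loci data frame of single-locus peptides.
#' @param gs_a,gs_b the two `pg_geneset`s (an empty set classifies
#'   everything intergenic).
#' @return `loci` with added columns `category_a`, `category_b`.
#' @export
classify_against_two <- function(loci, gs_a, gs_b) {
  loci$category_a <- classify_peptides(loci, gs_a)
  loci$category_b <- classify_peptides(loci, gs_b)
  loci
}

#' Cross-annotation novelty summary from per-category counts
#'
#' Computes row totals, half-up one-decimal row percentages and column
#' grand totals from the three per-category count columns (classified the
#' same by both annotations; one annotation only, each side).
#'
#' @param both,a_only,b_only integer vectors, one entry per category.
#' @param categories category names (defaults to [peptide_categories()]).
#' @return data frame of class `pg_novelty_summary`.
#' @export
novelty_summary_from_counts <- function(both, a_only, b_only,
                                        categories = peptide_categories()) {
  stopifnot(length(both) == length(categories),
            length(a_only) == length(categories),
            length(b_only) == length(categories))
  total <- both + a_only + b_only
  pct <- function(x) ifelse(total > 0, round_half_up(100 * x / total, 1), NA_real_)
  out <- data.frame(category = categories,
                    both = as.integer(both), a_only = as.integer(a_only),
                    b_only = as.integer(b_only), total = as.integer(total),
                    both_pct = pct(both), a_only_pct = pct(a_only),
                    b_only_pct = pct(b_only))
  attr(out, "grand") <- c(both = sum(out$both), a_only = sum(out$a_only),
                          b_only = sum(out$b_only), total = sum(out$total))
  class(out) <- c("pg_novelty_summary", "data.frame")
  out
}

#' Summarize paired peptide classifications across two annotations
#'
#' For each category c: `both` counts peptides classified c by both
#' annotation sets; `a_only`/`b_only` count peptides classified c by one
#' set and differently by the other. Row totals, percentages and grand
#' totals follow [novelty_summary_from_counts()].
#'
#' @param pairs data frame with columns `category_a`, `category_b` (as from
#'   [classify_against_two()]).
#' @return data frame of class `pg_novelty_summary`.
#' @export
summarize_novelty <- function(pairs) {
  cats <- peptide_categories()
  a <- factor(pairs$category_a, levels = cats)
  b <- factor(pairs$category_b, levels = cats)
  stopifnot(!anyNA(a), !anyNA(b))
  both <- vapply(cats, function(cc) sum(a == cc & b == cc), integer(1))
  a_only <- vapply(cats, function(cc) sum(a == cc & b != cc), integer(1))
  b_only <- vapply(cats, function(cc) sum(b == cc & a != cc), integer(1))
  novelty_summary_from_counts(both, a_only, b_only, cats)
}

#' @export
print.pg_novelty_summary <- function(x, ...) {
  g <- attr(x, "grand")
  cat("Novel peptide classification relative to two annotation sets\n")
  df <- data.frame(
    category = x$category,
    both = sprintf("%d (%s)", x$both, ifelse(is.na(x$both_pct), "-", x$both_pct)),
    a_only = sprintf("%d (%s)", x$a_only, ifelse(is.na(x$a_only_pct), "-", x$a_only_pct)),
    b_only = sprintf("%d (%s)", x$b_only, ifelse(is.na(x$b_only_pct), "-", x$b_only_pct)),
    total = x$total)
  print(df, row.names = FALSE)
  cat(sprintf("Totals: both=%d, A-only=%d, B-only=%d, all=%d\n",
              g["both"], g["a_only"], g["b_only"], g["total"]))
  invisible(x)
}
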