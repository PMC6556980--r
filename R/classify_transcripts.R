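## Classification of assembled transcripts against reference gene models by
## intron-chain comparison, novel-transcript (CXT) identifier assignment,
## exon-count and tissue-specificity statistics, and coordinate-based miRNA
## name transfer.

#' The six transcript categories
#'
#' @return character vector: matches_annotated, novel_isoform,
#'   five_prime_difference, three_prime_difference, intronic, intergenic.
#' @export
transcript_categories <- function() {
  c("matches_annotated", "novel_isoform", "five_prime_difference",
    "three_prime_difference", "intronic", "intergenic")
}

.tx_priority <- transcript_categories()

## intron chain as a 2-column matrix in genomic-ascending order
intron_chain <- function(t) {
  ir <- t$introns
  cbind(start = IRanges::start(ir), end = IRanges::end(ir))
}

.chains_equal <- function(a, b) nrow(a) == nrow(b) &&
  (nrow(a) == 0L || all(a == b))

## does the shorter chain equal the genomic prefix/suffix of the longer?
.shared_end <- function(a, b) {
  if (nrow(a) == nrow(b)) return(NULL)
  short <- if (nrow(a) < nrow(b)) a else b
  long <- if (nrow(a) < nrow(b)) b else a
  k <- nrow(short)
  if (k == 0L) return(NULL)
  if (all(short == long[seq_len(k), , drop = FALSE])) return("prefix")
  if (all(short == long[(nrow(long) - k + 1L):nrow(long), , drop = FALSE]))
    return("suffix")
  NULL
}

.n_shared_introns <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  sum(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2]))
}

.exonic_overlap_bp <- function(t, r) {
  sum(IRanges::width(IRanges::intersect(t$exons, r$exons)))
}

## category of tx against one same-strand reference transcript
.tx_vs_ref <- function(tx, r) {
  a <- intron_chain(tx); b <- intron_chain(r)
  if (nrow(a) == 0L && nrow(b) == 0L)
    return(if (.exonic_overlap_bp(tx, r) > 0L) "matches_annotated" else NA_character_)
  if (.chains_equal(a, b)) return("matches_annotated")
  shared <- .n_shared_introns(a, b)
  exonic <- .exonic_overlap_bp(tx, r)
  if (shared >= 1L || exonic > 0L) {
    side <- .shared_end(a, b)
    if (!is.null(side)) {
      ## splice chains share one genomic end and differ only at the other;
      ## map the differing genomic side to the transcript 5'/3' side
      if (tx$strand == "+")
        return(if (side == "suffix") "five_prime_difference" else "three_prime_difference")
      return(if (side == "prefix") "five_prime_difference" else "three_prime_difference")
    }
    return("novel_isoform")
  }
  sp <- tx_span(tx)
  within_intron <- length(r$introns) &&
    any(IRanges::start(r$introns) <= sp[1] & IRanges::end(r$introns) >= sp[2])
  if (within_intron) return("intronic")
  NA_character_
}

#' Classify one assembled transcript against a reference gene set
#'
#' An exact intron-chain match on the same strand (identical ordered intron
#' set; single-exon models compared by exonic overlap) matches the
#' annotation regardless of terminal-exon end differences — splice
#' junctions anchor identity, terminal ends carry unlimited slack. A
#' transcript sharing at least one intron or one exonic base but differing
#' is a novel isoform, refined to a 5'/3' difference when the splice chains
#' differ only at that transcript end. A transcript wholly inside an
#' annotated intron is intronic; one overlapping no same-strand gene is
#' intergenic.
#'
#' @param tx a `pg_transcript` (e.g. from [parse_gtf()]).
#' @param gs reference `pg_geneset`.
#' @param idx optional prebuilt index of `gs`.
#' @return a single category name.
#' @export
classify_transcript <- function(tx, gs, idx = NULL) {
  if (is.null(idx)) idx <- build_interval_index(gs)
  sp <- tx_span(tx)
  hits <- query_index(idx, tx$chrom, sp[1], sp[2], strand = tx$strand,
                      mode = "same", what = "transcripts")
  if (!nrow(hits)) return("intergenic")
  cats <- vapply(hits$tx_id, function(tid)
    .tx_vs_ref(tx, gs$transcripts[[tid]]), character(1))
  cats <- cats[!is.na(cats)]
  if (!length(cats)) return("intergenic")
  .tx_priority[min(match(cats, .tx_priority))]
}

#' Classify all transcripts of a gene set against a reference
#'
#' @param txs `pg_geneset` of assembled transcripts.
#' @param gs reference `pg_geneset`.
#' @return data frame with `tx_id` and `category`.
#' @export
classify_transcripts <- function(txs, gs) {
  idx <- build_interval_index(gs)
  data.frame(
    tx_id = names(txs$transcripts),
    category = vapply(txs$transcripts, classify_transcript, character(1),
                      gs = gs, idx = idx),
    row.names = NULL)
}

#' Assign CXT identifiers to novel transcripts
#'
#' Ids `CXT.N` are assigned in deterministic (chromosome, start, end,
#' transcript id) sort order, so the mapping is stable across reruns and
#' input shufflings.
#'
#' @param novel_txs `pg_geneset` (or list of `pg_transcript`) of the novel
#'   transcripts.
#' @return named character vector: transcript id -> CXT id.
#' @export
assign_cxt_ids <- function(novel_txs) {
  txs <- if (is(novel_txs, "pg_geneset")) novel_txs$transcripts else novel_txs
  if (!length(txs)) return(setNames(character(), character()))
  spans <- t(vapply(txs, tx_span, integer(2)))
  ids <- vapply(txs, `[[`, character(1), "id")
  chroms <- vapply(txs, `[[`, character(1), "chrom")
  ord <- order(chroms, spans[, 1], spans[, 2], ids, method = "radix")
  setNames(paste0("CXT.", seq_along(ord)), ids[ord])
}

#' Mean exons per transcript by group
#'
#' @param txs `pg_geneset` or list of `pg_transcript`.
#' @param grouping factor/character vector, one entry per transcript (a
#'   single value is recycled).
#' @return data frame with `group`, `n_transcripts`, `mean_exons` (exact)
#'   and `mean_exons_1dp` (half-up to one decimal, the display value).
#'   Factor levels with no members are omitted with a warning.
#' @export
exon_stats <- function(txs, grouping = "all") {
  txl <- if (is(txs, "pg_geneset")) txs$transcripts else txs
  n_ex <- vapply(txl, function(t) length(t$exons), integer(1))
  if (length(grouping) == 1L) grouping <- rep(grouping, length(txl))
  stopifnot(length(grouping) == length(txl))
  grouping <- as.factor(grouping)
  empty <- setdiff(levels(grouping), unique(as.character(grouping)))
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  means <- tapply(n_ex, droplevels(grouping), mean)
  data.frame(group = names(means),
             n_transcripts = as.integer(table(droplevels(grouping))[names(means)]),
             mean_exons = as.numeric(means),
             mean_exons_1dp = round_half_up(as.numeric(means), 1),
             row.names = NULL)
}

#' Tissue-specificity distribution of expression products
#'
#' @param m product-by-tissue abundance (or logical presence) matrix with
#'   named columns; a product is detected in a tissue when its cell exceeds
#'   `threshold`. Products detected nowhere are disallowed.
#' @param threshold detection cutoff on abundance (default 0: any non-zero
#'   abundance counts as detected; the cutoff is a user parameter, not a
#'   fixed rule).
#' @return list with `histogram` (named integer vector over 1..n_tissues:
#'   number of products detected in exactly that many tissues) and
#'   `fraction_single` (proportion of products detected in exactly one
#'   tissue).
#' @export
tissue_specificity <- function(m, threshold = 0) {
  stopifnot(is.matrix(m), ncol(m) >= 1L)
  det <- m > threshold
  k <- rowSums(det)
  if (any(k == 0L))
    stop("product(s) detected in no tissue at this threshold: ",
         paste(head(rownames(det)[k == 0L], 5), collapse = ", "))
  hist <- table(factor(k, levels = seq_len(ncol(m))))
  list(histogram = setNames(as.integer(hist), names(hist)),
       fraction_single = unname(mean(k == 1L)))
}

#' Transfer known miRNA names to predicted miRNAs by coordinate
#'
#' A prediction takes a known mature miRNA's name when both interval ends
#' lie within 5 nucleotides of the known mature coordinates on the same
#' strand; if several known matures qualify, the nearest by
#' `|dstart| + |dend|` wins, ties broken by lexicographic name. Failing
#' that, any same-strand overlap (>= 1 bp) with a known primary miRNA
#' transcript transfers the primary's name. Otherwise the prediction keeps
#' its own (novel) id.
#'
#' @param predicted data frame with `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param known_mature,known_primary data frames with `name`, `chrom`,
#'   `start`, `end`, `strand` (either may have zero rows).
#' @param tolerance maximum end shift for mature-name transfer (nt).
#' @return `predicted` with added columns `name` and `name_source`
#'   (`"mature"`, `"primary"` or `"novel"`).
#' @export
transfer_mirna_names <- function(predicted, known_mature, known_primary,
                                 tolerance = 5L) {
  n <- nrow(predicted)
  name <- predicted$id
  source <- rep("novel", n)
  for (i in seq_len(n)) {
    p <- predicted[i, ]
    if (nrow(known_mature)) {
      km <- known_mature[known_mature$chrom == p$chrom &
                           known_mature$strand == p$strand, , drop = FALSE]
      if (nrow(km)) {
        ds <- abs(km$start - p$start); de <- abs(km$end - p$end)
        ok <- ds <= tolerance & de <= tolerance
        if (any(ok)) {
          km <- km[ok, , drop = FALSE]
          o <- order(ds[ok] + de[ok], km$name, method = "radix")
          name[i] <- km$name[o[1]]
          source[i] <- "mature"
          next
        }
      }
    }
    if (nrow(known_primary)) {
      kp <- known_primary[known_primary$chrom == p$chrom &
                            known_primary$strand == p$strand &
                            known_primary$start <= p$end &
                            known_primary$end >= p$start, , drop = FALSE]
      if (nrow(kp)) {
        ovl <- pmin(kp$end, p$end) - pmax(kp$start, p$start) + 1L
        o <- order(-ovl, kp$name, method = "radix")
        name[i] <- kp$name[o[1]]
        source[i] <- "primary"
      }
    }
  }
  predicted$name <- name
  predicted$name_source <- source
  predicted
}
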