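## Exact peptide-to-genome mapping via the six frame translations, the
## single-locus filter, and annotated/novel partitioning against reference
## protein sets.

## Cache of the six frame translations per chromosome; reused by the
## mapper and by the fixture generator's uniqueness checks.
frame_cache <- function(genome) {
  genome <- check_genome(genome)
  lapply(genome, translate_six_frames)
}

## All loci of one peptide given a frame cache. Matching is full-chromosome
## (not segment-wise), so segment boundaries cannot hide occurrences; '*'
## never matches because accepted peptides are stop-free.
.peptide_loci_one <- function(pep, cache, chrom_lens) {
  out <- list()
  for (ch in names(cache)) {
    for (f in cache[[ch]]) {
      m <- gregexpr(pep, f$aa, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (pos in as.integer(m)) {  # 1-based aa position in the frame
        g <- segment_to_genomic(
          list(chrom = ch, strand = f$strand, frame = f$frame,
               aa_start = 0L, aa_seq = f$aa),
          pep_aa_offset = pos - 1L, pep_len = nchar(pep),
          chrom_len = chrom_lens[[ch]])
        out[[length(out) + 1L]] <-
          data.frame(peptide = pep, chrom = ch, strand = f$strand,
                     frame = f$frame, start = g$start, end = g$end)
      }
    }
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Map peptides exactly onto the six-frame translation of a genome
#'
#' Every exact, stop-free occurrence of each peptide in any of the six
#' reading frames of any chromosome is reported with its genomic interval
#' (1-based closed, width `3 * nchar(peptide)`); `n_loci_total` counts the
#' genome-wide loci of the peptide. Matching is literal character equality
#' (I/L are distinct; 'X' in the translation only matches 'X' in the
#' peptide).
#'
#' @param peptides character vector of '*'-free peptide sequences.
#' @param genome named character vector of chromosome sequences.
#' @return data frame of loci (`peptide`, `chrom`, `strand`, `frame`,
#'   `start`, `end`, `n_loci_total`); peptides with no locus contribute no
#'   rows and are listed in the `unmatched` attribute.
#' @export
map_peptides <- function(peptides, genome) {
  peptides <- unique(peptides)
  stopifnot(length(peptides) >= 1L, !any(grepl("*", peptides, fixed = TRUE)))
  genome <- check_genome(genome)
  cache <- frame_cache(genome)
  chrom_lens <- nchar(genome)
  rows <- lapply(peptides, .peptide_loci_one, cache = cache,
                 chrom_lens = chrom_lens)
  found <- !vapply(rows, is.null, logical(1))
  out <- if (any(found)) do.call(rbind, rows[found]) else
    data.frame(peptide = character(), chrom = character(), strand = character(),
               frame = integer(), start = integer(), end = integer())
  tab <- table(out$peptide)
  out$n_loci_total <- as.integer(tab[out$peptide])
  out <- out[order(out$peptide, out$chrom, out$start, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- peptides[!found]
  out
}

#' Keep only peptides that map to a single genomic location
#'
#' @param loci data frame from [map_peptides()].
#' @return rows of peptides with `n_loci_total == 1`.
#' @export
filter_unique_locus <- function(loci) {
  out <- loci[loci$n_loci_total == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition peptides into annotated and novel
#'
#' A peptide is annotated iff it occurs as an exact substring of any
#' protein in any of the supplied annotated protein sets; all remaining
#' peptides map only to regions currently characterized as non-coding and
#' are designated novel (proteogenomic) peptides.
#'
#' @param peptides character vector of peptide sequences.
#' @param protein_sets named list of protein sets, each a character vector
#'   (or `AAStringSet`) of protein sequences.
#' @return data frame with `peptide`, `annotated` (logical) and `sources`
#'   (comma-joined names of the sets containing the peptide).
#' @export
flag_annotated <- function(peptides, protein_sets) {
  stopifnot(is.list(protein_sets), length(protein_sets) >= 1L)
  if (is.null(names(protein_sets)))
    names(protein_sets) <- paste0("set", seq_along(protein_sets))
  ## collapse each set with a non-residue separator so substrings cannot
  ## span entries
  blobs <- lapply(protein_sets, function(s) {
    if (is(s, "AAStringSet")) s <- as.character(s)
    paste(s, collapse = "\1")
  })
  hit <- vapply(names(blobs), function(nm)
    vapply(peptides, function(p) grepl(p, blobs[[nm]], fixed = TRUE),
           logical(1)),
    logical(length(peptides)))
  hit <- matrix(hit, nrow = length(peptides),
                dimnames = list(NULL, names(blobs)))
  data.frame(peptide = peptides,
             annotated = rowSums(hit) > 0,
             sources = apply(hit, 1, function(r)
               paste(colnames(hit)[r], collapse = ",")))
}
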