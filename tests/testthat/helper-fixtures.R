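# Shared fixtures and independent brute-force oracles.

# Toy two-exon coding transcript used across annotation/classifier tests:
# exons [1001,1600] and [2001,2600], CDS [1201,1600]+[2001,2400].
toy_transcript <- function(strand = "+") {
  new_transcript("T1", "G1", "chr1", strand,
                 exons = cbind(c(1001L, 2001L), c(1600L, 2600L)),
                 cds = cbind(c(1201L, 2001L), c(1600L, 2400L)))
}

toy_gff3_lines <- function(with_cds = TRUE, exon_order = 1:2) {
  ex <- c("chr1\ttoy\texon\t1001\t1600\t.\t+\t.\tID=T1.e1;Parent=T1",
          "chr1\ttoy\texon\t2001\t2600\t.\t+\t.\tID=T1.e2;Parent=T1")[exon_order]
  c("##gff-version 3",
    "chr1\ttoy\tgene\t1001\t2600\t.\t+\t.\tID=G1",
    "chr1\ttoy\tmRNA\t1001\t2600\t.\t+\t.\tID=T1;Parent=G1",
    ex,
    if (with_cds) c("chr1\ttoy\tCDS\t1201\t1600\t.\t+\t0\tID=T1.c;Parent=T1",
                    "chr1\ttoy\tCDS\t2001\t2400\t.\t+\t2\tID=T1.c;Parent=T1"))
}

write_toy_gff3 <- function(..., file = tempfile(fileext = ".gff3")) {
  writeLines(toy_gff3_lines(...), file)
  file
}

# random genome as a named character vector
random_genome <- function(n_chroms = 2, len = 2000, seed = 1) {
  withr::with_seed(seed, setNames(
    vapply(seq_len(n_chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)),
    paste0("chr", seq_len(n_chroms))))
}

# Independent oracle: all-pairs overlap scan over transcript spans.
brute_overlap_scan <- function(gs, chrom, start, end, strand = NA,
                               mode = "any") {
  hits <- character()
  for (t in gs$transcripts) {
    sp <- c(min(IRanges::start(t$exons)), max(IRanges::end(t$exons)))
    if (t$chrom != chrom || sp[1] > end || sp[2] < start) next
    if (mode == "same" && t$strand != strand) next
    if (mode == "opposite" && t$strand == strand) next
    hits <- c(hits, t$id)
  }
  sort(hits)
}

# Independent oracle: per-position codon-table scan of both strands (no
# shared code path with map_peptides beyond the genetic-code table).
brute_peptide_scan <- function(pep, genome) {
  L <- nchar(pep)
  pp <- strsplit(pep, "")[[1]]
  gc_tab <- Biostrings::GENETIC_CODE
  out <- list()
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    n <- nchar(seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      # amino acid encoded by the codon starting at every position
      aa_at <- unname(gc_tab[substring(s, 1:(n - 2), 3:n)])
      aa_at[is.na(aa_at)] <- "X"
      for (p in seq_len(n - 3 * L + 1)) {
        if (all(aa_at[p + 3 * (seq_len(L) - 1)] == pp)) {
          if (strand == "+") {
            st <- p; en <- p + 3 * L - 1
          } else {
            st <- n - (p + 3 * L - 1) + 1; en <- n - p + 1
          }
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, strand = strand, start = st, end = en,
            frame = (p - 1) %% 3)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}
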