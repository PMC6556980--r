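# Loci are built around the toy transcript: exons [1001,1600]+[2001,2600],
# CDS [1201,1600]+[2001,2400], intron [1601,2000].
toy_gs <- function(strand = "+") new_geneset(list(toy_transcript(strand)),
                                             source_label = "toy")

locus <- function(start, end, strand = "+", chrom = "chr1")
  list(chrom = chrom, strand = strand, start = start, end = end)

test_that("rule-by-rule classification on the toy gene model", {
  gs <- toy_gs()
  # annotation-free desert
  expect_equal(classify_peptide(locus(5000, 5029), gs), "intergenic")
  # wholly inside the intron
  expect_equal(classify_peptide(locus(1700, 1729), gs), "intron")
  # antisense overlap with no same-strand gene is intergenic
  expect_equal(classify_peptide(locus(1700, 1729, strand = "-"), gs),
               "intergenic")
  # CDS overlap in a shifted frame; CDS frame at 1201 is phase 0, so a
  # peptide starting at 1202 is out of frame
  expect_equal(classify_peptide(locus(1202, 1231), gs), "coding_out_of_frame")
  # in-frame peptide abutting the CDS start from upstream
  expect_equal(classify_peptide(locus(1171, 1200), gs), "nter_extension")
  # in-frame but separated from the CDS start stays a UTR call
  expect_equal(classify_peptide(locus(1051, 1080), gs), "utr5")
  # in-frame continuation downstream of the CDS stop
  expect_equal(classify_peptide(locus(2401, 2430), gs), "cter_extension")
  # inside the 3' UTR with a gap from the stop
  expect_equal(classify_peptide(locus(2450, 2479), gs), "utr3")
  # crossing the transcript's 5'-most boundary
  expect_equal(classify_peptide(locus(985, 1014), gs), "exon5_extension")
  # crossing the 3'-most boundary
  expect_equal(classify_peptide(locus(2590, 2619), gs), "exon3_extension")
})

test_that("strand symmetry mirrors the terminal categories", {
  gs <- toy_gs("-")
  # on the minus strand the CDS 5' terminus is at 2400
  expect_equal(classify_peptide(locus(2401, 2430, strand = "-"), gs),
               "nter_extension")
  expect_equal(classify_peptide(locus(1171, 1200, strand = "-"), gs),
               "cter_extension")
  expect_equal(classify_peptide(locus(2450, 2479, strand = "-"), gs), "utr5")
  expect_equal(classify_peptide(locus(985, 1014, strand = "-"), gs),
               "exon3_extension")
  expect_equal(classify_peptide(locus(1700, 1729, strand = "-"), gs),
               "intron")
})

test_that("noncoding transcript exons classify transcript_noncoding", {
  nc <- new_transcript("N1", "GN", "chr1", "+",
                       exons = cbind(c(7001L, 7501L), c(7300L, 7800L)))
  gs <- new_geneset(list(nc))
  expect_equal(classify_peptide(locus(7050, 7079), gs), "transcript_noncoding")
  expect_equal(classify_peptide(locus(7350, 7379), gs), "intron")
})

test_that("classification against two annotations is independent per set", {
  gs_a <- toy_gs()
  gs_empty <- new_geneset(list(), source_label = "empty")
  loci <- data.frame(peptide = "X", chrom = "chr1", strand = "+",
                     start = 1700L, end = 1729L)
  pairs <- classify_against_two(loci, gs_a, gs_empty)
  expect_equal(pairs$category_a, "intron")
  expect_equal(pairs$category_b, "intergenic")
  # identical annotations agree everywhere
  pairs2 <- classify_against_two(loci, gs_a, gs_a)
  expect_equal(pairs2$category_a, pairs2$category_b)
})

test_that("the novelty cross-tab counts pairs under the declared reading", {
  s <- summarize_novelty(data.frame(category_a = "intron",
                                    category_b = "intron"))
  r <- s[s$category == "intron", ]
  expect_equal(c(r$both, r$a_only, r$b_only, r$total), c(1L, 0L, 0L, 1L))
  expect_equal(r$both_pct, 100)

  s2 <- summarize_novelty(data.frame(category_a = "intron",
                                     category_b = "intergenic"))
  expect_equal(s2$a_only[s2$category == "intron"], 1L)
  expect_equal(s2$total[s2$category == "intron"], 1L)
  expect_equal(s2$b_only[s2$category == "intergenic"], 1L)
  expect_equal(s2$total[s2$category == "intergenic"], 1L)
})

test_that("row percentages use half-up rounding to one decimal", {
  s <- novelty_summary_from_counts(both = c(87208L, rep(0L, 9)),
                                   a_only = c(3949L, rep(0L, 9)),
                                   b_only = c(15735L, rep(0L, 9)))
  expect_equal(s$total[1], 106892L)
  expect_equal(s$both_pct[1], 81.6)
  expect_equal(s$a_only_pct[1], 3.7)
  expect_equal(s$b_only_pct[1], 14.7)
  # explicit half-up cases that banker's rounding would change
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("summary grand totals are column sums and reconcile", {
  cats <- peptide_categories()
  pairs <- withr::with_seed(7, data.frame(
    category_a = sample(cats, 500, replace = TRUE),
    category_b = sample(cats, 500, replace = TRUE)))
  s <- summarize_novelty(pairs)
  g <- attr(s, "grand")
  expect_equal(unname(g["both"]), sum(s$both))
  expect_equal(unname(g["a_only"]), sum(s$a_only))
  expect_equal(unname(g["b_only"]), sum(s$b_only))
  expect_equal(unname(g["total"]), sum(s$total))
  expect_equal(unname(g["both"] + g["a_only"] + g["b_only"]),
               unname(g["total"]))
  expect_equal(s$total, s$both + s$a_only + s$b_only)
  # every discordant pair contributes once to each side
  expect_equal(unname(g["a_only"]), unname(g["b_only"]))
})

test_that("classification is independent of gene order and chromosome names", {
  ref <- generate_reference(seed = 29, chrom_len = 20000L, n_coding = 4L,
                            n_noncoding = 1L)
  pl <- plant_peptides(ref, counts = c(intron = 2L, utr5 = 2L,
                                       coding_out_of_frame = 2L),
                       seed = 30, n_divergent = 0L, n_duplicates = 0L)
  p <- pl$peptides
  loci <- data.frame(peptide = p$peptide, chrom = p$chrom, strand = p$strand,
                     start = p$start, end = p$end)
  gs <- pl$ref$geneset_a
  base <- classify_peptides(loci, gs)
  shuffled <- new_geneset(rev(gs$transcripts), source_label = "rev")
  expect_equal(classify_peptides(loci, shuffled), base)
  renamed <- gs
  for (i in seq_along(renamed$transcripts))
    renamed$transcripts[[i]]$chrom <- paste0("scaffold_",
                                             renamed$transcripts[[i]]$chrom)
  loci2 <- loci
  loci2$chrom <- paste0("scaffold_", loci2$chrom)
  expect_equal(classify_peptides(loci2, renamed), base)
})
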