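test_that("self-comparison identity: reference transcripts match themselves", {
  ref <- generate_reference(seed = 31, chrom_len = 20000L, n_coding = 4L,
                            n_noncoding = 1L)
  gs <- ref$geneset_a
  idx <- build_interval_index(gs)
  for (t in gs$transcripts)
    expect_equal(classify_transcript(t, gs, idx), "matches_annotated")
})

test_that("toy comparisons: identical chain, intronic and intergenic", {
  gs <- new_geneset(list(toy_transcript("+")))
  # same intron chain with longer terminal exons still matches
  same <- new_transcript("a1", "g", "chr1", "+",
                         cbind(c(900L, 2001L), c(1600L, 2700L)))
  expect_equal(classify_transcript(same, gs), "matches_annotated")
  # single-exon transcript inside the intron
  intr <- new_transcript("a2", "g", "chr1", "+", cbind(1650L, 1949L))
  expect_equal(classify_transcript(intr, gs), "intronic")
  # desert transcript
  far <- new_transcript("a3", "g", "chr1", "+", cbind(7000L, 7799L))
  expect_equal(classify_transcript(far, gs), "intergenic")
  # antisense overlap does not count as genic
  anti <- new_transcript("a4", "g", "chr1", "-",
                         cbind(c(1001L, 2001L), c(1600L, 2600L)))
  expect_equal(classify_transcript(anti, gs), "intergenic")
  # overlapping exons but a shifted splice site -> novel isoform
  shift <- new_transcript("a5", "g", "chr1", "+",
                          cbind(c(1001L, 2013L), c(1600L, 2600L)))
  expect_equal(classify_transcript(shift, gs), "novel_isoform")
})

test_that("planted transcript categories are recovered exactly", {
  fix <- make_fixture_set(seed = 37)
  tc <- classify_transcripts(fix$transcripts, fix$ref$geneset_a)
  m <- merge(tc, fix$tx_truth)
  expect_equal(m$category, m$category_a)
  tcb <- classify_transcripts(fix$transcripts, fix$ref$geneset_b)
  mb <- merge(tcb, fix$tx_truth)
  expect_equal(mb$category, mb$category_b)
})

test_that("CXT identifiers are coordinate-ordered and rerun-stable", {
  txs <- list(
    new_transcript("tB", "g", "chr1", "+", cbind(500L, 900L)),
    new_transcript("tA", "g", "chr2", "+", cbind(100L, 300L)),
    new_transcript("tC", "g", "chr1", "-", cbind(100L, 400L)))
  ids <- assign_cxt_ids(txs)
  expect_equal(ids[c("tC", "tB", "tA")],
               c(tC = "CXT.1", tB = "CXT.2", tA = "CXT.3"))
  expect_identical(assign_cxt_ids(rev(txs))[names(ids)], ids)
  expect_length(assign_cxt_ids(list()), 0L)
})

test_that("exon statistics are plain group means", {
  txs <- list(
    new_transcript("t1", "g", "chr1", "+", cbind(c(1L, 101L), c(50L, 150L))),
    new_transcript("t2", "g", "chr1", "+",
                   cbind(c(1L, 101L, 201L, 301L), c(50L, 150L, 250L, 350L))),
    new_transcript("t3", "g", "chr1", "+", cbind(1L, 50L)))
  s <- exon_stats(txs, c("annotated", "annotated", "novel"))
  expect_equal(s$mean_exons[s$group == "annotated"], 3)
  expect_equal(s$mean_exons_1dp[s$group == "annotated"], 3.0)
  expect_equal(s$mean_exons[s$group == "novel"], 1)
  expect_warning(
    exon_stats(txs, factor(rep("a", 3), levels = c("a", "b"))), "empty")

  # planted means recovered from a generated fixture
  ref <- generate_reference(seed = 41, chrom_len = 30000L, n_coding = 6L,
                            n_noncoding = 0L)
  want <- mean(vapply(ref$geneset_a$transcripts,
                      function(t) length(t$exons), integer(1)))
  expect_equal(exon_stats(ref$geneset_a)$mean_exons, want)
})

test_that("tissue specificity histograms and single-tissue fraction", {
  m <- rbind(p1 = c(1, 0, 0), p2 = c(0, 2, 0), p3 = c(1, 3, 0))
  colnames(m) <- paste0("t", 1:3)
  ts <- tissue_specificity(m)
  expect_equal(ts$histogram, c(`1` = 2L, `2` = 1L, `3` = 0L))
  expect_equal(round_half_up(100 * ts$fraction_single, 1), 66.7)
  expect_equal(sum(ts$histogram), nrow(m))

  all_m <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("t", 1:3)))
  expect_equal(tissue_specificity(all_m)$fraction_single, 0)
  none <- m; none["p2", ] <- 0
  expect_error(tissue_specificity(none), "no tissue")

  # planted fraction recovered exactly
  pm <- make_presence_matrix(n_products = 500L, n_tissues = 13L,
                             single_fraction = 0.98, seed = 43)
  expect_equal(tissue_specificity(pm)$fraction_single, 0.98)
  # the detection threshold is a parameter: raising it above every
  # abundance leaves nothing detected
  expect_error(tissue_specificity(pm, threshold = 1000), "no tissue")
})

test_that("miRNA names transfer by +/-5 nt (mature) or any overlap (primary)", {
  pred <- data.frame(id = paste0("novel", 1:4),
                     chrom = c("chr1", "chr2", "chr1", "chr1"),
                     start = c(103L, 106L, 300L, 900L),
                     end = c(125L, 122L, 320L, 920L), strand = "+")
  mature <- data.frame(name = c("miR-1", "miR-2", "miR-c"),
                       chrom = c("chr1", "chr1", "chr2"),
                       start = c(100L, 104L, 100L), end = c(122L, 126L, 122L),
                       strand = "+")
  primary <- data.frame(name = "mir-p1", chrom = "chr1", start = 320L,
                        end = 500L, strand = "+")
  got <- transfer_mirna_names(pred, mature, primary)
  # shifts (3,3) vs miR-1 and (1,1) vs miR-2: nearest wins
  expect_equal(got$name[1], "miR-2")
  expect_equal(got$name_source[1], "mature")
  # shift (6,0) exceeds the tolerance on one end
  expect_equal(got$name_source[2], "novel")
  # 1 bp overlap with the primary transcript is enough
  expect_equal(got$name[3], "mir-p1")
  expect_equal(got$name_source[3], "primary")
  # no known feature nearby: keeps its novel id
  expect_equal(got$name[4], "novel4")

  # exact tie between two known matures breaks lexicographically
  mat2 <- data.frame(name = c("miR-b", "miR-a"), chrom = "chr1",
                     start = c(101L, 105L), end = c(121L, 125L), strand = "+")
  tie <- transfer_mirna_names(pred[1, ], mat2, primary)
  expect_equal(tie$name, "miR-a")  # shifts (2,4) and (2,0): miR-a nearer
  mat3 <- data.frame(name = c("miR-b", "miR-a"), chrom = "chr1",
                     start = c(101L, 105L), end = c(123L, 127L), strand = "+")
  tie2 <- transfer_mirna_names(pred[1, ], mat3, primary)
  expect_equal(tie2$name, "miR-a")  # shifts (2,2) both: lexicographic
  # strand must agree
  minus <- pred[1, ]; minus$strand <- "-"
  expect_equal(transfer_mirna_names(minus, mature, primary)$name_source,
               "novel")
})
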