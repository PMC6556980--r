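test_that("GFF3 parsing builds a validated gene model", {
  gs <- parse_gff3(write_toy_gff3(), dialect = "ncbi-like")
  expect_s3_class(gs, "pg_geneset")
  expect_equal(length(gs$transcripts), 1L)
  t <- gs$transcripts$T1
  expect_equal(t$biotype, "coding")
  expect_equal(length(t$exons), 2L)
  expect_equal(IRanges::start(t$exons), c(1001L, 2001L))

  # CDS lines removed -> noncoding transcript
  gs2 <- parse_gff3(write_toy_gff3(with_cds = FALSE))
  expect_equal(gs2$transcripts$T1$biotype, "noncoding")

  # exons listed out of coordinate order are stored sorted ascending
  gs3 <- parse_gff3(write_toy_gff3(exon_order = 2:1))
  expect_equal(IRanges::start(gs3$transcripts$T1$exons), c(1001L, 2001L))
})

test_that("malformed GFF3 structures fail loudly", {
  bad <- toy_gff3_lines()
  bad[3] <- sub("Parent=G1", "Parent=GHOST", bad[3])
  f <- tempfile(fileext = ".gff3"); writeLines(bad, f)
  expect_error(parse_gff3(f), "orphan Parent")

  bad <- toy_gff3_lines()
  bad[4] <- sub("Parent=T1", "Parent=TX", bad[4])
  writeLines(bad, f)
  expect_error(parse_gff3(f), "orphan Parent")

  # exon outside the mRNA bounds
  bad <- toy_gff3_lines()
  bad[5] <- "chr1\ttoy\texon\t2001\t2900\t.\t+\t.\tID=T1.e2;Parent=T1"
  writeLines(bad, f)
  expect_error(parse_gff3(f), "outside the transcript bounds")

  # overlapping exons are rejected, not merged
  expect_error(
    new_transcript("T", "G", "chr1", "+",
                   exons = cbind(c(100L, 350L), c(400L, 600L))),
    "overlapping exons")
})

test_that("explicit UTR features override derivation in the ensembl-like dialect", {
  lines <- c(toy_gff3_lines(),
             "chr1\ttoy\tfive_prime_UTR\t1001\t1150\t.\t+\t.\tParent=T1")
  f <- tempfile(fileext = ".gff3"); writeLines(lines, f)
  gs <- parse_gff3(f, dialect = "ensembl-like")
  expect_equal(IRanges::end(gs$transcripts$T1$utr5), 1150L)
  # the ncbi-like dialect ignores the explicit feature and derives exon-CDS
  gs2 <- parse_gff3(f, dialect = "ncbi-like")
  expect_equal(IRanges::end(gs2$transcripts$T1$utr5), 1200L)
})

test_that("region derivation follows exon/CDS set algebra, strand-aware", {
  # plus strand: intron = gap, utr5 left of CDS, utr3 right of CDS
  t <- toy_transcript("+")
  expect_equal(as.data.frame(t$introns)[, 1:2],
               data.frame(start = 1601L, end = 2000L))
  expect_equal(IRanges::start(t$utr5), 1001L)
  expect_equal(IRanges::end(t$utr5), 1200L)
  expect_equal(IRanges::start(t$utr3), 2401L)
  expect_equal(IRanges::end(t$utr3), 2600L)

  # minus strand: utr5/utr3 swap genomic sides
  tm <- toy_transcript("-")
  expect_equal(IRanges::start(tm$utr5), 2401L)
  expect_equal(IRanges::start(tm$utr3), 1001L)

  # single-exon transcript has no introns
  ts <- new_transcript("S", "G", "chr1", "+", cbind(10L, 100L))
  expect_equal(length(ts$introns), 0L)
  expect_equal(length(ts$utr5), 0L)  # noncoding -> empty UTRs and frames
  expect_equal(nrow(ts$cds_frames), 0L)
})

test_that("CDS frame phases walk the spliced CDS 5' to 3'", {
  t <- toy_transcript("+")
  # first block starts at phase 0; second block continues after 400 bases
  expect_equal(t$cds_frames$phase5, c(0L, 400L %% 3L))
  # phase advances by genomic position within a block
  expect_equal(vapply(1201:1206, function(p) cds_phase_at(t, p),
                      integer(1)),
               rep(0:2, 2))
  # on the minus strand the walk reverses: 5'-most base is the highest coord
  tm <- toy_transcript("-")
  ord <- order(-tm$cds_frames$start)
  expect_equal(tm$cds_frames$phase5[ord][1], 0L)
  expect_equal(cds_phase_at(tm, 2400L), 0L)
  expect_equal(cds_phase_at(tm, 2399L), 1L)
})

test_that("GTF parsing groups exons into transcripts and genes", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tasm\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tA";',
    'chr1\tasm\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "tA";',
    'chr1\tasm\texon\t150\t380\t.\t+\t.\tgene_id "g1"; transcript_id "tB";'), f)
  gs <- parse_gtf(f)
  expect_equal(sort(names(gs$transcripts)), c("tA", "tB"))
  expect_equal(length(gs$transcripts$tA$exons), 2L)
  expect_equal(nrow(gs$genes), 1L)  # shared gene_id -> one gene
  expect_equal(gs$transcripts$tA$biotype, "noncoding")

  # empty file -> empty gene set
  writeLines(character(), f)
  expect_equal(length(parse_gtf(f)$transcripts), 0L)

  # missing transcript_id -> parse error
  writeLines('chr1\tasm\texon\t100\t200\t.\t+\t.\tgene_id "g1";', f)
  expect_error(parse_gtf(f), "transcript_id")
})

test_that("interval index equals the brute-force overlap scan", {
  gs <- new_geneset(list(toy_transcript("+")))
  idx <- build_interval_index(gs)
  # toy intron query
  hit <- query_index(idx, "chr1", 1700, 1730)
  expect_equal(hit$tx_id, "T1")
  reg <- query_index(idx, "chr1", 1700, 1730, what = "regions")
  expect_true("intron" %in% reg$type)
  # empty desert and unknown chromosome
  expect_equal(nrow(query_index(idx, "chr1", 9000, 9100)), 0L)
  expect_equal(nrow(query_index(idx, "chrZ", 1, 100)), 0L)

  # randomized property: 400 random queries vs the all-pairs scan
  ref <- generate_reference(seed = 11, chrom_len = 20000L, n_coding = 4L,
                            n_noncoding = 1L)
  idx <- build_interval_index(ref$geneset_a)
  withr::with_seed(5, {
    for (k in 1:400) {
      ch <- sample(names(ref$genome), 1)
      a <- sample.int(19000L, 1); b <- a + sample.int(900L, 1)
      s <- sample(c("+", "-"), 1)
      mode <- sample(c("any", "same", "opposite"), 1)
      got <- sort(unique(query_index(idx, ch, a, b, strand = s,
                                     mode = mode)$tx_id))
      want <- brute_overlap_scan(ref$geneset_a, ch, a, b, strand = s,
                                 mode = mode)
      expect_identical(got, want)
    }
  })
})

test_that("derived regions tile the exon union for coding transcripts", {
  ref <- generate_reference(seed = 3)
  for (t in ref$geneset_a$transcripts) {
    if (t$biotype != "coding") next
    tiles <- c(t$utr5, t$utr3,
               IRanges::IRanges(t$cds_frames$start, t$cds_frames$end))
    expect_equal(sum(IRanges::width(tiles)), sum(IRanges::width(t$exons)))
    expect_equal(sum(IRanges::width(IRanges::reduce(tiles))),
                 sum(IRanges::width(tiles)))  # pairwise disjoint
    expect_equal(sum(IRanges::width(IRanges::intersect(t$introns, t$exons))),
                 0L)
  }
})
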