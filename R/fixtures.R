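## Self-contained synthetic fixtures with ground-truth labels: a random
## genome with planted gene models (coding content written into CDS
## regions), two divergent annotation dialects, peptides planted to realize
## each annotation-relative category, assembled transcripts realizing each
## transcript category, simulated PSM tables with known filter outcomes,
## and a presence matrix with a known single-tissue fraction.
##
## Default scale (2 chromosomes x 50 kb, 10 genes, a few hundred peptides)
## keeps every end-to-end test in the seconds range.

#' Generate a synthetic reference: genome plus two annotation dialects
#'
#' Genes are packed with wide annotation-free deserts between them. Coding
#' genes get 3-4 exons, exonic UTR flanks and a stop-terminated CDS whose
#' codons are written into the genome (so annotated proteins are stop-free
#' by construction); noncoding genes get 2 exons of untouched random
#' sequence. Dialect A carries gene/mRNA/exon/CDS features (UTRs derived);
#' dialect B carries explicit UTR features and, when `edit_b` is on,
#' differs by controlled edits: two coding genes are dropped and two others
#' have their outer terminal-exon ends trimmed, so cross-annotation
#' categories are exercised.
#'
#' @param seed integer seed; outputs are byte-identical given the seed.
#' @param n_chroms,chrom_len genome shape.
#' @param n_coding,n_noncoding gene counts (split across chromosomes).
#' @param edit_b apply the dialect-B edits (drop/trim); with edits off the
#'   two gene sets contain identical models.
#' @return object of class `pg_reference`: `genome` (named character
#'   vector), `geneset_a`, `geneset_b`, `deserts` (data frame of
#'   annotation-free intervals), `genes` (per-gene design metadata),
#'   `seed`, `params`.
#' @export
generate_reference <- function(seed = 1L, n_chroms = 2L, chrom_len = 50000L,
                               n_coding = 8L, n_noncoding = 2L,
                               edit_b = TRUE) {
  stopifnot(n_chroms >= 1L, chrom_len >= 10000L, n_coding >= 0L,
            n_noncoding >= 0L)
  n_genes <- n_coding + n_noncoding
  withr::with_seed(as.integer(seed), {
    genome <- setNames(vapply(seq_len(n_chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = ""), character(1)),
      paste0("chr", seq_len(n_chroms)))
    codons <- aa_codon_table()
    stops <- codons[["*"]]

    chrom_of <- rep(names(genome), length.out = n_genes)
    cursor <- setNames(rep(200L, n_chroms), names(genome))
    genes <- list()
    deserts <- list()
    for (i in seq_len(n_genes)) {
      coding <- i <= n_coding
      ch <- chrom_of[i]
      strand <- sample(c("+", "-"), 1)
      if (coding) {
        n_ex <- sample(3:4, 1)
        ex_w <- sample(200:320, n_ex, replace = TRUE)
        in_w <- sample(260:700, n_ex - 1L, replace = TRUE)
      } else {
        n_ex <- 2L
        ex_w <- sample(200:300, n_ex, replace = TRUE)
        in_w <- sample(300:500, 1L)
      }
      gstart <- cursor[[ch]] + 2800L
      gend <- gstart + sum(ex_w) + sum(in_w) - 1L
      if (gend > chrom_len - 700L)
        stop("infeasible packing: gene ", i, " does not fit on ", ch)
      deserts[[length(deserts) + 1L]] <-
        data.frame(chrom = ch, start = cursor[[ch]] + 400L, end = gstart - 400L)
      cursor[[ch]] <- gend
      ex_starts <- gstart + cumsum(c(0L, head(ex_w, -1L) + in_w))
      exons <- IRanges::IRanges(start = ex_starts, width = ex_w)
      cds <- IRanges::IRanges(); u5 <- u3 <- NA_integer_
      if (coding) {
        tot <- sum(ex_w)
        u5 <- sample(63:117, 1); u3 <- sample(63:117, 1)
        cds_len <- tot - u5 - u3
        u3 <- u3 + cds_len %% 3L
        cds_len <- cds_len - cds_len %% 3L
        ## transcript-coordinate CDS [u5+1, u5+cds_len] mapped to genomic
        txlen <- tot
        tx_lo <- if (strand == "+") u5 + 1L else u3 + 1L  # in genomic-ascending exon walk
        tx_hi <- tx_lo + cds_len - 1L
        offs <- cumsum(c(0L, head(ex_w, -1L)))
        blocks <- list()
        for (k in seq_len(n_ex)) {
          lo <- max(tx_lo, offs[k] + 1L); hi <- min(tx_hi, offs[k] + ex_w[k])
          if (lo <= hi)
            blocks[[length(blocks) + 1L]] <-
              c(ex_starts[k] + lo - offs[k] - 1L, ex_starts[k] + hi - offs[k] - 1L)
        }
        bm <- do.call(rbind, blocks)
        cds <- IRanges::IRanges(start = bm[, 1], end = bm[, 2])
        ## write stop-free coding content (random codons) ending in a stop
        n_codons <- cds_len %/% 3L
        aa <- random_peptide(n_codons - 1L)
        nt <- paste0(reverse_translate(aa, codons), sample(stops, 1))
        nt_fwd <- if (strand == "+") nt else revcomp(nt)
        pos <- 0L
        for (k in seq_len(nrow(bm))) {
          w <- bm[k, 2] - bm[k, 1] + 1L
          piece <- substr(nt_fwd, pos + 1L, pos + w)
          substr(genome[[ch]], bm[k, 1], bm[k, 2]) <- piece
          pos <- pos + w
        }
        ## continue the reading frame stop-free into the UTR margins, so
        ## in-frame terminal extensions of the protein exist in the genome
        cds_lo <- min(bm[, 1]); cds_hi <- max(bm[, 2])
        k5 <- u5 %/% 3L; k3 <- u3 %/% 3L
        nt5 <- reverse_translate(random_peptide(k5), codons)
        nt3 <- reverse_translate(random_peptide(k3), codons)
        if (strand == "+") {
          substr(genome[[ch]], cds_lo - 3L * k5, cds_lo - 1L) <- nt5
          substr(genome[[ch]], cds_hi + 1L, cds_hi + 3L * k3) <- nt3
        } else {
          substr(genome[[ch]], cds_hi + 1L, cds_hi + 3L * k5) <- revcomp(nt5)
          substr(genome[[ch]], cds_lo - 3L * k3, cds_lo - 1L) <- revcomp(nt3)
        }
      }
      genes[[i]] <- list(gene_id = paste0("gene", i), tx_id = paste0("tx", i),
                         chrom = ch, strand = strand, coding = coding,
                         exons = exons, cds = cds,
                         drop_in_b = FALSE, trim_in_b = FALSE)
    }
    for (ch in names(genome))
      deserts[[length(deserts) + 1L]] <-
        data.frame(chrom = ch, start = cursor[[ch]] + 400L, end = chrom_len - 200L)
    deserts <- do.call(rbind, deserts)
    deserts <- deserts[deserts$end - deserts$start + 1L >= 400L, , drop = FALSE]
    rownames(deserts) <- NULL

    if (edit_b && n_coding >= 6L) {
      for (i in (n_coding - 1L):n_coding) genes[[i]]$drop_in_b <- TRUE
      for (i in 1:2) genes[[i]]$trim_in_b <- TRUE
    }

    mk_tx <- function(g, trim = FALSE) {
      ex <- g$exons
      if (trim) {
        trim_nt <- 40L
        if (g$strand == "+") {
          IRanges::start(ex)[1] <- IRanges::start(ex)[1] + trim_nt
        } else {
          IRanges::end(ex)[length(ex)] <- IRanges::end(ex)[length(ex)] - trim_nt
        }
      }
      new_transcript(g$tx_id, g$gene_id, g$chrom, g$strand, ex, g$cds)
    }
    gs_a <- new_geneset(lapply(genes, mk_tx), source_label = "ncbi-like")
    keep_b <- Filter(function(g) !g$drop_in_b, genes)
    gs_b <- new_geneset(lapply(keep_b, function(g) mk_tx(g, trim = g$trim_in_b)),
                        source_label = "ensembl-like")

    structure(list(genome = genome, geneset_a = gs_a, geneset_b = gs_b,
                   deserts = deserts, genes = genes, seed = as.integer(seed),
                   params = list(n_chroms = n_chroms, chrom_len = chrom_len,
                                 n_coding = n_coding, n_noncoding = n_noncoding,
                                 edit_b = edit_b)),
              class = "pg_reference")
  })
}

#' @export
print.pg_reference <- function(x, ...) {
  cat(sprintf("<synthetic reference: %d chrom(s) x %d nt, %d gene(s) (%d coding)>\n",
              length(x$genome), nchar(x$genome[[1]]), length(x$genes),
              sum(vapply(x$genes, `[[`, logical(1), "coding"))))
  invisible(x)
}

## genome-wide locus count of a peptide, given a frame cache
.locus_count <- function(pep, cache) {
  n <- 0L
  for (fr in cache) for (f in fr) {
    m <- gregexpr(pep, f$aa, fixed = TRUE)[[1]]
    if (m[1] != -1L) n <- n + length(m)
  }
  n
}

## extract peptide sequence from a genomic interval on a strand
.interval_peptide <- function(genome, chrom, strand, p1, p2) {
  nt <- substr(genome[[chrom]], p1, p2)
  if (strand == "-") nt <- revcomp(nt)
  translate_nt(nt)
}

## one candidate interval for (gene, category); NULL when the draw is
## geometrically impossible for this gene
.plant_candidate <- function(t, category, L, deserts, chrom_lens) {
  s <- t$strand
  w <- 3L * L
  pick <- function(a, b) if (b < a) NULL else sample(a:b, 1)
  if (category == "intergenic") {
    ok <- deserts[deserts$end - deserts$start + 1L >= w + 20L, , drop = FALSE]
    if (!nrow(ok)) return(NULL)
    d <- ok[sample(nrow(ok), 1), ]
    strand <- sample(c("+", "-"), 1)
    p1 <- pick(d$start, d$end - w + 1L)
    return(list(chrom = d$chrom, strand = strand, p1 = p1, p2 = p1 + w - 1L))
  }
  sp <- tx_span(t)
  if (category == "intron") {
    ir <- t$introns[IRanges::width(t$introns) >= w + 4L]
    if (!length(ir)) return(NULL)
    i <- sample(length(ir), 1)
    p1 <- pick(IRanges::start(ir)[i], IRanges::end(ir)[i] - w + 1L)
  } else if (category == "transcript_noncoding") {
    if (t$biotype != "noncoding") return(NULL)
    ex <- t$exons[IRanges::width(t$exons) >= w + 2L]
    if (!length(ex)) return(NULL)
    i <- sample(length(ex), 1)
    p1 <- pick(IRanges::start(ex)[i], IRanges::end(ex)[i] - w + 1L)
  } else if (category == "coding_out_of_frame") {
    cf <- t$cds_frames
    big <- which(cf$end - cf$start + 1L >= w + 4L)
    if (!length(big)) return(NULL)
    i <- sample(big, 1)
    p1 <- pick(cf$start[i], cf$end[i] - w - 1L)
    pep_ph <- if (s == "+") 0L else (w - 1L) %% 3L
    if (cds_phase_at(t, p1) == pep_ph) p1 <- p1 + 1L  # shift out of frame
  } else if (category %in% c("nter_extension", "cter_extension")) {
    cf <- t$cds_frames
    cds_lo <- min(cf$start); cds_hi <- max(cf$end)
    j <- if (category == "nter_extension") sample(0:2, 1) else 0L
    if (category == "nter_extension") {
      if (s == "+") { p2 <- cds_lo - 1L + 3L * j; p1 <- p2 - w + 1L }
      else { p1 <- cds_hi + 1L - 3L * j; p2 <- p1 + w - 1L }
    } else {
      if (s == "+") { p1 <- cds_hi + 1L; p2 <- p1 + w - 1L }
      else { p2 <- cds_lo - 1L; p1 <- p2 - w + 1L }
    }
    if (p1 < 1L || p2 > chrom_lens[[t$chrom]]) return(NULL)
    return(list(chrom = t$chrom, strand = s, p1 = p1, p2 = p2))
  } else if (category %in% c("utr5", "utr3")) {
    ir <- if (category == "utr5") t$utr5 else t$utr3
    ## leave a >= 1 nt gap at the CDS-proximal end so the plant cannot
    ## qualify as an in-frame terminal extension
    gap_low <- (category == "utr5") == (s == "-")  # CDS-proximal side is the low end?
    ir <- ir[IRanges::width(ir) >= w + 2L]
    if (!length(ir)) return(NULL)
    i <- sample(length(ir), 1)
    a <- IRanges::start(ir)[i]; b <- IRanges::end(ir)[i]
    p1 <- if (gap_low) pick(a + 1L, b - w + 1L) else pick(a, b - w)
  } else if (category %in% c("exon5_extension", "exon3_extension")) {
    m <- sample(3:12, 1)
    at_low <- (category == "exon5_extension") == (s == "+")
    if (at_low) { p2 <- sp[1] + m - 1L; p1 <- p2 - w + 1L }
    else { p1 <- sp[2] - m + 1L; p2 <- p1 + w - 1L }
    if (p1 < 1L || p2 > chrom_lens[[t$chrom]]) return(NULL)
    return(list(chrom = t$chrom, strand = s, p1 = p1, p2 = p2))
  } else stop("unknown category: ", category)
  if (is.null(p1)) return(NULL)
  list(chrom = t$chrom, strand = s, p1 = p1, p2 = p1 + w - 1L)
}

#' Plant peptides realizing each annotation-relative category
#'
#' For each requested category, peptides are drawn whose unique genomic
#' locus satisfies exactly that category's rule under the declared priority
#' order, against both annotation dialects (clean genes — present and
#' unedited in dialect B — are used, so the expected category is the same
#' under both). Single-locus status, stop/ambiguity freedom and novelty
#' (no substring of either annotated protein set) are enforced by rejection
#' sampling against the genome. Optionally also plants divergent peptides
#' in genes dropped from dialect B (expected intron vs A, intergenic vs B)
#' and duplicated peptides written into two desert locations (expected to
#' fail the single-locus filter with two loci).
#'
#' @param ref a `pg_reference`.
#' @param counts named integer vector of per-category peptide counts;
#'   defaults to 3 of each of the ten categories.
#' @param seed integer seed.
#' @param n_divergent peptides planted in dialect-B-dropped genes.
#' @param n_duplicates peptides written at two loci.
#' @return list with `ref` (genome possibly modified by duplicate plants)
#'   and `peptides`, a data frame with the planted sequence, locus, and
#'   expected labels (`category_a`, `category_b`, `expected_n_loci`).
#' @export
plant_peptides <- function(ref, counts = NULL, seed = 1L,
                           n_divergent = 2L, n_duplicates = 1L) {
  if (is.null(counts))
    counts <- setNames(rep(3L, 10L), peptide_categories())
  stopifnot(all(names(counts) %in% peptide_categories()))
  gs_a <- ref$geneset_a
  proteins <- c(get_protein_sequences(gs_a, ref$genome),
                get_protein_sequences(ref$geneset_b, ref$genome))
  blob <- paste(proteins, collapse = "\1")
  chrom_lens <- nchar(ref$genome)
  cache <- frame_cache(ref$genome)

  clean <- Filter(function(g) !g$drop_in_b && !g$trim_in_b, ref$genes)
  pools <- list(
    coding = Filter(function(g) g$coding, clean),
    noncoding = Filter(function(g) !g$coding, clean),
    dropped = Filter(function(g) g$drop_in_b, ref$genes))
  if (any(counts > 0 & names(counts) == "transcript_noncoding") &&
      !length(pools$noncoding))
    stop("category not realizable: transcript_noncoding needs a noncoding gene")
  if (sum(counts[setdiff(names(counts), c("intergenic", "transcript_noncoding"))]) >
      0 && !length(pools$coding))
    stop("category not realizable: no clean coding genes")

  withr::with_seed(as.integer(seed), {
    rows <- list()
    used <- character()
    plant_one <- function(category, gene_pool, label_b = category) {
      for (attempt in 1:400) {
        L <- sample(7:15, 1)
        g <- if (category == "intergenic") NULL else
          gene_pool[[sample(length(gene_pool), 1)]]
        t <- if (is.null(g)) NULL else gs_a$transcripts[[g$tx_id]]
        cand <- .plant_candidate(t, category, L, ref$deserts, chrom_lens)
        if (is.null(cand)) next
        pep <- .interval_peptide(ref$genome, cand$chrom, cand$strand,
                                 cand$p1, cand$p2)
        if (nchar(pep) != L || grepl("[*X]", pep)) next
        if (pep %in% used) next
        if (grepl(pep, blob, fixed = TRUE)) next
        if (.locus_count(pep, cache) != 1L) next
        used <<- c(used, pep)
        return(data.frame(peptide = pep, chrom = cand$chrom,
                          strand = cand$strand, start = cand$p1,
                          end = cand$p2,
                          frame = if (cand$strand == "+") (cand$p1 - 1L) %% 3L
                          else (chrom_lens[[cand$chrom]] - cand$p2) %% 3L,
                          gene_id = if (is.null(g)) NA_character_ else g$gene_id,
                          category_a = category, category_b = label_b,
                          expected_n_loci = 1L))
      }
      stop("could not plant a '", category, "' peptide after 400 attempts")
    }
    for (cat_name in names(counts)) {
      pool <- if (cat_name == "transcript_noncoding") pools$noncoding else pools$coding
      for (k in seq_len(counts[[cat_name]]))
        rows[[length(rows) + 1L]] <- plant_one(cat_name, pool)
    }
    if (n_divergent > 0L && length(pools$dropped)) {
      for (k in seq_len(n_divergent))
        rows[[length(rows) + 1L]] <-
          plant_one("intron", pools$dropped, label_b = "intergenic")
    }
    peptides <- do.call(rbind, rows)

    ## duplicates: write one random peptide's codons at two desert slots
    if (n_duplicates > 0L) {
      occupied <- peptides[, c("chrom", "start", "end")]
      free_slot <- function(w) {
        for (att in 1:200) {
          ok <- ref$deserts[ref$deserts$end - ref$deserts$start + 1L >= w + 40L, ,
                            drop = FALSE]
          d <- ok[sample(nrow(ok), 1), ]
          p1 <- sample(d$start:(d$end - w + 1L), 1)
          clash <- occupied$chrom == d$chrom & occupied$start <= p1 + w - 1L &
            occupied$end >= p1
          if (!any(clash)) return(list(chrom = d$chrom, p1 = p1))
        }
        stop("no free desert slot for a duplicate plant")
      }
      for (k in seq_len(n_duplicates)) {
        for (att in 1:50) {
          pep <- random_peptide(9L)
          if (pep %in% used || grepl(pep, blob, fixed = TRUE)) next
          nt <- reverse_translate(pep)
          w <- nchar(nt)
          s1 <- free_slot(w); s2 <- free_slot(w)
          if (s1$chrom == s2$chrom && abs(s1$p1 - s2$p1) < w + 10L) next
          g2 <- ref$genome
          substr(g2[[s1$chrom]], s1$p1, s1$p1 + w - 1L) <- nt
          substr(g2[[s2$chrom]], s2$p1, s2$p1 + w - 1L) <- nt
          cache2 <- frame_cache(g2)
          if (.locus_count(pep, cache2) != 2L) next
          ## inserted sequence must not disturb earlier plants
          if (any(vapply(peptides$peptide, .locus_count, integer(1),
                         cache = cache2) != 1L)) next
          ref$genome <- g2
          cache <- cache2
          used <- c(used, pep)
          occupied <- rbind(occupied,
                            data.frame(chrom = c(s1$chrom, s2$chrom),
                                       start = c(s1$p1, s2$p1),
                                       end = c(s1$p1, s2$p1) + w - 1L))
          peptides <- rbind(peptides, data.frame(
            peptide = pep, chrom = s1$chrom, strand = "+", start = s1$p1,
            end = s1$p1 + w - 1L, frame = (s1$p1 - 1L) %% 3L,
            gene_id = NA_character_, category_a = "intergenic",
            category_b = "intergenic", expected_n_loci = 2L))
          break
        }
      }
    }
    rownames(peptides) <- NULL
    list(ref = ref, peptides = peptides)
  })
}

#' Plant assembled transcripts realizing each transcript category
#'
#' Transcripts are constructed from clean reference gene models (present
#' and unedited in both dialects): an exact-splice copy with extended
#' terminal ends (matches_annotated); an internally shifted splice site
#' (novel_isoform); models missing the transcript-first or transcript-last
#' exon (5'/3' difference); a single-exon model inside an intron
#' (intronic); and a spliced model in an annotation desert (intergenic).
#'
#' @param ref a `pg_reference`.
#' @param counts named integer vector over [transcript_categories()]
#'   (default 2 of each).
#' @param seed integer seed.
#' @return list with `transcripts` (a `pg_geneset`) and `truth` (data
#'   frame: `tx_id`, `category_a`, `category_b`).
#' @export
plant_transcripts <- function(ref, counts = NULL, seed = 1L) {
  if (is.null(counts))
    counts <- setNames(rep(2L, 6L), transcript_categories())
  stopifnot(all(names(counts) %in% transcript_categories()))
  gs_a <- ref$geneset_a
  clean <- Filter(function(g) g$coding && !g$drop_in_b && !g$trim_in_b,
                  ref$genes)
  if (!length(clean)) stop("no clean multi-exon genes to build transcripts from")
  withr::with_seed(as.integer(seed), {
    txs <- list(); truth <- list(); n <- 0L
    add <- function(exons, strand, chrom, category) {
      n <<- n + 1L
      id <- paste0("asm", n)
      txs[[id]] <<- new_transcript(id, paste0("asmg", n), chrom, strand, exons)
      truth[[id]] <<- data.frame(tx_id = id, category_a = category,
                                 category_b = category)
    }
    for (cat_name in names(counts)) for (k in seq_len(counts[[cat_name]])) {
      g <- clean[[sample(length(clean), 1)]]
      t <- gs_a$transcripts[[g$tx_id]]
      ex <- t$exons
      ne <- length(ex)
      if (cat_name == "matches_annotated") {
        IRanges::start(ex)[1] <- IRanges::start(ex)[1] - sample(10:60, 1)
        IRanges::end(ex)[ne] <- IRanges::end(ex)[ne] + sample(10:60, 1)
        add(ex, t$strand, t$chrom, cat_name)
      } else if (cat_name == "novel_isoform") {
        ## shift an internal splice site: move the start of exon 2 inward
        IRanges::start(ex)[2] <- IRanges::start(ex)[2] + 12L
        add(ex, t$strand, t$chrom, cat_name)
      } else if (cat_name == "five_prime_difference") {
        drop_idx <- if (t$strand == "+") 1L else ne
        add(ex[-drop_idx], t$strand, t$chrom, cat_name)
      } else if (cat_name == "three_prime_difference") {
        drop_idx <- if (t$strand == "+") ne else 1L
        add(ex[-drop_idx], t$strand, t$chrom, cat_name)
      } else if (cat_name == "intronic") {
        ir <- t$introns[IRanges::width(t$introns) >= 240L]
        if (!length(ir)) stop("category not realizable: no wide intron")
        i <- sample(length(ir), 1)
        a <- IRanges::start(ir)[i] + 40L
        add(IRanges::IRanges(a, a + 139L), t$strand, t$chrom, cat_name)
      } else {  # intergenic
        ok <- ref$deserts[ref$deserts$end - ref$deserts$start + 1L >= 700L, ,
                          drop = FALSE]
        d <- ok[sample(nrow(ok), 1), ]
        a <- sample(d$start:(d$end - 650L), 1)
        add(IRanges::IRanges(c(a, a + 400L), c(a + 199L, a + 599L)),
            sample(c("+", "-"), 1), d$chrom, cat_name)
      }
    }
    list(transcripts = new_geneset(txs, source_label = "assembled"),
         truth = do.call(rbind, unname(truth)))
  })
}

#' Simulate a PSM table with known filter outcomes
#'
#' Builds deliberate scenario groups per peptide so that each row's fate
#' under the acceptance rules is known by construction: multi-spectrum
#' hits (kept), single-spectrum hits confirmed by two engines (kept),
#' single-spectrum single-engine hits (rejected by the spectral-count
#' rule), above-threshold E-values (rejected at the threshold), and one
#' spectrum matched in several database partitions (only the best E-value
#' survives deduplication). Decoy rows drawn from the same E-value law are
#' appended for FDR tests.
#'
#' @param peptides character vector of (planted) target peptides.
#' @param seed integer seed.
#' @param evalue_max acceptance threshold the scenarios are built around.
#' @param tissues,engines label pools.
#' @param decoy_fraction decoy rows as a fraction of target rows.
#' @return list with `psms` (data frame in [read_psm_table()] layout, plus
#'   a `scenario` column), and `truth`: `expected_kept_peptides` (peptide
#'   level, target stream) and per-row `expected_psm_survives`.
#' @export
simulate_psms <- function(peptides, seed = 1L, evalue_max = 0.01,
                          tissues = c("tissue1", "tissue2"),
                          engines = c("engineA", "engineB"),
                          decoy_fraction = 0.3) {
  stopifnot(length(peptides) >= 1L)
  withr::with_seed(as.integer(seed), {
    scenarios <- c("multi_spectrum", "single_dual_engine",
                   "single_single_engine", "high_evalue", "multi_partition")
    low_e <- function(n) 10^runif(n, -6, log10(evalue_max) - 0.5)
    rows <- list(); spec_n <- 0L
    new_spec <- function() { spec_n <<- spec_n + 1L; sprintf("spec%05d", spec_n) }
    add <- function(pep, spectrum, evalue, engine, tissue, partition,
                    survives, scenario)
      rows[[length(rows) + 1L]] <<- data.frame(
        spectrum_id = spectrum, peptide = pep, evalue = evalue,
        engine = engine, search_space = "genome", partition_id = partition,
        is_decoy = FALSE, tissue = tissue, scenario = scenario,
        expected_psm_survives = survives)
    kept <- character()
    for (i in seq_along(peptides)) {
      pep <- peptides[i]
      sc <- scenarios[(i - 1L) %% length(scenarios) + 1L]
      ti <- tissues[(i - 1L) %% length(tissues) + 1L]
      if (sc == "multi_spectrum") {
        for (k in 1:2) add(pep, new_spec(), low_e(1), engines[1], ti,
                           "part001", TRUE, sc)
        kept <- c(kept, pep)
      } else if (sc == "single_dual_engine") {
        s <- new_spec()
        for (e in engines) add(pep, s, low_e(1), e, ti, "part001", TRUE, sc)
        kept <- c(kept, pep)
      } else if (sc == "single_single_engine") {
        add(pep, new_spec(), low_e(1), engines[1], ti, "part001", TRUE, sc)
      } else if (sc == "high_evalue") {
        add(pep, new_spec(), 10^runif(1, log10(evalue_max) + 0.5, 0), engines[1],
            ti, "part001", FALSE, sc)
      } else {  # multi_partition
        s <- new_spec()
        ev <- sort(low_e(3))
        for (k in 1:3) add(pep, s, ev[k], engines[1], ti,
                           sprintf("part%03d", k), k == 1L, sc)
        add(pep, new_spec(), low_e(1), engines[1], ti, "part001", TRUE, sc)
        kept <- c(kept, pep)
      }
    }
    target <- do.call(rbind, rows)
    n_decoy <- ceiling(decoy_fraction * nrow(target))
    decoy <- data.frame(
      spectrum_id = vapply(seq_len(n_decoy), function(i) new_spec(),
                           character(1)),
      peptide = vapply(seq_len(n_decoy), function(i) random_peptide(10L),
                       character(1)),
      evalue = 10^runif(n_decoy, -4, 0),
      engine = engines[1], search_space = "genome", partition_id = "part001",
      is_decoy = TRUE,
      tissue = rep_len(tissues, n_decoy), scenario = "decoy",
      expected_psm_survives = NA)
    decoy$expected_psm_survives <- decoy$evalue <= evalue_max
    psms <- rbind(target, decoy)
    rownames(psms) <- NULL
    list(psms = psms,
         truth = list(expected_kept_peptides = sort(unique(kept)),
                      expected_psm_survives = psms$expected_psm_survives))
  })
}

#' Simulate a null PSM set for FDR calibration
#'
#' Equal numbers of target and decoy peptides with E-values drawn from the
#' same law (log-uniform over \[1e-6, 1\]) and two spectra each; after
#' identical filtering, the decoy/target ratio — the FDR — is 100% up to
#' binomial sampling error.
#'
#' @param n peptides per stream.
#' @param seed integer seed.
#' @return PSM data frame.
#' @export
simulate_null_psms <- function(n = 10000L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    mk <- function(prefix, decoy) {
      idx <- seq_len(n)
      data.frame(
        spectrum_id = sprintf("%s_s%06d", prefix, rep(idx, each = 2L) * 2L -
                                rep(c(1L, 0L), n)),
        peptide = rep(sprintf("%s_pep%06d", prefix, idx), each = 2L),
        evalue = 10^runif(2L * n, -6, 0),
        engine = "engineA", search_space = "genome", partition_id = "part001",
        is_decoy = decoy, tissue = "null")
    }
    rbind(mk("t", FALSE), mk("d", TRUE))
  })
}

#' Generate a product-by-tissue presence matrix with a planted
#' single-tissue fraction
#'
#' @param n_products,n_tissues matrix shape.
#' @param single_fraction fraction of products detected in exactly one
#'   tissue (planted exactly, up to rounding to a whole product count).
#' @param seed integer seed.
#' @return numeric abundance matrix (0 = not detected).
#' @export
make_presence_matrix <- function(n_products = 500L, n_tissues = 13L,
                                 single_fraction = 0.98, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    m <- matrix(0, n_products, n_tissues,
                dimnames = list(sprintf("prod%04d", seq_len(n_products)),
                                sprintf("tissue%02d", seq_len(n_tissues))))
    n_single <- round(single_fraction * n_products)
    for (i in seq_len(n_products)) {
      k <- if (i <= n_single) 1L else sample(2:n_tissues, 1)
      cols <- sample(n_tissues, k)
      m[i, cols] <- runif(k, 0.1, 100)
    }
    m
  })
}

#' Compose a complete fixture set
#'
#' Chains the generators: reference, planted peptides (including divergent
#' and duplicated plants), planted transcripts, a simulated PSM table over
#' the planted peptides, and a presence matrix.
#'
#' @param seed integer seed driving every stage (stage seeds are derived
#'   deterministically).
#' @param ... passed to [generate_reference()].
#' @return list of class `pg_fixture`: `ref`, `peptides`, `transcripts`,
#'   `tx_truth`, `psms`, `psm_truth`, `presence`.
#' @export
make_fixture_set <- function(seed = 1L, ...) {
  seed <- as.integer(seed)
  ref <- generate_reference(seed = seed, ...)
  pl <- plant_peptides(ref, seed = seed + 1L)
  tx <- plant_transcripts(pl$ref, seed = seed + 2L)
  sim <- simulate_psms(pl$peptides$peptide[pl$peptides$expected_n_loci == 1L],
                       seed = seed + 3L)
  pres <- make_presence_matrix(seed = seed + 4L)
  structure(list(ref = pl$ref, peptides = pl$peptides,
                 transcripts = tx$transcripts, tx_truth = tx$truth,
                 psms = sim$psms, psm_truth = sim$truth, presence = pres,
                 seed = seed),
            class = "pg_fixture")
}

#' Write a fixture set to disk
#'
#' Emits `genome.fasta`, `annotation_a.gff3` (gene/mRNA/exon/CDS dialect),
#' `annotation_b.gff3` (explicit-UTR dialect), `transcripts.gtf`,
#' `psms.tsv`, `presence.tsv` and `truth.json`.
#'
#' @param fix a `pg_fixture` from [make_fixture_set()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_fixture_set <- function(fix, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(unname(fix$ref$genome))
  names(g) <- names(fix$ref$genome)
  Biostrings::writeXStringSet(g, file.path(outdir, "genome.fasta"))
  write_gff3(fix$ref$geneset_a, file.path(outdir, "annotation_a.gff3"),
             dialect = "ncbi-like")
  write_gff3(fix$ref$geneset_b, file.path(outdir, "annotation_b.gff3"),
             dialect = "ensembl-like")
  write_gtf(fix$transcripts, file.path(outdir, "transcripts.gtf"))
  psm_cols <- c(psm_required_cols, "tissue")
  write.table(fix$psms[, psm_cols], file.path(outdir, "psms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(product = rownames(fix$presence), fix$presence,
                         check.names = FALSE),
              file.path(outdir, "presence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(seed = fix$seed, peptides = fix$peptides,
                transcripts = fix$tx_truth,
                expected_kept_peptides = fix$psm_truth$expected_kept_peptides)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
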