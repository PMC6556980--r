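## Annotation model: strand-aware gene sets parsed from GFF3/GTF, with
## derived introns, UTRs and per-base CDS reading-frame phase.
##
## All internal coordinates are 1-based closed intervals on the forward
## genome strand (the IRanges/GFF convention); "5'" and "3'" are always in
## transcript orientation.

#' Construct a transcript object
#'
#' Validates the structural invariants (sorted, non-overlapping exons; CDS a
#' subset of the exon union) and derives introns, UTRs and CDS frame phases.
#' Explicit UTR intervals, when supplied, override derivation.
#'
#' @param id transcript identifier.
#' @param gene_id parent gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds `IRanges` (or 2-column start/end matrices); `cds` may be
#'   empty.
#' @param utr5,utr3 optional explicit UTR `IRanges`; derived from
#'   `exons`/`cds` when `NULL`.
#' @return an object of class `pg_transcript`.
#' @export
new_transcript <- function(id, gene_id, chrom, strand, exons,
                           cds = IRanges::IRanges(), utr5 = NULL, utr3 = NULL) {
  as_ir <- function(x) {
    if (is.null(x)) return(NULL)
    if (is(x, "IRanges")) return(x)
    if (is.matrix(x)) return(IRanges::IRanges(start = x[, 1], end = x[, 2]))
    stop("intervals must be IRanges or a 2-column matrix")
  }
  sort_ir <- function(ir) ir[order(IRanges::start(ir), IRanges::end(ir))]
  exons <- sort_ir(as_ir(exons))
  cds <- sort_ir(as_ir(cds))
  stopifnot(strand %in% c("+", "-"), length(exons) >= 1L)
  if (length(exons) > 1L && any(IRanges::start(exons)[-1] <= IRanges::end(exons)[-length(exons)]))
    stop("transcript ", id, ": overlapping exons are rejected")
  if (length(cds)) {
    outside <- IRanges::setdiff(cds, exons)
    if (length(outside))
      stop("transcript ", id, ": CDS intervals outside the exon union")
  }
  t <- structure(list(
    id = id, gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, cds = cds,
    biotype = if (length(cds)) "coding" else "noncoding"
  ), class = "pg_transcript")
  reg <- derive_regions(t)
  t$introns <- reg$introns
  t$utr5 <- if (is.null(utr5)) reg$utr5 else sort_ir(as_ir(utr5))
  t$utr3 <- if (is.null(utr3)) reg$utr3 else sort_ir(as_ir(utr3))
  t$cds_frames <- reg$cds_frames
  t
}

#' @export
print.pg_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s], %d exon(s), %d CDS block(s)>\n",
              x$id, x$gene_id, x$chrom, min(IRanges::start(x$exons)),
              max(IRanges::end(x$exons)), x$strand, length(x$exons),
              length(x$cds)))
  invisible(x)
}

#' Derive introns, UTRs and CDS frame phases for a transcript
#'
#' Introns are the gaps between consecutive exons. UTRs are the exonic bases
#' outside the CDS, split 5'/3' of the CDS in transcript orientation. Frame
#' phases (0/1/2 = position within codon) are assigned to every CDS base by
#' walking the spliced CDS 5' to 3'; the GFF3 phase column is never used.
#'
#' @param t a `pg_transcript`.
#' @return list with `introns`, `utr5`, `utr3` (`IRanges`) and `cds_frames`,
#'   a data frame with one row per CDS block (`start`, `end`, `phase5`:
#'   codon phase of the block's transcript-5'-most base).
#' @export
derive_regions <- function(t) {
  stopifnot(is(t, "pg_transcript") || (is.list(t) && !is.null(t$exons)))
  ex <- t$exons
  n <- length(ex)
  introns <- if (n > 1L) {
    IRanges::IRanges(start = IRanges::end(ex)[-n] + 1L,
                     end = IRanges::start(ex)[-1] - 1L)
  } else IRanges::IRanges()
  cds <- t$cds
  if (!length(cds)) {
    return(list(introns = introns, utr5 = IRanges::IRanges(),
                utr3 = IRanges::IRanges(),
                cds_frames = data.frame(start = integer(), end = integer(),
                                        phase5 = integer())))
  }
  noncds <- IRanges::setdiff(ex, cds)
  cds_lo <- min(IRanges::start(cds))
  cds_hi <- max(IRanges::end(cds))
  left <- noncds[IRanges::end(noncds) < cds_lo]
  right <- noncds[IRanges::start(noncds) > cds_hi]
  if (t$strand == "+") { utr5 <- left; utr3 <- right } else { utr5 <- right; utr3 <- left }
  ## phase of the 5'-most base of each CDS block, walking in transcript order
  ord <- if (t$strand == "+") order(IRanges::start(cds)) else order(-IRanges::start(cds))
  w <- IRanges::width(cds)[ord]
  phase5 <- cumsum(c(0L, w[-length(w)])) %% 3L
  cf <- data.frame(start = IRanges::start(cds)[ord], end = IRanges::end(cds)[ord],
                   phase5 = phase5)
  sort_ir <- function(ir) ir[order(IRanges::start(ir), IRanges::end(ir))]
  list(introns = introns, utr5 = sort_ir(utr5), utr3 = sort_ir(utr3),
       cds_frames = cf)
}

## Codon phase of a CDS at genomic position pos (must lie in a CDS block),
## or NA when pos is not coding.
cds_phase_at <- function(t, pos) {
  cf <- t$cds_frames
  i <- which(cf$start <= pos & cf$end >= pos)
  if (!length(i)) return(NA_integer_)
  i <- i[1]
  if (t$strand == "+") (cf$phase5[i] + pos - cf$start[i]) %% 3L
  else (cf$phase5[i] + cf$end[i] - pos) %% 3L
}

tx_span <- function(t) c(min(IRanges::start(t$exons)), max(IRanges::end(t$exons)))

#' Construct a gene set
#'
#' @param transcripts list of `pg_transcript` objects.
#' @param source_label free label naming the annotation source/dialect.
#' @return object of class `pg_geneset`.
#' @export
new_geneset <- function(transcripts, source_label = "unnamed") {
  stopifnot(is.list(transcripts))
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "id")
  genes <- if (length(transcripts)) {
    unique(data.frame(
      gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
      chrom = vapply(transcripts, `[[`, character(1), "chrom"),
      strand = vapply(transcripts, `[[`, character(1), "strand"),
      row.names = NULL))
  } else data.frame(gene_id = character(), chrom = character(), strand = character())
  structure(list(transcripts = transcripts, genes = genes,
                 source_label = source_label), class = "pg_geneset")
}

#' @export
print.pg_geneset <- function(x, ...) {
  cat(sprintf("<gene set '%s': %d gene(s), %d transcript(s), %d coding>\n",
              x$source_label, nrow(x$genes), length(x$transcripts),
              sum(vapply(x$transcripts, function(t) t$biotype == "coding", logical(1)))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## GFF3 / GTF parsing (rtracklayer does the format work)

#' Parse a GFF3 annotation into a gene set
#'
#' Accepts the two annotation dialects this toolkit compares: an NCBI-like
#' dialect carrying gene/mRNA/exon/CDS features (UTRs derived as exon minus
#' CDS), and an Ensembl-like dialect that may additionally carry explicit
#' `five_prime_UTR`/`three_prime_UTR` features, which then override the
#' derivation.
#'
#' @param path GFF3 file.
#' @param dialect `"ncbi-like"` or `"ensembl-like"`.
#' @return a `pg_geneset`.
#' @export
parse_gff3 <- function(path, dialect = c("ncbi-like", "ensembl-like")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) gr$Parent else
    S4Vectors::splitAsList(character(0), factor(integer(0), levels = seq_along(gr)))

  first_parent <- function(i) {
    p <- parents[[i]]
    if (!length(p)) NA_character_ else as.character(p[1])
  }
  gene_idx <- which(type == "gene")
  gene_ids <- ids[gene_idx]
  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA")
  tx_idx <- which(type %in% tx_types)
  tx_ids <- ids[tx_idx]
  if (anyNA(tx_ids)) stop("transcript feature without an ID attribute")

  for (i in tx_idx) {
    p <- first_parent(i)
    if (is.na(p) || !(p %in% gene_ids))
      stop("orphan Parent reference on transcript feature '", ids[i], "'")
  }

  child_types <- c(exon = "exon", cds = "CDS",
                   utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  child <- list()
  for (nm in names(child_types)) {
    idx <- which(type == child_types[[nm]])
    rows <- lapply(idx, function(i) {
      ps <- as.character(parents[[i]])
      if (!length(ps))
        stop("orphan Parent reference on ", child_types[[nm]], " feature",
             if (!is.na(ids[i])) paste0(" '", ids[i], "'") else "")
      data.frame(parent = ps,
                 start = rep(GenomicRanges::start(gr)[i], length(ps)),
                 end = rep(GenomicRanges::end(gr)[i], length(ps)))
    })
    child[[nm]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(parent = character(), start = integer(), end = integer())
    bad <- setdiff(child[[nm]]$parent, tx_ids)
    if (length(bad))
      stop("orphan Parent reference '", bad[1], "' on a ",
           child_types[[nm]], " feature")
  }

  pick <- function(df, tid) {
    df <- df[df$parent == tid, , drop = FALSE]
    if (!nrow(df)) return(IRanges::IRanges())
    IRanges::IRanges(start = df$start, end = df$end)
  }
  txs <- lapply(seq_along(tx_idx), function(k) {
    i <- tx_idx[k]
    tid <- tx_ids[k]
    exons <- pick(child$exon, tid)
    if (!length(exons)) stop("transcript '", tid, "' has no exon features")
    tlo <- GenomicRanges::start(gr)[i]; thi <- GenomicRanges::end(gr)[i]
    if (min(IRanges::start(exons)) < tlo || max(IRanges::end(exons)) > thi)
      stop("transcript '", tid, "': exon outside the transcript bounds")
    u5 <- pick(child$utr5, tid); u3 <- pick(child$utr3, tid)
    new_transcript(
      id = tid, gene_id = first_parent(i),
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons, cds = pick(child$cds, tid),
      utr5 = if (dialect == "ensembl-like" && length(u5)) u5 else NULL,
      utr3 = if (dialect == "ensembl-like" && length(u3)) u3 else NULL)
  })
  new_geneset(txs, source_label = dialect)
}

#' Parse a GTF of assembled transcripts into a gene set
#'
#' Only exon features are used; assembled transcripts carry no CDS and are
#' treated as noncoding models. Transcripts sharing a `gene_id` are grouped
#' under one gene.
#'
#' @param path GTF file (attribute syntax `key "value";`).
#' @return a `pg_geneset`.
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^[^#]", lines)))
    return(new_geneset(list(), source_label = "gtf"))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (!length(gr)) return(new_geneset(list(), source_label = "gtf"))
  if (!("transcript_id" %in% names(S4Vectors::mcols(gr))) ||
      anyNA(gr$transcript_id))
    stop("GTF exon feature missing the transcript_id attribute")
  gid <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id else gr$transcript_id
  gid[is.na(gid)] <- gr$transcript_id[is.na(gid)]
  sp <- split(seq_along(gr), gr$transcript_id)
  txs <- lapply(names(sp), function(tid) {
    idx <- sp[[tid]]
    new_transcript(
      id = tid, gene_id = gid[idx[1]],
      chrom = as.character(GenomicRanges::seqnames(gr))[idx[1]],
      strand = as.character(GenomicRanges::strand(gr))[idx[1]],
      exons = IRanges::IRanges(start = GenomicRanges::start(gr)[idx],
                               end = GenomicRanges::end(gr)[idx]))
  })
  new_geneset(txs, source_label = "gtf")
}

## ---------------------------------------------------------------------------
## Interval index

#' Build a fast interval lookup over a gene set
#'
#' Backed by `GenomicRanges::findOverlaps`; results are defined to equal a
#' brute-force all-pairs overlap scan.
#'
#' @param gs a `pg_geneset`.
#' @return object of class `pg_interval_index`.
#' @export
build_interval_index <- function(gs) {
  stopifnot(is(gs, "pg_geneset"))
  txs <- gs$transcripts
  if (!length(txs)) {
    empty <- GenomicRanges::GRanges()
    return(structure(list(tx = empty, regions = empty, geneset = gs),
                     class = "pg_interval_index"))
  }
  spans <- t(vapply(txs, tx_span, integer(2)))
  tx_gr <- GenomicRanges::GRanges(
    seqnames = vapply(txs, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(start = spans[, 1], end = spans[, 2]),
    strand = vapply(txs, `[[`, character(1), "strand"),
    tx_id = names(txs))
  reg <- do.call(rbind, lapply(txs, function(t) {
    one <- function(ir, what) if (length(ir))
      data.frame(tx_id = t$id, type = what, chrom = t$chrom,
                 start = IRanges::start(ir), end = IRanges::end(ir),
                 strand = t$strand) else NULL
    rbind(one(t$exons, "exon"),
          if (length(t$cds)) data.frame(tx_id = t$id, type = "cds",
                                        chrom = t$chrom,
                                        start = t$cds_frames$start,
                                        end = t$cds_frames$end,
                                        strand = t$strand) else NULL,
          one(t$introns, "intron"), one(t$utr5, "utr5"), one(t$utr3, "utr3"))
  }))
  reg_gr <- if (is.null(reg)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(seqnames = reg$chrom,
                           ranges = IRanges::IRanges(reg$start, reg$end),
                           strand = reg$strand, tx_id = reg$tx_id,
                           type = reg$type)
  structure(list(tx = tx_gr, regions = reg_gr, geneset = gs),
            class = "pg_interval_index")
}

#' Query an interval index
#'
#' @param idx a `pg_interval_index`.
#' @param chrom,start,end query interval (1-based closed).
#' @param strand query strand, used only for `mode` `"same"`/`"opposite"`.
#' @param mode strand handling: any overlap, same strand only, or opposite
#'   strand only.
#' @param what return overlapping transcript spans or typed regions.
#' @return data frame of hits (zero rows for an unknown chromosome).
#' @export
query_index <- function(idx, chrom, start, end, strand = NA,
                        mode = c("any", "same", "opposite"),
                        what = c("transcripts", "regions")) {
  mode <- match.arg(mode)
  what <- match.arg(what)
  gr <- if (what == "transcripts") idx$tx else idx$regions
  cols <- if (what == "transcripts") c("tx_id") else c("tx_id", "type")
  empty <- cbind(data.frame(matrix(character(), 0, length(cols),
                                   dimnames = list(NULL, cols))),
                 data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character()))
  if (!length(gr) || !(chrom %in% GenomeInfoDb::seqlevels(gr))) return(empty)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(gr)
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  j <- S4Vectors::subjectHits(hits)
  if (mode != "any") {
    stopifnot(strand %in% c("+", "-"))
    hs <- as.character(GenomicRanges::strand(gr))[j]
    j <- if (mode == "same") j[hs == strand] else j[hs != strand]
  }
  if (!length(j)) return(empty)
  out <- data.frame(tx_id = gr$tx_id[j],
                    chrom = as.character(GenomicRanges::seqnames(gr))[j],
                    start = GenomicRanges::start(gr)[j],
                    end = GenomicRanges::end(gr)[j],
                    strand = as.character(GenomicRanges::strand(gr))[j])
  if (what == "regions") out <- cbind(out[1], type = gr$type[j], out[-1])
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Derived sequence + writers (used by fixtures and the pipeline)

#' Spliced protein sequences of the coding transcripts of a gene set
#'
#' Concatenates CDS blocks in transcript orientation, translates with the
#' standard code and trims one trailing stop if present.
#'
#' @param gs a `pg_geneset`.
#' @param genome named character vector of chromosome sequences.
#' @return named character vector (transcript id -> protein).
#' @export
get_protein_sequences <- function(gs, genome) {
  genome <- check_genome(genome)
  txs <- Filter(function(t) t$biotype == "coding", gs$transcripts)
  out <- vapply(txs, function(t) {
    cf <- t$cds_frames[order(t$cds_frames$start), , drop = FALSE]
    nt <- paste(substring(genome[[t$chrom]], cf$start, cf$end), collapse = "")
    if (t$strand == "-") nt <- revcomp(nt)
    aa <- translate_nt(nt)
    sub("\\*$", "", aa)
  }, character(1))
  out
}

#' Write a gene set as GFF3
#'
#' The `"ensembl-like"` dialect additionally emits explicit
#' `five_prime_UTR`/`three_prime_UTR` features; the CDS phase column is
#' computed from the derived frame phases.
#'
#' @param gs a `pg_geneset`.
#' @param path output file.
#' @param dialect which feature repertoire to emit.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gs, path, dialect = c("ncbi-like", "ensembl-like")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, src, type, s, e, strand, phase, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, src, type, s, e, strand, phase, attrs)
  src <- if (dialect == "ncbi-like") "refseq_like" else "ensembl_like"
  by_gene <- split(gs$transcripts,
                   vapply(gs$transcripts, `[[`, character(1), "gene_id"))
  for (gid in names(by_gene)) {
    txs <- by_gene[[gid]]
    spans <- t(vapply(txs, tx_span, integer(2)))
    g <- txs[[1]]
    writeLines(fmt(g$chrom, src, "gene", min(spans[, 1]), max(spans[, 2]),
                   g$strand, ".", paste0("ID=", gid)), con)
    for (t in txs) {
      sp <- tx_span(t)
      ttype <- if (t$biotype == "coding") "mRNA" else "transcript"
      writeLines(fmt(t$chrom, src, ttype, sp[1], sp[2], t$strand, ".",
                     paste0("ID=", t$id, ";Parent=", gid)), con)
      for (k in seq_along(t$exons))
        writeLines(fmt(t$chrom, src, "exon", IRanges::start(t$exons)[k],
                       IRanges::end(t$exons)[k], t$strand, ".",
                       paste0("ID=", t$id, ".exon", k, ";Parent=", t$id)), con)
      if (length(t$cds)) {
        cf <- t$cds_frames
        for (k in seq_len(nrow(cf)))
          writeLines(fmt(t$chrom, src, "CDS", cf$start[k], cf$end[k],
                         t$strand, (3L - cf$phase5[k]) %% 3L,
                         paste0("ID=", t$id, ".cds;Parent=", t$id)), con)
      }
      if (dialect == "ensembl-like") {
        emit_utr <- function(ir, type) {
          for (k in seq_along(ir))
            writeLines(fmt(t$chrom, src, type, IRanges::start(ir)[k],
                           IRanges::end(ir)[k], t$strand, ".",
                           paste0("Parent=", t$id)), con)
        }
        emit_utr(t$utr5, "five_prime_UTR")
        emit_utr(t$utr3, "three_prime_UTR")
      }
    }
  }
  invisible(path)
}

#' Write a gene set as a GTF of exon features
#'
#' @param gs a `pg_geneset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in gs$transcripts) {
    for (k in seq_along(t$exons))
      writeLines(sprintf(
        '%s\tassembly\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        t$chrom, IRanges::start(t$exons)[k], IRanges::end(t$exons)[k],
        t$strand, t$gene_id, t$id), con)
  }
  invisible(path)
}
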