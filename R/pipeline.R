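## End-to-end pipeline: chain database build, PSM filtering, mapping and
## classification, and write the report bundle.

#' Pipeline run configuration
#'
#' Defaults are the standard stage parameters: E-value threshold 0.01
#' (inclusive), 600-residue segments with 60-residue overlap, 50 000
#' segments per database file.
#'
#' @param genome path to a genome FASTA, or a named character vector.
#' @param ann_a,ann_b paths to the two reference annotations (GFF3), or
#'   `pg_geneset` objects; `ann_b` may be `NULL` for single-annotation
#'   mode.
#' @param gtf optional assembled-transcript GTF (or `pg_geneset`).
#' @param psms optional PSM TSV path (or data frame).
#' @param outdir output directory for the report bundle.
#' @param evalue_max,seg_len,overlap,per_file,decoy_seed stage parameters.
#' @param build_db write the partitioned six-frame database (skippable to
#'   save time when only the downstream tables are wanted).
#' @return list of class `pg_config`.
#' @export
pg_config <- function(genome, ann_a, ann_b = NULL, gtf = NULL, psms = NULL,
                      outdir, evalue_max = 0.01, seg_len = 600L,
                      overlap = 60L, per_file = 50000L, decoy_seed = 1L,
                      build_db = TRUE) {
  structure(list(genome = genome, ann_a = ann_a, ann_b = ann_b, gtf = gtf,
                 psms = psms, outdir = outdir, evalue_max = evalue_max,
                 db = db_config(seg_len, overlap, per_file, decoy_seed),
                 build_db = isTRUE(build_db)),
            class = "pg_config")
}

.load_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    g <- Biostrings::readDNAStringSet(x)
    setNames(as.character(g), sub("\\s.*$", "", names(g)))
  } else check_genome(x)
}

.load_geneset <- function(x, dialect = "ncbi-like") {
  if (is.null(x)) return(NULL)
  if (is(x, "pg_geneset")) return(x)
  parse_gff3(x, dialect = dialect)
}

#' Run the full proteogenomic pipeline
#'
#' Stages: load inputs; build the partitioned six-frame database and its
#' decoy; filter PSMs (E-value threshold, per-spectrum best match,
#' spectral-count rule) and compute the per-tissue FDR; map the surviving
#' target peptides onto the genome; split annotated from novel against
#' both protein sets; keep single-locus novel peptides and classify them
#' against each annotation; classify assembled transcripts and assign CXT
#' identifiers to the novel ones. Any stage failure aborts with the stage
#' name. All outputs are deterministic given the configuration.
#'
#' @param cfg a [pg_config()].
#' @return (invisibly) list with the report tables: `fdr`, `hits`, `loci`,
#'   `novelty` (a `pg_novelty_summary`, or a per-category count table in
#'   single-annotation mode), `tx_categories`, `cxt_ids`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is(cfg, "pg_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(files = character())
  emit <- function(df, name) {
    p <- file.path(cfg$outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <<- c(out$files, p)
    p
  }

  genome <- stage("load-genome", .load_genome(cfg$genome))
  gs_a <- stage("load-annotation-a", .load_geneset(cfg$ann_a, "ncbi-like"))
  gs_b <- stage("load-annotation-b", .load_geneset(cfg$ann_b, "ensembl-like"))

  if (cfg$build_db) {
    db <- stage("build-db", build_sixframe_db(
      genome, cfg$db, file.path(cfg$outdir, "db")))
    out$files <- c(out$files, db$files, db$decoy_file)
  }

  kept_target <- character()
  if (!is.null(cfg$psms)) {
    psms <- stage("read-psms", if (is.data.frame(cfg$psms)) cfg$psms else
      read_psm_table(cfg$psms))
    accepted <- stage("filter-psms", accept_psms(psms, cfg$evalue_max))
    hits <- stage("spectral-count",
                  spectral_count_filter(aggregate_peptide_hits(accepted)))
    fdr <- stage("fdr", fdr_report(psms, cfg$evalue_max))
    out$hits <- hits
    out$fdr <- fdr
    emit(hits, "accepted_peptides.tsv")
    emit(fdr, "fdr_report.tsv")
    kept_target <- unique(hits$peptide[!hits$is_decoy])
  }

  if (length(kept_target)) {
    loci <- stage("map-peptides", map_peptides(kept_target, genome))
    prot <- stage("protein-sets", {
      sets <- list(a = get_protein_sequences(gs_a, genome))
      if (!is.null(gs_b)) sets$b <- get_protein_sequences(gs_b, genome)
      sets
    })
    ann <- stage("flag-annotated", flag_annotated(unique(loci$peptide), prot))
    novel_peps <- ann$peptide[!ann$annotated]
    uniq <- stage("unique-locus",
                  filter_unique_locus(loci[loci$peptide %in% novel_peps, ,
                                           drop = FALSE]))
    out$loci <- loci
    emit(cbind(loci[, c("chrom", "start", "end", "peptide", "n_loci_total",
                        "strand", "frame")]),
         "peptide_loci.tsv")
    if (!is.null(gs_b)) {
      pairs <- stage("classify-peptides",
                     classify_against_two(uniq, gs_a, gs_b))
      out$novelty <- summarize_novelty(pairs)
      emit(as.data.frame(out$novelty), "novelty_summary.tsv")
      emit(pairs, "peptide_categories.tsv")
    } else {
      cats <- stage("classify-peptides", classify_peptides(uniq, gs_a))
      out$novelty <- as.data.frame(table(
        factor(cats, levels = peptide_categories())),
        responseName = "count", stringsAsFactors = FALSE)
      names(out$novelty)[1] <- "category"
      emit(out$novelty, "novelty_summary.tsv")
    }
  }

  if (!is.null(cfg$gtf)) {
    txs <- stage("read-gtf", if (is(cfg$gtf, "pg_geneset")) cfg$gtf else
      parse_gtf(cfg$gtf))
    tc <- stage("classify-transcripts", classify_transcripts(txs, gs_a))
    if (!is.null(gs_b)) {
      tc$category_b <- classify_transcripts(txs, gs_b)$category
      names(tc)[2] <- "category_a"
    }
    novel_ids <- tc$tx_id[tc[[2]] != "matches_annotated"]
    cxt <- assign_cxt_ids(txs$transcripts[novel_ids])
    out$tx_categories <- tc
    out$cxt_ids <- cxt
    emit(tc, "transcript_categories.tsv")
    emit(data.frame(tx_id = names(cxt), cxt_id = unname(cxt)), "cxt_ids.tsv")
  }

  manifest <- c(
    sprintf("package: genopept %s",
            as.character(utils::packageVersion("genopept"))),
    sprintf("evalue_max: %g", cfg$evalue_max),
    sprintf("seg_len: %d", cfg$db$seg_len),
    sprintf("overlap: %d", cfg$db$overlap),
    sprintf("per_file: %d", cfg$db$per_file),
    sprintf("decoy_seed: %d", cfg$db$decoy_seed))
  writeLines(manifest, file.path(cfg$outdir, "manifest.txt"))
  invisible(out)
}
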