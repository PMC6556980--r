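## Six-frame translation search database: genome-wide frame translations,
## overlapping fixed-length segmentation, partitioned FASTA output with
## coordinate-recoverable headers, and per-entry shuffled decoys.
##
## Frame convention: `frame` is the 0-based offset of the first translated
## base on the reading strand; reverse-strand frames are offsets into the
## reverse complement. Stops are kept as '*' in segments; ambiguous codons
## (any N) become 'X'.

#' Database build configuration
#'
#' Defaults are the standard build parameters for a genome-wide search
#' database: 600-residue segments with a 60-residue overlap (so any peptide
#' up to 60 residues long lies wholly within at least one segment), grouped
#' 50 000 segments per FASTA file.
#'
#' @param seg_len segment length in amino acids.
#' @param overlap between-segment overlap in amino acids; `0 <= overlap <
#'   seg_len`.
#' @param per_file segments per output FASTA file.
#' @param decoy_seed integer seed for decoy shuffling.
#' @return list of class `pg_db_config`.
#' @export
db_config <- function(seg_len = 600L, overlap = 60L, per_file = 50000L,
                      decoy_seed = 1L) {
  seg_len <- as.integer(seg_len); overlap <- as.integer(overlap)
  per_file <- as.integer(per_file)
  stopifnot(overlap >= 0L, overlap < seg_len, per_file >= 1L)
  structure(list(seg_len = seg_len, overlap = overlap, per_file = per_file,
                 decoy_seed = as.integer(decoy_seed)), class = "pg_db_config")
}

#' Translate a chromosome in all six reading frames
#'
#' Forward frames translate `seq[frame+1 ..]`; reverse frames translate the
#' reverse complement offset the same way. Trailing bases that do not fill a
#' codon are dropped.
#'
#' @param seq nucleotide string (A,C,G,T,N).
#' @param chrom_id optional chromosome label attached to the result.
#' @return list of six entries, named `"+0" ... "-2"`, each a list with
#'   `strand`, `frame` and the amino-acid string `aa`.
#' @export
translate_six_frames <- function(seq, chrom_id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence characters outside A,C,G,T,N")
  rc <- revcomp(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      aa <- translate_nt(substr(s, frame + 1L, nchar(s)))
      out[[paste0(strand, frame)]] <-
        list(chrom = chrom_id, strand = strand, frame = frame, aa = aa)
    }
  }
  out
}

#' Split one frame translation into overlapping segments
#'
#' Segments start at amino-acid offset 0 and step by `seg_len - overlap`;
#' emission stops as soon as a segment's end reaches the frame length, so
#' the final segment may be short but coverage is total. A frame shorter
#' than `seg_len` yields a single full-length segment.
#'
#' @param frame_aa amino-acid string of one frame.
#' @param cfg a [db_config()].
#' @param chrom,strand,frame coordinates attached to each segment.
#' @return data frame with one row per segment: `chrom`, `strand`, `frame`,
#'   `aa_start` (0-based offset within the frame) and `aa_seq`.
#' @export
segment_frame <- function(frame_aa, cfg = db_config(), chrom = NA_character_,
                          strand = NA_character_, frame = NA_integer_) {
  n <- nchar(frame_aa)
  if (n == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      frame = integer(), aa_start = integer(),
                      aa_seq = character()))
  step <- cfg$seg_len - cfg$overlap
  starts <- integer()
  s <- 0L
  repeat {
    starts <- c(starts, s)
    if (s + cfg$seg_len >= n) break
    s <- s + step
  }
  ends <- pmin(starts + cfg$seg_len, n)  # exclusive aa offsets
  data.frame(chrom = chrom, strand = strand, frame = frame,
             aa_start = starts,
             aa_seq = substring(frame_aa, starts + 1L, ends))
}

#' Build all six-frame segments of a genome
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param cfg a [db_config()].
#' @return data frame of segments across all chromosomes and frames, in
#'   deterministic (chromosome, strand, frame, offset) order.
#' @export
sixframe_segments <- function(genome, cfg = db_config()) {
  genome <- check_genome(genome)
  out <- lapply(names(genome), function(ch) {
    fr <- translate_six_frames(genome[[ch]], chrom_id = ch)
    do.call(rbind, lapply(fr, function(f)
      segment_frame(f$aa, cfg, chrom = ch, strand = f$strand, frame = f$frame)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

segment_header <- function(seg)
  sprintf("sf|%s|%s|%d|%d", seg$chrom, seg$strand, seg$frame, seg$aa_start)

#' Parse a segment FASTA header back to coordinates
#'
#' Inverts the header grammar `sf|<chrom>|<strand>|<frame>|<aa_start>`.
#'
#' @param header header string (without the `>`).
#' @return list with `chrom`, `strand`, `frame`, `aa_start`.
#' @export
parse_segment_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L || parts[1] != "sf")
    stop("not a segment header: ", header)
  list(chrom = parts[2], strand = parts[3],
       frame = as.integer(parts[4]), aa_start = as.integer(parts[5]))
}

#' Write segments as partitioned FASTA files
#'
#' Emits `ceiling(n / per_file)` files named `<prefix>_partNNN.fasta`;
#' headers encode (chromosome, strand, frame, amino-acid offset) so that any
#' entry can be re-sliced from the genome exactly.
#'
#' @param segments data frame from [sixframe_segments()].
#' @param cfg a [db_config()].
#' @param outdir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of file paths, invisibly.
#' @export
write_partitioned_fasta <- function(segments, cfg = db_config(), outdir,
                                    prefix = "sixframe") {
  stopifnot(nrow(segments) >= 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(segments)
  n_files <- ceiling(n / cfg$per_file)
  headers <- vapply(seq_len(n), function(i) segment_header(segments[i, ]),
                    character(1))
  paths <- character(n_files)
  for (f in seq_len(n_files)) {
    idx <- ((f - 1L) * cfg$per_file + 1L):min(f * cfg$per_file, n)
    set <- Biostrings::AAStringSet(segments$aa_seq[idx])
    names(set) <- headers[idx]
    paths[f] <- file.path(outdir, sprintf("%s_part%03d.fasta", prefix, f))
    Biostrings::writeXStringSet(set, paths[f])
  }
  invisible(paths)
}

#' Shuffle database entries into a decoy set
#'
#' Each entry's residues are independently and uniformly permuted, so length
#' and residue composition are preserved per entry; the result is
#' deterministic given `seed`. This is the randomized-database decoy used for
#' target-decoy FDR estimation.
#'
#' @param entries named character vector of sequences (or `AAStringSet`).
#' @param seed integer seed.
#' @return named character vector, names prefixed `decoy_`.
#' @export
make_decoy <- function(entries, seed = 1L) {
  if (is(entries, "AAStringSet"))
    entries <- setNames(as.character(entries), names(entries))
  stopifnot(is.character(entries), length(entries) >= 1L)
  out <- withr::with_seed(as.integer(seed), {
    vapply(entries, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ch[sample.int(length(ch))], collapse = "")
    }, character(1))
  })
  names(out) <- paste0("decoy_", if (is.null(names(entries)))
    seq_along(entries) else names(entries))
  out
}

#' Map a position inside a segment back to genomic coordinates
#'
#' For forward-strand segments the peptide's first base sits at nucleotide
#' offset `3 * (aa_start + pep_aa_offset) + frame` (0-based); reverse-strand
#' segments are mirrored from the chromosome end. Translating the returned
#' interval on the stated strand reproduces the peptide.
#'
#' @param seg one-row data frame (or list) with `chrom`, `strand`, `frame`,
#'   `aa_start`, `aa_seq`.
#' @param pep_aa_offset 0-based amino-acid offset of the peptide within the
#'   segment.
#' @param pep_len peptide length in amino acids.
#' @param chrom_len chromosome length in nucleotides.
#' @return list with `chrom`, `strand`, `frame`, `start`, `end` (1-based
#'   closed genomic interval of width `3 * pep_len`).
#' @export
segment_to_genomic <- function(seg, pep_aa_offset, pep_len, chrom_len) {
  if (pep_aa_offset < 0L || pep_aa_offset + pep_len > nchar(seg$aa_seq))
    stop("peptide offset out of segment range")
  nt0 <- 3L * (seg$aa_start + pep_aa_offset) + seg$frame  # 0-based on reading strand
  w <- 3L * pep_len
  if (seg$strand == "+") {
    start <- nt0 + 1L
    end <- nt0 + w
  } else {
    start <- chrom_len - nt0 - w + 1L
    end <- chrom_len - nt0
  }
  list(chrom = seg$chrom, strand = seg$strand, frame = seg$frame,
       start = start, end = end)
}

#' Build the full partitioned search database and its decoy
#'
#' Convenience wrapper: segments the genome, writes the partitioned target
#' FASTA files, and writes one decoy file obtained by shuffling the entries
#' of the first partition.
#'
#' @param genome named character vector of chromosome sequences.
#' @param cfg a [db_config()].
#' @param outdir output directory.
#' @param prefix file-name prefix.
#' @return list with `segments` (data frame), `files` (target FASTA paths)
#'   and `decoy_file`.
#' @export
build_sixframe_db <- function(genome, cfg = db_config(), outdir,
                              prefix = "sixframe") {
  segs <- sixframe_segments(genome, cfg)
  files <- write_partitioned_fasta(segs, cfg, outdir, prefix)
  first <- Biostrings::readAAStringSet(files[1])
  decoy <- make_decoy(first, seed = cfg$decoy_seed)
  decoy_file <- file.path(outdir, sprintf("%s_decoy.fasta", prefix))
  set <- Biostrings::AAStringSet(unname(decoy))
  names(set) <- names(decoy)
  Biostrings::writeXStringSet(set, decoy_file)
  list(segments = segs, files = files, decoy_file = decoy_file)
}
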