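## Low-level sequence and arithmetic helpers shared across modules.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (e.g. 0.25 -> 0.3 at one decimal).
#'
#' @param x numeric vector (non-negative values expected).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards values like 81.55 stored as 81.54999...
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Reverse complement of a nucleotide string
#'
#' @param x single character string over A,C,G,T,N.
#' @return reverse-complemented character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string with the standard genetic code
#'
#' Trailing 1-2 nt that do not fill a codon are dropped; codons containing N
#' (or any other ambiguity) translate to 'X'; stop codons are rendered '*'.
#' The first codon is not treated as an initiator, so alternative start
#' codons keep their plain amino acid.
#'
#' @param nt single nucleotide string.
#' @return amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n3 <- nchar(nt) - nchar(nt) %% 3L
  if (n3 == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n3)),
    no.init.codon = TRUE, if.fuzzy.codon = "X"
  ))
}

## Validate a genome: named character vector of uppercase A/C/G/T/N strings.
check_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  stopifnot(is.character(genome), length(genome) >= 1L)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must be a named character vector with unique chromosome ids")
  if (any(nchar(genome) < 1L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("chromosome(s) with characters outside A,C,G,T,N: ",
         paste(names(genome)[bad], collapse = ", "))
  genome
}

## Deterministic reverse-translation table: codons per amino acid.
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

## Sample one codon per residue of an amino-acid string (caller seeds RNG).
reverse_translate <- function(aa, codons = aa_codon_table()) {
  res <- strsplit(aa, "")[[1]]
  paste(vapply(res, function(a) {
    cs <- codons[[a]]
    if (is.null(cs)) stop("no codon for residue ", a)
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

## Random amino-acid string over the 20 standard residues.
random_peptide <- function(len) {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

## stable %s||%s key paste
.key <- function(...) paste(..., sep = "\r")
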