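#' In-memory genome sequence
#'
#' A `genome_seq` holds a set of named contigs as uppercase DNA strings
#' (alphabet A/C/G/T/N). All coordinates in the package are 0-based,
#' half-open and genomic; strand-aware retrieval returns the sequence in
#' transcript orientation.
#'
#' @param contigs named character vector or list of DNA strings; names are
#'   contig identifiers and must be unique.
#' @return an object of class `genome_seq`.
#' @examples
#' g <- genome_seq(c(chrT = "ACGTACGTTTAGGG"))
#' seq_slice(g, "chrT", 0, 4)
#' @export
genome_seq <- function(contigs) {
  nm <- names(contigs)
  contigs <- vapply(contigs, as.character, character(1), USE.NAMES = FALSE)
  names(contigs) <- nm
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    stop("contigs must have unique non-empty names")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain non-ACGTN characters: ",
         paste(names(contigs)[bad], collapse = ", "))
  structure(as.list(contigs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x), "contig(s)\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome a [genome_seq()] object.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome, nchar, integer(1))
}

#' Reverse-complement DNA strings
#'
#' Vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a genomic slice
#'
#' Retrieves `[start, end)` (0-based, half-open) from a contig. For strand
#' `"-"` the reverse complement is returned, i.e. the sequence read in
#' transcript orientation.
#'
#' @param genome a [genome_seq()].
#' @param contig contig name.
#' @param start,end 0-based half-open bounds.
#' @param strand `"+"` or `"-"`.
#' @return a character scalar.
#' @export
seq_slice <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_seq"))
  s <- genome[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  if (start < 0 || end > nchar(s) || start > end)
    stop(sprintf("slice [%d,%d) outside contig %s (length %d)",
                 start, end, contig, nchar(s)))
  out <- substr(s, start + 1L, end)
  if (identical(strand, "-")) out <- revcomp(out) else
    if (!identical(strand, "+")) stop("strand must be '+' or '-'")
  out
}

#' Single base at a genomic position, strand-aware
#' @inheritParams seq_slice
#' @param pos 0-based position.
#' @return one character.
#' @export
base_at <- function(genome, contig, pos, strand = "+") {
  seq_slice(genome, contig, pos, pos + 1L, strand)
}

# IUPAC nucleotide classes used for PAM matching
IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Compile an IUPAC pattern to a regular expression
#' @param pattern IUPAC string, e.g. `"NGG"`.
#' @return anchored regular expression.
#' @keywords internal
iupac_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(ch, names(IUPAC_CLASS))
  if (length(unknown))
    stop("invalid IUPAC code(s): ", paste(unknown, collapse = ","))
  paste0("^", paste(IUPAC_CLASS[ch], collapse = ""), "$")
}

#' Test sequences against an IUPAC pattern
#' @param x character vector of same-length sequences.
#' @param pattern IUPAC pattern of matching length.
#' @return logical vector.
#' @keywords internal
iupac_match <- function(x, pattern) {
  grepl(iupac_regex(pattern), x)
}
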