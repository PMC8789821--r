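# Transcript-model helpers. All coordinates 0-based half-open genomic;
# "transcript order" means 5'->3' of the transcript (descending genomic
# position on '-' transcripts).

#' Genomic positions of a transcript's exonic bases, in transcript order
#' @param tx a `transcript_model`.
#' @return integer vector of 0-based genomic positions.
#' @export
tx_exonic_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq.int(tx$exons[i, "start"], tx$exons[i, "end"] - 1L)))
  if (tx$strand == "-") rev(pos) else pos
}

#' Spliced transcript sequence (transcript orientation)
#' @param tx a `transcript_model`.
#' @param genome a [genome_seq()].
#' @return character scalar.
#' @export
tx_spliced_seq <- function(tx, genome) {
  chunks <- vapply(seq_len(nrow(tx$exons)), function(i)
    seq_slice(genome, tx$contig, tx$exons[i, "start"], tx$exons[i, "end"]),
    character(1))
  s <- paste(chunks, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Genomic positions of the CDS, in transcript (reading-frame) order
#' @inheritParams tx_exonic_positions
#' @return integer vector; empty for non-coding transcripts.
#' @export
tx_cds_positions <- function(tx) {
  if (is.na(tx$cds_start)) return(integer(0))
  pos <- tx_exonic_positions(tx)
  pos[pos >= tx$cds_start & pos < tx$cds_end]
}

#' Spliced CDS sequence in reading-frame orientation
#' @inheritParams tx_spliced_seq
#' @return character scalar ("" for non-coding).
#' @export
tx_cds_seq <- function(tx, genome) {
  pos <- tx_cds_positions(tx)
  if (!length(pos)) return("")
  bases <- strsplit(genome[[tx$contig]], "")[[1]][pos + 1L]
  s <- paste(bases, collapse = "")
  if (tx$strand == "-") chartr("ACGT", "TGCA", s) else s
}

#' Region of a genomic position within one transcript
#'
#' Returns one of `"CDS"`, `"three_prime_UTR"`, `"five_prime_UTR"`,
#' `"intron"`, `"none"` (no overlap). Positions inside non-coding
#' transcripts are classified at intron priority (the region vocabulary
#' has no non-coding-exon category).
#'
#' @param tx a `transcript_model`.
#' @param contig,pos genomic position (0-based).
#' @return character scalar.
#' @export
tx_region <- function(tx, contig, pos) {
  if (tx$contig != contig) return("none")
  span_lo <- tx$exons[1, "start"]
  span_hi <- tx$exons[nrow(tx$exons), "end"]
  if (pos < span_lo || pos >= span_hi) return("none")
  exonic <- any(tx$exons[, "start"] <= pos & pos < tx$exons[, "end"])
  if (!exonic) return("intron")
  if (is.na(tx$cds_start)) return("intron")  # documented non-coding convention
  if (pos >= tx$cds_start && pos < tx$cds_end) return("CDS")
  upstream <- pos < tx$cds_start
  if (tx$strand == "+") {
    if (upstream) "five_prime_UTR" else "three_prime_UTR"
  } else {
    if (upstream) "three_prime_UTR" else "five_prime_UTR"
  }
}

#' Translate codons with the standard genetic code
#' @param codons character vector of 3-mers.
#' @return character vector of single-letter amino acids (`*` = stop).
#' @export
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[toupper(codons)]
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(codons[is.na(aa)], collapse = ","))
  unname(aa)
}

#' Sequence-level validation of transcript models
#'
#' Checks, per coding transcript, that the spliced CDS length is a
#' multiple of 3, starts with ATG and ends with a stop codon. Violations
#' are warnings (annotation builds routinely contain exceptions), returned
#' invisibly as a data.frame.
#'
#' @param transcripts a `transcript_models` list.
#' @param genome a [genome_seq()].
#' @return (invisibly) data.frame of transcript_id/problem.
#' @export
validate_transcripts <- function(transcripts, genome) {
  probs <- list()
  note <- function(id, what)
    probs[[length(probs) + 1L]] <<- data.frame(
      transcript_id = id, problem = what, stringsAsFactors = FALSE)
  for (tx in transcripts) {
    if (is.na(tx$cds_start)) next
    cds <- tx_cds_seq(tx, genome)
    n <- nchar(cds)
    if (n %% 3L != 0L) note(tx$transcript_id,
                            sprintf("CDS length %d not a multiple of 3", n))
    if (substr(cds, 1, 3) != "ATG")
      note(tx$transcript_id, "CDS does not start with ATG")
    last <- substr(cds, n - 2L, n)
    if (n %% 3L == 0L && !last %in% c("TAA", "TAG", "TGA"))
      note(tx$transcript_id, sprintf("CDS ends with %s, not a stop", last))
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(transcript_id = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  if (nrow(out))
    warning("validate_transcripts: ", nrow(out), " problem(s) found")
  invisible(out)
}
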