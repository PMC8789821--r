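#' Read a genome FASTA
#'
#' @param path FASTA file (optionally with .fai alongside; read whole).
#' @return a [genome_seq()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_seq(stats::setNames(as.character(ss), nm))
}

#' Write a genome FASTA
#' @param genome a [genome_seq()].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_seq"))
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read single-nucleotide m6A sites from BED6
#'
#' Each interval must be exactly one base wide (`end == start + 1`) with a
#' `+`/`-` strand in column 6 (the transcript strand). Sites are validated
#' against the genome: the base at the site on the stated strand must be
#' `A`. Structurally malformed lines (wrong field count, non-numeric
#' coordinates) abort with the line number; semantically invalid records
#' (bad strand, wrong width, non-A base, unknown contig, duplicate id) are
#' excluded with a per-record reason and a summary warning.
#'
#' The BED name column is the site id; if it contains a `:` the prefix is
#' taken as the gene symbol (the convention used by [write_m6a_bed()]).
#'
#' @param path BED6 file.
#' @param genome a [genome_seq()] used for base validation.
#' @return data.frame with columns `site_id`, `contig`, `pos` (0-based),
#'   `strand`, `gene`; attributes `n_rejected` and `rejections`
#'   (data.frame of line/reason).
#' @export
read_m6a_bed <- function(path, genome) {
  stopifnot(inherits(genome, "genome_seq"))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  sites <- list()
  rej <- list()
  seen <- character(0)
  clen <- contig_lengths(genome)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop(sprintf("BED parse error at line %d: expected >= 6 fields, got %d",
                   lineno[i], length(f)))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("BED parse error at line %d: non-numeric coordinates",
                   lineno[i]))
    reason <- NULL
    if (end != start + 1L) {
      reason <- sprintf("interval width %d != 1", end - start)
    } else if (!f[6] %in% c("+", "-")) {
      reason <- sprintf("invalid strand '%s'", f[6])
    } else if (!f[1] %in% names(clen)) {
      reason <- sprintf("unknown contig '%s'", f[1])
    } else if (start < 0L || end > clen[[f[1]]]) {
      reason <- "position outside contig bounds"
    } else if (base_at(genome, f[1], start, f[6]) != "A") {
      reason <- sprintf("base on %s strand is '%s', not 'A'",
                        f[6], base_at(genome, f[1], start, f[6]))
    }
    site_id <- if (f[4] %in% c("", ".")) sprintf("site_%d", lineno[i]) else f[4]
    if (is.null(reason) && site_id %in% seen)
      reason <- sprintf("duplicate site_id '%s'", site_id)
    if (!is.null(reason)) {
      rej[[length(rej) + 1L]] <- data.frame(line = lineno[i], reason = reason,
                                           stringsAsFactors = FALSE)
      next
    }
    seen <- c(seen, site_id)
    gene <- if (grepl(":", site_id, fixed = TRUE))
      sub(":.*$", "", site_id) else NA_character_
    sites[[length(sites) + 1L]] <- data.frame(
      site_id = site_id, contig = f[1], pos = start, strand = f[6],
      gene = gene, stringsAsFactors = FALSE)
  }
  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(site_id = character(0), contig = character(0),
               pos = integer(0), strand = character(0),
               gene = character(0), stringsAsFactors = FALSE)
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(line = integer(0), reason = character(0),
               stringsAsFactors = FALSE)
  if (nrow(rejections))
    warning(sprintf("read_m6a_bed: accepted %d site(s), rejected %d record(s)",
                    nrow(out), nrow(rejections)))
  attr(out, "n_rejected") <- nrow(rejections)
  attr(out, "rejections") <- rejections
  out
}

#' Write m6A sites as BED6
#'
#' The name column is `gene:site_id` when a gene symbol is present so that
#' [read_m6a_bed()] round-trips the gene.
#'
#' @param sites data.frame as returned by [read_m6a_bed()].
#' @param path output file.
#' @export
write_m6a_bed <- function(sites, path) {
  nm <- ifelse(is.na(sites$gene) | !nzchar(sites$gene), sites$site_id,
               ifelse(grepl(":", sites$site_id, fixed = TRUE),
                      sites$site_id,
                      paste0(sites$gene, ":", sites$site_id)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t%s",
                     sites$contig, sites$pos, sites$pos + 1L, nm,
                     sites$strand), path)
  invisible(path)
}

#' Read transcript models from a GTF
#'
#' Imports exon and CDS features (via \pkg{rtracklayer}) grouped by
#' `transcript_id`; only the `gene_id` and `transcript_id` attributes are
#' used. GTF 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Exons must be non-overlapping and the CDS
#' must lie inside the exon union; violations abort, naming the transcript.
#'
#' Note: the package convention is that CDS bounds include the stop codon,
#' so a well-formed spliced CDS starts with ATG and ends with a stop.
#'
#' @param path GTF file.
#' @return a `transcript_models` list; each element has `transcript_id`,
#'   `gene`, `contig`, `strand`, `exons` (2-column matrix, 0-based
#'   half-open, sorted), `cds_start`, `cds_end` (NA for non-coding).
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  if (is.null(md$transcript_id) || anyNA(md$transcript_id))
    stop("GTF features lack transcript_id attributes")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene = if (is.null(md$gene_id)) NA_character_ else
      as.character(md$gene_id),
    tx = as.character(md$transcript_id),
    stringsAsFactors = FALSE)
  out <- lapply(split(df, df$tx), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L)
      stop("transcript ", d$tx[1], " has CDS but no exon features")
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("transcript ", d$tx[1], " has overlapping exons")
    if (length(unique(d$strand)) != 1L || !d$strand[1] %in% c("+", "-"))
      stop("transcript ", d$tx[1], " has inconsistent or missing strand")
    cds_start <- cds_end <- NA_integer_
    if (nrow(cds)) {
      cds_start <- min(cds$start)
      cds_end <- max(cds$end)
      inside <- any(ex$start <= cds_start & cds_end <= ex$end) ||
        all(vapply(seq_len(nrow(cds)), function(i)
          any(ex$start <= cds$start[i] & cds$end[i] <= ex$end), logical(1)))
      if (!inside)
        stop("CDS outside exon union for transcript ", d$tx[1])
    }
    structure(list(
      transcript_id = d$tx[1],
      gene = d$gene[1],
      contig = d$contig[1],
      strand = d$strand[1],
      exons = cbind(start = ex$start, end = ex$end),
      cds_start = cds_start,
      cds_end = cds_end), class = "transcript_model")
  })
  structure(out[order(names(out))], class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", length(x), "transcript(s),",
      sum(vapply(x, function(t) !is.na(t$cds_start), logical(1))),
      "coding\n")
  invisible(x)
}

#' Write transcript models as GTF
#'
#' Emits exon and CDS lines with `gene_id`/`transcript_id` attributes in
#' the dialect [read_transcripts()] consumes (round-trip identity on the
#' exon/CDS structure).
#'
#' @param transcripts a `transcript_models` list.
#' @param path output file.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene, tx$transcript_id)
    ex <- sprintf("%s\tm6ascreen\texon\t%d\t%d\t.\t%s\t.\t%s",
                  tx$contig, tx$exons[, "start"] + 1L, tx$exons[, "end"],
                  tx$strand, attrs)
    lines <- c(lines, ex)
    if (!is.na(tx$cds_start)) {
      cds <- cbind(pmax(tx$exons[, "start"], tx$cds_start),
                   pmin(tx$exons[, "end"], tx$cds_end))
      cds <- cds[cds[, 1] < cds[, 2], , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tm6ascreen\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        tx$contig, cds[, 1] + 1L, cds[, 2], tx$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# canonical column order of the guide-library table
LIBRARY_COLUMNS <- c("sgRNA_id", "sequence", "PAM", "contig",
                     "protospacer_start", "strand", "site_id", "gene",
                     "window_position_of_target_A", "bystander_positions",
                     "predicted_consequence")

#' Write a designed guide library as TSV
#'
#' Columns: sgRNA_id, sequence (20 nt), PAM, contig, protospacer_start
#' (0-based), strand, site_id, gene, window_position_of_target_A,
#' bystander_positions (comma-joined window positions, empty if none),
#' predicted_consequence. Round-trips losslessly through
#' [read_library_table()].
#'
#' @param designs design data.frame (see [design_library()]).
#' @param path output file.
#' @export
write_library_table <- function(designs, path) {
  if (is.null(designs) || nrow(designs) == 0L)
    stop("designs must be non-empty")
  if (anyDuplicated(designs$sgRNA_id))
    stop("duplicate sgRNA_id in designs")
  d <- designs
  for (col in LIBRARY_COLUMNS)
    if (is.null(d[[col]])) d[[col]] <- NA
  utils::write.table(d[LIBRARY_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a guide-library table written by [write_library_table()]
#' @param path TSV file.
#' @return design data.frame.
#' @export
read_library_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", na.strings = NULL,
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(LIBRARY_COLUMNS, names(d))
  if (length(missing))
    stop("library table lacks column(s): ", paste(missing, collapse = ", "))
  d$protospacer_start <- as.integer(d$protospacer_start)
  d$window_position_of_target_A <-
    suppressWarnings(as.integer(d$window_position_of_target_A))
  if (anyDuplicated(d$sgRNA_id)) stop("duplicate sgRNA_id in library table")
  d
}

#' Read an sgRNA count table
#'
#' Accepts the common pooled-screen layout `sgRNA <tab> gene <tab>
#' sample1 ...` (the layout of published supplementary count tables) and
#' returns a raw [count_matrix()]. Sample roles and replicate indices are
#' supplied via `sample_meta`, matched to the table's sample columns by
#' name.
#'
#' @param path TSV file.
#' @param sample_meta data.frame with columns `sample`, `role`,
#'   `replicate`; `sample` must match the count-table column names.
#' @param nontargeting optional character vector of sgRNA ids, or a regular
#'   expression matched against ids when length 1 and named pattern-like;
#'   defaults to ids starting with "NTC".
#' @return a raw [count_matrix()].
#' @export
read_count_table <- function(path, sample_meta,
                             nontargeting = "^(NTC|NonTargeting|CTRL)") {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3L || !tolower(names(d)[1]) %in% c("sgrna", "sgrna_id"))
    stop("count table must have header 'sgRNA<tab>gene<tab><samples...>'")
  ids <- as.character(d[[1]])
  genes <- as.character(d[[2]])
  counts <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- ids
  missing <- setdiff(sample_meta$sample, colnames(counts))
  if (length(missing))
    stop("sample_meta sample(s) absent from table: ",
         paste(missing, collapse = ", "))
  counts <- counts[, sample_meta$sample, drop = FALSE]
  is_ntc <- if (length(nontargeting) == 1L)
    grepl(nontargeting, ids) else ids %in% nontargeting
  count_matrix(counts, role = sample_meta$role,
               replicate = sample_meta$replicate,
               gene = genes, nontargeting = is_ntc)
}
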