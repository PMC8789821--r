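#' sgRNA count matrix with sample roles
#'
#' Rows are guides (targeting and non-targeting), columns are samples.
#' Each sample carries a role — `baseline_d0`, `CXCR4neg`, `CXCR4pos`, or
#' a timepoint such as `timepoint_d30` — and a replicate index. Raw
#' counts must be non-negative integers; [normalize_counts()] flips the
#' `normalized` flag and records size factors.
#'
#' @param counts numeric matrix, guides x samples, with rownames.
#' @param role character vector, one role per column.
#' @param replicate integer vector, one replicate index per column.
#' @param gene optional per-guide gene symbols.
#' @param site_id optional per-guide site ids.
#' @param nontargeting logical per-guide flag.
#' @return a `count_matrix`.
#' @export
count_matrix <- function(counts, role, replicate,
                         gene = NULL, site_id = NULL,
                         nontargeting = rep(FALSE, nrow(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have guide rownames")
  if (length(role) != ncol(counts) || length(replicate) != ncol(counts))
    stop("role/replicate must have one entry per sample column")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be >= 0")
  if (any(counts != round(counts))) stop("raw counts must be integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(role, "_r", replicate)
  structure(list(
    counts = counts,
    samples = data.frame(sample = colnames(counts), role = role,
                         replicate = as.integer(replicate),
                         stringsAsFactors = FALSE),
    gene = if (is.null(gene)) rep(NA_character_, nrow(counts)) else gene,
    site_id = if (is.null(site_id)) rep(NA_character_, nrow(counts)) else
      site_id,
    nontargeting = nontargeting,
    normalized = FALSE,
    size_factors = rep(NA_real_, ncol(counts))),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides (%d non-targeting) x %d samples%s\n",
              nrow(x$counts), sum(x$nontargeting), ncol(x$counts),
              if (x$normalized) " [normalized]" else " [raw]"))
  print(x$samples)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

role_columns <- function(x, role) {
  idx <- which(x$samples$role == role)
  if (!length(idx)) stop("no samples with role '", role, "'")
  idx[order(x$samples$replicate[idx])]
}

#' Count guides in pooled-screen FASTQ reads
#'
#' Each read is expected to carry a constant 5' flank, a 20-nt guide
#' insert, then (optionally) a 3' flank. The 5' flank is located by exact
#' match at a 5' stagger offset of 0 to `max_stagger` nt (stagger primers
#' are standard in single-step amplicon protocols); the insert is then
#' looked up against the library by exact 20-mer match. No mismatch
#' rescue is attempted. If fewer than 10% of the first 1000 reads of a
#' file contain the flank the run aborts with diagnostics.
#'
#' @param fastq_paths character vector of FASTQ files, one per sample.
#' @param library design data.frame with `sgRNA_id` and `sequence`
#'   (targeting plus non-targeting guides).
#' @param flank5 constant 5' flank sequence (required).
#' @param flank3 constant 3' flank (unused for matching; documented
#'   amplicon structure).
#' @param sample_meta data.frame with columns `sample`, `role`,
#'   `replicate` aligned with `fastq_paths`.
#' @param max_stagger maximum 5' stagger offset searched (default 8).
#' @param nontargeting logical per-library-row flag (default: ids
#'   starting with NTC).
#' @return raw [count_matrix()]; attribute `unmatched` gives per-sample
#'   unmatched read counts, `total_reads` the per-sample totals.
#' @export
match_and_count <- function(fastq_paths, library, flank5, flank3 = "",
                            sample_meta, max_stagger = 8L,
                            nontargeting = grepl("^NTC", library$sgRNA_id)) {
  stopifnot(nrow(sample_meta) == length(fastq_paths), nzchar(flank5))
  L <- nchar(library$sequence[1])
  counts <- matrix(0L, nrow = nrow(library), ncol = length(fastq_paths),
                   dimnames = list(library$sgRNA_id, sample_meta$sample))
  unmatched <- total <- integer(length(fastq_paths))
  f5 <- nchar(flank5)
  for (j in seq_along(fastq_paths)) {
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(fastq_paths[j],
                                                format = "fastq")),
      error = function(e) character(0))
    total[j] <- length(reads)
    if (!length(reads)) {
      warning("empty FASTQ: ", fastq_paths[j], " (all-zero column)")
      next
    }
    # locate the constant flank at stagger offsets 0..max_stagger
    start <- rep(NA_integer_, length(reads))
    for (st in 0:max_stagger) {
      cand <- is.na(start) &
        substr(reads, st + 1L, st + f5) == flank5
      start[cand] <- st + f5 + 1L
    }
    n_check <- min(1000L, length(reads))
    if (sum(!is.na(start[seq_len(n_check)])) < 0.1 * n_check)
      stop(sprintf(
        "flank '%s' found in %d/%d of the first reads of %s; check flank5/stagger",
        flank5, sum(!is.na(start[seq_len(n_check)])), n_check,
        fastq_paths[j]))
    insert <- substr(reads, start, start + L - 1L)
    idx <- match(insert, library$sequence)
    idx[is.na(start)] <- NA
    tab <- table(factor(idx, levels = seq_len(nrow(library))))
    counts[, j] <- as.integer(tab)
    unmatched[j] <- sum(is.na(idx))
  }
  cm <- count_matrix(counts, role = sample_meta$role,
                     replicate = sample_meta$replicate,
                     gene = library$gene, site_id = library$site_id,
                     nontargeting = nontargeting)
  attr(cm, "unmatched") <- stats::setNames(unmatched, sample_meta$sample)
  attr(cm, "total_reads") <- stats::setNames(total, sample_meta$sample)
  cm
}

#' Normalize a count matrix
#'
#' `total`: per-column factor `mean(library sizes) / column sum`, so all
#' column sums equal the mean raw library size afterwards. `median_ratio`:
#' DESeq-style size factors — per-sample median of the ratios to the
#' row-wise geometric-mean reference, computed over guides with no zero
#' count.
#'
#' @param x a raw [count_matrix()].
#' @param method `"total"` or `"median_ratio"`.
#' @return normalized `count_matrix` with `size_factors` recorded
#'   (normalized counts = raw / size factor).
#' @export
normalize_counts <- function(x, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "count_matrix"))
  if (x$normalized) stop("matrix is already normalized")
  cs <- colSums(x$counts)
  if (any(cs == 0)) stop("all-zero sample column(s): ",
                         paste(colnames(x$counts)[cs == 0], collapse = ", "))
  if (method == "total") {
    sf <- cs / mean(cs)
  } else {
    keep <- rowSums(x$counts == 0) == 0L
    if (!any(keep)) stop("no guide free of zeros for median-ratio reference")
    logref <- rowMeans(log(x$counts[keep, , drop = FALSE]))
    sf <- apply(x$counts[keep, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col) - logref)))
  }
  x$counts <- sweep(x$counts, 2, sf, "/")
  x$normalized <- TRUE
  x$size_factors <- stats::setNames(sf, colnames(x$counts))
  x$normalization <- method
  x
}

#' Per-guide replicate log2 fold changes and their median
#'
#' Replicates are paired by replicate index between the two roles; each
#' pair contributes `log2((num + pc) / (den + pc))` and the per-guide
#' summary is the sample median across replicate LFCs (for a single pair
#' the median is that value).
#'
#' @param x a normalized [count_matrix()].
#' @param numerator_role,denominator_role sample roles.
#' @param pseudocount added to both sides (default 1).
#' @return data.frame with `sgRNA_id`, one `lfc_r<k>` column per
#'   replicate pair, and `median_lfc`; attribute `pseudocount`.
#' @export
compute_lfc <- function(x, numerator_role, denominator_role,
                        pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (!x$normalized) stop("normalize the matrix before computing LFCs")
  num <- role_columns(x, numerator_role)
  den <- role_columns(x, denominator_role)
  rn <- x$samples$replicate[num]
  rd <- x$samples$replicate[den]
  common <- intersect(rn, rd)
  if (!length(common) || length(rn) != length(rd) ||
      !setequal(rn, rd))
    stop("replicate indices of '", numerator_role, "' and '",
         denominator_role, "' do not pair up")
  lfc <- sapply(sort(common), function(r)
    log2((x$counts[, num[match(r, rn)]] + pseudocount) /
         (x$counts[, den[match(r, rd)]] + pseudocount)))
  lfc <- matrix(lfc, nrow = nrow(x$counts),
                dimnames = list(rownames(x$counts),
                                paste0("lfc_r", sort(common))))
  out <- data.frame(sgRNA_id = rownames(x$counts), lfc,
                    median_lfc = apply(lfc, 1, stats::median),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Remove guides with low sorted-population coverage
#'
#' A guide is removed iff its replicate-averaged normalized count is
#' below `threshold` in *either* of the given roles (logical OR): low
#' coverage in one sorted population already makes its fold change
#' unreliable.
#'
#' @param x a normalized [count_matrix()].
#' @param roles roles whose means are screened (default the two sorted
#'   populations).
#' @param threshold minimum mean normalized count (default 200).
#' @return list with character vectors `retained` and `removed`
#'   (disjoint; union = all guides).
#' @export
low_count_filter <- function(x, roles = c("CXCR4neg", "CXCR4pos"),
                             threshold = 200) {
  stopifnot(inherits(x, "count_matrix"))
  if (!x$normalized) stop("normalize the matrix before filtering")
  low <- rep(FALSE, nrow(x$counts))
  for (role in roles) {
    cols <- role_columns(x, role)
    low <- low | rowMeans(x$counts[, cols, drop = FALSE]) < threshold
  }
  list(retained = rownames(x$counts)[!low],
       removed = rownames(x$counts)[low])
}
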