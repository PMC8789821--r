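# Synthetic-data generators: toy references with planted m6A sites, a
# ground-truth screen simulator, and a FASTQ emitter. Everything is
# deterministic under its seed argument.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulation configuration for a pooled sorted-population screen
#'
#' Defaults describe the study conditions the package models: three
#' biological replicates, two sorted populations (~6% FACS tails) plus
#' an undifferentiated baseline, NB counts with variance
#' `mu + k*mu^b`, and a mean per-guide depth of 500 reads.
#'
#' @param n_replicates replicates per population.
#' @param depth mean per-guide sequencing depth. The default (750) is
#'   set so that, with the default abundance spread, the standard
#'   low-count filter (mean normalized count < 200) removes about 0.4%
#'   of guides — the removal rate observed in real sorted-population
#'   base-editor screens.
#' @param k,b mean-variance trend parameters.
#' @param sdlog log-normal spread of latent per-guide abundance.
#' @param effects data.frame with columns `lfc` and `fraction`: each row
#'   assigns `fraction` of the targeting guides a true
#'   log2(CXCR4pos/CXCR4neg) of `lfc`. Unassigned guides (and all
#'   non-targeting guides) are null.
#' @param sort_fraction FACS tail fraction collected per population
#'   (recorded; effects enter through the latent means, not an extra
#'   sampling layer).
#' @param baseline list: `fraction_toxic`, `fraction_proliferative`,
#'   `shift` (baseline log2 offset vs both populations; toxic guides get
#'   `+shift`, proliferative `-shift`).
#' @param include_baseline emit baseline samples.
#' @param efficiency optional per-guide editing efficiency in `[0, 1]`
#'   scaling realized LFCs (single value or vector; default 1).
#' @param seed integer seed.
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_replicates = 3L, depth = 750, k = 0.1,
                              b = 1.5, sdlog = 0.5,
                              effects = data.frame(lfc = numeric(0),
                                                   fraction = numeric(0)),
                              sort_fraction = 0.06,
                              baseline = list(fraction_toxic = 0,
                                              fraction_proliferative = 0,
                                              shift = 2),
                              include_baseline = TRUE,
                              efficiency = 1, seed = 1L) {
  stopifnot(depth > 0, k >= 0, n_replicates >= 1,
            sort_fraction > 0, sort_fraction <= 1,
            all(effects$fraction >= 0), sum(effects$fraction) <= 1,
            all(efficiency >= 0), all(efficiency <= 1))
  structure(list(n_replicates = as.integer(n_replicates), depth = depth,
                 k = k, b = b, sdlog = sdlog, effects = effects,
                 sort_fraction = sort_fraction, baseline = baseline,
                 include_baseline = include_baseline,
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' A generic guide library for statistics-only simulations
#'
#' Guide ids, gene and site assignments without sequences (sufficient
#' for [simulate_screen_counts()] and the testing layer). About 20% of
#' targeting guides share a site pairwise, the rest are single-guide
#' sites, echoing the restricted design space of base-editor libraries.
#'
#' @param n_guides targeting guides.
#' @param n_nontargeting non-targeting controls.
#' @return data.frame with `sgRNA_id`, `gene`, `site_id`,
#'   `is_nontargeting`.
#' @export
make_generic_library <- function(n_guides, n_nontargeting = 0L) {
  n_paired <- floor(0.2 * n_guides / 2) * 2
  site <- c(rep(seq_len(n_paired / 2), each = 2),
            seq.int(n_paired / 2 + 1,
                    length.out = n_guides - n_paired))
  targ <- data.frame(
    sgRNA_id = sprintf("g%05d", seq_len(n_guides)),
    gene = sprintf("gene%04d", site),
    site_id = sprintf("site%05d", site),
    is_nontargeting = FALSE, stringsAsFactors = FALSE)
  if (n_nontargeting > 0L) {
    ntc <- data.frame(
      sgRNA_id = sprintf("NTC_%04d", seq_len(n_nontargeting)),
      gene = NA_character_, site_id = NA_character_,
      is_nontargeting = TRUE, stringsAsFactors = FALSE)
    targ <- rbind(targ, ntc)
  }
  targ
}

#' Simulate a sorted-population screen with known ground truth
#'
#' Latent per-guide abundance is log-normal around the configured depth;
#' true effects shift the two sorted-population means symmetrically
#' (`2^(+lfc/2)` in CXCR4pos, `2^(-lfc/2)` in CXCR4neg) so the NB
#' sampling noise is the only stochastic layer on top of the latent
#' means. Baseline samples receive the toxic/proliferative shifts.
#'
#' @param library guide data.frame (e.g. [make_generic_library()] or a
#'   designed library with an `is_nontargeting` column; ids starting
#'   with NTC are recognised otherwise).
#' @param config a [screen_sim_config()].
#' @return list with `matrix` (raw [count_matrix()]) and `truth`
#'   (data.frame: `sgRNA_id`, `true_lfc`, `class`, `baseline_class`,
#'   `latent_abundance`).
#' @export
simulate_screen_counts <- function(library, config = screen_sim_config()) {
  set.seed(config$seed)
  n <- nrow(library)
  is_ntc <- if (!is.null(library$is_nontargeting))
    library$is_nontargeting else grepl("^NTC", library$sgRNA_id)
  A <- config$depth * exp(stats::rnorm(n, 0, config$sdlog))
  eff <- rep(config$efficiency, length.out = n)
  true_lfc <- rep(0, n)
  targ_idx <- which(!is_ntc)
  pool <- sample(targ_idx)  # random assignment order
  taken <- 0L
  if (nrow(config$effects))
    for (i in seq_len(nrow(config$effects))) {
      m <- round(config$effects$fraction[i] * length(targ_idx))
      if (m == 0) next
      true_lfc[pool[taken + seq_len(m)]] <- config$effects$lfc[i]
      taken <- taken + m
    }
  true_lfc <- true_lfc * eff
  baseline_class <- rep("none", n)
  bl <- config$baseline
  n_tox <- round(bl$fraction_toxic * length(targ_idx))
  n_pro <- round(bl$fraction_proliferative * length(targ_idx))
  if (n_tox + n_pro > 0) {
    rest <- pool[taken + seq_len(n_tox + n_pro)]
    baseline_class[rest[seq_len(n_tox)]] <- "toxic"
    if (n_pro > 0) baseline_class[rest[n_tox + seq_len(n_pro)]] <-
        "proliferative"
  }
  R <- config$n_replicates
  roles <- c(rep("CXCR4neg", R), rep("CXCR4pos", R),
             if (config$include_baseline) rep("baseline_d0", R))
  reps <- c(seq_len(R), seq_len(R),
            if (config$include_baseline) seq_len(R))
  mu_for <- function(role) {
    switch(role,
           CXCR4neg = A * 2^(-true_lfc / 2),
           CXCR4pos = A * 2^(true_lfc / 2),
           baseline_d0 = A * 2^(ifelse(baseline_class == "toxic",
                                       bl$shift,
                                       ifelse(baseline_class ==
                                                "proliferative",
                                              -bl$shift, 0))))
  }
  counts <- vapply(seq_along(roles), function(j) {
    mu <- mu_for(roles[j])
    rnbinom_meanvar(n, mu, mu + config$k * mu^config$b)
  }, numeric(n))
  rownames(counts) <- library$sgRNA_id
  colnames(counts) <- paste0(roles, "_r", reps)
  cm <- count_matrix(counts, role = roles, replicate = reps,
                     gene = library$gene, site_id = library$site_id,
                     nontargeting = is_ntc)
  truth <- data.frame(
    sgRNA_id = library$sgRNA_id, true_lfc = true_lfc,
    class = ifelse(true_lfc > 0, "enriched_CXCR4pos",
                   ifelse(true_lfc < 0, "enriched_CXCR4neg", "null")),
    baseline_class = baseline_class, latent_abundance = A,
    stringsAsFactors = FALSE)
  list(matrix = cm, truth = truth)
}

#' Emit FASTQ reads reproducing a raw count column exactly
#'
#' Each guide contributes exactly its count of reads
#' (`flank5 + spacer + flank3`), shuffled, with constant quality, so
#' [match_and_count()] on the output returns the input counts. An
#' optional fraction of reads is corrupted by mutating one insert base
#' (those reads become unmatched).
#'
#' @param x a raw [count_matrix()].
#' @param library design data.frame with `sgRNA_id`, `sequence`.
#' @param flank5,flank3 constant flanks.
#' @param dir output directory (created if needed).
#' @param seed integer seed (read shuffling/corruption).
#' @param corrupt_fraction fraction of reads to corrupt (default 0).
#' @return character vector of FASTQ paths, named by sample; aligned
#'   with `x$samples`.
#' @export
simulate_fastq <- function(x, library, flank5, flank3 = "", dir,
                           seed = 1L, corrupt_fraction = 0) {
  stopifnot(inherits(x, "count_matrix"), !x$normalized)
  idx <- match(rownames(x$counts), library$sgRNA_id)
  if (anyNA(idx)) stop("count matrix guides missing from library")
  seqs <- library$sequence[idx]
  if (anyNA(seqs)) stop("library lacks sequences for some guides")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(ncol(x$counts))
  for (j in seq_len(ncol(x$counts))) {
    cnt <- x$counts[, j]
    ins <- rep(seqs, cnt)
    if (corrupt_fraction > 0 && length(ins)) {
      nc <- round(corrupt_fraction * length(ins))
      if (nc > 0) {
        pick <- sample(length(ins), nc)
        pos <- sample(nchar(seqs[1]), nc, replace = TRUE)
        for (t in seq_len(nc)) {
          s <- ins[pick[t]]
          old <- substr(s, pos[t], pos[t])
          substr(s, pos[t], pos[t]) <-
            setdiff(c("A", "C", "G", "T"), old)[1]
          ins[pick[t]] <- s
        }
      }
    }
    reads <- paste0(flank5, ins, flank3)
    if (length(reads)) reads <- reads[sample(length(reads))]
    qual <- strrep("I", nchar(reads))
    ids <- sprintf("@read_%s_%06d", colnames(x$counts)[j],
                   seq_along(reads))
    paths[j] <- file.path(dir, paste0(colnames(x$counts)[j], ".fastq"))
    writeLines(as.vector(rbind(ids, reads, "+", qual)), paths[j])
  }
  stats::setNames(paths, colnames(x$counts))
}

# -- toy reference ----------------------------------------------------------

# recode in-frame internal stop codons (keeps toy ORFs clean)
scrub_internal_stops <- function(cds) {
  n <- nchar(cds)
  for (i in seq(1, n - 5, 3)) {
    cod <- substr(cds, i, i + 2)
    if (cod %in% c("TAA", "TAG", "TGA"))
      substr(cds, i, i) <- "C"
  }
  cds
}

#' Generate a toy genome, transcript models and planted m6A sites
#'
#' Builds one contig per transcript: single- or multi-exon models on
#' both strands with a clean ORF (ATG...stop, no internal stops) and a
#' 3'UTR long enough to hold the assigned m6A adenines. Sites are
#' planted in DRACH context (GGACT, A at the centre) in the last exon's
#' 3'UTR, biased 3'-ward as in real m6A maps. Each site is guaranteed at
#' least one valid protospacer+PAM on the transcript strand — except a
#' deliberate `p_untargetable` fraction whose candidate PAMs are
#' scrubbed — and a fraction receives a second PAM so some sites carry
#' multiple guides. Deterministic under `seed`.
#'
#' @param n_sites number of m6A sites (>= 1).
#' @param n_transcripts number of transcripts/contigs (default scales
#'   with `n_sites`).
#' @param seed integer seed.
#' @param p_untargetable fraction of sites made untargetable.
#' @param p_second_pam fraction of targetable sites given a second PAM
#'   (default 0.258, reproducing the ~74% single-guide-site fraction
#'   characteristic of base-editor libraries).
#' @param params ABE [editor_params()] used for the targetability
#'   guarantee.
#' @return list: `genome` ([genome_seq()]), `transcripts`
#'   (`transcript_models`), `sites` (data.frame as from
#'   [read_m6a_bed()], plus `designed_targetable`).
#' @export
make_toy_reference <- function(n_sites, n_transcripts = NULL, seed = 1L,
                               p_untargetable = 0.1, p_second_pam = 0.258,
                               params = editor_params()) {
  stopifnot(n_sites >= 1)
  if (is.null(n_transcripts))
    n_transcripts <- max(5L, ceiling(n_sites / 3))
  set.seed(seed)
  sites_per_tx <- tabulate(sort(rep_len(seq_len(n_transcripts), n_sites)),
                           nbins = n_transcripts)
  if (max(sites_per_tx) > 5)
    stop("too many sites per transcript; increase n_transcripts")
  contigs <- list()
  txs <- list()
  site_rows <- list()
  margin <- 150L
  for (t in seq_len(n_transcripts)) {
    u5 <- sample(30:80, 1)
    cdslen <- 3L * sample(60:150, 1)
    u3 <- sample(280:380, 1)
    slen <- u5 + cdslen + u3
    spl <- sample(c("A", "C", "G", "T"), slen, replace = TRUE)
    # clean ORF
    cds <- paste(spl[(u5 + 1):(u5 + cdslen)], collapse = "")
    substr(cds, 1, 3) <- "ATG"
    substr(cds, cdslen - 2, cdslen) <- sample(c("TAA", "TAG", "TGA"), 1)
    cds <- scrub_internal_stops(cds)
    spl[(u5 + 1):(u5 + cdslen)] <- strsplit(cds, "")[[1]]
    # plant sites in the 3'UTR (kept inside the last exon, below)
    k_sites <- sites_per_tx[t]
    site_spl <- integer(0)
    if (k_sites > 0) {
      lo <- u5 + cdslen + 20L
      hi <- slen - 40L
      site_spl <- lo + sort(sample.int(floor((hi - lo) / 45), k_sites)) * 45L
      for (p in site_spl)
        spl[(p - 1):(p + 3)] <- c("G", "G", "A", "C", "T")  # A at index p+1
    }
    site_spl1 <- site_spl + 1L  # 1-based spliced index of the A
    # exon structure: splits only 5' of the last 30 CDS nt, so the last
    # exon holds the whole 3'UTR
    n_ex <- sample(1:3, 1)
    cuts <- integer(0)
    if (n_ex > 1) {
      cand <- seq(40L, u5 + cdslen - 60L, by = 1L)
      cuts <- sort(sample(cand, n_ex - 1))
      while (length(cuts) > 1 && min(diff(cuts)) < 40) # keep exons >= 40 nt
        cuts <- sort(sample(cand, n_ex - 1))
    }
    bounds <- c(0L, cuts, slen)  # spliced half-open exon bounds
    ex_len <- diff(bounds)
    introns <- if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE)
    else integer(0)
    strand <- sample(c("+", "-"), 1)
    # assemble genomic plus strand
    ex_chunks <- lapply(seq_len(n_ex), function(i)
      spl[(bounds[i] + 1):(bounds[i + 1])])
    if (strand == "-")
      ex_chunks_g <- lapply(rev(ex_chunks), function(ch)
        unname(COMP[rev(ch)]))
    else ex_chunks_g <- ex_chunks
    gchars <- sample(c("A", "C", "G", "T"), margin, replace = TRUE)
    ex_g <- matrix(0L, n_ex, 2)
    for (i in seq_len(n_ex)) {
      ex_g[i, 1] <- length(gchars)
      gchars <- c(gchars, ex_chunks_g[[i]])
      ex_g[i, 2] <- length(gchars)
      if (i < n_ex)
        gchars <- c(gchars, sample(c("A", "C", "G", "T"),
                                   introns[i], replace = TRUE))
    }
    gchars <- c(gchars, sample(c("A", "C", "G", "T"), margin,
                               replace = TRUE))
    contig <- sprintf("chr%d", t)
    tx <- structure(list(
      transcript_id = sprintf("tx%03d", t),
      gene = sprintf("GENE%03d", t),
      contig = contig, strand = strand,
      exons = cbind(start = ex_g[, 1], end = ex_g[, 2]),
      cds_start = NA_integer_, cds_end = NA_integer_),
      class = "transcript_model")
    tx_pos <- tx_exonic_positions(tx)  # transcript order
    cds_g <- tx_pos[(u5 + 1):(u5 + cdslen)]
    tx$cds_start <- min(cds_g)
    tx$cds_end <- max(cds_g) + 1L
    txs[[t]] <- tx
    if (k_sites > 0) {
      g_sites <- tx_pos[site_spl1]
      for (si in seq_along(g_sites))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          site_id = sprintf("%s:m6A_%d", tx$gene, si),
          contig = contig, pos = g_sites[si], strand = strand,
          gene = tx$gene, stringsAsFactors = FALSE)
    }
    contigs[[contig]] <- gchars
  }
  sites <- do.call(rbind, site_rows)
  # targetability pass. The PAM dinucleotide of window position w sits at
  # fixed genomic offsets from the site; the union of those offsets over
  # the whole window is first scrubbed to a PAM-free background, then
  # exactly one (or two) PAMs are planted, so guides-per-site is a
  # designed property rather than an accident of the random background.
  untarget <- stats::runif(nrow(sites)) < p_untargetable
  second <- stats::runif(nrow(sites)) < p_second_pam
  L <- params$spacer_length
  wlo <- params$window[1]; whi <- params$window[2]
  for (i in seq_len(nrow(sites))) {
    ct <- sites$contig[i]
    ch <- contigs[[ct]]
    p <- sites$pos[i]  # 0-based
    if (sites$strand[i] == "+") {
      # window-w PAM GG occupies 0-based p+L+2-w .. p+L+3-w
      union_idx <- (p + L + 2L - whi):(p + L + 3L - wlo) + 1L  # 1-based
      ch[union_idx] <- "T"
      plant <- function(w) {
        ch[c(p + L + 2L - w, p + L + 3L - w) + 1L] <<- "G"
      }
    } else {
      # mirrored: plus-strand CC at 0-based p+w-L-3 .. p+w-L-2
      union_idx <- (p + wlo - L - 3L):(p + whi - L - 2L) + 1L
      ch[union_idx] <- "A"
      plant <- function(w) {
        ch[c(p + w - L - 3L, p + w - L - 2L) + 1L] <<- "C"
      }
    }
    if (!untarget[i]) {
      w <- sample(wlo:whi, 1)
      plant(w)
      if (second[i]) {
        # adjacent windows share a PAM base (GGG is fine); windows two
        # apart would create a spurious third PAM, so exclude them
        ok <- setdiff(wlo:whi, w)
        ok <- ok[abs(ok - w) == 1L | abs(ok - w) >= 3L]
        if (length(ok)) plant(ok[sample.int(length(ok), 1)])
      }
    }
    contigs[[ct]] <- ch
  }
  genome <- genome_seq(vapply(contigs, paste, character(1), collapse = ""))
  # the scrub guarantees this, but verify the designed targetability
  for (i in seq_len(nrow(sites))) {
    n_designs <- nrow(enumerate_editor_sgrnas(sites[i, ], genome, params))
    if (untarget[i] && n_designs > 0)
      stop("internal: untargetable site ", sites$site_id[i], " has designs")
    if (!untarget[i] && n_designs == 0)
      stop("internal: targetable site ", sites$site_id[i], " lacks designs")
  }
  sites$designed_targetable <- !untarget
  structure(list(genome = genome,
                 transcripts = structure(txs, class = "transcript_models"),
                 sites = sites),
            class = "toy_reference")
}

#' Write a toy reference to FASTA/GTF/BED files
#'
#' @param ref a [make_toy_reference()] result.
#' @param dir output directory.
#' @return named character vector of paths (`fasta`, `gtf`, `bed`).
#' @export
write_toy_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "transcripts.gtf"),
             bed = file.path(dir, "m6a_sites.bed"))
  write_genome_fasta(ref$genome, paths["fasta"])
  write_transcripts_gtf(ref$transcripts, paths["gtf"])
  write_m6a_bed(ref$sites, paths["bed"])
  paths
}
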