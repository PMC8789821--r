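# Shared fixtures and independent brute-force oracles.

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# oracle-local reverse complement, independent of the package's
# implementation
rc <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")

# Brute-force protospacer enumeration: scans EVERY placement on the
# contig instead of deriving placements from window arithmetic, so it is
# an independent oracle for enumerate_editor_sgrnas().
oracle_enumerate <- function(site, genome, params = editor_params(),
                             flank = 30L) {
  g <- genome[[site$contig]]
  len <- nchar(g)
  L <- params$spacer_length
  plen <- nchar(params$pam)
  pamre <- m6ascreen:::iupac_regex(params$pam)
  pos <- site$pos
  rows <- list()
  flank_ok <- pos - flank >= 0L && pos + 1L + flank <= len
  if (site$strand == "+") {
    for (s in 0:(len - L - plen)) {
      if (!(s <= pos && pos <= s + L - 1L)) next
      pam <- substr(g, s + L + 1L, s + L + plen)
      if (!grepl(pamre, pam)) next
      w <- pos - s + 1L
      if (w < params$window[1] || w > params$window[2] || !flank_ok) next
      spacer <- substr(g, s + 1L, s + L)
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer_start = s, w = w, sequence = spacer, pam = pam,
        stringsAsFactors = FALSE)
    }
  } else {
    for (s in plen:(len - L)) {
      if (!(s <= pos && pos <= s + L - 1L)) next
      pam <- rc(substr(g, s - plen + 1L, s))
      if (!grepl(pamre, pam)) next
      w <- s + L - pos
      if (w < params$window[1] || w > params$window[2] || !flank_ok) next
      spacer <- rc(substr(g, s + 1L, s + L))
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer_start = s, w = w, sequence = spacer, pam = pam,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protospacer_start = integer(0), w = integer(0),
               sequence = character(0), pam = character(0))
  # independent bystander computation from the spacer string
  if (nrow(out)) {
    out$bystanders <- vapply(seq_len(nrow(out)), function(i) {
      wp <- params$window[1]:params$window[2]
      ch <- strsplit(out$sequence[i], "")[[1]][wp]
      paste(wp[ch == params$edited_base & wp != out$w[i]], collapse = ",")
    }, character(1))
  } else out$bystanders <- character(0)
  out[order(out$protospacer_start), , drop = FALSE]
}

# Single-exon coding fixture on the plus or minus strand:
# 5'UTR (9 nt) + CDS + 3'UTR (configurable), one contig.
coding_fixture <- function(cds = "ATGTATCCATAA", strand = "+",
                           utr3 = "CCCCCCCCCCCC", utr5 = "GGGGGGGGG") {
  spl <- paste0(utr5, cds, utr3)
  gstr <- if (strand == "-") revcomp(spl) else spl
  slen <- nchar(spl)
  u5 <- nchar(utr5)
  if (strand == "+") {
    cds_start <- u5
    cds_end <- u5 + nchar(cds)
  } else {
    cds_end <- slen - u5
    cds_start <- slen - u5 - nchar(cds)
  }
  tx <- structure(list(transcript_id = "t1", gene = "G1", contig = "c1",
                       strand = strand,
                       exons = cbind(start = 0L, end = slen),
                       cds_start = cds_start, cds_end = cds_end),
                  class = "transcript_model")
  list(genome = genome_seq(c(c1 = gstr)),
       transcripts = structure(list(t1 = tx), class = "transcript_models"),
       tx = tx)
}

# Design row pointing the editor at one genomic position (window pos 6);
# PAM validity is irrelevant to consequence prediction.
design_row_at <- function(contig, pos, strand = "+", id = "d1",
                          bystanders = "") {
  s <- if (strand == "+") pos - 5L else pos + 6L - 20L
  data.frame(sgRNA_id = id, contig = contig, protospacer_start = s,
             strand = strand, window_position_of_target_A = 6L,
             bystander_positions = bystanders, stringsAsFactors = FALSE)
}

# Full-translation oracle: apply a plus-strand substitution, re-extract
# and translate the whole CDS with Biostrings, and classify by diffing
# the protein sequences.
oracle_translation_effect <- function(genome, tx, pos, alt_plus) {
  g2raw <- genome[[tx$contig]]
  substr(g2raw, pos + 1L, pos + 1L) <- alt_plus
  contigs <- stats::setNames(lapply(names(genome), function(n)
    if (n == tx$contig) g2raw else genome[[n]]), names(genome))
  g2 <- genome_seq(unlist(contigs))
  cds_ref <- tx_cds_seq(tx, genome)
  cds_alt <- tx_cds_seq(tx, g2)
  idx <- which(strsplit(cds_ref, "")[[1]] != strsplit(cds_alt, "")[[1]])
  if (!length(idx)) return("synonymous")
  ci <- (idx[1] - 1L) %/% 3L + 1L
  ref_cod <- substr(cds_ref, (ci - 1) * 3 + 1, ci * 3)
  alt_cod <- substr(cds_alt, (ci - 1) * 3 + 1, ci * 3)
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(ref_cod)
  p_alt <- tr(alt_cod)
  if (ci == 1L && ref_cod == "ATG" && alt_cod != "ATG") return("start_lost")
  if (p_ref == "*" && p_alt == "*") return("synonymous")
  if (p_ref != "*" && p_alt == "*") return("stop_gained")
  if (p_ref == "*" && p_alt != "*") return("stop_lost")
  if (p_ref == p_alt) return("synonymous")
  "missense"
}

# Brute-force CRISPR-STOP oracle: every protospacer placement on both
# strands, every window C, single C>T edit, full-CDS translation; keep
# edits that gain a stop. Returns the set of
# (protospacer_start, strand, edited genomic position).
oracle_stop_edits <- function(tx, genome, params = editor_params("CBE")) {
  g <- genome[[tx$contig]]
  len <- nchar(g)
  L <- params$spacer_length
  plen <- nchar(params$pam)
  pamre <- m6ascreen:::iupac_regex(params$pam)
  hits <- list()
  cds_pos <- tx_cds_positions(tx)
  for (strand in c("+", "-")) {
    s_range <- if (strand == "+") 0:(len - L - plen) else plen:(len - L)
    for (s in s_range) {
      if (strand == "+") {
        spacer <- substr(g, s + 1L, s + L)
        pam <- substr(g, s + L + 1L, s + L + plen)
      } else {
        spacer <- rc(substr(g, s + 1L, s + L))
        pam <- rc(substr(g, s - plen + 1L, s))
      }
      if (!grepl(pamre, pam)) next
      for (w in params$window[1]:params$window[2]) {
        gp <- if (strand == "+") s + w - 1L else s + L - w
        base <- substr(g, gp + 1L, gp + 1L)
        proto_base <- if (strand == "+") base else chartr("ACGT", "TGCA", base)
        if (proto_base != "C") next
        if (!gp %in% cds_pos) next
        alt_plus <- if (strand == "+") "T" else "A"
        eff <- oracle_translation_effect(genome, tx, gp, alt_plus)
        if (eff == "stop_gained")
          hits[[length(hits) + 1L]] <- data.frame(
            protospacer_start = s, strand = strand, pos = gp,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(protospacer_start = integer(0), strand = character(0),
               pos = integer(0))
  out[order(out$strand, out$protospacer_start, out$pos), , drop = FALSE]
}

# Deterministic count table with exactly equal column sums (so total
# normalization is the identity and expectations stay exact): `target`
# is a guides x samples matrix of desired values; a filler guide tops
# every column up to `total`.
balanced_counts <- function(target, total = NULL) {
  cs <- colSums(target)
  if (is.null(total)) total <- max(cs) + 1000
  filler <- total - cs
  rbind(target, filler = filler)
}
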