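#' Base-editor parameters
#'
#' Defaults describe the canonical editing geometry shared by the
#' ABE7.10 and BE3 editor families: a 20-nt spacer, NGG PAM, and an
#' editing window spanning protospacer positions 4-8 with position 1 at
#' the PAM-distal 5' end.
#'
#' @param editor_class `"ABE"` (A>G) or `"CBE"` (C>T).
#' @param window inclusive protospacer position range, length-2 integer.
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer.
#' @param spacer_length protospacer length in nt.
#' @return an `editor_params` list.
#' @export
editor_params <- function(editor_class = c("ABE", "CBE"),
                          window = c(4L, 8L), pam = "NGG",
                          spacer_length = 20L) {
  editor_class <- match.arg(editor_class)
  window <- as.integer(window)
  spacer_length <- as.integer(spacer_length)
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2] ||
      window[2] > spacer_length)
    stop("require 1 <= w_lo <= w_hi <= spacer_length")
  if (nchar(pam) < 2L) stop("PAM pattern must have length >= 2")
  iupac_regex(pam)  # validates the pattern
  structure(list(editor_class = editor_class, window = window, pam = pam,
                 spacer_length = spacer_length,
                 edited_base = if (editor_class == "ABE") "A" else "C"),
            class = "editor_params")
}

#' @export
print.editor_params <- function(x, ...) {
  cat(sprintf("%s editor: %s>%s, window [%d,%d], PAM %s, spacer %d nt\n",
              x$editor_class, x$edited_base,
              if (x$editor_class == "ABE") "G" else "T",
              x$window[1], x$window[2], x$pam, x$spacer_length))
  invisible(x)
}

# genomic coordinate of protospacer position w (1 = PAM-distal 5' end)
# for a protospacer whose genomic footprint starts at s (0-based)
window_pos_to_genomic <- function(s, w, strand, L) {
  if (strand == "+") s + w - 1L else s + L - w
}

empty_designs <- function() {
  data.frame(sgRNA_id = character(0), sequence = character(0),
             PAM = character(0), contig = character(0),
             protospacer_start = integer(0), strand = character(0),
             site_id = character(0), gene = character(0),
             window_position_of_target_A = integer(0),
             bystander_positions = character(0),
             predicted_consequence = character(0),
             flank_up = character(0), flank_down = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate base-editor sgRNAs covering one m6A site
#'
#' Slides the editing window one nucleotide at a time: for every window
#' position `w` in `[w_lo, w_hi]` the protospacer placement putting the
#' site's adenine at position `w` is tested for a PAM match immediately 3'
#' of the protospacer. The protospacer strand is the site's transcript
#' strand (the deaminated A must sit on the protospacer strand; on the
#' opposite strand the site reads T). Other window adenines are recorded
#' as bystanders. Placements running off the contig, lacking a PAM, or
#' without the full +/-30 nt flanking context are skipped.
#'
#' @param site one-row data.frame (or list) with `site_id`, `contig`,
#'   `pos`, `strand`, `gene`.
#' @param genome a [genome_seq()].
#' @param params an [editor_params()]; must be ABE.
#' @param flank flanking context length checked/recorded around the site
#'   (default 30 nt each side).
#' @return design data.frame (possibly 0-row), ordered by genomic start;
#'   attribute `skipped` counts placements skipped at the contig edge.
#' @export
enumerate_editor_sgrnas <- function(site, genome, params = editor_params(),
                                    flank = 30L) {
  if (params$editor_class != "ABE")
    stop("enumerate_editor_sgrnas is for ABE designs; see design_stop_gain_controls")
  L <- params$spacer_length
  plen <- nchar(params$pam)
  contig <- site$contig
  pos <- as.integer(site$pos)
  strand <- site$strand
  clen <- nchar(genome[[contig]])
  if (is.null(genome[[contig]])) stop("unknown contig: ", contig)
  if (base_at(genome, contig, pos, strand) != "A")
    stop("site ", site$site_id, " base is not 'A' on strand ", strand)
  n_skipped <- 0L
  rows <- list()
  for (w in seq.int(params$window[1], params$window[2])) {
    if (strand == "+") {
      s <- pos - w + 1L
      ok <- s >= 0L && s + L + plen <= clen
      if (ok) {
        spacer <- seq_slice(genome, contig, s, s + L)
        pam <- seq_slice(genome, contig, s + L, s + L + plen)
      }
    } else {
      s <- pos + w - L
      ok <- s - plen >= 0L && s + L <= clen
      if (ok) {
        spacer <- seq_slice(genome, contig, s, s + L, "-")
        pam <- seq_slice(genome, contig, s - plen, s, "-")
      }
    }
    flank_ok <- pos - flank >= 0L && pos + 1L + flank <= clen
    if (!ok || !flank_ok) { n_skipped <- n_skipped + 1L; next }
    if (!iupac_match(pam, params$pam)) next
    win_chars <- strsplit(substr(spacer, params$window[1],
                                 params$window[2]), "")[[1]]
    win_pos <- seq.int(params$window[1], params$window[2])
    bystanders <- win_pos[win_chars == params$edited_base & win_pos != w]
    if (strand == "+") {
      f_up <- seq_slice(genome, contig, pos - flank, pos)
      f_dn <- seq_slice(genome, contig, pos + 1L, pos + 1L + flank)
    } else {
      f_up <- seq_slice(genome, contig, pos + 1L, pos + 1L + flank, "-")
      f_dn <- seq_slice(genome, contig, pos - flank, pos, "-")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sgRNA_id = NA_character_, sequence = spacer, PAM = pam,
      contig = contig, protospacer_start = s, strand = strand,
      site_id = site$site_id, gene = as.character(site$gene),
      window_position_of_target_A = w,
      bystander_positions = paste(bystanders, collapse = ","),
      predicted_consequence = NA_character_,
      flank_up = f_up, flank_down = f_dn,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_designs()
  out <- out[order(out$protospacer_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- n_skipped
  out
}

#' Summary statistics of a designed library
#'
#' @param designs targeting designs (non-targeting controls excluded).
#' @param n_sites total number of input sites.
#' @return a `design_stats` list: `n_sgrnas`, `n_sites_targeted`,
#'   `n_sites_untargetable`, `per_site_multiplicity` (table),
#'   `fraction_single_sgrna_sites`.
#' @export
design_stats <- function(designs, n_sites) {
  per_site <- table(designs$site_id)
  mult <- table(as.integer(per_site))
  n_targeted <- length(per_site)
  structure(list(
    n_sgrnas = nrow(designs),
    n_sites_targeted = n_targeted,
    n_sites_untargetable = n_sites - n_targeted,
    per_site_multiplicity = mult,
    fraction_single_sgrna_sites =
      if (n_targeted) sum(per_site == 1L) / n_targeted else NA_real_),
    class = "design_stats")
}

#' @export
print.design_stats <- function(x, ...) {
  cat(sprintf("sgRNA library: %d guides over %d sites (%d untargetable)\n",
              x$n_sgrnas, x$n_sites_targeted, x$n_sites_untargetable))
  cat(sprintf("  sites with a single guide: %.1f%%\n",
              100 * x$fraction_single_sgrna_sites))
  cat("  guides-per-site histogram:\n")
  print(x$per_site_multiplicity)
  invisible(x)
}

#' Generate non-targeting control sequences
#'
#' Random 20-mers verified absent (exact match, both strands) from the
#' genome. Exact matching mirrors the use of control sequences drawn from
#' an established library; no mismatch-tolerant search is attempted.
#'
#' @param n number of controls.
#' @param genome a [genome_seq()].
#' @param spacer_length spacer length.
#' @param seed optional integer seed.
#' @return character vector of length `n`.
#' @export
make_nontargeting_controls <- function(n, genome, spacer_length = 20L,
                                       seed = NULL) {
  if (n == 0L) return(character(0))
  if (!is.null(seed)) set.seed(seed)
  both <- c(unlist(genome), revcomp(unlist(genome)))
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i)
      paste(sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
            collapse = ""), character(1))
    hit <- vapply(cand, function(s)
      any(vapply(both, function(g) grepl(s, g, fixed = TRUE), logical(1))),
      logical(1))
    out <- unique(c(out, cand[!hit]))
  }
  out[seq_len(n)]
}

#' Design an ABE sgRNA library for a set of m6A sites
#'
#' Concatenates per-site window enumeration, attaches predicted edit
#' consequences, flags protospacers whose sequence occurs at multiple
#' designed loci (`multi_locus`), optionally filters on bystander count,
#' computes [design_stats()], and appends non-targeting controls.
#'
#' @param sites validated site data.frame (see [read_m6a_bed()]).
#' @param genome a [genome_seq()].
#' @param transcripts a `transcript_models` list (used for consequence
#'   annotation; may be NULL to skip annotation).
#' @param params an ABE [editor_params()].
#' @param n_nontargeting number of non-targeting controls to generate
#'   (ignored when `nontargeting_seqs` is supplied).
#' @param nontargeting_seqs optional caller-supplied control sequences.
#' @param max_bystanders drop designs with more window bystanders than
#'   this (default `Inf`, i.e. bystanders never disqualify).
#' @param unique_only drop multi-locus protospacers instead of flagging.
#' @param seed seed for control generation.
#' @return list with `designs` (targeting guides), `stats`
#'   (a [design_stats()]), and `nontargeting` (data.frame of control
#'   guides with `sgRNA_id`, `sequence`).
#' @export
design_library <- function(sites, genome, transcripts = NULL,
                           params = editor_params(),
                           n_nontargeting = 0L, nontargeting_seqs = NULL,
                           max_bystanders = Inf, unique_only = FALSE,
                           seed = NULL) {
  if (is.null(sites) || nrow(sites) == 0L) stop("empty site list")
  per_site <- lapply(seq_len(nrow(sites)), function(i)
    enumerate_editor_sgrnas(sites[i, ], genome, params))
  designs <- do.call(rbind, c(per_site, list(empty_designs())))
  if (nrow(designs)) {
    nby <- ifelse(nzchar(designs$bystander_positions),
                  lengths(strsplit(designs$bystander_positions, ",")), 0L)
    designs <- designs[nby <= max_bystanders, , drop = FALSE]
  }
  if (nrow(designs)) {
    designs$sgRNA_id <- stats::ave(
      designs$site_id, designs$site_id,
      FUN = function(x) paste0(x, "_sg", seq_along(x)))
    designs$multi_locus <- duplicated(designs$sequence) |
      duplicated(designs$sequence, fromLast = TRUE)
    if (unique_only)
      designs <- designs[!designs$multi_locus, , drop = FALSE]
    if (!is.null(transcripts)) {
      calls <- predict_edit_consequence(designs, transcripts, genome,
                                        params = params)
      designs$predicted_consequence <- ifelse(
        calls$coding_effect == "none", calls$region,
        paste(calls$region, calls$coding_effect, sep = ":"))
      designs$region <- calls$region
      designs$coding_effect <- calls$coding_effect
    }
  }
  rownames(designs) <- NULL
  ntc_seqs <- if (!is.null(nontargeting_seqs)) nontargeting_seqs else
    make_nontargeting_controls(n_nontargeting, genome,
                               params$spacer_length, seed = seed)
  ntc <- data.frame(
    sgRNA_id = if (length(ntc_seqs))
      sprintf("NTC_%04d", seq_along(ntc_seqs)) else character(0),
    sequence = ntc_seqs, stringsAsFactors = FALSE)
  list(designs = designs,
       stats = design_stats(designs, nrow(sites)),
       nontargeting = ntc)
}

#' Design CRISPR-STOP (CBE) control guides
#'
#' Enumerates C>T edits inside the editing window that convert a coding
#' codon into a premature stop: sense-strand edits of CAA/CAG/CGA codons
#' and antisense edits of the Cs paired with the G2/G3 of TGG codons.
#' Each design is annotated with the reference codon, 1-based codon index
#' and resulting stop codon. Genes without a CDS are skipped with a
#' warning.
#'
#' @param gene_ids genes to target (matched against transcript `gene`).
#' @param transcripts a `transcript_models` list.
#' @param genome a [genome_seq()].
#' @param params a CBE [editor_params()].
#' @return design data.frame with extra columns `codon_ref`, `codon_index`,
#'   `codon_alt`, `edit_genomic_pos`.
#' @export
design_stop_gain_controls <- function(gene_ids, transcripts, genome,
                                      params = editor_params("CBE")) {
  if (params$editor_class != "CBE") stop("params must describe a CBE editor")
  L <- params$spacer_length
  plen <- nchar(params$pam)
  rows <- list()
  for (gid in gene_ids) {
    txs <- Filter(function(t) identical(t$gene, gid), transcripts)
    coding <- Filter(function(t) !is.na(t$cds_start), txs)
    if (!length(coding)) {
      warning("gene ", gid, " has no coding transcript; skipped")
      next
    }
    for (tx in coding) {
      cds_pos <- tx_cds_positions(tx)
      cds_seq <- tx_cds_seq(tx, genome)
      codons <- substring(cds_seq, seq(1, nchar(cds_seq) - 2, 3),
                          seq(3, nchar(cds_seq), 3))
      clen <- nchar(genome[[tx$contig]])
      for (ci in seq_along(codons)) {
        ref <- codons[ci]
        if (ref %in% c("TAA", "TAG", "TGA")) next
        for (off in 1:3) {
          base <- substr(ref, off, off)
          # the editable C sits on the strand where the base reads C
          if (base == "C") ed_strand <- tx$strand
          else if (base == "G") ed_strand <- if (tx$strand == "+") "-" else "+"
          else next
          alt <- ref
          substr(alt, off, off) <- if (base == "C") "T" else "A"
          if (!alt %in% c("TAA", "TAG", "TGA")) next
          g <- cds_pos[(ci - 1L) * 3L + off]
          for (w in seq.int(params$window[1], params$window[2])) {
            if (ed_strand == "+") {
              s <- g - w + 1L
              if (s < 0L || s + L + plen > clen) next
              spacer <- seq_slice(genome, tx$contig, s, s + L)
              pam <- seq_slice(genome, tx$contig, s + L, s + L + plen)
            } else {
              s <- g + w - L
              if (s - plen < 0L || s + L > clen) next
              spacer <- seq_slice(genome, tx$contig, s, s + L, "-")
              pam <- seq_slice(genome, tx$contig, s - plen, s, "-")
            }
            if (!iupac_match(pam, params$pam)) next
            win_chars <- strsplit(substr(spacer, params$window[1],
                                         params$window[2]), "")[[1]]
            win_pos <- seq.int(params$window[1], params$window[2])
            bystanders <- win_pos[win_chars == "C" & win_pos != w]
            rows[[length(rows) + 1L]] <- data.frame(
              sgRNA_id = NA_character_, sequence = spacer, PAM = pam,
              contig = tx$contig, protospacer_start = s,
              strand = ed_strand, site_id = NA_character_, gene = gid,
              window_position_of_target_A = w,
              bystander_positions = paste(bystanders, collapse = ","),
              predicted_consequence = paste0("CDS:stop_gained"),
              flank_up = NA_character_, flank_down = NA_character_,
              codon_ref = ref, codon_index = ci, codon_alt = alt,
              edit_genomic_pos = g,
              transcript_id = tx$transcript_id,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_designs()
    e$codon_ref <- e$codon_alt <- e$transcript_id <- character(0)
    e$codon_index <- e$edit_genomic_pos <- integer(0)
    e
  }
  # one record per distinct protospacer placement x edited base
  key <- paste(out$contig, out$protospacer_start, out$strand,
               out$edit_genomic_pos)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$gene, out$contig, out$protospacer_start), ,
             drop = FALSE]
  if (nrow(out))
    out$sgRNA_id <- sprintf("STOP_%s_%02d", out$gene,
                            stats::ave(seq_len(nrow(out)), out$gene,
                                       FUN = seq_along))
  rownames(out) <- NULL
  out
}
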