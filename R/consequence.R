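# Region- and codon-level consequence prediction for base-editor edits:
# a small, deterministic subset of a variant-effect predictor covering
# the categories {CDS, 3'UTR, 5'UTR, intron, intergenic} and the coding
# effects {missense, synonymous, stop_gained, stop_lost, start_lost}.

REGION_PRIORITY <- c(CDS = 5L, three_prime_UTR = 4L, five_prime_UTR = 3L,
                     intron = 2L, intergenic = 1L, none = 0L)

#' Classify a genomic position into a region across all isoforms
#'
#' Evaluates the position against every transcript and returns the
#' highest-priority region achieved by any isoform, with priority
#' CDS > 3'UTR > 5'UTR > intron > intergenic. Ties between isoforms are
#' broken by lexicographically smallest transcript id; the achieving
#' isoform is returned as an attribute.
#'
#' @param contig,pos genomic position (0-based).
#' @param transcripts a `transcript_models` list.
#' @return region string; attribute `transcript_id` names the
#'   priority-achieving isoform (NA for intergenic).
#' @export
classify_region <- function(contig, pos, transcripts) {
  best <- "intergenic"
  best_tx <- NA_character_
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  for (i in order(ids)) {
    tx <- transcripts[[i]]
    r <- tx_region(tx, contig, pos)
    if (r == "none") next
    if (REGION_PRIORITY[[r]] > REGION_PRIORITY[[best]]) {
      best <- r
      best_tx <- tx$transcript_id
    }
  }
  structure(best, transcript_id = best_tx)
}

# classify the effect of substitutions inside one codon
codon_effect <- function(ref, alt, codon_index) {
  if (ref == alt) return("synonymous")
  ref_aa <- translate_codons(ref)
  alt_aa <- translate_codons(alt)
  if (codon_index == 1L && ref == "ATG" && alt != "ATG") return("start_lost")
  if (ref_aa == "*" && alt_aa == "*") return("synonymous")  # stop retained
  if (ref_aa != "*" && alt_aa == "*") return("stop_gained")
  if (ref_aa == "*" && alt_aa != "*") return("stop_lost")
  if (ref_aa == alt_aa) return("synonymous")
  "missense"
}

# genomic positions edited by one design row (target first)
design_edited_positions <- function(d, params) {
  L <- params$spacer_length
  w_target <- d$window_position_of_target_A
  w_by <- if (nzchar(d$bystander_positions) &&
              !is.na(d$bystander_positions))
    as.integer(strsplit(d$bystander_positions, ",")[[1]]) else integer(0)
  vapply(c(w_target, w_by), window_pos_to_genomic, integer(1),
         s = d$protospacer_start, strand = d$strand, L = L)
}

# plus-strand ref/alt for the editor conversion on the protospacer strand
editor_plus_strand_change <- function(params, protospacer_strand) {
  if (params$editor_class == "ABE") {
    if (protospacer_strand == "+") c(ref = "A", alt = "G")
    else c(ref = "T", alt = "C")
  } else {
    if (protospacer_strand == "+") c(ref = "C", alt = "T")
    else c(ref = "G", alt = "A")
  }
}

consequence_one <- function(d, transcripts, genome, params,
                            include_bystanders) {
  pos_all <- design_edited_positions(d, params)
  if (!include_bystanders) pos_all <- pos_all[1]
  chg <- editor_plus_strand_change(params, d$strand)
  for (g in pos_all)
    if (base_at(genome, d$contig, g) != chg[["ref"]])
      stop("stale design ", d$sgRNA_id, ": base at ", d$contig, ":", g,
           " is ", base_at(genome, d$contig, g), ", expected ", chg[["ref"]])
  regions <- lapply(pos_all, classify_region, contig = d$contig,
                    transcripts = transcripts)
  pri <- vapply(regions, function(r) REGION_PRIORITY[[r]], integer(1))
  region <- as.character(regions[[which.max(pri)]])
  achieving_tx <- attr(regions[[which.max(pri)]], "transcript_id")
  effect <- "none"
  codon_ref <- codon_alt <- NA_character_
  if (region == "CDS") {
    # classify in the smallest-id coding isoform containing the edits in CDS
    ids <- sort(vapply(transcripts, `[[`, character(1), "transcript_id"))
    for (id in ids) {
      tx <- transcripts[[match(id, vapply(transcripts, `[[`, character(1),
                                          "transcript_id"))]]
      if (is.na(tx$cds_start) || tx$contig != d$contig) next
      cds_pos <- tx_cds_positions(tx)
      idx <- match(pos_all, cds_pos)
      # anchor on the target's codon; if only a bystander lands in this
      # isoform's CDS (include_bystanders case), anchor there instead
      anchor <- if (!is.na(idx[1])) 1L else which(!is.na(idx))[1]
      if (is.na(anchor) || !length(anchor)) next
      cds_seq <- tx_cds_seq(tx, genome)
      ci <- (idx[anchor] - 1L) %/% 3L + 1L
      codon_ref <- substr(cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
      alt <- codon_ref
      for (j in seq_along(pos_all)) {
        if (is.na(idx[j])) next
        cj <- (idx[j] - 1L) %/% 3L + 1L
        if (cj != ci) next  # bystander in a different codon
        off <- (idx[j] - 1L) %% 3L + 1L
        # convert the plus-strand alt base to the coding strand
        alt_base <- if (tx$strand == "+") chg[["alt"]] else
          chartr("ACGT", "TGCA", chg[["alt"]])
        substr(alt, off, off) <- alt_base
      }
      codon_alt <- alt
      effect <- codon_effect(codon_ref, codon_alt, ci)
      achieving_tx <- tx$transcript_id
      break
    }
  }
  data.frame(sgRNA_id = d$sgRNA_id, region = region,
             coding_effect = effect, codon_ref = codon_ref,
             codon_alt = codon_alt,
             affected_transcript_id = achieving_tx,
             includes_bystanders = include_bystanders,
             stringsAsFactors = FALSE)
}

#' Predict the consequence of a base-editor edit
#'
#' Applies the editor conversion (A>G for ABE, C>T for CBE, on the
#' protospacer strand) at the design's target base and, when
#' `include_bystanders = TRUE`, at bystander window positions; classifies
#' the edited position(s) through [classify_region()]; and for CDS edits
#' recomputes the affected codon to classify
#' missense/synonymous/stop_gained/stop_lost/start_lost. With
#' `include_bystanders = FALSE` (default) the call depends on the target
#' base alone. Stop-to-stop codon changes are reported as synonymous.
#'
#' @param designs design data.frame (one or more rows).
#' @param transcripts a `transcript_models` list.
#' @param genome a [genome_seq()].
#' @param include_bystanders fold bystander window edits into region and
#'   codon classification.
#' @param params the [editor_params()] the designs were made with.
#' @return data.frame of consequence calls, one row per design.
#' @export
predict_edit_consequence <- function(designs, transcripts, genome,
                                     include_bystanders = FALSE,
                                     params = editor_params()) {
  if (nrow(designs) == 0L)
    return(data.frame(sgRNA_id = character(0), region = character(0),
                      coding_effect = character(0),
                      codon_ref = character(0), codon_alt = character(0),
                      affected_transcript_id = character(0),
                      includes_bystanders = logical(0),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(designs)), function(i)
    consequence_one(designs[i, ], transcripts, genome, params,
                    include_bystanders))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Should a guide be excluded as missense-inducing?
#'
#' TRUE iff the predicted coding effect is missense. Significantly
#' enriched guides predicted to change an amino acid may act through the
#' protein rather than the methyl mark, so hit calling filters them out;
#' only missense is excluded (synonymous, UTR and stop-affecting calls
#' pass).
#'
#' @param calls consequence-call data.frame from
#'   [predict_edit_consequence()], or a design data.frame carrying a
#'   `coding_effect` column.
#' @return logical vector.
#' @export
is_missense_excluded <- function(calls) {
  if (is.null(calls$coding_effect)) stop("calls lack a coding_effect column")
  calls$coding_effect == "missense"
}
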