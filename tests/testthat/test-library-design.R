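# Editing-window sgRNA enumeration, library assembly, CRISPR-STOP designs.

test_that("the sliding window finds exactly the one valid placement", {
  g <- genome_seq(c(chrT = "TTTTTATTTTTTTTTTTTTTTGGTTTT"))
  site <- data.frame(site_id = "s1", contig = "chrT", pos = 5L,
                     strand = "+", gene = "G")
  d <- enumerate_editor_sgrnas(site, g, flank = 0)
  expect_equal(nrow(d), 1L)
  expect_equal(d$sequence, "TTTTTATTTTTTTTTTTTTT")
  expect_equal(d$PAM, "TGG")
  expect_equal(d$window_position_of_target_A, 6L)
  expect_equal(d$bystander_positions, "")
  expect_equal(d$protospacer_start, 0L)
})

test_that("no PAM downstream means no designs", {
  g <- genome_seq(c(chrT = paste(rep("T", 60), collapse = "")))
  ch <- strsplit(g[["chrT"]], "")[[1]]; ch[31] <- "A"
  g <- genome_seq(c(chrT = paste(ch, collapse = "")))  # no GG anywhere
  site <- data.frame(site_id = "s", contig = "chrT", pos = 30L,
                     strand = "+", gene = "G")
  expect_equal(nrow(enumerate_editor_sgrnas(site, g)), 0L)
})

test_that("enumeration equals the brute-force oracle on random contigs", {
  set.seed(101)
  params <- editor_params()
  for (i in 1:30) {
    len <- 300L
    ch <- strsplit(rand_dna(len), "")[[1]]
    pos <- sample(40:(len - 40), 3)
    strand <- sample(c("+", "-"), 3, replace = TRUE)
    for (k in 1:3)
      ch[pos[k] + 1] <- if (strand[k] == "+") "A" else "T"
    g <- genome_seq(c(c1 = paste(ch, collapse = "")))
    for (k in 1:3) {
      site <- data.frame(site_id = "s", contig = "c1", pos = pos[k],
                         strand = strand[k], gene = "G")
      mine <- enumerate_editor_sgrnas(site, g, params)
      orc <- oracle_enumerate(site, g, params)
      expect_equal(mine$protospacer_start, orc$protospacer_start)
      expect_equal(mine$sequence, orc$sequence)
      expect_equal(mine$PAM, orc$pam)
      expect_equal(mine$window_position_of_target_A, orc$w)
      expect_equal(mine$bystander_positions, orc$bystanders)
    }
  }
})

test_that("shifting a site by +1 shifts shared window positions consistently", {
  mk <- function(p, st) data.frame(site_id = "s", contig = "c1", pos = p,
                                   strand = st, gene = "G")
  # plus strand: AA at 100-101, the only PAM GG at 116-117 selects the
  # protospacer starting at 95 (window positions 6 and 7)
  ch <- rep("T", 200)
  ch[c(101, 102)] <- "A"
  ch[c(117, 118)] <- "G"
  g <- genome_seq(c(c1 = paste(ch, collapse = "")))
  d0 <- enumerate_editor_sgrnas(mk(100L, "+"), g)
  d1 <- enumerate_editor_sgrnas(mk(101L, "+"), g)
  shared <- intersect(d0$protospacer_start, d1$protospacer_start)
  expect_true(length(shared) >= 1)
  for (s in shared)
    expect_equal(
      d1$window_position_of_target_A[d1$protospacer_start == s],
      d0$window_position_of_target_A[d0$protospacer_start == s] + 1L)
  # minus strand (every plus-strand T reads A): plus-strand CC at 84-85
  # selects the antisense protospacer starting at 86; the window index
  # runs the other way
  ch2 <- rep("T", 200)
  ch2[c(84, 85)] <- "C"
  g2 <- genome_seq(c(c1 = paste(ch2, collapse = "")))
  m0 <- enumerate_editor_sgrnas(mk(100L, "-"), g2)
  m1 <- enumerate_editor_sgrnas(mk(101L, "-"), g2)
  shared <- intersect(m0$protospacer_start, m1$protospacer_start)
  expect_true(length(shared) >= 1)
  for (s in shared)
    expect_equal(
      m1$window_position_of_target_A[m1$protospacer_start == s],
      m0$window_position_of_target_A[m0$protospacer_start == s] - 1L)
})

test_that("an edited protospacer differs from reference at 1 + n_bystanders", {
  ref <- make_toy_reference(n_sites = 20, seed = 9)
  lib <- design_library(ref$sites, ref$genome, ref$transcripts)
  d <- lib$designs
  for (i in seq_len(nrow(d))) {
    nby <- if (nzchar(d$bystander_positions[i]))
      length(strsplit(d$bystander_positions[i], ",")[[1]]) else 0L
    edited <- chartr("A", "G", substr(d$sequence[i], 4, 8))
    before <- substr(d$sequence[i], 4, 8)
    ndiff <- sum(strsplit(edited, "")[[1]] != strsplit(before, "")[[1]])
    expect_equal(ndiff, 1L + nby)
  }
})

test_that("design_library counts sites and guides as set arithmetic demands", {
  # three sites on separate contigs with 1 / 1 / 2 controlled placements
  base <- "TTTTTATTTTTTTTTTTTTTTGGTTTT"         # one design (w = 6)
  two <- "TTTTTATTTTTTTTTTTTTTTGGGTTT"          # GGG: w = 6 and w = 5
  pad <- function(s) paste0(strrep("C", 40), s, strrep("C", 40))
  g <- genome_seq(c(c1 = pad(base), c2 = pad(base), c3 = pad(two)))
  sites <- data.frame(site_id = c("s1", "s2", "s3"),
                      contig = c("c1", "c2", "c3"),
                      pos = 45L, strand = "+", gene = "G",
                      stringsAsFactors = FALSE)
  lib <- design_library(sites, g, transcripts = NULL)
  expect_equal(lib$stats$n_sgrnas, 4L)
  expect_equal(lib$stats$n_sites_targeted, 3L)
  expect_equal(lib$stats$fraction_single_sgrna_sites, 2 / 3)
  expect_equal(sum(lib$stats$per_site_multiplicity *
                     as.integer(names(lib$stats$per_site_multiplicity))),
               lib$stats$n_sgrnas)
  # invariant to site input order
  lib2 <- design_library(sites[c(3, 1, 2), ], g, transcripts = NULL)
  expect_equal(lib2$stats$fraction_single_sgrna_sites, 2 / 3)
  expect_equal(nrow(design_library(sites, g, NULL,
                                   n_nontargeting = 0)$nontargeting), 0L)
  expect_error(design_library(sites[0, ], g, NULL), "empty")
})

test_that("non-targeting controls are absent from the genome and seeded", {
  ref <- make_toy_reference(n_sites = 10, seed = 2)
  ntc <- make_nontargeting_controls(25, ref$genome, seed = 99)
  expect_length(ntc, 25L)
  expect_false(any(duplicated(ntc)))
  both <- c(unlist(as.list(ref$genome)), revcomp(unlist(as.list(ref$genome))))
  for (s in ntc)
    expect_false(any(vapply(both, grepl, logical(1), pattern = s,
                            fixed = TRUE)))
  expect_identical(make_nontargeting_controls(25, ref$genome, seed = 99), ntc)
})

test_that("CRISPR-STOP designer annotates the forced codon conversions", {
  # CDS with a CAG codon whose C can reach the window with a valid PAM:
  # codon 4 = CAG at spliced 10..12
  cds <- paste0("ATG", "AAA", "TTT", "CAG", strrep("GGA", 12), "TAA")
  fx <- coding_fixture(cds = cds, utr5 = strrep("T", 30),
                       utr3 = paste0(strrep("T", 10), "GG", strrep("T", 28)))
  d <- design_stop_gain_controls("G1", fx$transcripts, fx$genome)
  expect_gt(nrow(d), 0L)
  cag <- d[d$codon_ref == "CAG", ]
  expect_true(all(cag$codon_alt == "TAG"))
  expect_true(all(cag$codon_index == 4L))
  expect_true(all(d$predicted_consequence == "CDS:stop_gained"))
  # a gene with no CDS is skipped with a warning
  nc <- fx$transcripts
  nc[["t1"]]$cds_start <- NA_integer_
  nc[["t1"]]$cds_end <- NA_integer_
  expect_warning(d0 <- design_stop_gain_controls("G1", nc, fx$genome),
                 "no coding transcript")
  expect_equal(nrow(d0), 0L)
})

test_that("TGG codons are convertible to stops through the antisense C", {
  # TGG at codon 3; antisense protospacer needs a CCN PAM on the plus
  # strand upstream; surround with Cs to supply it
  cds <- paste0("ATG", "AAA", "TGG", strrep("GAT", 10), "TAA")
  fx <- coding_fixture(cds = cds, utr5 = strrep("C", 30),
                       utr3 = strrep("T", 30))
  d <- design_stop_gain_controls("G1", fx$transcripts, fx$genome)
  tgg <- d[d$codon_ref == "TGG", ]
  expect_gt(nrow(tgg), 0L)
  expect_true(all(tgg$strand == "-"))
  expect_true(all(tgg$codon_alt %in% c("TAG", "TGA")))
})

test_that("stop-gain designs match the brute-force translation oracle", {
  set.seed(404)
  for (rep in 1:4) {
    # random 60-codon ORF seeded with 4 CAA codons, random background
    codons <- vapply(1:58, function(i)
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
            collapse = ""), character(1))
    codons[codons %in% c("TAA", "TAG", "TGA")] <- "CTT"
    codons[sample(10:50, 4)] <- "CAA"
    cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    fx <- coding_fixture(cds = cds, strand = sample(c("+", "-"), 1),
                         utr5 = rand_dna(40), utr3 = rand_dna(40))
    mine <- design_stop_gain_controls("G1", fx$transcripts, fx$genome)
    mine_key <- mine[order(mine$strand, mine$protospacer_start,
                           mine$edit_genomic_pos),
                     c("protospacer_start", "strand", "edit_genomic_pos")]
    orc <- oracle_stop_edits(fx$tx, fx$genome)
    expect_equal(unname(as.matrix(mine_key)),
                 unname(as.matrix(orc)), label = paste("rep", rep))
  }
})

test_that("bystander cap and multi-locus handling prune as configured", {
  # a window full of As yields bystanders; max_bystanders = 0 drops it
  g <- genome_seq(c(c1 = paste0(strrep("C", 40), "AAAAA",
                                strrep("C", 15), "CGG", strrep("C", 40))))
  # A's at offsets 40..44; targeting offset 44 puts it at window position
  # 5 of the protospacer starting at 40, with the A at 43 as a bystander
  site <- data.frame(site_id = "s", contig = "c1", pos = 44L,
                     strand = "+", gene = "G")
  d <- enumerate_editor_sgrnas(site, g)
  expect_true(any(nzchar(d$bystander_positions)))
  lib <- design_library(site, g, NULL, max_bystanders = 0)
  expect_equal(lib$stats$n_sgrnas, 0L)
})
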