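---
title: "Methods: base-editor screens for single-nucleotide m6A sites"
author: "m6ascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-editor screens for single-nucleotide m6A sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ascreen)
```

## The problem

N6-methyladenosine (m6A) marks individual adenosines on mRNAs and tunes
their stability and translation. Knockouts of writer or eraser enzymes
perturb thousands of sites at once, so they cannot say which *single*
site matters for a phenotype. An adenine base editor (ABE) offers a
site-level handle: an sgRNA placing the methylated adenosine inside the
editor's activity window converts it A>G on the DNA, permanently
removing the acceptor adenosine from the transcript. Pooling thousands
of such guides, differentiating the edited cells, and sorting the
phenotypic tails (here: CXCR4-positive definitive-endoderm cells versus
CXCR4-negative cells) turns m6A site function into a guide-abundance
readout.

`m6ascreen` implements the computation around such a screen: guide
design, edit-consequence annotation, read counting and normalization, a
negative-binomial (NB) enrichment test, and every classification rule
applied downstream. A synthetic-data module generates all inputs with
known ground truth, so each stage is testable without any external
download.

## Guide design

For a validated site (an `A` on the transcript strand at a known
genomic position), the designer slides the editing window one
nucleotide at a time: for every window position $w \in [w_{lo},
w_{hi}]$ it tests the unique protospacer placement that puts the site
at position $w$ (position 1 = PAM-distal 5' end) and keeps the
placement iff the PAM pattern matches immediately 3' of the
protospacer. Defaults are the canonical geometry shared by the
ABE7.10 and BE3 families: window 4–8, PAM NGG, 20-nt spacer, i.e. at
most five candidate protospacers per site. The protospacer strand is
forced to the transcript strand: deamination acts on the protospacer
strand, and on the opposite strand the site reads `T`.

Other window adenines are recorded as *bystanders* but never
disqualify a design (a `max_bystanders` filter exists, default
unlimited), and duplicated protospacer sequences are flagged
`multi_locus` rather than dropped — both choices reflect how pooled
base-editor libraries are actually built, where the design space is so
tight that most sites admit a single guide. Non-targeting controls are
random 20-mers screened against the genome by exact match only (they
stand in for controls drawn from an established library; no
mismatch-tolerant off-target search is attempted). Poly-T stretches
(Pol III terminators) are not filtered by default.

CRISPR-STOP control guides use the same placement machinery with the
CBE conversion (C>T): a design is kept iff the window edit converts a
coding codon to TAA/TAG/TGA — sense-strand edits of CAA/CAG/CGA, or
antisense edits of the cytosines paired with the G2/G3 of TGG.

## Consequence annotation

A small, deterministic subset of a variant-effect predictor covers the
categories the screen analysis needs. A genomic position is classified
against **all** isoforms and receives the highest-priority region any
isoform achieves, with priority CDS > 3'UTR > 5'UTR > intron >
intergenic; ties between isoforms are broken toward the
lexicographically smallest transcript id. For CDS edits the affected
codon is recomputed and classified as missense / synonymous /
stop_gained / stop_lost / start_lost. Conventions worth stating:

* stop-to-stop changes (e.g. TAA>TGA) are synonymous; ATG>GTG at the
  initiator is start_lost;
* by default the call depends on the target base only
  (`include_bystanders = FALSE`); folding bystanders in edits every
  recorded window position and classifies the combined codon;
* splice-site effects are not modelled — an intronic edit is "intron"
  whatever its distance to the junction;
* the category set has no non-coding-exon label, so positions inside
  non-coding transcripts are classified at intron priority (the
  synthetic generator emits coding transcripts only);
* region percentages reported for a real library depend on the gene
  build supplied as GTF; the package accepts any GTF with `gene_id`
  and `transcript_id` attributes.

Guides predicted to induce missense changes may act through the amino
acid rather than the methyl mark, so hit calling excludes them; only
missense is excluded (synonymous, UTR and stop-affecting calls pass).

## Quantification

Reads carry a constant 5' flank, the 20-nt guide, then vector
sequence. The flank is located by exact match at a 5' stagger offset
of 0–8 nt (stagger primers are standard in single-step amplicon
protocols) and the insert is looked up by exact 20-mer match — no
mismatch rescue, matching pooled-screen practice. If fewer than 10% of
the first 1000 reads contain the flank, the run aborts with
diagnostics rather than producing a silently empty column.

Normalization is total-count by default: counts are scaled so every
column sums to the mean raw library size. A DESeq-style median-ratio
alternative is provided (`method = "median_ratio"`; guides with any
zero are excluded from the reference) because screen-analysis
pipelines differ on this point. Per-guide log2 fold changes are
computed per replicate pair as $\log_2((n_i + c)/(d_i + c))$ with
pseudocount $c = 1$ by default (zeros occur in sorted-population
data), and summarized by the **median across replicates**. Guides
whose replicate-averaged normalized count falls below 200 in either
sorted population are removed from testing (low-coverage fold changes
are unstable); they are retained in all outputs with a
`low_count_removed` flag for auditability.

## The NB enrichment test

The statistical core is `screen_nb_test()`, which returns a classed
fit with `print`, `summary`, `coef`, `plot` and `simulate` methods.

**Mean–variance trend.** Per-replicate count variance is modelled as
$\sigma^2 = \mu + k\mu^b$ (Poisson noise plus power-law
overdispersion, the family used by count-based screen testers). With
three replicates an individual sample variance has ~2 degrees of
freedom; regressing $\log(s^2 - \hat\mu)$ on $\log\hat\mu$ guide by
guide is therefore badly biased (Jensen bias of the log of a noisy
variance, plus selection on $s^2 > \hat\mu$). The fit instead orders
guides by mean, pools them into equal-count bins (default 50), and
fits $\log(\mu + k\mu^b)$ to the log of the bin-averaged variance by
Nelder–Mead least squares; bin averages of many 2-df variances are
unbiased for the trend, and the guide-level regression supplies the
starting values. On simulated screens (20,000 guides, $k = 0.1$,
$b = 1.5$) both parameters are recovered within 15%.

**Tail probabilities.** For each guide the observed statistic is the
mean treatment abundance $\bar{x}_t$; the null is an NB distribution
moment-matched to mean $\hat\mu_c$ (the control mean) and variance

$$ v \;=\; (\hat\mu_c + k\hat\mu_c^{\,b})
   \left(\tfrac{1}{n_t} + \tfrac{1}{n_c}\right). $$

The $1/n_t$ term accounts for averaging over treatment replicates and
the $1/n_c$ term for the control mean itself being an estimate;
without this scaling the test is conservative and its size drifts far
from the nominal level. Tails are
$p_\mathrm{low} = P(X \le \lfloor \bar{x}_t \rfloor)$ and
$p_\mathrm{high} = P(X \ge \lceil \bar{x}_t \rceil)$, so both tails
contain the observed point and
$p_\mathrm{low} + p_\mathrm{high} \ge 1$. When the matched variance
falls at or below the mean the NB degenerates; a variance-matched
shifted Poisson is used instead. A zero control mean is a degenerate
null: $p_\mathrm{low} = 1$, and any non-zero observation is maximally
enriched. Under null NB simulation the fraction of guides with
$p_\mathrm{high} < 0.05$ sits at $0.05 \pm 0.01$ (10,000 guides).

**Hit rules.** Exactly the thresholds a sorted-tail base-editor screen
uses: a guide is enriched in the CXCR4+ population iff
$p_\mathrm{high} < 0.05$ and median LFC $> 0.58$ (fold change 1.5),
and in the CXCR4− population iff $p_\mathrm{low} < 0.05$ and median
LFC $< -0.58$; high-confidence calls tighten the LFC floor to 1. No
multiple-testing correction is applied — the joint p/LFC rule is
calibrated empirically by the non-targeting false-positive rate, which
`estimate_nontargeting_fpr()` reports per direction (a BH-adjusted
column can be added by the user from the raw tails). Missense-predicted
and non-targeting guides are never counted as hits. Sites are
direction-enriched iff at least one of their guides is, so site counts
never exceed guide counts.

Two further rules operate outside the sorted comparison: guides whose
baseline (undifferentiated) abundance exceeds both sorted populations
by more than 2-fold (replicate-median LFC > 1 against **both**) are
*toxic*, the mirror image *proliferative*; and two-timepoint
proliferation screens threshold the day-N/day-0 LFC at $|LFC| > 1$.

## The synthetic-data generator

`make_toy_reference()` builds one contig per transcript: 1–3 exons on
either strand, a clean ORF (ATG…stop, internal stops recoded), a 5'UTR
of 30–80 nt, a CDS of 60–150 codons and a 3'UTR of 280–380 nt. m6A
adenines are planted in DRACH context (GGACT, A central) inside the
last exon's 3'UTR — the region where the mark concentrates in real
maps. The PAM neighbourhood of each site is fully controlled: the
window-PAM union is scrubbed to a PAM-free background and exactly one
PAM planted (a second for a 25.8% fraction, reproducing the ~74%
single-guide-site fraction characteristic of base-editor libraries);
10% of sites are left deliberately untargetable. Guides-per-site is
therefore a designed property, not an accident of the random
background.

`simulate_screen_counts()` draws a latent per-guide abundance
(log-normal, spread 0.5) around a mean depth of 750 reads per guide —
chosen so the standard low-count filter removes about 0.4% of guides,
the removal rate seen in real sorted screens. True effects shift the
two sorted-population means symmetrically ($2^{+lfc/2}$ and
$2^{-lfc/2}$), so the NB noise (variance $\mu + k\mu^b$, defaults
$k = 0.1$, $b = 1.5$) is the only stochastic layer; toxic and
proliferative guides shift the baseline samples. An optional per-guide
editing efficiency in $[0,1]$ scales realized LFCs (default off),
emulating the observation that efficiently edited guides dominate real
hits. The 6% FACS tail fraction is recorded in the configuration; no
extra sampling layer is attached to it.

What the generator deliberately does **not** model: FACS gating noise,
multiple infection at higher MOI, PCR jackpotting beyond NB
overdispersion, position-dependent editing efficiency, and bystander
effects on the phenotype. Passing tests on synthetic screens therefore
demonstrate the correctness and calibration of the computation under
the stated noise model, not robustness to every artefact of real
data.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open genomic; BED is
  consumed natively, GTF converted on read. Converting a GTF exon in
  and back out is the identity.
* Readers reject rather than coerce: structurally malformed BED lines
  abort with the line number; semantically invalid records (bad
  strand, width ≠ 1, non-A base, duplicate id) are excluded with
  per-record reasons and counted.
* CDS bounds include the stop codon, so a well-formed spliced CDS
  starts with ATG and ends with a stop; sequence-level violations are
  warnings, not errors, because real annotation builds contain
  exceptions.
* The trend optimizer runs Nelder–Mead on $(\log k, b)$, so $k > 0$ by
  construction; a Poisson-limit dataset drives $k\mu^b$ toward zero
  rather than producing a negative dispersion. Fewer than 50
  overdispersed guides or fewer than two reference replicates are hard
  errors.
* Tail conventions use floor/ceiling of the (non-integer) replicate
  mean, which keeps the shared-point-mass invariant exact for integer
  and non-integer observations alike.
* RNG: each generator takes one integer seed; pipeline stages used
  together derive distinct small offsets from a single root seed, so
  every stage is reproducible in isolation and end-to-end runs are
  byte-identical under a fixed seed.

## Problem sizes used by the test-suite

The suite validates the designer against a brute-force
every-placement oracle on 100 random 2-kb contigs, the codon
classifier against a full-CDS translation oracle on 200+ random edits
(exact agreement required), type-I error on three null screens of
10,000 guides, trend recovery at 20,000 guides, and spiked-effect
recovery (200 true ±1.5-LFC guides among 8000, three seeds: recall
≥ 0.8, empirical FDR ≤ 0.15). These sizes were chosen as the smallest
at which the statistical assertions are stable across seeds.

## Known limitations

* The NB test is this package's own implementation of the
  sgRNA-level moment-matched tail test; it is calibrated against its
  stated null but does not promise numerical identity with any
  external screen-analysis tool's p-values.
* Consequence prediction covers the region/codon subset above — no
  splice, regulatory, NMD or protein-domain annotation.
* Exact-match counting discards reads with sequencing errors in the
  spacer; at typical error rates this costs a few percent of depth,
  uniformly across guides.
* Gene-level aggregation (α-RRA, MLE beta-scores), copy-number
  correction, off-target scoring and editing-efficiency prediction are
  out of scope; a supplied per-guide efficiency column is carried
  through unchanged.
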