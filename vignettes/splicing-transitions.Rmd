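---
title: "Calling and interpreting developmental splicing transitions with psitrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting developmental splicing transitions with psitrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psitrans)
```

## The analysis

Postnatal tissue maturation — the motivating system here is mouse skeletal
muscle between late gestation and adulthood — remodels the transcriptome on
two largely independent axes: which genes are expressed, and which protein
isoforms each gene produces through alternative splicing. `psitrans`
implements the computational core of that analysis as a small, fully tested
pipeline:

1. **PSI quantification.** Percent spliced in (PSI) of a cassette exon is
   the fraction of a gene's transcripts that include it, in percent. From
   RT-PCR band densitometry it is `100 * inclusion / (inclusion + skipping)`
   (`psi_from_bands()`). From junction read counts it is the
   length-normalized proportion
   `100 * (incl/len_incl) / (incl/len_incl + excl/len_excl)`
   (`psi_from_junction_counts()`), with a 95% credible interval from the
   Beta(incl + 1, excl + 1) posterior under a flat prior, mapped through the
   same normalization. The flat-prior Beta interval is a deliberately
   minimal substitute for a full Bayesian isoform model: closed form, no
   tuning, and its calibration is checked empirically (coverage within ±3
   points of 95% at depth 200 in the test suite).
2. **Transition calling.** For an ordered time course (default: E18.5 at
   −1.5 d, PN2, PN14, PN28 and adult at 154 d = 22 weeks), ΔPSI is computed
   per consecutive interval as *later − earlier*, so positive values mean
   more inclusion during development. An interval passes when |ΔPSI| ≥ 15
   points; the comparison is inclusive because the rule is "15 points or
   greater". Expression transitions use the analogous inclusive ±2-fold
   rule on floored values (`(later + 0.1)/(earlier + 0.1)`; the 0.1
   pseudo-value in FPKM-like units avoids division by zero and is a
   documented knob). Events are then timing-classified: `single_interval`
   (exactly one passing interval), `multi_interval`, or `none`, and interval
   counts can be duration-normalized to per-day rates
   (`rate_normalize()`), which matters because the intervals span 3.5 to
   126 days.
3. **ORF impact.** Each alternative exon is classified for reading-frame
   effect (cassette: length divisible by three; mutually exclusive pair:
   *difference* of partner lengths divisible by three, since the partners
   replace each other) and for its relative position `100·k/N`, where `k`
   numbers the exon within the inclusion transcript in transcription order
   and `N` is that transcript's exon count (the alternative exon counts in
   both — a 14-exon transcript with an alternative 13th exon is "13 of
   14"). The protein-level consequence is predicted by a coordinate
   cascade (`classify_coding_consequence()`) and independently verified by
   a translation oracle (`verify_against_oracle()`) that splices both
   isoforms, translates from the annotated start, and diffs the proteins.
4. **Conservation.** A transition is conserved between two species when
   both orthologous events change by ≥ 15 points in the same direction
   (`call_conservation()`); zero ΔPSI has no direction and can never be
   conserved.

The statistical surroundings are intentionally thin: the pipeline uses the
point-estimate thresholds above rather than per-interval significance
testing, hypergeometric over-representation with Benjamini–Hochberg
correction for gene-set enrichment (`enrichment_test()`, tested against a
brute-force enumeration oracle), and no negative-binomial differential
testing. These are documented simplifications, not omissions: the package's
contribution is the transition/consequence logic, and each simplification
is isolated behind one function.

## The coding-consequence cascade

Given a splice event and the reference transcript (the gene's transcript
with the longest exonic CDS; ties broken by lexicographic id, which favors
the full-length protein deterministically), the cascade is:

1. Mutually exclusive events are partner swaps (`mutually_exclusive_swap`).
2. An exon entirely outside the CDS is `utr5_only`/`utr3_only`
   (strand-aware).
3. An exon containing the annotated start codon is `start_codon`; one
   containing the annotated stop, or introducing an in-frame stop
   (standard nuclear code; scanned from sequence when available, otherwise
   supplied as an event annotation), is `stop_codon` — a C-terminal
   truncation at the protein level.
4. A frame-preserving exon fully inside the CDS is an internal peptide
   `insertion` or `deletion`. The orientation comes from the developmental
   direction: exons *gained* during development (positive ΔPSI) insert
   peptide into the adult isoform; exons lost delete it. This rule is an
   inference from the consistent pairing of positive ΔPSI with insertions
   and negative with deletions among validated calcium-gene events; the
   package makes it explicit and configurable via the `dpsi_sign` argument.
5. A frame-shifting exon produces an alternative N-terminus when it lies in
   the 5'-most quintile of exon positions (`relative_position ≤ 20`), an
   alternative C-terminus in the 3'-most quintile (≥ 80), and a mid-ORF
   amino-acid change otherwise. The quintile boundary is a configuration
   knob (`terminal_quintile`, default 0.2): the underlying observation is
   only that such exons are enriched near the mRNA ends, so any sharp
   boundary is a modeling choice; 20% makes the three classes exhaustive
   and mutually exclusive.

Two open points are resolved as follows. For mutually exclusive events whose
partner length is unknown (the packaged fixture prints only one partner),
the partner is assumed equal length — hence frame-preserving — and every
such row is flagged (`mxe_partner_assumed`). Exon numbering on minus-strand
genes uses transcription order, not genomic order.

The translation oracle is the package's independent check: it never reuses
the cascade's geometry beyond the definitional position quintiles for
frameshift subclassification, instead diffing actual translated proteins
(identical → UTR-only; missing start → start codon; truncated in-frame
inclusion → introduced stop; contiguous internal indel →
insertion/deletion; anything else → frameshift). On generated cohorts the
two routes must agree on 100% of events; disagreements are enumerated and
the test requires the list to be empty.

## What the generator emulates — and what it does not

`simulate_genome()` builds one gene per event: a 10–16 exon chain with
90–240 bp exons and 80–160 bp introns on its own chromosome, a CDS spanning
internal exons, random strand, and a planted event whose category is drawn
from weights loosely following the observed distribution (about 60%
frame-preserving, insertions outnumbering deletions, terminal changes
enriched at the 3' end, UTR-only events rare, 15% mutually exclusive). The
first ten genes deterministically cover all ten categories so every code
path is exercised at any cohort size. Coding sequence is drawn codon-wise
from the 61 non-stop codons (ATG start, TAA stop), so the clean isoform
translates end to end; planted stop-codon events inject an in-frame TAA
inside the alternative exon. Each built gene is immediately checked against
the translation oracle and rebuilt on the rare draws where a splice
junction happens to create a spurious stop; persistent failure is an error,
not a silent fallback.

`simulate_timecourse()` plants logistic PSI steps centered in the assigned
interval(s), steep enough that ≥ 99% of the step completes between the
interval's two sampled time points; the amplitude is scaled so the planted
ΔPSI is realized within 0.5 points. Planted magnitudes are drawn from
25–65 points (single-interval) or 20–45 (multi-interval) — deliberately
clear of the 15-point threshold so ground-truth labels remain meaningful at
finite sequencing depth; with depth-200 binomial counts the ΔPSI
measurement noise is about 5 points, giving a worst-case flip probability
of ~2% per interval. Non-transitioning events are flat with < 5 points of
jitter, half the calling threshold. Junction counts are
Binomial(Poisson-depth, PSI/100); expression is negative-binomial (size 25)
around log-normal baselines with planted 2.8–8-fold step changes in 30% of
genes; ortholog pairs copy the species-A ΔPSI plus Gaussian noise (default
SD 5 points) for conserved pairs (planted rate 11/17) and sign-flip or
shrink the rest.

Defaults encode the emulated study design: five time points at −1.5, 2,
14, 28 and 154 days; interval assignment weights 13:32:5:16 (most
transitions in the PN2–PN14 window); a 0.67 single-interval fraction; 500
events at depth 200 for recovery experiments. Those problem sizes keep the
full test suite under a minute of simulation while leaving binomial
recovery bounds tight (±4 points on a fraction at n ≈ 400 called events).

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: realistic splice-site motifs or alignment
artifacts, overdispersed or correlated junction counts (real biological
replicates vary more than binomial), overlapping genes and multi-event
genes, nonsense-mediated decay of stop-gaining isoforms, downstream-ATG
rescue of N-terminal frameshifts, and ortholog identification itself
(pairs arrive pre-matched). Recovery results on synthetic cohorts bound the
pipeline's algorithmic error, not the biological error of the thresholds.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed internally (the native R/Bioconductor
  convention); GTF is read/written 1-based closed and BED 0-based
  half-open, with round-trip tests guarding both conversions.
* PSI is carried in percent throughout; thresholds are inclusive (≥).
* PSI is undefined (error or `NA` cell, depending on context) when
  inclusion + exclusion evidence is zero; intervals with a missing PSI are
  *uncallable* and excluded from timing denominators rather than counted as
  failures. A cohort with nothing called reports a single-interval
  fraction of 0 alongside an explicit called-count of 0.
* Ties and determinism: event enumeration orders output by coordinate,
  prefers inclusion/exclusion transcript pairs that differ exactly by the
  alternative exon(s), and breaks remaining ties lexicographically; the
  generator derives independent RNG streams per stage from one seed, so
  changing the read depth cannot change the gene models.
* The enrichment significance flag uses adjusted p ≤ 0.05, the
  q-equivalent of the common −log10(p) ≥ 1.3 display cutoff, which is
  ambiguous in its usual presentation and therefore stated explicitly here.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_genes = 50)
dir <- tempfile()
simulate_dataset(cfg, dir)
res <- run_pipeline(dir, file.path(dir, "out"))

res$splicing_timing$single_fraction   # ~0.67 by construction
res$conservation$fraction             # ~11/17 by construction
head(res$consequences)                # per-event frame, position, category
write_report(file.path(dir, "out"))   # markdown summary of all six sections
```

## Known limitations

Only cassette and mutually exclusive events are typed and classified;
retained introns and alternative 5'/3' splice sites pass through I/O
untyped. The fold-change rule calls expression transitions without a
dispersion model, so its false-positive behavior on noisy single-replicate
designs is threshold-dependent. The insertion/deletion orientation rule
presumes the supplied ΔPSI sign summarizes the developmental direction; for
non-monotonic events the anchor interval choice matters (the pipeline uses
the PN2→PN28 change, matching the validated-event convention).
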