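---
title: "Methods: miRNA host-gene fusion analysis in mirfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA host-gene fusion analysis in mirfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `mirfuse`, the
decisions taken where the design was genuinely open, and what the synthetic
cohort does and does not emulate. It states no empirical result beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## The biological question and the analysis model

An intronic miRNA is processed co-transcriptionally from its host gene's
primary transcript. A fusion transcript with the host as **3′ partner**
replaces the host promoter with that of the 5′ partner; if the breakpoint
lies upstream of the miRNA (in the host's orientation), the miRNA remains in
the product (*miRNA-including*) and is now expressed from a foreign promoter.
Because any sufficiently active 5′ partner will do, recurrence is counted per
host gene ("miRNA-convergent" fusions), not per partner pair. The package
tests four linked hypotheses on a cohort: (i) host genes are overrepresented
among fusion partners beyond what gene size explains; (ii) the 5′ partners of
host fusions are highly expressed and have hypomethylated promoters; (iii)
they are enriched for cancer-relevant pathways and TF targets; and (iv) the
hosted miRNAs rise in samples carrying the fusion.

## Filtering

Fusion callers emit many artefacts. Two filters are applied before any
statistics:

* **Flag blacklist.** Events carrying any of 44 description flags
  (`fusioncatcher_blacklist()`) are removed. Matching is exact string
  equality after trimming and lower-casing — the list is a closed vocabulary.
  Substring matching would conflate entries such as `multi` with
  `1k<gap<10k`-style flags, so it is deliberately not used.
* **Proximity.** Intra-chromosomal events whose partner gene spans are
  separated by less than 10 000 bases are removed as probable read-through
  transcription, as are events flagged `adjacent`. The distance is the gap
  between the nearest span edges (overlapping spans count as 0) because
  read-through is a property of gene adjacency, not of the particular
  junction; the boundary is strict (`gap < 10000` removed, exactly 10 000
  kept). Whether the original analyses measured span edges or breakpoints is
  not documented anywhere we know of; the convention is recorded in the
  filter report so users can audit it.

Events whose partners are missing from the annotation are quarantined with a
warning, never silently dropped, and duplicated rows (same sample, partners
and breakpoints) collapse to one event keeping the maximum read count.

## Host assignment and inclusion classification

A precursor is assigned to a gene iff its interval is fully contained in the
gene span with matching strand. Nested genes are resolved by smallest span,
remaining ties lexicographically (logged). `intronic` is computed against
exon structure when the GTF provides it, otherwise assumed true and flagged.
Gene spans stand in for transcripts throughout — the analysis is gene-level
and exon-level splicing of the chimera is not modelled.

Inclusion classification is a pure function of coordinates and strand. For a
3′ host partner the retained region runs junction → transcription end in the
host's orientation (on `+`, larger coordinates; on `−`, smaller); for a 5′
host partner, transcription start → junction. The junction base itself is
treated as disrupted, so a precursor touching it is excluded. A breakpoint
inside the precursor therefore yields `MIREXCL` — a disrupted precursor
cannot yield a mature miRNA. Multi-miRNA hosts (clusters) are classified per
precursor and the event is `INCLUDED` if at least one precursor survives,
with per-precursor detail emitted. The test suite checks the classifier
against a brute-force retained-base-set oracle at every junction position of
a toy gene, on both strands and in both roles.

## Receptor status

ER/HER2 status is derived from marker expression (ESR1, ERBB2): positive iff
FPKM ≥ threshold. The inclusive boundary is a package convention; published
cutoffs state values, not boundaries. Default thresholds are 5.7 (ER) and
73.5 (HER2) FPKM. When IHC labels are available, a cohort-specific threshold
is fitted by scanning midpoints of sorted unique log2(FPKM+1) values for
minimal misclassification; the pseudocount stabilises the grid near zero.
Equivocal/intermediate labels are excluded from the fit but still receive
FPKM-based labels — the point of expression-based status is to rescue samples
with missing or ambiguous IHC. If the classes are inseparable the fit is
flagged degenerate (misclassification within 15% of the smaller class prior,
an allowance for the \(O(1/\sqrt{n})\) undershoot of an empirical optimal
cut).

## Host overrepresentation

The model is a binomial GLM: `fused ~ host + log10(size) + host:log10(size)`.
Gene size enters as log10 of the span because fusion probability plausibly
scales with length across orders of magnitude; it is centred so that, with
the interaction present, the host main effect is the log odds ratio at the
average gene size instead of an extrapolation to size zero. The model runs on
the expressed protein-coding universe. Perfect separation is detected
(non-convergence or |coef| > 15) and handled by a lightly ridge-penalised
refit, clearly labelled. The fit is validated in the tests against a
hand-written IRLS oracle to 1e-6, and on synthetic cohorts it recovers a
planted odds ratio of 3 within the stated tolerance; with a planted odds
ratio of 1 the Wald test holds its 5% size. Residual saturation bias (a gene
fused twice counts once) is why recovery is assessed at modest event counts.

## Partner distance

Distances are junction-to-junction, intra-chromosomal events only. The
primary test dichotomises at the pooled median and applies Fisher's exact
test to the 2×2 host-by-above/below table; a rank-sum test is reported as a
sensitivity check. The dichotomy was chosen as the declared primary because
the underlying claim ("host partners lie further apart") is about exceedance,
and the 2×2 form is robust to the heavy right tail of genomic distances.

## Expression and methylation contrasts

For each 5′ partner gene and category of its 3′ partner (host
miRNA-including, host miRNA-excluding, non-host, plus the same genes in
samples without fusions), the per-gene summary is the mean log2(FPKM+1) over
the relevant samples; categories are compared with two-sided Welch tests
(safer than pooled-variance when category sizes and spreads differ), BH
adjusted. The mirrored analysis for 3′ partners of 5′-host fusions is
available via `side = "3prime"`. Promoter methylation averages island betas
over CpG islands overlapping the strand-aware TSS−1000..+200 window
(closed-interval overlap) and tests log2(beta + ε) with ε = 1e-3 — the offset
for beta = 0 is not fixed by any convention we know; it is declared and
configurable.

## Overrepresentation with balanced subsampling

The universe is the expressed genes (per-gene 95th-percentile FPKM > 1,
linear-interpolation quantile). Gene lists and sets are intersected with the
universe before testing (standard ORA practice; logged). The p-value is the
one-sided hypergeometric upper tail; BH runs within each collection (GO,
KEGG, HALLMARK, REACTOME, TF targets are reported per collection). Because
the non-host 5′ partner list is several times larger than the host list,
three random subsamples of the non-host list matched to the host list's size
are tested and the per-set **mean of the BH-adjusted p-values** across draws
is reported. Averaging adjusted p-values is statistically unconventional
(Fisher combination would be the textbook route) but is kept for fidelity
with how such balanced comparisons are reported; the per-draw tables are
attached for anyone who prefers to combine differently. 5′ partners of
canonical snoRNA hosts are excluded from the non-host list since snoRNA hosts
are themselves fusion-prone and would contaminate the contrast. Sets smaller
than 5 (within the universe) are skipped by default; the bound is
configurable.

## miRNA differential expression

The exact test follows the edgeR `exactTest` tradition in a deliberately
simplified form: library sizes are equalised by scaling each column to the
geometric-mean library size; a single common dispersion is estimated by the
method of moments (median over features of `(var − mean)/mean²` on equalised
counts, clamped to [0, 5]); per feature, the rounded group totals are tested
conditionally on their sum. With a common per-library mean and dispersion the
sum over a group of libraries is negative binomial and the conditional law of
the split is free of the mean, so the two-sided p is the sum of conditional
probabilities of all outcomes at most as likely as the observed one, capped
at 1. As the dispersion goes to 0 this law is exactly Binomial(t, nA/(nA+nB)),
which the tests exploit as a closed-form oracle; edgeR itself serves as an
independent cross-check, never as the implementation. The simplification
(geometric-mean scaling + moment dispersion instead of quantile-adjusted CML)
is intentional: the scientific claim — which miRNAs rise when their host
gains a 3′ fusion — rests on the exact-test principle, not on the estimator
internals. Log fold-changes use group means with a prior count of 0.125 per
library. Groups are tumour-only: fused = samples where the host is a 3′
partner; unfused = samples with no event involving the host in either role;
samples with only 5′-role events are excluded from both, since such fusions
keep the host promoter and are not predicted to change miRNA expression.

Correlations between miRNA CPM and predicted-target expression use Pearson on
log2(x+1); protein-level (RPPA-like) values are used untransformed because
such arrays report already-normalised scores. Pairs with fewer than 10
complete observations are skipped; BH runs across all tested pairs per level.

## DNA-level confirmation

A fusion is confirmed when at least one read pair has one primary,
non-duplicate, mapq ≥ 1 mate inside each partner's gene span, counted once
per read name. The single-pair rule is kept as the confirmation criterion,
with the pair count exposed so users can demand more. mapq ≥ 1 excludes
unmapped and fully ambiguous placements; no proper-pair flag condition is
imposed — span membership of both mates is the criterion. Secondary and
supplementary alignments are ignored to avoid double counting split reads.

## The synthetic cohort

The generator plants exactly the statistical structure the analysis consumes:

* genes laid out without overlap on ≥2 chromosomes, both strands; a
  configured fraction host one intronic precursor (two mature products) in a
  genuine intron between two terminal exons;
* per tumour sample a Poisson number of fusions; the 3′ partner is sampled
  with weight `rank(expression)/n` times the planted odds ratio for hosts —
  the linear rank weight is the simplest monotone encoding of the observation
  that fusion detection depends on expression;
* breakpoints uniform within spans, resampled away from mature miRNAs by
  default so classifier branches can be tested in isolation;
* planted effects: +1.0 log2 expression uplift for 5′ partners of host
  fusions, −0.15 beta promoter shift for the same genes, and +2 log2
  fold-change for hosted matures in fused samples. The uplift and shift are
  calibration choices in natural units (no published effect sizes exist for
  them), chosen once as plausible mid-size effects;
* miRNA counts are negative binomial (dispersion 0.2 by default) with
  library sizes varying at most two-fold; methylation betas are Beta
  distributed around per-island baselines with clamping into (0, 1);
* marker-gene expression comes from two shifted log-normal components per
  receptor whose intersections sit near the packaged FPKM cutoffs, so
  threshold derivation has a recoverable target;
* WGS alignments are valid SAM with 1–10 bridging pairs planted for a
  configured fraction of events plus concordant background pairs.

Every generator section draws from a deterministically derived sub-seed of
one configuration seed, so a cohort is byte-identical under a fixed seed and
adding a section never perturbs earlier output. Default cohort dimensions
(100 samples, 400 genes, 20 fusions/sample) are desk-scale choices; the test
suite states the dimensions each experiment uses (e.g. 2 000 genes for the
odds-ratio recovery, 30 vs 300 samples for the DE recovery, 200 small
replicates for null calibration).

**What the generator does not emulate:** read sequences or sequencing error;
genome-wide methylation (one promoter island per gene); exon-level splicing
of chimeras; copy-number structure; correlated co-expression modules; normal
tissue receives no fusions. Passing tests therefore demonstrate correctness
of the statistical machinery under the planted model, not performance on
real tumour data, where artefact structure is richer than the flag vocabulary
and effect sizes vary per gene.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive throughout; BED input/output converts at
  the boundary.
* Shares are rounded half away from zero at the printed precision
  (`round_half_up()`), matching how cohort ratios are conventionally printed.
* Zero-total DE features get p = 1, logFC = 0, and a flag; zero-variance
  contrasts return p = 1 (equal means) or NA.
* Hypergeometric ties: the two-sided exact-test comparison uses a 1+1e-8
  relative tolerance when collecting outcomes "no more likely than observed",
  protecting against floating-point ties.
* The balanced-subsampling RNG is seeded explicitly and the seeds are logged;
  reruns are identical.
* Isoform-to-mature aggregation assigns by the isoform's 5′ end (larger
  coordinate on `−`), the only well-defined anchor when isoforms span arm
  boundaries. Coordinate-system conversion between assemblies is out of
  scope: all inputs are assumed on one assembly.

## Known limitations

* The logistic response is "ever fused", which saturates in dense cohorts;
  recurrence counts would need a count model (left to users).
* Averaged adjusted p-values from balanced subsampling have no direct
  error-rate interpretation; treat them as a comparable-scale summary.
* The moment estimator of dispersion is biased low for strongly unbalanced
  groups; supplying a known dispersion is supported and used by the tests
  where exactness matters.
* `run_pipeline()` is single-process by design; no workflow-manager
  integration.
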