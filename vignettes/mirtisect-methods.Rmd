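---
title: "Detecting tissue-enriched, tissue-specific and organ-specific miRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue-enriched, tissue-specific and organ-specific miRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtisect)
```

## The problem

A multi-tissue small-RNA sequencing atlas measures each miRNA's read count
across samples drawn from many tissues — here modelled on a rat body atlas
of 23 tissues grouped into 14 organs (four brain regions form the brain
organ; cortex, kidney and medulla the kidney; the two stomach compartments
the stomach; duodenum, ileum and jejunum the intestine; biceps and soleus
the muscle; the remaining tissues are their own organ), with ten animals
per tissue and five for the sex-specific tissues. The scientific question
is which miRNAs are *tissue-enriched* (TE: abundant in one tissue relative
to the rest), *tissue-specific* (TS: near-exclusive to one tissue) or
*organ-specific* (OS: near-exclusive to one organ). No single decision
rule is canonical, so mirtisect implements three complementary pipelines
that approach the question from different statistical angles, plus a
continuous summary (the tissue-specificity index) and an exact set-overlap
comparison of the pipelines' verdicts. Calls supported by several
pipelines carry more confidence than calls private to one.

## Normalization

Library depth varies across samples, so all display values and
proportion-based rules operate on trimmed-mean-of-M-values (TMM)
normalized counts-per-million. `tmm_factors()` computes the
Robinson–Oshlack factors via `edgeR::calcNormFactors` with the standard
trims (30% on log-ratios, 5% on absolute expression) and the usual
reference choice (the sample whose upper-quartile-scaled library is
closest to the mean); genes with a zero in either member of a pair are
excluded from the M/A computation because their log-ratios are undefined.
Factors are rescaled to geometric mean exactly 1 so they are comparable
across runs — the convention is arbitrary but fixing it makes factor
tables reproducible. `apply_tmm()` then computes
`count / (library_size × factor) × 1e6`.

The quasi-Poisson pipeline instead models per-million-ceiled counts
(`per_million_ceil()`): reads-per-million rounded up to integers, which
keeps a count-like support for the GLM. For short miRNA reads the
per-million transform is a pure depth scaling; no transcript length enters
(the "TPM" label this transform sometimes carries means something else in
mRNA work — a naming collision, not length normalization).

Each pipeline has its own abundance filter, applied exactly as stated by
its rule: strict `> 10` (NMF pipeline) or `> 3` (quasi-Poisson) summed
counts in at least one tissue, and for the proportion pipeline removal of
miRNAs whose TMM value is below 10 in *all* samples. All filters are
idempotent and preserve row order.

## Pipeline 1 — expression stratification and NMF

Tissue-level counts (summed over a tissue's animals) are collapsed to the
organ level by the **element-wise maximum** over member tissues: the
maximum, unlike the average, does not dilute a signal confined to one
member tissue of a multi-tissue organ.

Because a factorization of the raw matrix is dominated by the
highest-expressed miRNAs, the pipeline first fits a two-component Poisson
mixture by EM to a per-miRNA expression-level statistic and factorizes the
two strata separately. The statistic is the per-miRNA **total tissue
count**: a per-miRNA scalar is what makes "apply NMF to miRNAs of similar
expression level" actionable. A miRNA joins the high stratum when its
posterior probability of the high-rate component exceeds 0.5 (exactly 0.5
goes low — the tie rule matters only for the degenerate single-component
fallback, where all responsibilities are 0.5 by construction). The test
suite demonstrates the stratification's purpose directly: a
low-expression organ-exclusive miRNA that a single global factorization
misses (its share diluted below threshold by factors spent on
high-expression structure) is recovered when the low stratum is
factorized on its own.

Each stratum's matrix X (miRNA × organ, and miRNA × tissue) is decomposed
as X ≈ WH with W, H ≥ 0 by multiplicative updates minimizing the
generalized Kullback–Leibler divergence — the Poisson-compatible
objective for count data. The rank defaults to the number of columns of
the matrix being factorized (14 at organ level, 23 at tissue level,
capped at the stratum size), so each factor *can* specialize to one
column. Restart 1 uses a column-anchored initialization (each factor's
basis column starts as one of the rank highest-mass columns of X, with a
small positive floor so no entry is locked at zero by the multiplicative
updates); the remaining restarts are seeded random draws, and the run
with the lowest final objective wins, ties to the lowest restart index.
The anchored start exists because random initializations of
column-structured atlases frequently converge to local optima that merge
two exclusive columns into one factor; anchoring reaches the specialized
optimum reliably while the random restarts preserve generality. An
epsilon of 1e-12 guards all divisions and logs; the objective trace is
non-increasing (asserted in tests) and the whole procedure is
deterministic given the seed.

How "% of total expression" falls out of the factorization is a design
choice: rows of W are scaled to sum to 1 (the miRNA's loading
distribution over factors) and rows of H to sum to 1 (each factor's
distribution over organs), and the product of the two is the miRNA's
share vector over organs. The thresholds then read: TE in every organ
whose share reaches 0.60 (by default a miRNA may be TE in more than one
organ; `te_mode = "exclusive"` instead withholds TE when several organs
qualify — both readings of "60% in more than one tissue/organ" are
defensible, so both are exposed); OS for the maximum-share organ when its
share reaches 0.80; TS when the specific-level share occurs in exactly
one tissue **and** that tissue's organ carries an OS call — a TS miRNA
has to be OS, enforced structurally and checked by `validate_calls()`.

## Pipeline 2 — one-vs-rest quasi-Poisson GLM

For a target tissue, each miRNA's per-million-ceiled counts are modelled
as quasi-Poisson with log link: mean μ differs between target and rest,
variance φμ. The fit is an in-package IRLS (deliberately implemented
rather than wrapped, with `stats::glm(family = quasipoisson)` kept as an
independent cross-check in the tests, where the two agree to 1e-6); the
dispersion φ is the Pearson χ²/df estimate and the target-vs-rest
log-mean-ratio is tested two-sided against a t reference on n − 2 df.
TE requires `p < α` (strict; nominal by default, Benjamini–Hochberg
behind a flag) *and* a positive direction — the two-sided test with a
separate sign condition is the conservative reading of "significant with
a positive difference".

TS promotes a TE call when the target's TMM mean stands far enough above
every other group. "A number of percentage points above the maximum other
mean" admits two formalizations, both provided:
`excess = 100 (m_t − max other) / m_t ≥ P` (default) and
`share = 100 m_t / Σ m ≥ P`, with P = 90. The bundled liver/brain table
shows why both are kept: rno-miR-122-5p clears 90 points under either
reading while rno-miR-101b-3p (liver 9673.30 vs cerebellum 9333.53)
fails both. OS repeats the TE machinery with organ-vs-rest grouping
followed by the percentage rule on organ means.

Degenerate inputs are flagged, never silent: an all-zero miRNA reports
p = 1 and coefficient 0 (`all_zero`); a miRNA expressed in only one of
the two groups is perfectly separated, its coefficient capped at
log(1e8) with flag `separation` and p reported as 0 — no pseudocounts
are added, and perfect separation toward the target is maximal evidence
of enrichment, so it must not be lost to an infinite standard error.

Simulation places the test's operating characteristics where
quasi-likelihood theory predicts: on null negative-binomial counts
(mean 100, size 5, five samples per group) the empirical type-I error at
α = 0.05 sits near 0.045, the dispersion estimate averages ≈ 21 (the
theoretical φ = 1 + μ/size = 21), and planted 10× enrichments are
detected with ≥ 99% sensitivity.

## Pipeline 3 — proportion of total

Counts are first divided by each miRNA's number of genomic loci
(multi-mapped reads should not count once per locus), TMM-normalized and
filtered, then collapsed to per-tissue (and per-organ) means, and each
miRNA's shares are its row normalized to sum 1. TE requires the maximum
share strictly above 0.5; TS (tissue level) or OS (organ level) strictly
above 0.9. Proportions are computed on group *means* rather than pooled
totals, for consistency with the TMM means every pipeline displays; a
raw-count mode is available by flag since the rule was originally phrased
in aligned reads.

The same pipeline compares isomiRs: each isomiR's per-tissue proportion
is its mean divided by the summed mean of all isomiRs of the same mature
miRNA in that tissue; the dominant isomiR is the argmax (exact ties
broken lexicographically and flagged), and a mature miRNA is reported
when its dominant isomiR is not identical across the evaluated tissues.
The literal reading "differs between **all** tissues" (pairwise
all-different) is unsatisfiable for more tissues than isomiRs, so "not
identical across tissues" is used and documented here.

## Tissue-specificity index

For miRNA j over N ≥ 2 groups, with x_ij the group mean scaled by the
miRNA's maximal group mean,

TSI_j = Σ_i (1 − x_ij) / (N − 1).

TSI is 0 for a uniform profile, 1 for an exclusive one, invariant to
rescaling a profile, and unaffected by ties in the maximum. It is
computed on TMM group means. Zero-expression miRNAs are excluded with a
warning (the index is undefined at 0/0).

## Cross-pipeline comparison

`reconcile_ids()` maps each pipeline's identifiers through an optional
alias table (identity by default) onto a common namespace — pipelines
built on different annotation versions name the same molecule
differently — with a hard error for non-functional maps and a warned
deduplication when two members of one set collapse. `overlap_sets()`
partitions the union of two or three call sets into exact disjoint Venn
regions with member lists; region counts always sum to the union size.

## The synthetic atlas generator

`generate_atlas()` draws counts from
NB(mean = baseline_j × fold × library factor, size = dispersion) under
the full 23-tissue/14-organ layout with its real replicate numbers
(10 per tissue; 5 for ovary, uterus, testicle, with the appropriate sex
structure). Choices, made once:

* **Negative binomial, size 5** — overdispersed counts are the norm in
  RNA-seq and make the quasi-Poisson dispersion estimate meaningful
  (Poisson available via `dispersion = Inf`).
* **Per-miRNA baselines log-normal, median 100, sdlog 1.5** — real
  atlases span several orders of magnitude in expression; the spread is
  what gives the Poisson-mixture stratification something to stratify.
* **Library factors log-normal, sd 0.2** — moderate depth variation, so
  normalization does real work without dominating.
* **Planted effects** multiply the baseline in the target tissue or
  organ by a fold > 1; loci counts are drawn from {1, 2, 3} with
  probabilities (0.85, 0.10, 0.05).

The generator emulates the count structure, replicate design and
enrichment geometry of a real atlas. It does **not** emulate alignment
artefacts, ligation bias, annotation ambiguity between overlapping
miRNAs, correlated miRNAs from shared clusters, or sex effects within a
tissue — so passing recovery tests demonstrates the decision rules and
their thresholds behave as intended on clean planted signal, not that
any upstream processing is correct.

## Validation scale and reproducibility

The validation suite exercises: TSI against an independently coded
evaluation of the formula on 1,000 random profiles (agreement to 1e-12);
the IRLS against `stats::glm` on 20 random datasets (1e-6); TMM against a
straight-line transcription of the published procedure; type-I error and
sensitivity on 1,000 null plus 200 planted miRNAs; mixture recovery of
rates (5, 500) from 2,000 draws; NMF monotonicity over 50 seeded runs,
exact rank-1 reconstruction and block-support recovery; and an
end-to-end run on the full 215-sample atlas with 300 miRNAs and 20
planted tissue-exclusive miRNAs (fold 1000), where all three pipelines
recover ≥ 90% of the planted set and the three-way overlap region holds
≥ 80% of it. These sizes were chosen to give stable Monte-Carlo
estimates while keeping a full validation run in the tens of seconds.
Every stochastic step is seeded; `run_detection()` stamps each output
file with a hash of its configuration.

## Known limitations

* The share construction from W and H is one defensible reading of
  "post-normalization of the basis and coefficient matrices"; other
  constructions (e.g. column-normalized W) would shift TE/TS boundaries.
* The NMF rank is not selected from the data (no consensus clustering /
  cophenetic analysis); the each-factor-per-column default is a
  structural convention.
* Quasi-Poisson inference here is the plain dispersion-adjusted Wald
  test; spline-adjusted likelihood-ratio machinery found in dedicated
  packages is intentionally out of scope.
* The percentage-point TS rule's two modes can disagree near the
  threshold; neither is asserted as ground truth.
* P-values are nominal by default across many one-vs-rest contrasts;
  users scanning all tissues should consider the BH flag.
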