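---
title: "Occurrence-based core/transient partitioning of longitudinal reactor microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occurrence-based core/transient partitioning of longitudinal reactor microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremicro)
```

## The model and its assumptions

The package analyses longitudinal OTU count tables from multi-reactor
surveys: `n` reactors sampled at regular (monthly) timepoints, each sample a
vector of non-negative integer read counts over a common OTU set, with
bacterial and archaeal assays handled as independent tables. Three
assumptions shape every design choice:

1. **Detection is depth-limited.** An OTU "present" in a sample means "at
   least `detection_min_count` reads after subsampling to a fixed depth".
   Comparing presence across samples of different depth conflates biology
   with sequencing effort, so occurrence, diversity and membership
   (Jaccard) statistics are defined on the subsampled table; computing them
   on a raw table is possible but is the caller's explicit choice.
2. **Occurrence, not abundance, defines the core.** An OTU belongs to the
   core of a sample scope when its occurrence fraction exceeds the core
   threshold (default 0.80, strict), regardless of how abundant it is; it is
   transient when detected but below the transient threshold (default 0.20,
   strict). Abundance is accounted per partition afterwards. This
   deliberately includes rare-but-persistent taxa in the core, in contrast
   to "top-N most abundant" core definitions, which are out of scope.
3. **Scopes are first-class.** Digestion systems with distinct communities
   (wastewater digesters versus agricultural/bio-waste reactors) get their
   own cores by re-running the partition with the scope restricted to their
   samples — never by re-thresholding occurrences computed on the pooled
   scope. The same mechanism reproduces any other reading of "the analysed
   samples" (e.g. with or without storage-tank samples, which the metadata
   distinguishes via `reactor_role`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| subsampling depth | 11,550 (bacteria), 2,070 (archaea) | reads/sample | conventional fixed depths for the two assays; the detection floor is `1/depth` (0.0087% resp. 0.048%) |
| `min_total` (singleton filter) | 2 | reads | an OTU represented by a single read survey-wide is indistinguishable from sequencing error |
| `core_min_occurrence` | 0.80 (exclusive) | fraction | "present in over 80% of samples"; strict inequality so boundary ties are deterministic |
| `transient_max_occurrence` | 0.20 (exclusive) | fraction | "present in less than 20%"; exact boundary values land in `intermediate` |
| `detection_min_count` | 1 | reads | presence = at least one read at fixed depth |
| ANOSIM `n_permutations` | 999 | – | add-one p-value floor of 1/1000 |

Subsampling is **without replacement** (multivariate hypergeometric), one
independent draw per sample, matching rarefaction semantics: subsampled
counts can never exceed the originals and each retained sample sums exactly
to the depth. Each sample's draw uses an RNG substream derived as
`seed + sample index`, so dropping one sample never perturbs another
sample's draw. Samples below depth are dropped with a warning (their count
is logged in the pipeline manifest), never padded: fixed-depth comparability
is the point of the operation.

## Estimator variants and numerical choices

- **Inverse Simpson.** Two modes are provided: the plug-in `1 / sum(p_i^2)`
  ("mle") and the finite-sample `N(N-1) / sum(n_i(n_i-1))` ("unbiased", the
  default, matching the usual calculator in amplicon workflows). The
  unbiased form is undefined for all-singleton samples and returns `Inf`
  with a warning rather than a spurious number. **Evenness** always uses the
  mle form divided by richness: the unbiased ratio can exceed 1 (e.g. counts
  (5,5) give 2.25/2), which would break the documented 0–1 scale of the
  evenness coefficient. This divergence between the two conventions is
  deliberate and documented here.
- **Rarefaction.** The analytic curve is the exact hypergeometric
  expectation `E[S_d] = sum_j (1 - C(N-n_j, d)/C(N, d))`, evaluated in log
  space (`lchoose`) to avoid overflow; the resampling route is provided for
  cross-validation and agrees within Monte-Carlo error (the tests assert 3
  standard errors). At `d = N` both recover observed richness exactly.
- **Ties and determinism.** Rank-abundance curves break abundance ties by
  OTU id; ANOSIM uses mid-ranks for tied distances; hierarchical clustering
  and every stochastic routine take an explicit seed. Rerunning the pipeline
  with the same config and seed reproduces byte-identical text outputs.
- **ANOSIM.** `R = (mean between-group rank - mean within-group rank) /
  (M/2)` with `M = n(n-1)/2` ranked distances, Clarke's scaling, so `R = 1`
  at perfect separation and `R = 0` for exchangeable (e.g. constant)
  distances. Permutation p-values use the add-one estimator; for small
  designs `exact = TRUE` enumerates all distinct label sequences instead
  (two groups of three: 20 sequences), and the tests verify the permutation
  route against that enumeration.
- **NMDS.** Monotone-regression stress minimisation (stress-1) from a
  classical-scaling start plus random restarts; the reported `r2` is the
  squared Pearson correlation between ordination distances and input
  dissimilarities (the "linear fit" of a Shepard plot) — one of several
  conventions in circulation, so it is named explicitly in the output
  documentation.
- **Cluster assignment.** Ordination clusters in survey reports are usually
  delineated visually; as a reproducible stand-in the package uses
  average-linkage agglomeration on Bray–Curtis with user-chosen `k`,
  validated post hoc with ANOSIM. This is a pragmatic default, not a claim
  that average linkage is the "true" cluster model.
- **Partition subsets.** Dissimilarities on core-only or transient-only
  tables use the subset counts **without renormalisation** (a
  renormalisation is available via `to_relative` on the subset), keeping the
  Bray–Curtis numerator and denominator interpretable as read overlap at
  the original depth.
- **Degenerate inputs.** Zero-total samples are an error wherever relative
  abundance is needed, and are reported by `validate_dataset`; empty OTU
  subsets give a zero-column table with a warning; OTUs never detected in a
  scope are excluded from that scope's partition universe (they cannot be
  "transient in" samples they never appear in); all-zero pairs make
  Bray–Curtis and Jaccard undefined and raise errors rather than returning
  0 or 1.
- **Stability schemes.** Within-group dissimilarity summaries support
  `all_pairs` (default: boxplot-style aggregation over every within-group
  pair) and `consecutive` (month-to-month pairs only); both are labelled in
  the output so either pooling convention can be reproduced, including
  grouping by reactor or by externally assigned cluster.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults encode the survey design the pipeline targets:
20 reactors (2 farm, 12 bio-waste, 3 municipal-solid-waste, 3 wastewater) in
10 units, 12 monthly samples each, 6,000 OTUs at depth 11,550, a core
fraction of 2.5% of OTUs planted to carry 70% of reads per sample, 84%
transient OTUs planted to carry ~3.5%, and two digestion systems whose core
pools share 10% of their members.

The generative model, per reactor: core OTUs receive system-specific
log-normal base abundances rescaled to the target core share; intermediate
OTUs are system-specific and present in a uniform 30–70% fraction of their
system's reactors; transient OTUs appear in each sample as independent
Bernoulli(0.02) events at low abundance. Each month's composition is a
Dirichlet draw around the reactor profile, mixed with the previous month via
an AR(1) coefficient (default 0.3), and reads are multinomial at the target
depth. Nominated "turnover" reactors instead draw fresh low-concentration
compositions every month, providing a planted stability contrast.

Three internal constants deserve justification:

- **Dirichlet concentration 600** makes replicate samples of one reactor
  differ by a Bray–Curtis of roughly 0.2–0.3 — the within-reactor spread a
  stably operated digester plausibly shows — while keeping the two systems
  fully separable.
- **Abundance floors** (core 2×10⁻³, intermediate ~1.05×10⁻³ expected
  relative abundance) keep planted labels *observable*: below about one
  expected read per 10³ at depth 5,000, Dirichlet skew makes per-sample
  detection so unreliable that a planted core OTU's realised occurrence
  would drift under 0.8 — a property of detection, not of the partition
  logic. The floors are computed from the binomial detection probability at
  the working depths, not fitted to any result.
- **System-specific intermediates.** A shared intermediate pool cannot
  simultaneously satisfy the per-sample abundance budget (1 − 0.70 − 0.035
  = 26.5% of reads over ~800 OTUs) and per-reactor detectability; splitting
  intermediates between systems (like the cores, mirroring the observation
  that only a minority of OTUs are common to both systems) resolves the
  tension and is ecologically the more realistic structure.

What the generator does **not** emulate: taxonomic structure (lineages are
plumbing only), sequence-level artefacts (chimeras, primer bias), covariate
effects on composition (physicochemical metadata are cosmetic draws from
category-typical ranges unless a caller wires them in), seasonal phenology
beyond AR(1) drift, and the real survey's unequal library sizes. Passing the
planted-recovery tests therefore demonstrates that the *pipeline* is correct
and well-calibrated under its stated detection model — not that any
particular biological dataset will show an equally clean partition.

## Scoring recovery against planted truth

`recovery_report()` compares a partition with the planted labels of its
system: precision and recall of the core and transient sets, and the
absolute error between the recovered core's read share and the planted
target. Recall is computed over planted OTUs *detected in the scope*
(`n_detected` alongside `n_planted` makes the distinction visible): with a
2% per-sample presence rate, a few percent of planted transients never
materialise as a read in a given scope and are unclassifiable in principle.
An empty recovered set flags precision as `NA` rather than reporting a
misleading 0 or 1.

## Problem sizes used by the test suite

The suite validates operations on small enumerable fixtures (hand-computed
hypergeometric and rank statistics, exact ANOSIM enumeration at n = 6),
property checks on randomly generated tables, and full-size synthetic
surveys: 240 samples × 6,000 OTUs for the partition-algebra checks, five
seeds of the 20-reactor design at depth 5,000 for label recovery, ten seeds
of a 6-reactor design for stability contrasts, and 1,000 null simulations
(12 samples, 199 permutations) for ANOSIM type-I calibration at the 5%
level. These sizes were chosen as the smallest at which each property is
statistically unambiguous.

## Known limitations

- Occurrence thresholds are step functions: an OTU at occurrence 0.79 versus
  0.81 lands in different partitions despite a biologically negligible
  difference. The thresholds are configurable, and the monotonicity of the
  core in the threshold (asserted in the tests) makes sensitivity analyses
  cheap.
- The unbiased inverse Simpson estimator and the mle-based evenness are
  internally consistent but not interchangeable with every published
  convention; compare like with like.
- ANOSIM assumes exchangeability of samples under the null; with strong
  within-reactor autocorrelation, whole-sample permutation across reactors
  is anti-conservative for reactor-level questions. For such designs,
  aggregate per reactor first.
- NMDS from random starts can converge to local optima; the multi-start
  default (classical-scaling start plus random restarts under a fixed seed)
  mitigates but does not eliminate this.
- The Dirichlet-multinomial noise model has a single concentration per
  reactor; real surveys show OTU-specific dispersion that the generator does
  not attempt to reproduce.
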