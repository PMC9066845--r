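---
title: "Direct-target gene signatures from ChIP-seq and RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct-target gene signatures from ChIP-seq and RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hif2sig)
```

# The scientific problem

Loss or mutation of the VHL tumor suppressor stabilizes the transcription
factor HIF2α, whose chromatin binding reprograms renal carcinoma cells. Two
kinds of evidence identify the genes HIF2α *directly* drives: a ChIP-seq
peak in the gene's promoter, and a transcriptional response in a
mutant-vs-control RNA-seq contrast. `hif2sig` operationalizes the
intersection of the two into a signed gene signature, scores patient
cohorts with it, and asks whether the score tracks EMT, hypoxia, tumor
status and survival. This vignette explains each model, its assumptions,
and the package's numerical and design choices.

# Coordinates and peak geometry

All internal coordinates are **0-based, half-open** — the BED convention.
Conversion happens exactly once, at the GTF boundary (`read_gene_model`,
`write_gene_model`), which prevents the classic off-by-one drift between
tools. The TSS of a plus-strand gene is its span start; for a minus-strand
gene it is `end − 1`, the 0-based coordinate of the first transcribed base.

A peak is represented by its **anchor**: the narrowPeak summit when one was
called, otherwise the floor midpoint. Anchor-based classification (rather
than whole-interval overlap) makes every peak fall in exactly one category
and matches the dominant annotation convention. The category priority is

> Promoter ≤ 1 kb > Promoter 1–2 kb > Promoter 2–3 kb > 5′UTR > 3′UTR >
> Exon > Intron > Downstream ≤ 3 kb > Distal intergenic,

mirroring ChIPseeker-style defaults. Promoter bins are two-sided (unsigned
TSS distance), because pie-chart annotation categories are conventionally
unsigned. "Downstream" means within 3 kb past the strand-aware 3′ end.

The promoter window for direct-target calling is **TSS ± 5 kb with both
endpoint bases included** (`promoter_window` returns
`[TSS − 5000, TSS + 5000 + 1)`), reading "±" inclusively. Peak-to-gene
assignment uses anchor containment in that window; a peak can support
several genes when windows overlap, and every supporting peak is recorded.
Where whole-peak overlap rather than anchor containment is wanted, the
window can simply be widened by the peak half-width.

`compare_peak_sets` declares a peak "common" when it overlaps a peak of the
other set by at least `min_overlap` bp (default 1); abutting half-open
intervals do not overlap. Overlap queries run on GenomicRanges/IRanges
internally; the test suite checks them against a brute-force O(n·m) scan.

# The differential-expression model

The DE module re-implements the negative-binomial Wald framework rather
than wrapping an existing implementation, in a deliberately documented
simplification:

* **Size factors** are classical median-of-ratios: for sample *j*,
  `s_j = median_g k_gj / (∏_j k_gj)^{1/m}` over genes with nonzero counts
  in every sample. Factors are not renormalized. (The test suite
  cross-checks against DESeq2's `estimateSizeFactorsForMatrix`; agreement
  is ~1e−5, the residual coming from DESeq2 interpolating the even-count
  median on the log scale.)
* **Dispersions**: per-gene method-of-moments
  `α̂ = max(α_min, (v − μ̄)/μ̄²)` with `v` the pooled within-condition
  variance of normalized counts; a mean–dispersion trend `α(μ) = a0 + a1/μ`
  fit by least squares over genes with `α̂ > α_min` (coefficients clamped
  ≥ 0); and log-space shrinkage
  `log α* = (1 − δ) log α̂ + δ log α_trend(μ̄)` with `δ = 0.5`, clamped to
  `[1e−8, 10]`. This replaces Cox–Reid empirical Bayes with a fixed-weight
  geometric compromise — cruder, but transparent, testable, and adequate at
  the 2–6-replicate scale the package targets. With only two replicates
  per condition the per-gene estimate is very noisy; pooling variance
  across all conditions and shrinking toward the trend is what makes the
  two-replicate design workable.
* **The Wald test** fits, per gene, an NB GLM with log link, intercept +
  condition indicator, and `log s_j` offsets, by expected-information IRLS
  at the fixed final dispersion (weights `μ/(1 + αμ)`), vectorized across
  genes. `log2fc = β₁/ln 2`, its standard error comes from the 2×2
  expected-information matrix, and the two-sided p-value from the normal
  approximation. All-zero genes report `log2fc = 0, p = 1`; genes that do
  not converge in 50 iterations (or run away, `|β₁| > 50` nats, the
  separation signature of an all-zero group) get `p = NA` and are excluded
  from the BH denominator. No independent filtering, outlier replacement
  or LFC shrinkage is applied: rankings use the raw Wald statistic.
* **DE calls** use FDR < 0.05 (strict) and |log2fc| ≥ 1 (inclusive). The
  fold-change boundary is inclusive because "≥ 1" is the natural reading of
  the threshold; at exactly 2-fold a gene is called.
* **VST** uses the closed form for the `a0 + a1/μ` trend,
  `v(q) = log2((1 + a1 + 2a0·q + 2√(a0·q(1 + a1 + a0·q)))/(4a0))`,
  strictly increasing with slope → 1 (in log2 units) at large counts. When
  the fitted `a0` is not positive — essentially Poisson data, which have no
  stabilizing asymptote — the transform falls back to `log2(q + 1)` with a
  warning.

The four-condition design (EV, VHL-WT, S65P, S65W; two replicates each) is
analyzed as pairwise two-condition contrasts (mutant vs WT, or vs EV);
multi-factor designs are out of scope.

# Preranked GSEA

Genes are ranked by the Wald statistic, descending, ties broken
lexicographically so the ranking is a deterministic function of the input.
The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic with exponent 1 ("weighted"): hits add `|score|/N_R`, misses
subtract `1/(N − N_H)`; the ES is the extremum of maximal absolute
deviation, and the leading edge collects hits at or before it (at or after,
for negative ES).

The null is **size-matched random gene sets** drawn from the ranked
universe — the appropriate preranked null here, since with two replicates
per condition sample permutation is impossible. The nominal p-value is the
same-sign tail frequency with a +1 pseudocount (never exactly zero), NES
divides the ES by the mean |same-sign null ES| of its size class, and the
FDR q pools all size-normalized null NES against observed NES of the same
sign. Defaults follow the tool conventions of the target analysis: 1000
permutations, maximum set size 5000; the minimum size (5) is the usual tool
default family and is exposed as a parameter rather than asserted. For
permutation work the ES uses a closed form over hit positions only
(extremes can occur only adjacent to hits), which the tests verify against
the full walk and, for the observed statistic, against `fgsea`'s
`calcGseaStat`. Fixed seed gives bit-identical results.

# Signature construction and cohort scoring

`build_signature` intersects DE calls with the promoter-binding map and
assigns weight **sign(log2fc) ∈ {+1, −1}**. Sign weights are the minimal
reading of "weighted sums", make the score scale-free, and avoid letting a
single extreme fold change dominate; magnitude weighting
(`weight_by = "log2fc"`) is available behind a flag. Each signature gene
records its provenance: fold change, FDR, and the supporting peak closest
to the TSS.

Cohort "normalized expression" is the **per-gene cohort z-score**
(population of the cohort at hand; constant genes become zeros), which
makes weighted sums comparable across genes and platforms. The EMT score is
the mesenchymal-minus-epithelial difference of mean z-scores over a signed
76-gene set; higher = more mesenchymal. The hypoxia score follows the
median-dichotomization rule of the mRNA-based hypoxia-score literature:
per gene, +1 above the cohort median, −1 otherwise, summed over the
signature; values exactly at the median count −1, a deterministic tie rule
(with even cohorts and continuous expression the choice is immaterial; the
tests pin it down).

Association tests are the field's standard ones, called from base R /
`survival` behind the module interface: Pearson correlation with the
t-transform p-value; Mann–Whitney U (exact for combined n ≤ 10 without
ties, normal approximation with tie correction otherwise) or
Kruskal–Wallis for >2 groups; pooled-variance two-sided t for assay-style
two-group comparisons.

# Survival analysis

`signature_survival` composes z-scoring → weighted-sum scoring → median
split → per-stratum Kaplan–Meier + log-rank, plus a Cox fit on the
continuous standardized score — the score's effect size (HR per SD) is
better estimated continuously, while KM curves need strata. Median-split
ties go to the low stratum. Estimation is delegated to the `survival`
package with **Breslow tie handling** (simpler than the Efron default and
adequate at cohort scale; the choice is pinned in code and tests, including
the identity between the Cox score test at β = 0 and the log-rank
statistic). Monotone-likelihood warnings from `coxph` are promoted to
errors naming the condition. One caveat is inherent to the design: the
median split is performed on the full matched cohort, so the log-rank
p-value is in-sample and should be read as association, not as a validated
prognostic classifier.

# The synthetic-data generators

Every generator is a pure function of (parameters, seed) via a scoped RNG,
so fixtures are bit-reproducible and carried as code, not files.

* `make_genome` lays out genes at fixed spacing (default 2000 genes, 10 kb
  spans, 30 kb spacing, two chromosomes) with random strands, 2–5 exons and
  terminal UTRs — enough geometry for every annotation category to occur.
* `simulate_counts` draws NB counts with constant dispersion (default
  α = 0.05, a typical well-behaved bulk value) around log-uniform baseline
  means, mild log-normal library factors, and planted per-condition log2
  fold changes. The default design is the target study's: four conditions
  × two replicates.
* `simulate_peaks` plants one 400-bp summit-bearing peak inside TSS ± 5 kb
  of each target gene and places background peaks with a controlled
  promoter-proximal fraction. Background summits avoid the promoter
  windows of genes declared DE-only, because the ground-truth categories
  (direct target / DE-only / peak-only) must stay disjoint for
  recall/precision to be well defined.
* `simulate_cohort` gives each sample a latent signature activity (tumors
  shifted up by 1.5 SD — a strong but realistic bulk separation), EMT and
  hypoxia axes correlated with standardized activity at the requested r
  (default 0.6), and expression = (signed signature loading · activity) +
  unit Gaussian noise, analogously for EMT/hypoxia genes, plus pure-noise
  background genes. Survival is exponential with hazard
  `∝ exp(β · standardized activity)` (default β = 0.7, HR ≈ 2 per SD) and
  uniform censoring calibrated to a 30% censored fraction by choosing the
  censoring scale as the empirical (1 − frac) quantile of `T/U`.

What the generators deliberately do **not** emulate: per-gene dispersion
heterogeneity (available as an option but off by default to keep oracle
math closed-form), batch effects, GC/length bias, fragment-level ChIP
coverage, correlated gene-gene noise, and non-proportional hazards. Passing
tests therefore demonstrate correctness of the *statistical machinery* on
data satisfying the model assumptions — not robustness to the full mess of
real data.

# Problem sizes, tolerances and numerical choices

The test and acceptance workloads were sized to what the statistics need,
not more: 2000-gene experiments for DE calibration and recovery (binomial
standard error ~0.5% on a 5% rate), 1000 Monte-Carlo replicates for
log-rank and Cox type-I calibration (se ~0.7%), 10⁵ permutations against
exact enumeration for the GSEA null (3× binomial se criterion), 200
repetitions for p-value uniformity KS checks, and n = 300–500 cohorts for
correlation and hazard recovery (se of r ~0.04 at n = 300). Tolerances in
tests derive from these Monte-Carlo standard errors, never from matching a
desired answer.

Numerical guards worth knowing: IRLS convergence is `|Δβ| < 1e−8` with a
50-iteration cap; dispersions clamp to `[1e−8, 10]`; trend coefficients
clamp at 0 with a positive floor when evaluated; the GSEA p-value carries a
+1 pseudocount; file writers format floats at 6 significant digits so
byte-identical inputs give byte-identical outputs (the pipeline manifest
records MD5 checksums on that basis).

# Known limitations

* Two-condition contrasts only; no likelihood-ratio tests, no multi-factor
  or paired designs.
* Gene identity is the symbol, matched case-sensitively; cross-annotation
  identifier reconciliation is the caller's responsibility.
* The dispersion shrinkage is a fixed-weight compromise, not empirical
  Bayes; with many replicates it over-shrinks relative to Cox–Reid.
* The packaged EMT/hypoxia gene sets are synthetic stand-ins with the
  documented sizes (76 signed genes; 200-gene pathway set); real signed
  lists should replace them in applied work.
* Survival stratification is in-sample (see above); endpoints
  (progression-free, disease-specific, overall) are whatever the clinical
  table's `time`/`event` columns encode.
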