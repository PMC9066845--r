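# hif2sig

Discovery and clinical evaluation of transcription-factor **direct-target
gene signatures**, built for the VHL/HIF2α axis in clear cell renal cell
carcinoma (ccRCC) but applicable to any factor with ChIP-seq peaks and a
matched differential-expression experiment.

When the von Hippel–Lindau tumor suppressor (pVHL) is defective — or carries
gain-of-function missense mutations such as S65P/S65W — the hypoxia-inducible
factor HIF2α escapes degradation, binds chromatin, and rewires the
transcriptome. A gene is a *direct target* when it satisfies both criteria:

1. **binding** — a HIF2α ChIP-seq peak whose summit (or midpoint) lies in the
   promoter window TSS ± 5 kb, and
2. **response** — differential expression in the mutant-vs-wild-type
   RNA-seq contrast at FDR < 0.05 and |log2 fold change| ≥ 1.

Direct targets form a signed signature (+1 up, −1 down). A cohort sample's
signature score is the weighted sum of its per-gene z-scored expression,

  score(j) = Σ_g w_g · z_gj ,

which is then tested for association with epithelial–mesenchymal transition
(EMT) and hypoxia scores (Pearson), tumor/normal status (Mann–Whitney /
Kruskal–Wallis), and survival (median split → Kaplan–Meier + log-rank, plus a
Cox proportional-hazards fit on the continuous score).

## What the package implements

| Stage | Functions | Notes |
|---|---|---|
| IO | `read_bed`, `read_gene_model`, `read_gmt`, `read_signed_set`, `read_matrix`, `read_clinical` (+ writers) | strict validation; BED/narrowPeak stay 0-based half-open, GTF converts 1-based↔0-based at the boundary |
| Peak geometry | `tss_position`, `promoter_window`, `compare_peak_sets`, `annotate_peaks`, `annotation_summary`, `map_peaks_to_genes` | promoter ≤1/1–2/2–3 kb > 5′UTR > 3′UTR > exon > intron > downstream ≤3 kb > distal intergenic |
| Differential expression | `size_factors`, `estimate_dispersions`, `nb_wald_test`, `bh_adjust`, `vst_transform`, `call_de`, `sample_distance_matrix` | re-implemented NB–Wald framework: median-of-ratios, method-of-moments dispersions shrunk toward an `a0 + a1/μ` trend, expected-information IRLS |
| GSEA | `ranked_list`, `enrichment_score`, `preranked_gsea` | weighted-KS statistic, size-matched gene-permutation null, NES/FDR |
| Signatures & scoring | `build_signature`, `zscore_normalize`, `signature_score`, `emt_score`, `hypoxia_score`, `pearson_correlation`, `compare_groups`, `two_sample_t` | the integration step; EMT = mesenchymal − epithelial mean z; hypoxia = ±1 median dichotomization |
| Survival | `km_estimate`, `logrank_test`, `cox_fit`, `median_stratify`, `signature_survival` | fronts the `survival` package (Breslow ties) |
| Synthetic data | `make_genome`, `simulate_counts`, `simulate_peaks`, `simulate_cohort`, `simulate_study` | planted ground truth for every stage |
| Orchestration | `validate_config`, `run_pipeline` | YAML config → staged TSV outputs + checksum manifest |

## Worked example

The `"paperlike"` synthetic study mirrors the target experimental design:
four conditions (EV, VHL-WT, S65P, S65W) with two replicates each, 2000
genes, 30 planted direct targets of the S65W condition.

```r
library(hif2sig)

st <- simulate_study(seed = 42)
cm <- filter_low_counts(st$cm)           # "< 2 cumulative reads" filter
sf <- size_factors(cm)
disp <- estimate_dispersions(cm, sf)
de <- nb_wald_test(cm, c("S65W", "WT"), disp, sf)
print(de)
#> de_result: 2000 genes (S65W vs WT)
#>   padj < 0.05: 75 genes

sig <- build_signature(de, map_peaks_to_genes(st$peaks, st$ann, 5000))
print(sig)
#> signature: 30 genes ( 20 up, 10 down )
head(as.data.frame(sig), 3)
#>    gene weight   log2fc         padj      peak_id tss_distance
#> 1 G0001      1 2.086459 1.597917e-07 target_G0001        -2845
#> 2 G0021      1 2.769100 2.293519e-08 target_G0021        -4501
#> 3 G0041      1 2.557002 5.755745e-36 target_G0041           25
```

All 30 planted targets are recovered, each with its supporting peak and TSS
distance. Scoring a synthetic 300-patient cohort generated from this
signature and splitting at the median score:

```r
co <- simulate_cohort(sig, seed = 43)
sv <- signature_survival(co$expr, sig, co$clinical)
print(sv$cox)
#> cox_result: HR = 1.88921 (95% CI 1.62314 - 2.19891 ), p = 2.14069e-16
sv$logrank
#> log-rank chi2 = 39.0, p = 4.22e-10 (n_high = 150, n_low = 150)
```

A hazard ratio of 1.89 per SD of signature score and the strongly separated
Kaplan–Meier strata reproduce, in direction and magnitude, the planted
hazard coefficient (0.7, i.e. HR ≈ 2).

The same analysis runs from a config file over TSV/BED/GTF inputs:

```r
run_pipeline(list(
  paths = list(counts = "counts.tsv", samples = "samples.tsv",
               peaks = "peaks.narrowPeak", gtf = "genes.gtf",
               gmt = "sets.gmt", cohort = "cohort.tsv",
               clinical = "clinical.tsv", emt = "emt.tsv",
               hypoxia = "hypoxia.tsv"),
  params = list(contrast = "S65W,WT"),
  outdir = "results/"))
```

(or `Rscript inst/scripts/run_pipeline.R config.yaml` from a shell).

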