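# enhancerpair

Differential enhancer and super-enhancer analysis for paired tumor
cohorts profiled by H3K27ac ChIP-seq.

The package addresses a recurring design in cancer epigenomics: adjacent
normal tissue (Nor), primary tumor (EC) and lymph-node metastasis (LNC)
collected from the *same* patients. Because ChIP signal varies strongly
between patients, elements are called gained or lost from **per-pair
evidence**: for element *e* and patient *p*, with quantile-normalized
input-subtracted RPKM *x*,

> pair *p* votes "gain" iff (x<sub>case</sub> + ε)/(x<sub>ref</sub> + ε) ≥ 2
> and x<sub>case</sub> − x<sub>ref</sub> ≥ 0.5,

(ε = 0.1; losses symmetric), and an element is called when ≥ 6 of the
complete pairs agree. Combining the EC-vs-Nor and LNC-vs-Nor calls yields
the six tissue-specificity groups G1–G6 (EC-specific/LNC-specific/common
gain and loss). Super-enhancers are stitched at 12.5 kb, ranked by total
signal, and cut at the slope-1 tangency point of the scaled rank curve;
differential SEs combine a group-mean-difference strategy (|Δ| > 2) with a
paired-recurrence strategy (FC > 2 gain, < 0.7 loss, ≥ 5 pairs).
Downstream, elements link to nearest-TSS genes for dose-response,
Spearman signal–expression correlation, biomarker panels with tissue
signatures, priming classification, and Kaplan–Meier/log-rank survival
stratification by gene expression.

A synthetic paired-cohort generator (`simulate_cohort()`) plants labeled
G1–G6 effects with configurable effect size, recurrence and noise, so the
whole pipeline is validated by parameter recovery against known truth.

For whom: computational biologists analyzing paired ChIP-seq cohorts, and
anyone needing a tested reference implementation of recurrence-based
differential enhancer calling and ROSE-style SE ranking with ground-truth
simulation.

## Worked example

```r
library(enhancerpair)
library(dplyr)

co <- simulate_cohort(cohort_config(n_elements = 2000, seed = 42))
el <- classify_elements(co$elements, co$tss)
count(el, element_class)
#>   element_class        n
#> 1 enhancer          1400
#> 2 promoter_element   600

norm  <- quantile_normalize(co$signal)
pairs <- patient_pairs(co$sheet)
enh_sig <- filter(norm, element_id %in% el$element_id[el$element_class == "enhancer"])
grp <- assign_groups(
  call_differential(pairwise_change(enh_sig, pairs, "EC_vs_Nor"),  recurrence_min = 6),
  call_differential(pairwise_change(enh_sig, pairs, "LNC_vs_Nor"), recurrence_min = 6))
count(grp, group)
#>   group     n
#> 1 G1       60
#> 2 G2       39
#> 3 G3       86
#> 4 G4       52
#> 5 G5       49
#> 6 G6       98
#> 7 none   1016
```

The generator planted 50/50/100/50/50/100 elements in G1–G6; the caller
recovers them (the small excesses are near-threshold noise calls at the
default noise level). Super-enhancers from the same cohort:

```r
enh <- filter(el, element_class == "enhancer")
stitched <- stitch_enhancers(enh)                     # 12.5 kb stitching
sig <- se_signal(stitched, el, norm)
ranked <- rank_superenhancers(
  tibble(se_id = sig$se_id, signal = rowMeans(as.matrix(sig[, -1]))))
glance(ranked)
#>   n_regions  n_se cutoff_signal cutoff_rank
#> 1      1206   126          8.08        1080
```

126 of 1206 stitched regions sit above the tangency cutoff.
`autoplot(ranked)` draws the hockey-stick curve. A 2-year survival rate
from a 9-patient group with 3 deaths before 24 months:

```r
low <- tibble(time = c(4, 11, 19, rep(26, 6)),
              event = c(rep(TRUE, 3), rep(FALSE, 6)))
100 * survival_at(km_estimate(low), 24)
#> [1] 66.7
```

`run_pipeline(pipeline_config(seed = 1))` executes every stage from one
configuration and writes result tables plus an md5 manifest; identical
config and seed reproduce identical digests.

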