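# splicescape

Alternative-splicing analysis for bulk RNA-seq junction counts: PSI
quantification, differential-splicing calling, regulator-correlation
screens, RBP-motif RNA maps, divergence scoring against a developmental
reference, and PSI-based patient stratification — with a synthetic
cohort generator that gives every stage a ground truth.

## The problem

Event-based splicing studies — for example, of a transcription factor that
reshapes exon inclusion in an embryonal brain tumour — all run the same
quantitative pipeline: count junction reads supporting the inclusion and
skipping isoforms of each event, estimate percent spliced in (PSI), call
events that change between conditions, relate exon inclusion to a
regulator's expression across a tumour cohort, ask which RBP motifs sit
near the regulated exons, score how far each tumour's splicing has drifted
from its developmental tissue of origin, and test whether exon inclusion
stratifies patient outcome. The tumour cohorts behind such studies are
controlled-access, so this package pairs the full pipeline with a
junction-count simulator with *planted, recorded* structure: every stage
can be checked against truth at realistic depths and sample sizes. It is
aimed at computational biologists who want the event-level machinery as
tested, reusable functions rather than one-off scripts.

## The model

For an event with inclusion count $I$, skipping count $S$ and effective
junction lengths $l_I$, $l_S$ (SE/RI: 2 vs 1; MXE: 2 vs 2; A5SS/A3SS:
1 vs 1):

$$\psi = \frac{I/l_I}{I/l_I + S/l_S}$$

Two-group comparisons pool counts within groups and test the inclusion
probability with a binomial likelihood-ratio test ($\chi^2_1$; optional
beta-binomial overdispersion correction). An event is significant when
$|\Delta\mathrm{PSI}| > 10\%$, it is supported by $\ge 15$ junction reads
in each group, and BH-FDR $< 0.05$. Around this core: Spearman
regulator–PSI screens (BH-adjusted $p < 0.01$), sliding-window motif
density maps with per-position Wilcoxon rank-sum tests, per-tumour
significant-event counts against a pooled reference on the minimal shared
exon set (box-plot-whisker outlier removal, type-7 quartiles), exact 1-D
2-means stratification, chi-squared subtype association, Kaplan–Meier /
log-rank survival, and hypergeometric set-overlap statistics. The methods
vignette (`vignettes/splicescape-methods.Rmd`) derives and justifies each
choice.

## Worked example

```r
library(splicescape)

cohort <- generate_cohort(synthetic_config(seed = 1))  # 1,000 events, 3 vs 3
md <- cohort$metadata
rec <- diff_splice(cohort$counts,
                   md$sample_id[md$group == "knockdown"],
                   md$sample_id[md$group == "control"])
sig <- apply_significance_filters(rec)

attr(sig, "funnel")
#>      tested   supported significant
#>        1000        1000         205

head(sig[, c("event_id", "psi_a", "psi_b", "delta_psi", "fdr", "direction")], 3)
#>         event_id psi_a psi_b delta_psi      fdr      direction
#> ev00006  ev00006 0.139 0.495    -0.355 9.06e-21 inclusion-down
#> ev00009  ev00009 0.518 0.215     0.304 7.48e-15   inclusion-up
#> ev00018  ev00018 0.582 0.216     0.366 1.26e-20   inclusion-up

mean(names(cohort$truth$true_delta) %in% sig$event_id)
#> [1] 1        # all 100 planted |dPSI| = 0.4 events recovered
```

The funnel says all 1,000 events were testable and read-supported, and 205
passed the filter triple: the 100 planted differential events (all with
the correct direction), the planted regulator-linked exons (whose PSI
genuinely varies between samples), and a handful of false positives
consistent with the FDR level. Smaller building blocks work standalone:

```r
estimate_psi(10, 10, 2, 1)                               # 0.333...
exon_length(parse_region("chr12:42778741-42778798"))     # 57
frame_preserving(57)                                     # TRUE
```

## The analysis workflow

`analysis/` holds numbered drivers that run the full study on the
synthetic cohorts and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the knockdown, tumour and reference cohorts |
| `02_diff_splice.R` | differential splicing + filter funnel + truth recovery |
| `03_correlation_screen.R` | regulator-expression vs PSI screen |
| `04_rna_maps.R` | RBFOX-motif RNA map around regulated exons |
| `05_divergence.R` | per-tumour divergence from the reference, subtype ranking |
| `06_stratification.R` | k-means PSI strata, chi-squared, KM/log-rank, exon frame arithmetic |

Run them in order with `Rscript analysis/01_simulate.R` etc.
`run_full_pipeline(run_config(...))` orchestrates the same stages
programmatically with a manifest of checksummed artifacts.

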