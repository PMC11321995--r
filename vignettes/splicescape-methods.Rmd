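---
title: "Methods: PSI quantification, differential splicing and cohort-level splicing analyses"
author: "splicescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSI quantification, differential splicing and cohort-level splicing analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

# Scope and model

splicescape implements the quantitative machinery of an alternative-splicing
study of a transcription-factor-driven tumour: percent-spliced-in (PSI)
quantification from splice-junction counts, event-level differential-splicing
calling with the standard significance filter triple, a cohort-wide screen
for exons whose inclusion tracks a splicing regulator's expression,
positional RNA maps of RNA-binding-protein (RBP) motifs around regulated
cassette exons, a per-tumour splicing-divergence score against a
developmental reference tissue, and PSI-based patient stratification with
subtype-association and survival analyses. Because the tumour data such
studies rest on are controlled-access, the package ships a synthetic
junction-count generator with known planted structure, so that every stage
can be validated against ground truth.

## PSI from junction counts

An alternative-splicing event of any of the five canonical types — skipped
exon (SE), mutually exclusive exons (MXE), retained intron (RI), and
alternative 5'/3' splice sites (A5SS/A3SS) — is observed through two
junction read counts per sample: $I$ reads supporting the inclusion isoform
and $S$ reads supporting the skipping isoform. Because the two isoforms are
supported by different numbers of distinct junctions, the counts are
normalized by effective lengths $l_I$ and $l_S$:

$$\psi \;=\; \frac{I/l_I}{\,I/l_I + S/l_S\,}.$$

In junction-count mode the effective lengths follow the event geometry:
SE and RI have two inclusion junctions against one skipping junction
($l_I = 2$, $l_S = 1$), MXE has two of each, and A5SS/A3SS one of each.
$\psi$ is undefined (missing) where $I + S = 0$; it is invariant under
joint scaling of the counts; and the generator's count link (below) is its
exact inverse, which the test suite verifies analytically for every event
geometry.

## Differential splicing

For a two-group comparison the counts are pooled within each group and the
per-read inclusion probability $p$ is compared by a likelihood-ratio test:
the alternative fits a group-specific binomial proportion, the null a
shared one, and the deviance is referred to $\chi^2_1$. Group PSI is
computed from the length-normalized pooled counts (not the mean of
per-sample PSI), which is stable at low depth and consistent with the
pooled likelihood. The reference event-based tool this emulates fits a
hierarchical replicate model; we use the pooled (beta-)binomial LRT as a
documented, simulation-validated test of the same null — the thresholds,
not a particular likelihood implementation, define the published procedure.
Its operating characteristics are established empirically by the test
suite: type-I error at the nominal level on null cohorts, and near-complete
recovery of planted $|\Delta\text{PSI}| = 0.4$ events at the study's depth
and replicate numbers.

With `model = "betabinomial"`, between-replicate overdispersion is
estimated per event as a Pearson-$\chi^2$ dispersion factor over the
per-sample inclusion proportions and the LRT statistic is deflated by it
(a Williams-type quasi-likelihood correction). With a single sample per
group the two models coincide; the generator's `overdispersion` parameter
exists precisely so the test can be exercised at and away from its nominal
model.

An event is *significant* when it passes the filter triple, with the
boundary conventions mirroring the usual wording exactly:

* $|\Delta\text{PSI}| > 0.10$ (strict),
* read support: at least 15 junction reads (inclusive) — by default summed
  within **each** group, the intermediate of the three defensible
  granularities (per sample / per group / whole comparison), all three of
  which are exposed via the `support` argument because published wording
  rarely pins this down;
* FDR $< 0.05$ (strict), Benjamini–Hochberg across events with a defined
  p-value only — events with zero support in either group are reported but
  excluded from the FDR denominator so untestable events do not deflate it.

Whether the $\Delta$PSI threshold applies to pooled-group PSI or to the
mean of per-sample PSI is another under-specified point; we apply it to the
pooled-group value, consistent with the pooled test.

## Regulator-correlation screen

The cohort screen correlates each exon's PSI with the regulator's
expression across samples. Two detection filters precede it, in a fixed
order: first the $\lfloor 0.05\,n \rfloor$ samples with the fewest detected
exons are dropped (floor, so never more than stated; ties break by
sample-id order), then exons detected in at least 25% of the *remaining*
samples are kept (inclusive). Sample-first ordering makes the exon fraction
well defined on the final cohort. Spearman rank correlation is the default
— the generator's logistic link makes planted exons monotone but not
linear in the covariate, and rank correlation is invariant to any
increasing transform of expression — with Pearson available by flag;
BH-adjusted two-sided p-values are thresholded at 0.01. Constant-PSI or
under-sampled exons are flagged untestable and excluded from the FDR
denominator.

## RNA maps

The RNA map scores a motif's positional density around regulated cassette
exons against a background of unregulated exons. The layout follows the
convention of the established RNA-map tools: 50-nt exon edges, 250-nt
flanking intron segments, a 50-nt sliding window at 1-nt steps (all
configurable; the source studies typically do not restate these numbers).
Density at a position is the number of motif match *start sites* within the
window centred there, divided by the window width — start-site counting is
the simplest unambiguous rule and lets a brute-force window enumeration
serve as an oracle in the tests. Matching is IUPAC-degenerate
(`U` $\equiv$ `T`, case-insensitive) and overlap-counting, so a poly-U run
contains every start of a poly-U motif. Windows are confined to their
region and truncated at region edges with a fixed denominator; regions
missing from an event contribute missing values which means and tests
exclude. Per position, a two-sided Wilcoxon rank-sum test compares
per-event densities of each regulated direction against the background;
positions where the combined densities are constant get $p = 1$. No
correction across positions is applied — the map reports raw positional p
curves, and the output carries a metadata note saying so.

## Divergence from a developmental reference

Each tumour is scored by the number of events significantly spliced
relative to a pooled reference: (1) events expressed at $\ge 15$ reads are
called per sample; (2) tumours with outlying expressed-event counts are
removed by the box-plot whisker rule, $n < Q_1 - 1.5\,\mathrm{IQR}$ or
$n > Q_3 + 1.5\,\mathrm{IQR}$, with quartiles by linear interpolation
between order statistics (`quantile` type 7 — the rule names only box-plot
whiskers, so the convention is fixed and used identically by the test
oracles); (3) the kept tumours' expressed-exon lists are intersected into
the minimal shared set, making scores comparable across tumours of unequal
depth; (4) each tumour is tested 1-vs-reference with the pooled LRT on the
shared set and the filter triple is applied. Subtypes are ranked by
ascending median score (ties alphabetically). Outlier removal applies to
whatever cohort the function is given; the reference samples are always
retained. The whisker rule needs at least four samples.

## Stratification, association, survival, overlap

Patients are stratified on a single exon's PSI by one-dimensional k-means
with $k = 2$. An optimal 1-D k-means partition is a set of contiguous
intervals of the sorted values, so for $k = 2$ the implementation finds the
global optimum exactly and deterministically by scanning every threshold
cut with prefix sums. We deliberately do not use iterative Lloyd refinement
here: Lloyd from fixed initial centres can stop in a local optimum on some
inputs, which would make the "high"/"low" split depend on the
initialization heuristic; the exact cut is both deterministic and provably
optimal (the suite checks it against an independent exhaustive-cut oracle).
Lloyd with evenly spaced centres is retained for $k > 2$. Strata are
labelled so `high` has the larger centre.

Stratum–subtype association uses Pearson's chi-squared without continuity
correction (the correction is available by flag); survival is compared with
Kaplan–Meier product-limit curves (Greenwood standard errors) and the
unweighted Mantel–Haenszel log-rank test; and gene-set overlaps are
assessed by the upper-tail hypergeometric probability
$P(X \ge \text{observed})$ with expected overlap $n_1 n_2 / N$. A joint
two-exon signature (e.g. high inclusion of one exon and low of another) is
composed by intersecting the per-exon strata.

# The synthetic-data generator

`generate_cohort()` emulates the data-generating process the analyses
assume. Per event and sample, a total junction depth
$n \sim \mathrm{Poisson}(\texttt{depth\_mean})$ (floored at 1) is split as
$I \sim \mathrm{Binomial}(n, p)$, $S = n - I$, with
$p = \psi l_I / (\psi l_I + (1-\psi) l_S)$ — the exact inverse of the PSI
estimator. Setting `overdispersion` $\rho > 0$ replaces the binomial with a
beta-binomial of intra-class correlation $\rho$ (binomial is the $\rho = 0$
limit). Planted structure, all recorded in a truth object:

* **Differential events** (default 10% of events at $|\Delta\psi| = 0.4$,
  random sign): group-specific true PSI. These defaults are the conditions
  under which the power properties are stated.
* **Regulator-linked exons** (default 10%, slope 2): per-sample
  $\mathrm{logit}(\psi) = \mathrm{logit}(\psi_0) + \beta x$ with regulator
  expression $x \sim N(0,1)$ — standard-normal expression with a
  configurable logistic slope makes the planted rank correlation provably
  monotone in expectation.
* **Motif planting**: one concrete instance of the configured IUPAC motif
  (default the RBFOX hexamer `UGCAUG`) whose match starts at offset 100 of
  the 250-nt downstream intron of every inclusion-down differential event;
  all other flank sequence is uniform ACGT.
* **Survival**: exponential times with the hazard multiplied by
  `hazard_ratio` (default 3) in the high-inclusion stratum, censored
  administratively at the 80th percentile of the drawn event times — the
  closed-form hazard ratio keeps log-rank power checks interpretable.
* **Reference cohorts** (`generate_reference_cohort()`): reference samples
  share one base PSI vector drawn uniform on $[0.15, 0.85]$; each tumour of
  a subtype deviates at a subtype-specific number of events (resampled per
  tumour, recorded in the truth) by $|\Delta\psi| = 0.5$ toward whichever
  side keeps PSI in $[0,1]$.

Default cohort sizes follow the designs the analyses target: 3-vs-3
replicates for the knockdown comparison, 200 samples for the cohort screen,
4 reference samples with 8 tumours per subtype for the divergence analysis,
around 100 junction reads per event per sample (tumour-cohort depth
distributions are rarely published; the default is configurable and
documented, not inferred). All randomness flows from the single `seed`; the
generator restores the caller's RNG state, and repeated calls with the same
configuration are byte-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mapping and duplicate-filtering artefacts,
annotation errors in event definition, correlated events within a gene,
GC/coverage biases along transcripts, realistic motif co-occurrence and
secondary structure in flanks, non-exponential survival, and confounding
between regulator expression and cohort composition. Results on the
generator certify the implementation and its operating characteristics
under the stated model, not biological conclusions.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (the BED / `exonStart_0base`
  convention), so interval length is `end - start`; under this reading the
  printed coordinates of the two morpholino-validated exons give 57 nt and
  63 nt — both divisible by three, i.e. frame-preserving. Event tables
  store only the target interval; flanking regions are defined implicitly
  by the RNA-map layout rather than duplicated as coordinate lists.
* Unknown strand is accepted and treated as `+` wherever an orientation is
  needed; counts-only analyses never consult it.
* The binomial log-likelihood uses the $0\log 0 = 0$ convention; the LRT
  statistic is clamped at 0 against floating-point negatives.
* Identical groups give $\Delta\text{PSI} = 0$ and $p = 1$ exactly;
  swapping group labels negates $\Delta$PSI and leaves p unchanged.
* Degenerate stratification input (fewer distinct PSI values than
  clusters) is an error naming the exon; ties exactly at the optimal
  k-means threshold resolve by stable sort order.
* An empty minimal shared exon set is a warning (score missing), not an
  error; an empty RNA-map target direction yields missing curves, not an
  error.
* Pipeline sub-seeds are derived deterministically from the master seed
  and kept below $2^{31}$.

# Validation design

Every stage is validated two ways: exact oracles and operating
characteristics. The oracles are independent re-computations — brute-force
likelihood maximization for the LRT, risk-table enumeration for the
log-rank test, exhaustive threshold cuts for 1-D 2-means, direct window
enumeration for motif densities, and explicit subset enumeration for the
expected overlap on all universes up to $N = 12$. The operating
characteristics are measured on generated cohorts at the design sizes
stated above: 20 replicate null cohorts for type-I error, 20 for power,
10 for the correlation screen (1,000 exons, 200 samples), 10 for RNA-map
peak localization, and 10 for divergence ordering with subtype distances
0/30/100 — sizes chosen so each property is measured on thousands of
events while the whole suite stays quick to run. `scripts/acceptance.R`
recomputes all of these from scratch for any seed.

# Known limitations

* Junction-count mode only: no exon-body read counting, no isoform-level
  quantification, and no paired designs.
* The pooled LRT treats replicates as exchangeable within a group; with
  strong replicate structure the beta-binomial correction is coarse
  (method-of-moments, per event) compared to a full hierarchical fit.
* The correlation screen fits no covariates and reports no partial
  correlations.
* RNA maps use literal IUPAC matching, not PWMs, and ship no motif
  compendium beyond user-supplied tables.
* The divergence score depends on the shared-exon set and therefore on the
  cohort given; it is a within-cohort ranking device, not an absolute
  measure.
* Survival analysis is limited to KM/log-rank; no Cox regression or
  multivariable modelling.
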