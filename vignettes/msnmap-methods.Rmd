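---
title: "Morphometric similarity mapping: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity mapping: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnmap)
```

## The morphometric similarity model

A morphometric similarity network (MSN) represents one brain as a graph
whose nodes are cortical regions and whose signed, weighted edges are the
Pearson correlations between regional morphometric profiles. For subject
$i$, each region $j$ carries a vector of $F$ features (grey-matter volume,
surface area, cortical thickness, Gaussian and mean curvature, fractional
anisotropy, mean diffusivity; $F = 7$ by default). Each (region, feature)
value is first z-scored across the subjects of its study — `zscore_features()`
— so that features measured on wildly different scales (mm$^3$ vs.
unit-free diffusivity) contribute equally. The similarity matrix is then

$$M_i[j,k] = \mathrm{cor}\big(z_{ij\cdot},\, z_{ik\cdot}\big),$$

the correlation of the two regions' z-scored feature vectors
(`build_msn()`). The diagonal is excluded everywhere. Regional *strength*
$\bar M_i[j]$ is the mean of row $j$ — the weighted degree of node $j$ —
and the global mean similarity is the mean over all off-diagonal entries;
both are in $[-1, 1]$ (`regional_strength()`, `global_mean()`).

Two readings of "normalized for sample mean and SD" exist in the MSN
literature: across subjects within study (our default, `scope =
"subjects"`), or across regions within subject (`scope = "regions"`).
We default to the across-subjects reading because "sample" most naturally
denotes the participant sample, and per-study scoping prevents scanner
effects leaking between cohorts, which are analyzed separately throughout.
Normalization pools cases and controls within study; a control-referenced
variant would change effect-size units but not signs.

## Case-control inference

For every region (and for the global mean), per-subject strength is
regressed on group with age, sex, and the age-by-sex interaction as
covariates (`fit_group_model()`): ordinary least squares, with the group
coefficient's $t$ statistic as the regional effect (positive = higher in
cases). Hedge's $g$ is obtained from $t$ by the standard conversion
$g = t\sqrt{1/n_1 + 1/n_2}\,J(\nu)$ with the exact small-sample correction
$J(\nu) = \Gamma(\nu/2)\,/\,\big(\sqrt{\nu/2}\,\Gamma((\nu-1)/2)\big)$.
Because the design matrix is shared across regions, all 308 regional fits
use a single QR decomposition. With both covariates omitted the model is
identically the pooled-variance two-sample t-test, which the tests exploit
as an oracle.

Per-region p-values from the separate studies are combined with Fisher's
method, $\chi^2 = -2\sum_s \log p_s$ on $2k$ degrees of freedom
(`combine_fisher()`), and the combined map is thresholded by
Benjamini-Hochberg FDR at $q = 0.05$ over regions (`fdr_bh()`). A caution
worth stating: Fisher's combination of $k$ equal p-values is *more*
extreme than the single p only below a crossover (about 0.3 for $k = 3$);
combining several genuinely weak results is rightly less extreme.

Three companion analyses contextualize the regional map:

* **Distribution comparison** (`compare_strength_distributions()`): a
  two-sample Kolmogorov-Smirnov test between case and control values.
  On *subject-level* global similarity the observations are independent
  and the p-value is calibrated. On *group-mean regional maps* it is not:
  every region shares each subject's global offset, so even null cohorts
  produce coherently shifted maps. We therefore treat the map-level KS as
  a descriptive statistic and calibrate only the subject-level use.
* **Hub vulnerability** (`hub_vulnerability()`): the Pearson correlation
  between mean control strength and the mean case-control $t$ map, with a
  region-label permutation p-value. Label permutation assumes regional
  exchangeability; maps that are spatially smooth on a shared geometry
  violate it, which is why a `surrogates` argument accepts user-supplied
  autocorrelation-preserving null maps (e.g. spin-test surrogates) in
  place of naive shuffling.
* **Class aggregation** (`class_aggregation_test()`): per-subject mean
  strength within cytoarchitectonic classes or functional networks, the
  same group model per class, Fisher across studies, BH across classes.

## PLS imaging transcriptomics

`fit_pls()` relates regional gene expression (regions $\times$ genes,
left-hemisphere subset so that the expression matrix and the t-maps cover
the same parcels with intrahemispheric edges only) to the per-study
case-control t-maps treated as a joint multi-column response. Genes are
z-scored across regions before fitting — without this the weights are
dominated by high-variance genes, and the bootstrap-Z convention presumes
comparable scales. The implementation is SIMPLS; only component 1 is
interpreted downstream, and for a single response the first weight vector
is exactly proportional to the predictor-response covariance vector, which
the tests verify against both direct computation and an independent PLS
implementation. Variance explained is reported as the proportion of pooled
response variance (all response columns stacked); a per-column average is
recoverable from the stored loadings. The sign indeterminacy of every
component is resolved deterministically: scores are flipped to correlate
positively with the mean response map, ties broken toward a positive
weight sum, so that all reported signs are reproducible and negating the
response negates every score and weight exactly.

Significance of the component-1 variance explained is assessed by jointly
permuting the response rows `n_perm = 1000` times
(`permutation_test_variance()`), with the add-one convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$ used
for every resampling p-value in the package, so no p-value is ever zero.
Gene ranking uses bootstrap resampling of the analysis regions
(`bootstrap_gene_weights()`, `n_boot = 1000`): each replicate's component
is sign-aligned to the original before accumulation (otherwise the
arbitrary per-replicate orientation inflates every SE), the bootstrap SD
is the SE, and $Z = w / \mathrm{SE}$ orders the genes. The bootstrap
resamples the regions actually present in the analysis matrix — the
left-hemisphere subset when the analysis is left-hemisphere. Tail sets
with $Z > 3$ (PLS+) and $Z < -3$ (PLS−) feed the enrichment stage
(`select_gene_sets()`); tail sets are monotone in the threshold by
construction.

## Gene-set enrichment

* `median_rank_enrichment()`: the observed median rank of a gene set in
  the PLS ordering against the median ranks of `n_resample = 10000`
  same-size sets drawn from a background universe (by default the ranked
  genes; in practice a brain-expressed list). Ranks are recomputed within
  the universe, so the test depends only on the ordering — invariant to
  any monotone transform of the Z-scores. Because the direction of
  "extreme" differs for PLS+ and PLS− style sets, the tail is a
  parameter, with a two-sided option that doubles the smaller tail. A set
  that deliberately spans both tails has a central median rank and is
  invisible to this test — test its halves.
* `sign_concordance_test()`: Wilcoxon rank-sum comparison of the PLS
  weights of externally labeled up- versus down-regulated genes.
* `ppi_edge_enrichment()`: the count of interaction edges internal to a
  gene set versus same-size sets drawn uniformly from the universe.
  Uniform (not degree-preserving) resampling is the default because the
  "expected edges" framing corresponds to uniform set draws; a
  degree-preserving null can be emulated by supplying a restricted
  universe.

## What the synthetic data emulate — and what they do not

`generate_cohort()` builds control subjects from a latent regional
architecture: regions sit at angles $\theta_j$ spanning $[0, 0.8\pi]$
along a one-dimensional gradient (homologous across hemispheres) and load
two orthogonal feature patterns by $\cos\theta_j$ and $\sin\theta_j$, with
subject-level factors on each pattern. Expected inter-regional similarity
is then approximately $\cos(\theta_j - \theta_k)$: nearby regions
correlate positively, distant ones negatively, and mid-gradient regions
have the highest expected strength — the simulated hubs
(`default_affected_regions()` returns them). This reproduces the
qualitative features the analysis relies on: a mix of positive and
negative strengths, a reproducible control topography, and meaningful
hubness.

The case effect is *feature decorrelation*, not a mean shift: affected
regions of case subjects receive extra independent noise with SD
`effect_size` (in units of the unit latent amplitude). This attenuates the
region's correlation with every other region — the phenotype is similarity
change, with feature means untouched, which is why the downstream group
model is fit on strengths rather than on features. Age and sex act
linearly on every feature with configurable slopes, exactly the terms the
downstream model adjusts for. Default study conditions follow the
three-cohort case-control setting the pipeline targets: 83/68, 33/82 and
69/77 subjects, 308 regions (152 left-hemisphere), 7 features, ages 18-65,
noise SD 0.5.

Parameter choices worth recording:

* **Default `effect_size = 1`** is a moderate decorrelation (regional
  similarity attenuated by roughly a quarter), giving per-study,
  per-region power near 0.8 at $\alpha = 0.05$ at these cohort sizes.
* **The recovery condition uses `effect_size = 1.2`**, calibrated by
  simulation so that per-region detection through the full
  Fisher-combination + FDR chain is about 0.9 at the default three-study
  sizes. Detection is nearly all-or-nothing per simulated dataset because
  the shared subject-level global component couples regions.
* **Problem sizes in the test suite** are scaled to the property being
  checked: deterministic oracles run on 3-10 regions; calibration uses
  200 null cohorts of 100 subjects x 100 regions; planted-effect recovery
  runs once at the full 308-region, three-cohort, 2000-gene condition.

`generate_expression()` plants `n_signal_genes` whose regional profile is
$\rho\,z(\text{target}) + \sqrt{1-\rho^2}\,\varepsilon$; the remaining
genes are independent noise. `generate_network()` is an Erdős–Rényi graph
with an optional planted clique. The pipeline flips half of the signal
genes around their mean so both PLS tails carry known truth, and plants
the interaction-network module inside the negative-tail genes.

Known departures from real data, and their visible consequences:

* **No spatial autocorrelation** beyond the single latent gradient, in
  either morphometry or expression. Consequence: naive region-label
  permutation is anti-conservative for any pair of generator-derived
  maps (they share the gradient); calibration tests therefore pair a
  pipeline map with an unstructured map, and real-data users should
  supply surrogate maps.
* **Column-independent noise genes.** Real transcriptomes are strongly
  inter-correlated (low effective rank), so a single PLS component of
  real expression explains little of a random map; with 2,000 independent
  genes and 152 regions, the *null* variance explained is itself large.
  Consequence: at the synthetic study conditions the permutation test of
  variance explained is honestly non-significant even when every
  planted-gene quantity is recovered — the test's machinery is instead
  verified in the $n > p$ regime, where a planted response drives the
  permutation p to its floor.
* **No site/scanner effects beyond study-scoped normalization, no
  symptom-severity structure, and no image-quality confounds.** Passing
  tests demonstrate the statistical machinery, not robustness to those
  real-world nuisances.

## Numerical and degenerate-input policy

Constant feature vectors, zero-variance predictors, rank-deficient
designs, groups with fewer than 3 subjects, p-values outside $(0,1]$, and
region-set mismatches are hard errors naming the offending region,
feature, or gene — never silent `NA`s. Bootstrap replicates with five or
fewer distinct regions are redrawn. Fisher inputs are floored at the
smallest positive double to guard against underflow of extremely small
per-study p-values. All resampling seeds are taken from the pipeline
configuration and recorded, with derived per-stage offsets, in the run
manifest; two runs with the same configuration produce byte-identical
outputs and manifests.

## Pipeline

`run_pipeline()` executes simulate → MSN → case-control → PLS →
enrichment from a single configuration (see
`default_pipeline_config()`; YAML overrides merge over complete
defaults), writes every stage output as self-describing TSV, and records
parameters, seeds and md5 checksums in `manifest.json`. The bundled
`inst/extdata/demo_config.yaml` runs two 50-subject studies on a
60-region atlas in a few seconds:

```{r demo, eval = FALSE}
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "msnmap"))
res <- run_pipeline(cfg, outdir = "demo_run")
print(res)
summary(res$case_control$full)
```

## Known limitations

* The permutation null for map-map correlations is spatially naive;
  supply surrogate maps for autocorrelated data.
* The KS comparison of group-mean regional maps is descriptive, not a
  calibrated test (regions share subject-level offsets).
* Enrichment resampling matches set size only, not expression level or
  transcript length.
* The generator does not emulate expression covariance structure, so
  variance-explained magnitudes are not comparable to real-data values.
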