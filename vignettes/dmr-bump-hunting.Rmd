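---
title: "Bump-hunting detection of differentially methylated regions across cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bump-hunting detection of differentially methylated regions across cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-CpG association tests on 450K-style methylation arrays produce long
lists of probes that are hard to interpret and replicate poorly across
case-control cohorts, particularly in heterogeneous brain disorders where
effect sizes are modest. Functionally meaningful methylation differences tend
to span *regions* -- runs of neighbouring CpGs shifted in the same direction.
`dmrbump` implements the bump-hunting strategy for calling such
differentially methylated regions (DMRs) from processed beta-value matrices,
attaches resampling-based uncertainty to each region, and intersects
significant regions across independent cohorts so that only consistently
differentially methylated loci survive.

## The model and procedure

Methylation at probe $j$ in sample $i$ is measured as a beta value
$\beta_{ij} \in [0,1]$ and modelled on the logit scale as an M-value,
$M_{ij} = \log_2\{\beta_{ij}/(1-\beta_{ij})\}$, which is closer to
homoscedastic and unbounded. For each probe we fit by ordinary least squares

$$M_{ij} = \alpha_j + \delta_j\,\mathrm{case}_i + \gamma_j^\top z_i + \varepsilon_{ij},$$

where $z_i$ collects the nuisance covariates sex, age and post-mortem
interval (each used only when observed for every sample in the cohort, and
dropped with a warning otherwise) and $\delta_j$ is the adjusted
case-minus-control difference in mean M-value.

Probes are grouped into clusters such that neighbouring probes within a
cluster are at most `maxgap` bp apart (500 bp by default). Within each
cluster the $\hat\delta_j$ profile is smoothed with a running median of
window `smooth_k` (default 5), using truncated windows at cluster edges;
clusters smaller than the window are left unsmoothed. Medians rather than
means keep single outlying probes from manufacturing bumps.

The effect-size cut-off is not fixed a priori but taken from a bootstrap
empirical null: the group column is removed from the design, the null model
is fitted, and `n_boot` bootstrap data sets are formed as null fitted values
plus residual columns resampled with replacement across samples (preserving
the probe-wise covariance structure). Each bootstrap data set is re-fitted
and smoothed exactly like the observed data. The cut-off is the
`cutoff_quantile` (default 95%) interpolated quantile of the pooled absolute
smoothed null statistics. Candidate regions are maximal within-cluster runs
of probes with smoothed effect strictly beyond $\pm$cut-off, summarised by
their average smoothed $\Delta M$ and their *area* $A = \sum_j
|\tilde\delta_j|$.

Region-level inference reuses the bootstrap null: each bootstrap profile is
scanned for null regions at the same cut-off, and for an observed region of
area $A$,

* `p_value` = proportion of all pooled null regions with area $\ge A$
  (0 when the pool is empty), so P-values far below $1/B$ are attainable;
* `fwer` = proportion of bootstraps whose *maximum* null area $\ge A$;
* `fdr` = Benjamini-Hochberg adjustment of `p_value` across the candidates.

Finally, per-cohort significant regions (`p_value < alpha`, default 0.05)
are intersected across cohorts, stratified by direction: a consensus region
requires one region per cohort, all hyper- or all hypo-methylated, sharing a
common intersection of at least `min_overlap` bp (default 2). Consensus
regions can be annotated with the nearest gene (unstranded gap distance,
0 when the region and gene intervals intersect; ties broken by smaller gene
start, then name).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `maxgap` | 500 (sensitivity: 1000) | bp | cluster definition |
| `cutoff_quantile` | 0.95 (sensitivity: 0.975) | -- | effect cut-off from the null |
| `n_boot` | 1000 | -- | bootstrap samples |
| `smooth_k` | 5 | probes | running-median window |
| `min_probes` | 1 | probes | minimum region size |
| `alpha` | 0.05 | -- | per-cohort region significance |
| `fwer_alpha` | 0.1 | -- | FWER threshold in summaries |
| `epsilon` | 1e-3 | -- | beta clamp before the logit |
| `min_overlap` | 2 | bp | consensus intersection width |

`epsilon` exists because downloaded beta matrices can contain exact 0/1
values whose logit is infinite; clamping to $[\epsilon, 1-\epsilon]$ keeps
M-values finite while moving interior values not at all. `min_probes`
defaults to 1 so that no region is silently discarded; users wanting
multi-probe regions only can raise it.

## Probe filtering

Before detection, probes are removed in a fixed stage order, with per-stage
accounting on the surviving set: (1) probes whose detection P-value exceeds
0.05 (strictly) in *any* sample; (2) probes with an annotated SNP at the
single-base extension (offset 0) or CpG site (offsets 1-2); (3) all probes
on the X and Y chromosomes; (4) any named exclusion lists, typically the
cell-type-specific marker probes whose inclusion is toggled in the
sensitivity analysis. The final probe *set* is order-independent (removals
are set unions); only the per-stage counts depend on the order. SNP
annotation is consumed as a manifest column, not recomputed from dbSNP:
it is a static probe property.

## The synthetic study generator

Because the pipeline targets cohort-scale array data, the package ships a
generator of complete multi-cohort studies with known ground truth, used by
the test suite and the acceptance script. Its defaults are the study
conditions everything is validated under:

* three cohorts of 24/24, 20/23 and 18/15 cases/controls -- the cohort
  shapes of the prefrontal-cortex schizophrenia data sets this design
  emulates;
* 250 probe clusters of 4-12 probes (about 2000 probes), within-cluster
  gaps uniform on 20-400 bp, clusters 5000 bp apart so that cluster
  structure is unambiguous for any `maxgap` up to a few kb;
* baseline M-values from a three-component mixture (unmethylated $-3$,
  intermediate $0$, methylated $+3$; weights 0.45/0.10/0.45), giving the
  bimodal marginal beta histogram typical of 450K data;
* probe noise sd 0.5 M units -- a mid-range per-probe residual spread for
  brain tissue at these sample sizes;
* five shared hyper- and two shared hypo-methylated DMRs of $|\Delta M| =
  0.7$ over 4-10 probes, planted at identical coordinates in every cohort,
  plus two cohort-private DMRs each (which must *not* reach consensus);
* covariate effects: sex shift 0.2, age slope 0.01/yr, PMI slope 0.01/hr,
  with sex ~ Bernoulli(0.5), age ~ U(30, 90) yr, PMI ~ U(5, 40) h --
  plausible post-mortem ranges;
* planted filter failures: 1% of probes fail detection (per cohort), 2%
  carry SNP offsets, 3% sit on sex chromosomes, 2% are in the cell-type
  list; none of these intersect planted DMRs, so filtering and detection can
  be validated independently.

Effects are planted additively in M-space, not beta-space, because the
inference operates on M-values and the reported $\Delta M$ is an M-scale
quantity. What the generator does *not* emulate: Infinium I/II chemistry
differences, spatially correlated residuals, batch structure beyond a single
optional global cohort shift, and cell-composition heterogeneity (the
cell-type probe list is consumed as a mask, never derived). Passing tests
therefore demonstrate correctness of the algorithmic machinery and its error
control under the assumed data model -- not robustness to every artefact of
real arrays.

## Numerical and design choices

* **Quantiles** use linear interpolation between order statistics (type 7),
  the common default; the choice is pinned by a direct-evaluation oracle in
  the tests.
* **Smoothing at edges** uses truncated windows (median over the window
  clipped to the cluster) rather than shrinking or extrapolating endrules,
  mirroring cluster-wise running-median smoothing as used in reference
  bump-hunting implementations.
* **Ties at the cut-off** are excluded: a probe enters a region only when
  its smoothed effect is strictly beyond the cut-off.
* **The region statistic** for the resampling null is the area
  $\sum|\tilde\delta|$; it is sensitive to both effect size and region
  length, and monotone counting against it makes `p_value` and `fwer`
  non-increasing in area.
* **Bootstrap scheme**: residual columns are resampled unstratified; the
  null fit removes only the group column, so covariate structure is
  preserved in the resampled data.
* **Degenerate inputs**: a zero-residual matrix yields an all-zero null, a
  cut-off of 0 and no candidate regions; an empty null region pool gives
  `p_value = 0` for any observed region; clusters smaller than the smoothing
  window pass through unsmoothed.
* **Consensus multiplicity**: when one cohort contributes several regions
  overlapping the same locus, the largest-area one is used, with a warning.
  Sequential intersection (not merely pairwise overlap) is required, since
  the consensus is reported as a single interval per locus.
* **Missing covariates** drop the covariate for the whole cohort rather than
  dropping samples; sample sizes here are small enough that losing samples
  costs more than losing a nuisance adjustment.
* **Alignment** is strict everywhere: readers and the fitting function
  reject mismatched probe/sample indices instead of silently reordering;
  `bumphunt()` itself aligns by probe id and sorts by (chrom, pos), so row
  order of the inputs never matters.

## Validation scale

The test suite and the acceptance script exercise the pipeline at desk
scale: recovery of the planted 5+2 shared DMRs is checked over 20 simulated
three-cohort studies of ~2000 probes with 100 bootstrap samples, and
family-wise error control under the global null over 50 single-cohort
simulations (8 vs 8 samples, ~500 probes, 200 bootstraps). These sizes are
the package's validation design; full-scale runs (450K probes, 1000
bootstraps) use identical code paths and are linear in probes and
bootstraps.

## Known limitations

* Region P-values are conditional on the selected cut-off; no adjustment is
  made for the data-dependence of the cut-off itself (the standard
  bump-hunting convention).
* The per-cohort "significant" set for consensus uses `p_value < alpha`;
  with few bootstraps the null-area pool is granular and P-values are
  correspondingly coarse.
* Nearest-gene annotation is distance-only; transcript context (promoter,
  exon, CpG island/shore) is out of scope.
* The reader rejects missing beta values by design; matrices with missing
  entries need imputation or masking upstream.

## A worked example

```{r, eval = FALSE}
library(dmrbump)

study <- simulate_study(sim_config(), seed = 11)
fits <- lapply(names(study$cohorts), function(nm) {
  coh <- study$cohorts[[nm]]
  man <- study$manifest[match(rownames(coh$beta), study$manifest$probe_id), ]
  filt <- run_filter_stack(coh$beta, coh$detp, man,
    filter_config(exclusion_lists = list(celltype = study$truth$celltype_probes)))
  bumphunt(filt$matrix, filt$manifest, coh$samples, n_boot = 100, seed = 42)
})

sig <- lapply(fits, function(f) select_significant(f$regions, 0.05))
names(sig) <- names(study$cohorts)
cons <- consensus_overlap(sig, min_overlap = 2)
table(cons$direction)
```
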