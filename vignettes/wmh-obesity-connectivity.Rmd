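---
title: "Methods: degree-centrality analysis of WMH burden and obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-centrality analysis of WMH burden and obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhconnect)
```

## The analysis model

The package implements a node-level functional-connectivity comparison
across four groups defined by crossing two binary factors:

* **WMH burden** (low/high): the cohort is split at the *median* lesion
  volume, separately for total, deep, and periventricular white-matter
  hyperintensity (WMH) volume. A subject is high-burden iff its volume is
  strictly greater than the median.
* **Obesity** (non-obese/obese): a subject is obese iff the waist-hip
  ratio (WHR) strictly exceeds 0.90 (males) or 0.85 (females). WHR is used
  rather than BMI because it tracks metabolically unhealthy (abdominal)
  obesity; BMI categories are carried for reporting only.

For each subject, region time series $x_i(t)$, $i = 1,\dots,R$ (either
supplied directly or extracted as unweighted voxel means within an integer
parcellation) are turned into a weighted graph:

$$ r_{ij} = \mathrm{cor}(x_i, x_j), \qquad
   w_{ij} = \left(\frac{r_{ij} + 1}{2}\right)^{\beta}, \qquad
   z_{ij} = \mathrm{arctanh}(w_{ij}), $$

with $\beta = 6$ by default. The soft-threshold map sends $r = -1 \to 0$
and $r = 1 \to 1$ and is strictly increasing, so strong edges are
emphasised without binarising the graph; $\beta = 6$ is the conventional
scale-free index for weighted correlation networks (a log–log degree
distribution $R^2$ diagnostic, `scale_free_fit()`, is provided but never
used for selection). Degree centrality is the incident edge-weight sum
$d_i = \sum_{j \ne i} z_{ij}$.

Per node, degree centrality is residualised on age and sex by OLS across
all subjects pooled (adjusting within groups would absorb the group
effects under study), then compared with a 2x2 between-subjects ANOVA:
both main effects and the interaction, each on 1 numerator df and $N - 4$
denominator df. ANOVA p-values are Benjamini–Hochberg corrected across
nodes, separately per effect; nodes whose interaction q-value falls below
$\alpha = 0.05$ receive post-hoc pooled-variance two-sample t-tests for
the six group pairs, BH-corrected within the node.

## Numerical and procedural choices

* **arctanh is applied to the soft-thresholded weight**, not to the raw
  correlation, so self-edges ($w = 1$) would be infinite; the pole is
  clipped at $1 - 10^{-7}$ and self-connections are excluded from
  centrality.
* **Ties at the median go to "low"**, mirroring the strict ">" used for
  the obesity cutoff. One consequence worth knowing: with $t$ subjects
  tied at the median the low/high imbalance can reach $2t - 1$, because
  ties just above the middle order statistic all fall to "low".
* **Type III sums of squares with sum-to-zero contrasts** are the default
  (cells are unbalanced after data-driven stratification; this is the
  dominant convention in neuroimaging statistics software). Type II is
  available via `ss_type = 2`; both give identical results in balanced
  designs, and the residual df $N - 4$ is the same either way. In a 2x2
  design every term has 1 df, so the Type III F is the squared
  t-statistic of the corresponding sum-to-zero coefficient.
* **Pooled-variance Student's t** is the post-hoc default because its
  df convention is $n_1 + n_2 - 2$; Welch's t is available with
  `var_equal = FALSE`.
* **FDR families**: across nodes for the ANOVA (separately per effect —
  the joint-versus-separate choice is not dictated by the design, and
  separate families keep the three effect maps independently
  interpretable); across the six pairs within a node for post-hoc tests.
* **Degenerate inputs**: a perfect-fit node (zero residual variance)
  reports p = 0 with a warning when the effect sum of squares is nonzero,
  and p = 1 when the data are constant, so an all-zero centrality matrix
  yields no significant nodes.

## The synthetic cohort: a stated world

The cohort generator exists because the motivating data are
access-restricted. Its defaults are fixed once, to the conditions the
analysis was designed around, and are not tuning knobs:

* **n = 182 subjects**, 35 nodes, 490 timepoints per series.
* **Age** ~ Normal(55.21, 7.16) years; **sex** male with probability
  100/182.
* **WHR** is drawn as (sex-specific cutoff) + offset + Normal(0, 0.03),
  with offset $-0.06$ for non-obese and $+0.05$ for obese subjects. Means
  relative to the cutoff (rather than absolute) are necessary because the
  male and female cutoffs differ by 0.05, which is larger than the
  within-group spread; absolute group means would misclassify a large
  share of one sex. With these values the WHR rule recovers the
  generating obesity label for ~96.5% of subjects (measured over 100
  seeds) and the marginal WHR mean lands near 0.85.
* **Total WMH volume** is lognormal per burden group
  (low: meanlog 6.96, sdlog 0.41; high: meanlog 8.35, sdlog 0.63),
  matching the observed group means/SDs (~1150 ± 490 and ~5150 ± 3570
  mm³) and the strong right skew of lesion volumes (cohort SD of the
  order of the mean). The cohort-median split recovers the generating
  burden label for ~91% of subjects.
* **Periventricular share** of the total volume is Beta-distributed with
  mean 0.87 (the observed periventricular-to-total ratio) and
  concentration 20; deep + periventricular sum exactly to total.
* **Time series** are zero-mean multivariate normal with a block
  correlation structure: background correlation 0.1 between all pairs,
  and `base_correlation` (default 0.2) between one designated effect node
  and its neighbour set (default the next 3 nodes), to which an obesity
  main-effect increment and/or an hw-o-only interaction increment can be
  added. Multivariate normality is the minimal structure under which the
  Pearson-to-ANOVA chain has predictable behaviour, which is exactly what
  a test bed needs. Every implied correlation matrix is checked for
  positive semi-definiteness and infeasible parameter combinations are
  rejected up front — e.g. an effect-edge correlation of 0.75 to three
  mutually weakly-correlated neighbours is geometrically impossible, which
  caps the implantable interaction at about 0.43 above a 0.2 base with
  the default neighbourhood.
* **Confounds**: optional age/sex parameters shift all off-diagonal
  correlations of a subject's matrix uniformly (correlation units per
  covariate unit). They are expressed on the correlation scale, not the
  centrality scale, because centrality is computed downstream — a
  confound must enter through the series for the residualisation step to
  have something real to remove.

### What the generator does not emulate

No hemodynamics, autocorrelation, scanner noise, head motion, or lesion
geometry; series are temporally white. A green test therefore establishes
that the *statistical chain* behaves as specified (calibrated type-I
error, FDR control, effect recovery, exact residualisation), not that the
pipeline is robust to fMRI artefacts — those are handled upstream of this
package's scope.

### Power, misclassification, and cohort size

One property of the stated world deserves emphasis. Stratification is
data-driven, so ~5–10% of subjects carry the wrong group label. For an
implanted effect of size $s$ on the centrality scale, misclassified
subjects create within-cell mixture variance proportional to $s^2$ —
noise that scales with the signal. Consequently single-run top-hit
recovery of the implanted node does not improve with larger effects and
is unreliable (~80–85%) at n = 48; it concentrates with cohort size
instead. The recovery harness therefore runs at the default n = 182,
where the implanted node is the top interaction hit in ~97–98% of runs
(the effect size 0.4 was chosen by a pilot run at the PSD feasibility
ceiling). The null-calibration harness runs at n = 48, R = 10, where the
per-node interaction test rejects at 4.8–4.9% for a nominal 5% and BH
keeps the null discovery probability at the nominal level within
Monte-Carlo error.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 48, n_regions = 10, n_timepoints = 200,
                    seed = 42, effect_node = 3, interaction_delta = 0.4)
res <- run_pipeline_once(spec)
subset(res$anova, effect == "interaction")
```

## Known limitations

* The median-volume cutoff is implemented as stated, not defended; it is
  a data-driven convention whose validity is an open question.
* Post-hoc df in any external table that disagree with $n_1 + n_2 - 2$
  are not emulated; this package always reports the pooled-t convention.
* No correction is applied across the three WMH criteria — they are three
  separate analyses by design.
* Only weighted degree centrality is offered; no betweenness or
  eigenvector centrality, and no binary/hard-thresholded graphs.
* NIfTI support is a minimal NIfTI-1 subset (single-file, common
  datatypes, no orientation handling): inputs must already be
  voxel-aligned, and nothing is resampled.
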