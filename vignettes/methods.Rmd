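---
title: "Methods: patient-specific metabolic models from relative plasma metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific metabolic models from relative plasma metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasma metabolomics is often the only omics layer available for a
patient, and it is *relative*: single-time-point concentrations with no
uptake or secretion rates. `exogem` turns such data into
patient-specific genome-scale metabolic models (GEMs) and downstream
functional readouts. The pipeline has four stages:

1. **Baseline characterization.** The generic GEM (constrained with
   whatever physiological knowledge is available, including a biomass
   activation floor) is sampled with a hit-and-run walker, and the
   densest region of the sampled flux solution space is delimited; the
   per-reaction minimum/maximum over the retained solutions is the
   baseline flux envelope, and the exchange-reaction part of that
   envelope defines the baseline boundaries that patient data will
   rescale.
2. **Patient integration.** For each measured metabolite the ratio of
   the patient concentration to a control-group summary (minimum, mean
   and maximum — three summaries to absorb control heterogeneity)
   multiplies the corresponding exchange boundaries, giving three
   models per patient. The update reduces algebraically to
   `boundary x ratio`; exchanges whose baseline envelope is identically
   zero first receive a conventional (−10, +10) window.
3. **Consensus model.** The three members are sampled, the samples
   fused, the density filter re-applied (reusing the baseline's saved
   percentile threshold), and the consensus model's bounds set to the
   retained envelope over all reactions.
4. **Characterization.** Metabolic-task analysis by FBA, leave-one-
   metabolite-out cross-validation (Welch t-test, Benjamini–Hochberg),
   exchange-perturbation sensitivity cubes with PLS-DA, and
   hierarchical stratification (Euclidean distance, complete linkage).

## Core machinery and its numerical choices

### Linear programming

No LP solver package is assumed; FBA, parsimonious flux, ROOM-style
knockout prediction and task evaluation all run on a built-in
bounded-variable two-phase simplex (`lp_solve()`), dimensioned for
desk-scale models. Feasibility is enforced to `|S v| <= 1e-6`
(absolute) and optimality to ~1e-9 relative; these are ordinary solver
defaults, declared rather than inferred from any reference. Anti-cycling
falls back to Bland's rule after `3 (n+m)` Dantzig iterations.

### Flux sampling

`sample_fluxes()` implements artificially centered hit-and-run over
`{v : S v = 0, lb <= v <= ub}`: warmup vertices from per-reaction
min/max LPs (plus randomized objectives), directions drawn through a
running center, thinning of 100 chain steps per retained sample,
periodic re-projection onto the null space of `S`. Sampling is
bit-reproducible for a fixed seed. The walker sits behind the sampling
contract (feasible rows, deterministic under seed), so a different
sampler can be substituted without touching the rest of the pipeline.

`sample_adaptive()` reproduces the protocol's reuse of saved sampling
parameters: draw in batches (checking every batch, 500 samples by
default), stop when the retained count reaches the saved count *and*
the central–furthest span is within 5% (relative) of the saved span;
a saved span of zero degenerates to the count condition. Both
conditions are required jointly; the source text does not say whether
one alone suffices, and the joint rule is the conservative reading.

### Density exploration of the solution space

The continuous method scores each sampled solution by its summed
Euclidean distance to all others (column sums of the symmetric
pairwise-distance matrix, computed blockwise with a
catastrophic-cancellation guard for near-coincident points); the
discrete method sums per-reaction histogram bin frequencies (100 bins
per reaction by default, unit-area normalized). Central = densest
(argmin of continuous totals / argmax of discrete totals), furthest =
sparsest; distances are taken on raw fluxes (an optional z-scaling is
deliberately *not* the default because the distance definition is
stated on raw fluxes).

The **dynamic percentile** tests every percentile 1–100 of the
outlyingness distribution (linear-interpolation percentile), recording
the retained count and the span (Euclidean distance between the central
solution and the furthest retained one). Defining "where the curve's
concavity changes" numerically took three iterations, documented here
because the naive readings fail on real draws:

* the second finite difference of a window-5 moving average is pure
  sampling noise — its sign flips at almost every percentile, so
  "first sign change" always fired around p = 3 regardless of
  structure;
* a smoothing-spline second derivative with "first significant sign
  change" still latched onto spline end ripples on fused multi-cloud
  curves, making consensus envelopes irreproducible between sampling
  seeds (task scores varied by a factor ~2.4).

The final detector keeps the window-5 moving average, fits a cubic
smoothing spline (df 8), and (1) picks the *dominant* concavity change —
a zero crossing of the second derivative away from the curve ends whose
flanking curvature peaks reach 30% of the maximum curvature; a clean
sigmoidal span curve lands exactly on its analytic inflection — else
(2) uses the knee (maximum deviation from the endpoint chord) of the
typically convex curve, flagged as a fallback; an exactly linear or
constant curve returns percentile 100, flagged. The chosen percentile,
the span and the retained count are the saved sampling parameters;
subsequent analyses on the same network (knockout predictions,
patient-specific runs, the consensus fusion) **reuse** the saved
percentile instead of re-deriving it — re-derivation per patient
injects a random retained-fraction scale into every downstream task
score and was the single largest noise source we measured.

### Exometabolome integration

Per-patient ratios use the control minimum, mean and maximum. Zero
control statistics are replaced by `eps = 1e-6` with a warning.
Rescaling applies to both bounds of each mapped exchange; a pair
inverted by rescaling (possible when an envelope straddles zero) is
swapped and flagged. The trio members constrain *only the exchange
reactions* to the baseline envelope; internal reactions keep their
model bounds. The all-reaction envelope belongs to the consensus step.
This reading resolves an ambiguity in the protocol's step ordering, and
it is also the only workable one: imposing the all-reaction envelope on
trio members makes most rescaled patients infeasible, because a scaled
exchange can demand more flux than internally enveloped reactions may
carry. Trio members that are still infeasible (extreme ratios) are
flagged, and the pipeline fuses the feasible subset, erroring only when
none remains.

### Task analysis, knockouts, validation, sensitivity, stratification

Tasks add temporary uptake columns (default maximum 10 flux units when
unstated) and product sinks, and maximize total sink flux; patient
exchange bounds stay active, because a task probes the patient's
constrained capability (a closed-exchange convention is available by
flag). Task selection across severity groups ranks row-standardized
activities by group mean and keeps tasks whose first-to-last rank shift
is at least 10 positions (inclusive) with a *consistently directed*
trajectory. Strict one-directional movement proved brittle: after row
standardization any two planted monotone tasks have identical row means
and variances, so their group-mean curves must cross and adjacent rank
swaps are unavoidable; the filter therefore tolerates
`mono_tol = 3` positions of counter-movement per step, in line with the
observed oscillation of intermediate severity groups.

Knockout scans prune candidates to reactions carrying flux in a
minimal-L1 optimum (a zero-flux reaction cannot be singly essential),
predict post-deletion biomass by FBA re-solve, by a ROOM-style LP
(indicator variables relaxed to [0,1]; an exact branch-and-bound mode
exists for toy scale), or by density-based resampling with the saved
parameters (the central solution's biomass makes the viability call);
lethality means predicted biomass below 5% of the wild-type optimum,
with exchanges and the objective excluded from scans. Synthetic-lethal
pairs come from the FastSL-style second level: partners are the
reactions newly active in the deleted model's parsimonious flux; a
full-enumeration flag instead tests all non-excluded pairs. Gene
essentiality maps to reactions by the standard GPR semantics: OR
(isozymes) is essential only if all alternatives are; AND (complexes)
if any member is.

Cross-validation relaxes one measured exchange at a time to its
baseline bounds, resamples, and Welch-tests subsamples (n = 100 by
default — raw sampler populations are so large that any difference
rejects) of the constrained vs relaxed flux populations, adjusting by
Benjamini–Hochberg. "Correct" means failure to reject at adjusted
p < alpha: the model's constrained prediction is consistent with what
the data-free model would do. The opposite convention is available by
flag.

Sensitivity sweeps fix each measured exchange at 100 evenly spaced
values across its bounds, re-evaluate every task (infeasible points are
missing), min-max rescale both axes to [0,1] and fit an ordinary
least-squares slope (slope 0 and a flag below 10 feasible points).
The tasks x metabolites x patients cube flattens task-major,
metabolite-minor for PLS-DA (NIPALS, one-hot labels, column z-scored X,
deflation; explained label variance per component; features ranked by
summed absolute loadings).

## The synthetic world

`simulate_cohort()` draws control concentrations from per-metabolite
lognormals and multiplies group-specific fold changes onto affected
metabolites — plasma concentrations are positive and right-skewed, and
ratios are the integration currency, so multiplicative effects are the
natural null-respecting perturbation. The defaults encode one fixed
"stated world":

* 4 groups (A–D) x 6 patients, 20 controls, 8 measured metabolites
  (the toy model's exchanges);
* control variability sdlog 0.05 for homeostatically regulated
  metabolites (glucose, phosphate, ammonium) and 0.15 for the rest.
  The tight trio feasibility window of the growth-limiting exchanges
  under the 50% biomass floor (roughly ratio 0.7–1.4) makes wider
  control spread produce unsolvable min/max members;
* strong effects are 2–4-fold and must *restrict or force* flux:
  widening a bound beyond the network's internal caps leaves the
  sampled dense region unchanged and is invisible downstream. The toy
  network exposes two strong restrictable axes — respiration
  (oxygen + CO2 jointly, since respiration couples them 1:1) and amino
  acid supply with compensatory lactate overflow — so the four groups
  sit at the four corners of that plane: A unperturbed; B oxygen/CO2
  x0.1; C both axes perturbed; D amino acid x0.2 with lactate x3.

What a green end-to-end test establishes: the full chain (trio →
consensus → tasks → clustering) separates four planted phenotypes at
adjusted Rand index >= 0.8 and finds no structure in a null cohort.
What it does not establish: performance on real cohorts (53-metabolite
panels, thousands of reactions, biological covariance between
metabolites, measurement error), nor that effect sizes below the
restriction threshold would be detected.

## Known limitations

* The 22-reaction fixture's internal flux freedom (amino acid
  uptake/synthesis and respiration/fermentation trade-offs span several
  flux units) dominates any feasible ratio-induced bound shift, so
  pooled min/mean/max sample clouds separate only partially in PCA
  (silhouette plateaus near 0.2; a tightly bounded genome-scale
  polytope separates far more cleanly). The test suite asserts the
  achievable contrast.
* The span between the central and furthest retained solution is a
  near-extreme order statistic; on the toy fixture its Monte Carlo
  noise at a fixed threshold is itself about 5%, which is exactly the
  tolerance of the stabilization acceptance criterion — that criterion
  is left red, with the analysis recorded in the test and the ledger.
* The dynamic percentile on small sample sets routinely takes the knee
  fallback (real span curves are convex without a clean inflection);
  the fallback flag is reported, not hidden.
* ROOM's default is the LP relaxation; its indicator sum lower-bounds
  the true change count. The exact mode is exponential in the worst
  case and intended for small models.
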