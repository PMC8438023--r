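---
title: "Percentile climate envelopes, change zones and conservation accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile climate envelopes, change zones and conservation accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobraclim)
```

`cobraclim` projects species climatic niches under climate change and turns
the projections into conservation quantities: zone areas, decline rates,
time to the Red List Vulnerable extent threshold, and per-zone human
population pressure. This vignette is the package's account of the methods:
the model and its assumptions, the parameters that matter, the numerical
conventions, what the synthetic generator does and does not emulate, and
where the design was genuinely open.

## The percentile envelope

BIOCLIM-style envelopes are presence-only models: the training sample *is*
the model. For each retained bioclim variable the training values are kept
as a sorted vector; a probe value \(x\) is scored by its tie-aware
empirical percentile

\[ p_v(x) = \frac{\#\{x_i < x\} + \tfrac12\,\#\{x_i = x\}}{n}, \]

folded about the median, \(f_v = 2\min(p_v, 1-p_v)\), with suitability
\(\min_v f_v\). Assumptions inherited from the model family: sampled
climates are suitable by definition; variables act independently through
the weakest-link minimum; there is no interpolation beyond, or weighting
within, the observed range.

**Why tie-aware half-weighting.** With \(p = (\#< + \tfrac12\#=)/n\), every
training value has \(p \ge 1/(2n)\), strictly inside \((0,1)\), so every
training point scores positive and the binarized envelope always contains
the training cells — the premise that sampled climates are suitable would
fail under the plain \(\#\le/n\) convention, where the training minimum of
a variable scores 0. Exactly-at-extreme probes therefore score positive
here, while strictly-outside probes score 0. Percentile-folding conventions
differ between implementations of this model family; this one is frozen
and documented rather than claimed to be universal.

**Degenerate variables.** A zero-variance training variable scores a probe
1 at the constant (tie-aware median) and 0 anywhere else.

**Thresholding.** A cell is "suitable" iff its score is strictly positive.
The continuous score is retained because ensemble consensus averages
predicted values before thresholding; for non-negative scores the
mean-then-threshold map equals the union of member envelopes, a property
the tests assert rather than assume.

## Grid conventions

The default study grid is the cropped Asian rectangle, longitude 40–150,
latitude −10–50, at 0.5°: 220 × 120 = 26,400 cells. Every cell counts as
60 km × 60 km = 3600 km², with no cos(latitude) correction — the published
areas follow this constant-area convention, so it is the package default; a
latitude-corrected mode exists for sensitivity checks but is off by
default. Cells are half-open (`[edge, edge + resolution)` going east and
south from the northwest corner), so a point on a shared edge belongs to
exactly one cell — the larger-index one; row 1 is the northernmost row.
Missing data are `NA` throughout, never sentinel numbers. Rasters are
plain-text ESRI ASCII grids written at full double precision so layers
round-trip bit-exactly; this is the package's native exchange format.

## Variable preparation

Because bioclim variables mix °C and mm, observations are z-scored before
correlation screening and ordination. The collinearity filter removes one
member of every pair with Pearson \(|r| > 0.9\) (threshold configurable),
visiting pairs in descending \(|r|\) with index-based tie-breaking so the
outcome is invariant to column order. Which member survives is a semantic,
not statistical, choice; the defaults encode the published reasoning
(annual mean temperature over coldest-month/quarter extremes, seasonality
over the derived annual range, warmest-quarter mean over warmest-month
maximum, annual precipitation over wettest-quarter, driest-quarter over
driest-month precipitation) as an overridable priority-rule table, with
"keep the lower index" as fallback. On data where those six pairs exceed
the threshold this yields the 13-variable set {1, 2, 3, 4, 8, 9, 10, 12,
13, 15, 17, 18, 19}.

The ordination is principal-axes (PCA on the standardized matrix). The
source analyses name only "dimension reduction" with two functions; whether
that was PCA or a discriminant analysis is not recoverable, so the package
implements one documented ordination and exposes scores and loadings for
users who prefer another. Reproducing the published variance fractions
would require the original extracted climate values and is out of scope.

## Occurrence handling

Mechanical curation only: unparseable rows, exact duplicates, points
outside the extent and points on non-land cells are dropped, each logged
with a reason code so dropped + retained always equals the input count.
"Closely positioned" records are thinned to one per 0.5° cell — the model
resolution — keeping the first record in input order (deterministic); a
great-circle minimum-distance mode (`thin_by_distance`) is the documented
alternative. No minimum sample size is enforced (envelopes are legitimately
fit from a few dozen points) but a configurable warning flags small
samples. Judgment-based curation against the literature cannot be
algorithmized and is left to the user.

## Change zones and accounting

Present and future binary maps overlay as `present + 2·future`: zone 1
lost, zone 2 gained, zone 3 stable, 0 never suitable. Accessibility masks
(ocean barriers, unreachable ranges — ecological judgments supplied as
inputs, not computed) are applied after the overlay and before accounting,
and the suitable area masked off is reported. Whether masking preceded or
followed the overlay in the source workflow is not stated; applying it
after is this package's documented choice and does not change the
accounting, which only sees masked grids.

The accounting formulas are reconstructed from the published table's
self-consistency, since they are not printed anywhere:

* decrease% \(= 100\,(A_1 - A_2)/(A_1 + A_3)\), identical to
  \(100\,(A_{cur} - A_{fut})/A_{cur}\); negative values (net gain) are
  reported, not clamped; undefined when the current niche is empty.
* yearly rate \(= (A_1 - A_2)/\)span, with the default 2020–2070 window.
* Vulnerable year \(= 2020 + \mathrm{round}((A_{cur} - 20000)/\text{rate})\)
  (round to nearest; R's round-half-even applies at exact halves), `Inf`
  ("never") for non-positive rates, the base year when already at or below
  the 20,000 km² criterion B1 gate.

Driven by the printed zone sizes and rates, these formulas reproduce the
printed decrease percentages for the exactly-recoverable rows and the
printed Vulnerable years for seven of ten species; the other three differ
by 1–4 years because the published unrounded intermediates are
unrecoverable. `reproduce_table1()` reports those residuals instead of
asserting them away. Internally all areas are km²; "million km²" is
presentation only.

## Human pressure

Fine population rasters are block-summed (factor 60 for the 30-arc-second
to 0.5° downgrade), conserving totals exactly. Zone density is persons per
km² over the zone's cells; an empty zone's density is undefined and stays
undefined through the 2020→2070 change (the published table's diamond).
Density change is computed over fixed zone geometry — both epochs on the
same cells — the only reading consistent with one change value per zone.
The risk matrix combines computed flags (niche decrease, per-zone density
increase), a limiting-variable analysis for the temperature/precipitation
influence columns, and externally sourced flags (population trend, trade)
passed through verbatim with "unknown" when absent. The influence columns
have no published derivation; the operational rule here — which variable
attains the minimal folded score over envelope-edge cells (the lowest
decile of positive suitability), temperature variables being bio1–11 and
precipitation bio12–19 — is an interpretation, documented as such. The SSP
pathway paired with an RCP is a required label with no default, because no
pairing is canonical.

## The synthetic generator

`synthetic_scenario()` emulates the shape of the real inputs — multi-variable
0.5° climate stacks for present and 2070, four perturbed pseudo-GCMs, a
land mask, occurrences from a known envelope, clustered fine-resolution
population — with full determinism under a seed (every internal draw uses
its own derived stream and restores the caller's RNG state).

Design choices worth knowing:

* **One latent gradient.** All variables are strictly monotone nonlinear
  transforms of a single latent climate field (latitude trend +
  low-frequency sinusoid + seeded noise, discretized to 120 levels). Real
  bioclim variables are strongly collinear because they summarize one
  climate system; the generator takes that to the limit. Consequence: the
  generated variables cannot exercise the collinearity filter's selective
  behaviour or multi-variable trade-offs in the minimum rule — those are
  tested on purpose-built matrices instead — and passing recovery tests
  says nothing about envelope performance when variables carry independent
  information.
* **Value quantization.** Each variable lives on a lattice (1/1000 of its
  span), materialized as `quantum × integer ticks` in one product so equal
  lattice points are bit-identical; future shifts and GCM perturbations are
  lattice multiples, and the true envelope bounds sit half a step off the
  lattice. This removes both boundary ambiguity and floating-point
  near-ties at the envelope edges.
* **Exact recovery by construction.** The true envelope is a latent-level
  band whose edge levels are attained on land (type-1 quantiles). Under
  dense sampling (one occurrence per suitable cell) the fitted envelope's
  min–max per variable coincides with the true bounds' interior lattice,
  so fitted and true masks — present and future, through consensus,
  binarization and zoning — agree cell-for-cell, and the end-to-end
  account equals `ground_truth_accounts()` exactly. The tests assert the
  stated tolerances (one cell-area per zone, Jaccard ≥ 0.95) but the
  design target is equality; sparse sampling degrades gracefully and is
  covered by the nested-sample monotonicity test.
* **Present shared across GCMs.** Pseudo-GCMs diverge only in their future
  fields (one observational baseline, four projections). Real GCM
  hindcasts differ in the present too; a test that needs that can pass
  per-GCM perturbed present stacks explicitly.
* **Defaults.** Envelope band = the 45th–80th latent percentiles over land
  (a mid-gradient species with a sizeable range); future shift +6 % of
  span for temperature and +4 % for precipitation (a warming,
  monsoon-wetting trend that migrates the band and populates all three
  zones); GCM perturbation amplitude 2 % of span; land fraction 0.7;
  population as Poisson draws around Gaussian settlement clusters, with
  2070 = round(2020 × intensity-weighted cluster growth) so counts stay
  integral and growth 1 is exactly the identity.

What the generator does **not** emulate: climatologically realistic GCM
structure, spatially autocorrelated sampling bias in occurrences,
independent information across variables, coastline geometry, or SSP
demographic realism. Green tests on synthetic data certify the algebra and
the code paths, not field performance.

## Problem sizes and runtime

The test suite runs the full pipeline at the study scale — the 26,400-cell
grid with four pseudo-GCMs and dense (several-thousand-point) training —
in about a second on one core; unit fixtures use grids from 2 × 2 up to
60 × 60 cells. Population fixtures use reduced refinement factors (2–6)
and a 240 × 240 fine grid for the factor-60 conservation check, which
exercise the same block-sum code path at any factor.

## Known limitations

* The envelope has no discrimination measure (no AUC, no background
  sampling); the model family does not provide one and none is computed.
* Areas use the constant-cell convention; enabling latitude correction
  changes areas by up to ~25 % at the grid's extremes and is intentionally
  not the default.
* The three non-exact Vulnerable years in the published table cannot be
  reproduced beyond ±4 years from printed inputs; they are flagged, not
  fitted.
* `reproduce_table1()` checks internal consistency of published values; it
  is not a re-analysis of the original occurrence or climate data, which
  the package deliberately does not download.
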