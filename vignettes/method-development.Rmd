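---
title: "Discovering and separating unknown mixtures: the models behind chromdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and separating unknown mixtures: the models behind chromdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdev)
```

## The problem

Retention modelling in reversed-phase LC needs one retention time per
component per calibration run. For an unknown mixture nobody can supply
those assignments: peaks overlap, selectivity changes reorder them between
runs, and the number of components is itself unknown. `chromdev` treats the
screening chromatograms as second-order data (time x wavelength, or time x
m/z) and lets the spectra do the tracking: curve resolution recovers each
component's spectrum wherever it elutes cleanly enough, and spectral
correlation carries the identification across runs.

## The bilinear resolution model

A baseline-delimited section of one run (a *peak cluster*) with `m` time
points and `n` channels is modelled as

$$X = C\,S^{\mathsf T} + E,$$

with non-negative elution profiles `C` (m x N), non-negative spectra `S`
(n x N) and residuals `E`. Bilinear decompositions are rotationally
ambiguous; the package restricts the solution set with the two constraints
that chromatographic data genuinely satisfy: non-negativity of both factors
and unimodality of each elution profile. Alternating least squares starts
from SIMPLISMA's purest time points: the purity of row *i* is
$p_i = \sigma_i / (\mu_i + \alpha)$ with $\alpha$ set to 3 % of the
mean-spectrum maximum (typical literature values are 1-5 %; smaller values
let low-signal rows win, larger ones bias selection toward intense rows),
and each subsequent selection is down-weighted by the determinant of the
correlation-around-origin matrix with the rows already chosen, so the
selections probe independent directions.

Numerical choices: the non-negative least squares subproblems are solved on
the normal equations — the unconstrained solution is used whenever it is
already feasible, with a Lawson-Hanson active set as fallback (the rank is
at most six, so the systems are tiny). Unimodality is imposed by isotonic
regression toward the profile maximum on each side. Iterations stop when
the relative change of the lack of fit (lof, in percent of the total sum of
squares, root-mean form) drops below 1e-6 or after 500 iterations; ten
consecutive lof increases flag a non-converged fit. The best accepted state
is returned, which makes the reported lof trajectory non-increasing by
construction.

The number of components per cluster is chosen by a singular-value screen
against a noise floor estimated from the cluster's edge rows, refined by
fitting ranks upward until the lof falls below 2 % (synthetic-data default;
instrument data may need a looser value), and **capped at six**: beyond six
components per cluster the extra factors almost always model noise and
inflate the false-positive load downstream. The cap can be raised, with a
warning.

## Segmentation

Peak picking runs on the maxplot (UV) or TIC (MS), after clipping negative
values — autozeroed detectors legitimately produce small negatives that
would otherwise break the non-negativity assumption. The trace is smoothed
by a Savitzky-Golay filter (window 11 points, order 3, matching the
recommended sampling of at least 5 points per second so a typical peak
spans dozens of samples); apexes require a negative smoothed second
derivative. Two statistics drive the baseline decision: a robust cell-noise
level (1.4826 x MAD of first differences over the quiescent fraction,
corrected for differencing) and the baseline *level* `b0`, because a
maxplot baseline rides at the expected maximum of the channel noise rather
than at zero. Points within `noiseK` (default 3) ripple units of `b0` for
at least `minPoints` (default 5) consecutive samples are baseline; signal
stretches shorter than the baseline run length are discarded as noise
excursions, and apex candidates must clear the baseline by twice the
detection band and survive a prominence check against neighbouring valleys.
Composite clusters are cut at interior minima dropping below `valleyRatio`
(default 0.5) of the smaller adjacent apex, measured above `b0`; the pieces
tile the parent exactly.

## Catalog, assignment, review

Components extracted alone from rank-1 clusters are *pure*; a profile
peaking on its cluster boundary is treated as a split fragment and not used
to seed catalog entries (it remains assignable). Pure spectra merge into
one catalog entry at Pearson r >= 0.95 on unit-normalized spectra; when MS
evidence is present, entries whose base peaks differ stay separate even at
UV r >= 0.95 — this is what separates positional isomers with identical UV
spectra. Assignment is per run, greedy in descending correlation,
one-to-one; r >= 0.95 assigns the extracted apex time, 0.8 < r < 0.95
raises an alert and leaves the cell unassigned, ties within 1e-9 go to the
candidate closer to the entry's median assigned time. Entries correlating
(|r| >= 0.95, either sign) with any run's baseline-mean spectrum are
flagged as background artifacts and excluded from modelling — flagged, not
deleted, because every removal decision belongs to the chromatographer.
The diagnostics report lists redundancy pairs (same spectrum, same times),
sum-spectrum candidates (an "entry" matching the normalized sum of two
co-eluting entries), and per-column inconsistencies; edits (merge, delete,
manual assignment) are scripted, and retention fitting refuses to run while
alert cells remain unresolved unless explicitly waived. The redundancy
time tolerance defaults to 0.05 min (a few sampling intervals); the
mixed-set pass reuses the 0.95 limit, there being no reason to treat the
two correlation analyses differently.

## Retention model

The linear solvent strength relation is the core:

$$\log_{10} k = \log_{10} k_0 - S\,\varphi + a\,(T - T_{\mathrm{ref}}),$$

with the van't-Hoff-like temperature term included only when the design
varies temperature and `Tref` at the design centre. Two fitting modes are
exposed because the gradient data do not observe `k` directly:

* **lss** (default): nonlinear least squares on the observed retention
  times, each candidate parameter vector pushed through the stepwise
  gradient simulator under every run's own program (multistart grid over
  log k0 in {1,2,3} x S in {3,5,8,15}, refined by Levenberg-Marquardt).
  This yields parameters directly usable for simulating *arbitrary*
  programs, which the optimizer requires.
* **pls**: partial least squares of tR on the coded design factors expanded
  to second order, latent variables chosen by leave-one-out on the
  calibration runs (capped at calibration runs minus two). This is a purely
  empirical interpolator within the design region.

Validation runs are predicted but never fitted; a mis-assigned retention
time surfaces as an outlying residual, though a bad value at a
high-leverage design corner can drag a neighbouring run's residual up with
it — the goodness-of-fit report flags standardized residuals beyond 3 and
keeps calibration and validation pairs distinct.

## Gradient simulation and optimization

Migration under an arbitrary program is integrated as small isocratic
steps: per step of length `dt` the solute advances `dt / (t0 k(phi))` of
the column, with the inlet composition delayed by the dwell time; elution
interpolates inside the final step, and once the program composition is
constant the remaining migration is finished in closed form — isocratic
retention is therefore exact (`tR = t0 (1 + k)`), and a linear gradient
matches the textbook LSS solution to well under 0.5 % at `dt = t0/100`.
The default step is `t0/50`; halving it moves retention times by less than
0.1 %. Solutes still on the column are given three gradient times of
final-composition overtime before being flagged non-eluting. Peak width
uses the isocratic plate expression at the retention factor prevailing at
elution, `sigma = t0 (1 + k_e) / sqrt(N)`; gradient peak compression is not
modelled, which biases simulated widths slightly upward — conservative for
resolution ranking. Resolution is `Rs = (tR_j - tR_i) / (2 (sigma_i +
sigma_j))` over adjacent pairs, and the critical Rs is the minimum.

The optimizer is differential evolution, rand/1/bin with F = 0.7, CR = 0.9
and population 40 — standard settings that are robust on low-dimensional
program spaces. Bounds are handled by reflection, and decoded programs are
always valid (phi clipped to [0, 1], node times sorted). The Pareto mode
replaces a parent only when the trial dominates it and maintains an
external archive of all non-dominated programs (objectives: critical Rs to
maximize, elution time of the last component — not the programmed gradient
time — to minimize). Trials in which any component fails to elute are
penalized below every feasible point, never fatal. The critical Rs is
capped at 1000 so that a single-component "mixture" degenerates cleanly to
runtime minimization. Weighted and resolution-threshold scalarizations are
available for single-objective use.

## What the synthetic generator emulates — and what it does not

`simulateCampaign()` realizes a screening campaign with known truth: each
component elutes as a Gaussian centred at the simulator's retention time
with plate-model width and a flow-corrected area equal to its amount;
the matrix is the bilinear sum plus optional polynomial baseline drift, an
early broad injection hump (to exercise the background-artifact filter),
and iid Gaussian cell noise. Negative noise excursions are kept, so the
non-negativity preprocessing is exercised. The reference campaign uses
6 components, smooth random spectra with pairwise |r| < 0.9, log10 k0 in
1.2-3, S in 3-8, small negative temperature coefficients, amounts spanning
10x, 5 points/s sampling, 5000 plates and noise placing the smallest
component's apex signal-to-noise near 100 (the configured 0.013 response
units correspond to that height at typical simulated widths) — values
chosen once as representative of small-molecule screening on short
columns. Test problem sizes (9 runs of roughly 2000-5000 time points x 39
channels; optimizer budgets of 40 x 60; 20 campaigns for slope recovery;
50 x 50 oracle grids) were likewise fixed as the package's reference
conditions.

Passing tests on these data show that the *algorithmic chain* is correct
under its own assumptions. They do not certify behaviour on real data,
where peaks tail, spectra shift slightly with temperature, noise is
heteroscedastic and correlated, and baselines wander non-polynomially.
Notably, when a pair of components co-elutes in *every* run (possible for
nearly parallel LSS lines), no pure spectrum exists and the catalog
honestly reports one entry fewer — the method's stated precondition is
that each component elutes pure, or nearly so, in at least one run, which
is also why the screening design deliberately spreads selectivity.

## Design choices made where the field leaves them open

* The economical screening designs are irregular three-level fractions with
  the canonical 2/6/8/18 run counts; the 2- and 4-factor model matrices
  have full second-order column rank, while the 8-run 3-factor design is
  saturated (rank 8 against 10 second-order terms) — its quadratic
  information is partial by construction, which the LSS mode does not need.
* pH is refused as a factor under UV-only detection (it shifts UV spectra
  and would break spectral tracking) and admitted with a warning when MS is
  present.
* m/z binning is half-open and left-inclusive at 1 Da, matching
  unit-resolution quadrupoles; times are minutes everywhere, with
  second-based files converted on load.
* Each column of a multi-column screen is modelled as a separate campaign;
  column identity never enters a retention model.
* Dead time and dwell time are required campaign metadata (dwell defaults
  to 0), not estimated from data.

## Known limitations

Tailing/fronting peak shapes, detector saturation, closure/selectivity
constraints, trilinear models, rotational-ambiguity span analysis,
pH-dependent retention, curvature corrections to the LSS line, flow-rate
optimization and robustness assessment of the chosen program are all out
of scope. Enantiomers — identical UV and MS spectra — cannot be
distinguished by any spectral-correlation strategy, this one included.
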