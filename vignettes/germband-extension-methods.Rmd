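---
title: "Methods: quantifying and simulating germband extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and simulating germband extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbex)
```

`gbex` analyses convergent extension of the *Drosophila* germband from
tracked apical cell meshes and tests the differential-identity model of
junctional Myosin II polarisation in a vertex-model simulator. This vignette
is the package's own account of the methods: the models, their assumptions,
the tunable parameters, and the design choices made where the design was
genuinely open. All quantitative statements here are computed by the test
suite or the acceptance script; none are asserted from memory.

## The data model

Everything operates on a `tracked_tissue`: tibbles of cells (polygon vertex
lists, centroids, parasegment and stripe labels, a germband/mesectoderm/
excluded flag), vertices, interfaces (vertex pair, flanking cell pair,
length, mean fluorescence), and forward track links for cells and interfaces
that persist through neighbour exchanges. Coordinates are embryonic AP–DV
micrometres (AP positive towards the posterior); angles are degrees
anticlockwise from East = posterior, matching the convention used to unwrap
perimeter signals. Polygons are stored counter-clockwise and interfaces once
per cell pair. Missing labels are explicit `NA`s. `validate_tissue()`
enforces the invariants (polygon simplicity and orientation, interface
lengths equal to vertex distances, link injectivity) and reports violations
with frame and object ids.

Because no public tracked-movie accession exists, the `synthetic_data`
generators are first-class citizens: they produce every input the pipeline
needs with known ground truth, and all tests run against them.

## Perimeter signals and the two polarity measures

A cell's junctional Myosin II is summarised as a *castellated* signal: the
perimeter is unwrapped from 0 to 360 degrees anticlockwise, each interface
occupying an arc proportional to its share of the perimeter, and the layout
rotated so arc centres best align (circular least squares) with the
interfaces' true directions from the centroid — on a regular hexagon every
side then sits exactly at its geometric angle, and the construction stays
well-defined for irregular, even non-star-shaped cells, where angular
subtension is not. Two measures are computed from the castellated signal:

* **Fourier**: period-1 and period-2 amplitude/phase by *exact* integration
  of the piecewise-constant signal against `cos(kθ)`/`sin(kθ)` — no
  discrete sampling, so results are independent of how finely arcs happen to
  be split. Period 1 measures unidirectional, period 2 bidirectional
  enrichment. On castellated signals a purely unidirectional peak leaks into
  period 2 (the harmonic is in phase with period 1), which is why the
  Fourier bipolarity overstates late-stage bipolarity.
* **Gaussian**: least-squares fit of baseline plus two Gaussians with means
  fixed at 0° (posterior) and 180° (anterior), free amplitudes and one
  shared sd. The model is integrated over each arc (so the fit respects the
  castellation) and the squared error is weighted by arc length. The smaller
  amplitude is bipolarity; the signed remainder is unipolarity, positive
  for posterior enrichment. Both are normalised: *amplitude area*
  `A · σ · √(2π) / 360` divided by the cell's mean perimeter intensity
  ("pp" units), so polarity is comparable across embryos with different
  absolute fluorescence.

Fitting choices: amplitudes are bounded below by 0 and the shared sd
constrained to 5–120°; Gaussians are evaluated with ±720° wrap-around images
so large sds stay well-defined; a free baseline absorbs residual background
(background is subtracted first, but any remainder would otherwise bias the
amplitude areas). The optimiser (L-BFGS-B) restarts from three deterministic
initialisations and keeps the lowest objective; a fit that fails everywhere
is flagged `converged = FALSE` and excluded from averages. The generator
(`make_perimeter_signal()`) uses the same generative family with the same
integration convention, which makes parameter recovery a sharp test: on
noise-free six-sided signals the fit recovers amplitudes and sd essentially
exactly. At a signal-to-noise ratio of 5 (defined here as the smaller
Gaussian amplitude over the additive noise sd), individual six-arc fits are
noisy and right-skewed — the amplitude–width trade-off lets a narrow, tall
pair of Gaussians chase single noisy sides — so recovery is assessed, and in
practice performed, on the pooled perimeter signal of a batch of cells,
where it is again accurate. Per-cell outputs carry the normalised `pp`
values whose *averages* are the analysis quantities; single-cell raw
amplitudes at low SNR should not be over-read.

**Background** is the modal intensity: the left edge of the most populated
fixed-width histogram bin (width 1 by default, exact for integer-valued
data — the exact binning used for "modal intensity" is not standardised, so
the width is exposed as a parameter), subtracted with clipping at zero.

**Doming correction.** Imaging produces a smooth dome of intensity (corners
dimmer than the centre) which masquerades as unipolarity. A local-linear
kernel smoother (Gaussian kernel, sd = 1/20 of the field width) is fitted to
the interface intensities; each cell's perimeter intensities are divided by
the smooth's local trend (value at the interface midpoint over value at the
centroid) and rescaled so the cell's arc-length-weighted mean is unchanged
to 1e-9 relative. Local-linear (not kernel-mean) regression is used because
it reproduces a linear field exactly, so a pure ramp is removed completely.

**Maps.** Polarity maps bin cells into an 80 (time) × 60 (AP) grid with the
DV dimension averaged out; each square gets a mean, count, and two-sided
one-sample t-test against zero. Squares with fewer than two observations
have undefined variance and are masked. The confidence level is the caller's
choice: 99.9% for bipolarity and 95% for unipolarity maps, reflecting the
different sided-ness of the two signals.

## Kinematics

**Strain rates.** For each focal germband cell, a domain (focal cell + first
corona) is followed over a window of 5 frames (2 min at the default 0.5-min
interval), centred by default — the window placement is configurable because
the natural choice is not unique. Per consecutive frame pair the affine map
best fitting the domain centroids is estimated by least squares and its
matrix logarithm divided by the interval gives the velocity gradient; the
symmetric part is the **tissue** strain-rate tensor (per hour). Each cell's
**shape** tensor comes from the unique symmetric positive-definite map
carrying its second-moment (best-fit-ellipse) matrix to the next frame's.
**Intercalation** is tissue minus mean cell shape — exact by construction,
which the tests assert to machine precision. Using matrix logarithms makes
pure exponential deformations (e.g. `diag(exp(k dt), 1)` per frame) yield
the rate `k` exactly at any frame interval. Collinear domains or failed
logarithms flag the row `singular`.

**Synchronisation** sets time zero at the last frame before the proportional
AP extension rate of the germband (from centroid extent) first exceeds
0.01/min; a movie that never exceeds it returns an explicit no-onset result.

**T1 detection** registers a neighbour exchange when a cell pair loses
adjacency while the orthogonal pair of the same quartet gains it, then
debounces with a 5-min window: a swap is productive only if the new topology
persists for the window (or to the end of the movie) without reverting to
the previously accepted diagonal. Flickers collapse to a single event at
the time of the last persisting swap; pure reversions produce none;
unresolved four-way configurations produce none. Quartets are identified by
track ids, so detection is unaffected by frame-rate doubling or time shifts.

**Voronoi deviation.** The Voronoi tessellation of the observed centroids is
taken as a mechanically relaxed reference; per interface the deviation is
observed minus predicted length (negative = shorter than relaxed =
geometrically stressed). The tessellation is computed by half-plane
clipping with generator labels (no suitable tessellation backend is
available to R here, and labelled edges are needed anyway); predictions are
only scored for interfaces whose two cells have Voronoi cells bounded
entirely by neighbours and lie off the convex hull, since hull cells have
unbounded regions. Per-cell perimeter deviations additionally require the
cell to have no tissue-border interface. On regular hexagonal lattices the
deviations are zero to 1e-9, a self-consistency the tests assert, and
perturbed lattices are checked against an independent
nearest-two-generators sampling oracle.

**Recoil regression** takes a plain table of vertex distances, fits ordinary
least squares to the first 5 post-ablation points per ablation (the slope is
the recoil velocity), and compares groups with an equal-slopes test (the
interaction term of `distance ~ time * group`). Kymograph image handling is
out of scope; the input is already-measured distances.

## Boundary analysis

Parasegment labels assigned at a reference frame (in practice the last,
where Myosin cables are obvious) propagate to all frames through the track
links; conflicting labels raise an error naming the cell. Interface classes
(PSB, S1/2B, S2/3B, S3/4B, superboundary, nonboundary, other) derive from
the flanking cells' labels; interfaces touching excluded cell types or the
tissue border are `other` and excluded from statistics. "Superboundary"
interfaces separate identities two apart in the 4-cycle — the geometric
signature that an intervening stripe has local width zero.

The within-parasegment coordinate ranks cells by AP centroid within each
parasegment and DV row and places them at cell-centre positions
`(rank − 0.5)/n` in `[0, 1]`; rank interpolation is monotone, dimensionless,
and robust to the exact parasegment width. DV rows are centroid bins of
height equal to the median cell DV extent — adequate for meshes whose rows
are offset by half a cell, which pure `y`-clustering mis-handles.
Cells-per-parasegment divides the parasegment width (extreme centroid span
plus half a mean cell width each side) by the mean centroid spacing; on a
row of `n` equally spaced cells this returns exactly `n`.

Per-minute Myosin comparisons report the mean over embryos per class and
1-min bin with a ribbon of half-width
`sqrt(var(embryo means) + mean(within-embryo variances))`, and per-bin
significance from a linear mixed model with embryo as random intercept
(`lmerTest`), thresholded at `0.05 / n_bins` (Bonferroni over the time
bins — 81 bins for a −20…60-min movie). With a single embryo the random
effect is unidentifiable and the test is reported `NA` rather than faked.

Co-alignment reports the proportion of interfaces in the closed 60–90° band
(endpoints included — the open/closed choice is not standardised, and with
continuous orientations it is measure-zero), LOWESS-smoothed with a 10-point
window; cumulative orientation distributions and pairwise two-sample KS
tests at a chosen time; and the von Mises concentration κ estimated on
doubled angles, as appropriate for axial data — κ uses the *unreflected*
0–180° angles, since reflecting first would manufacture spurious
concentration.

## The receptor code

Identities repeat every double parasegment: 8 cells on a circle with PSBs
between cells 4|5 and 8|1. A receptor is a subset of cells; pair-rule
patterns occupy exactly 4 of 8. The robustness score counts grey boxes:
interfaces with ≥1 receptor difference (Hamming distance); single deletions
whose bridging interface strictly exceeds both replaced interfaces; and
contiguous double deletions whose bridge strictly exceeds both overlapping
single-deletion bridges. The first line *counts* heterotypic interfaces
rather than summing difference magnitudes — both readings reproduce the
canonical two- and three-receptor totals (10 and 20), so the choice is not
empirically forced; counting keeps every line on the same 0–8 scale and is
the default, with `line1 = "sum"` as a documented switch. The double-
deletion baseline is the maximum of the two overlapping single-deletion
bridges; this is the unique simple reading that yields 0 grey boxes for the
two-receptor scenario and 4 for the three-receptor one, verified in the
tests by an independent loop-written oracle.

Exhaustive search enumerates multisets of the 70 pair-rule patterns
(receptor-label permutations cannot change the score, which the tests
assert), scores them by table lookup over the 24 cell-pair XOR columns, and
re-weights by multiplicity so the returned histogram counts ordered
placements; `choose(8,4)^4 ≈ 2.4 × 10⁷` four-receptor placements reduce to
~1.1M multisets and take on the order of a minute. Randomised search draws
placements uniformly with a seed.

## The vertex model

Cells are polygons sharing vertices; vertex positions follow overdamped
gradient flow `η dr/dt = −∂U/∂r` with

`U = Σ_cells K/2 (A − A0)² + Σ_cells Γ/2 P² + Σ_interfaces f(l)`

integrated by explicit Euler (all positions updated simultaneously), with
T1 swaps applied at the start of every step: any interior edge shorter than
`d_min` whose endpoints are three-valent is rotated 90° about its midpoint
to length `p·d_min`, and the quartet's adjacency is rewired. Swaps that
would create a two-sided cell, involve border (two-valent) or higher-order
vertices, are suppressed and counted — these are the unresolved
configurations. Defaults are non-dimensional: `η = 1, Δt = 0.001,
d_min = 0.01, p = 1.5, K = 1, A0 = 1, Γ = 0.04, Λ_int = 0.05,
Λ_bdy = 2Λ_int, Λ_sup = 8Λ_int`, end time 500. The 1:2 non-boundary to
boundary ratio matches the factor-2 recoil-velocity difference measured at
parasegment boundaries by laser ablation.

The four tension laws: (1) `Λ l` everywhere, with `Λ_bdy` on
stripe-boundary interfaces; (2) `Λ_bdy log l` on boundary interfaces —
positive feedback between shortening and contractility; (3) `Λ_bdy log L`,
where `L` is the smaller, over the interface's two cells, of the summed
*contiguous* boundary-interface length including the focal interface — the
feedback acts on whole boundary cables so vertices can slide independently
along a boundary; (4) adds `Λ_sup log L` for *skipped* boundaries
(identities two apart in the 4-cycle, e.g. 2|4, including across PSBs by
mod-4 arithmetic). Tissue-border interfaces always use the linear `Λ_int`
law. Forces are analytic gradients of all terms (chain terms distribute
`Λ/L` over every edge of the defining run); the tests check them against
finite differences of the energy for all four variants, and chain lengths
against a graph-walk oracle.

Numerical choices that the published description leaves open:

* how the chain tension acts. Writing the boundary term of the free energy
  as one `Λ log L` contribution per interface and taking its exact gradient
  makes every interface's energy pull on every interface of its chain; the
  total inward pull on a cable then scales with the number of its
  interfaces over its length, the energy is unbounded below, and long runs
  collapse whole cables — and eventually whole cells — to points
  (observable as nested, degenerate polygons). The default `chain_force =
  "local"` instead carries tension `Λ/L` on each boundary interface itself,
  treating the chain length as a frozen coefficient: tension is shared
  equally along a cable, vertices slide freely along it, and the published
  phenotypes (no exchange under linear tension; convergent extension under
  the chain law; stripe-order repair under supercontractility) all emerge.
  The exact-gradient mode remains available for comparison, and the force
  routine is verified against a finite-difference gradient of the energy in
  that mode.

* the energy of log laws is unbounded below as lengths vanish, and edges can
  dwell below `d_min` when their swap is suppressed (border vertices,
  rosettes). Lengths entering the log laws are therefore floored at `d_min`:
  below the rearrangement threshold the T1 machinery, not the tension law,
  is in charge, and the floor bounds the forces so the explicit Euler
  integration stays finite. A per-step displacement cap is available
  (`step_cap`) but off by default — the collapse of whole boundary cables,
  which the chain-level feedback is designed to produce, proceeds through
  exactly the large transient forces a cap would suppress, and capping them
  was found to abolish convergent extension.
* the min defining `L` ties on symmetric lattices; ties resolve to the
  lower cell index, deterministically.
* the post-swap edge is perpendicular to the removed edge through its
  midpoint, with the vertex retained by each side cell placed on that
  cell's side of the line.
* the pre-relaxation phase (uniform linear tension, as in the main
  simulations' setup) terminates when the maximum vertex speed falls below
  1e-6, with a configurable time cap.

The initial condition is a fresh hexagonal lattice (cell area `A0`) of 14
columns × 20 rows organised into parasegments of alternating width 4 and 3;
in each parasegment the first two columns are S1 and S2 and the remaining
1–2 columns carry the discontinuous S3/S4 region, interleaved between
successive DV rows so that neither stripe forms a continuous column. Only
the interleaving pattern — not the existence of the discontinuity — is a
generator choice (`default_stripe_plan()` exposes it), since the published
description fixes the combined S3+S4 width at 1.5 cells but not the exact
arrangement.

Runs export frames at a configurable stride as a `tracked_tissue` with
stable cell ids and per-cell-pair interface ids, so the whole analysis
pipeline — painting, polarity, T1 detection, Voronoi deviation — applies to
simulations exactly as to synthetic movies.

## What the synthetic data does and does not emulate

The painted movies place intensity `1` on homotypic interfaces, `2` on
heterotypic boundary interfaces and `8` on skipped boundaries (mirroring the
tension ratios), with optional multiplicative radial doming and
additive/multiplicative white noise on interface means. They emulate the
*castellated interface-mean* representation of the data after tracking —
not raw pixels: no point-spread function, no medial myosin pool, no
photobleaching, no segmentation error, and noise is white rather than
intensity-dependent (the noise statistics of the real reporter are not
characterised, so they are parameters, not defaults). Passing tests
therefore demonstrate that the *methods* recover known ground truth from
perfectly tracked meshes; they do not certify robustness to tracking error.

## Problem sizes

The test and acceptance workloads are desk-scale by design: simulated
tissues of 8 columns × 6 rows run to the full end time T = 500 (a few
minutes each) with frames exported every 25 simulation time units,
parameter-recovery batches of 60 synthetic cells, 6×6 tissues for geometry oracles, and the
full 24M-configuration receptor search vectorised to about a minute. The
full-size 14-column × 20-row configuration runs unchanged through the same
interface when more patience is available.

Stripe-order violations are counted between AP-neighbour cells (centroid
vector more AP than DV) over interfaces longer than 5% of the frame's
median interface length: contacts at the cell-rearrangement scale are
transient topology, not ordered adjacency. The discrimination between the
chain law with and without supercontractility is robust to this choice —
without it the supercontractile runs retain only sub-threshold sliver
contacts while the plain chain law retains full-length disordered ones.

## Known limitations

* The Gaussian polarity model projects onto the AP axis only (means fixed at
  0° and 180°); free-phase bipolarity off-axis is out of scope, as the
  orientation distributions motivating the projection are strongly AP-biased.
* Voronoi deviations are undefined for hull-adjacent cells; small tissues
  therefore score only their interior.
* T1 pairing uses quartet identity; rosettes (>4 cells) are recorded as
  unresolved, never as events.
* The simulator's free boundary means border cells are under-constrained;
  border-adjacent quantities (and anything at small tissue sizes) should be
  read with the interior in mind.
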