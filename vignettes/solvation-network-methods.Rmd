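---
title: "Methods: hydrogen-bond network analysis of solvated solutes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond network analysis of solvated solutes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvgraph)
```

## The model

`solvgraph` treats the hydrogen-bond structure between a solvated organic
solute and its water shell as a time series of graphs. In every trajectory
frame, atom-level interaction sites — the solute's hydroxyl and methoxy
oxygens, hydroxyl hydrogens, and each water's O, H1 and H2 — form the
vertex set, and a geometric criterion decides which intermolecular pairs
are connected by an edge. The analyses then ask three kinds of question of
this graph sequence:

* **structural** — how many hydrogen bonds does each site carry
  (degree census), and how far apart are two sites along the bonded
  network (geodesic distances)?
* **dynamic** — how long does a particular site–partner contact persist
  (residence times, correlation lifetimes)?
* **metric** — at what distances do the hydration shells sit, and where
  should the hydrogen-bond cutoff be drawn (distance distributions)?

The two supported criteria reflect the two traditions in the field. The
graph-formalism criterion measures the *nonbonded* oxygen–hydrogen
distance, `r(O···H) < 0.30 nm`, and deliberately leaves the bond angle
unspecified so that every orientation counts; this maximises sensitivity
to loosely oriented contacts and is the package default. The comparison
criterion used by the standard GROMACS analysis measures the
donor-oxygen–acceptor-oxygen distance, `r(DA) ≤ 0.35 nm`, with an H–D–A
angle of at most 30°. The strictness of the two comparisons (`<` versus
`≤`) follows the criteria as usually quoted; both are configurable in
`hb_rule()`. The canonical linear geometry — covalent O–H of 0.10 nm plus
an O···H hydrogen bond of 0.18 nm — gives a donor–acceptor distance of
0.28 nm and passes the second criterion at an angle of exactly zero, which
the acceptance suite verifies as a worked example.

Because the two hydrogens of a water are separate vertices, a water that
orients both hydrogens into the cutoff sphere of a site contributes two
edges. This raw "hydrogen-counting" degree is intentional: it carries
orientational information. Dividing the weighted mean degree by two
(`weighted_mean_degree(..., halve = TRUE)`) recovers a water-molecule-level
count comparable with donor–acceptor analyses. The same double-counting
has a dynamic counterpart: in hydrogen mode a bound water that swaps its
pointing hydrogen ends one persistence event and starts another, so the
estimated lifetime is doubled by convention; in molecule mode the partner
is the water's identity and no correction applies. Both conventions are
implemented and cross-checked against each other on synthetic data.

## Periodic boundaries

All distances and angle vectors use the minimum-image convention in a
cubic box, so graph edges cross the periodic boundary and each edge
records the integer image shift actually used. How the reference software
handled PBC-crossing edges internally is not documented; minimum image is
the standard choice and the one implemented here. Coordinates need not be
wrapped, but the convention is exact only when intermolecular separations
are below 1.5 box lengths, which holds for any wrapped or near-wrapped
trajectory. The box edge is taken from the gro file or the topology and is
assumed constant over the trajectory — box fluctuations from
constant-pressure simulations are ignored, a documented limitation.

## Estimators and numerical choices

**Degree census.** `N(i)` is tallied per frame and per site (not
aggregated over sites), so `sum_i N(i)` equals the frame count for every
site — an invariant asserted in the tests. The edge-distribution total
over all vertices equals twice the edge count.

**Geodesics.** The Floyd–Warshall algorithm runs on the full vertex set
with `Inf` as the unreachable sentinel (excluded from any averaging,
counted separately). A next-hop matrix reconstructs one canonical shortest
path per pair; ties are resolved toward the lowest-index intermediate
vertex considered first, which is arbitrary among equals and documented as
such. Per-pair persistence tracking uses breadth-first search from one
endpoint, which is exact on unweighted graphs and cheaper per frame; the
test suite proves Floyd–Warshall and BFS identical on random graphs.
Water–water edges are only computed when requested (they are needed for
geodesics through the solvent but would dominate the cost of the default
solute–water analyses).

**Residence times.** "Uninterrupted" means zero gap tolerance: one absent
frame ends an event. A configurable `gap_tolerance` exists because the
continuous/intermittent distinction is exactly the point of comparing
estimators. Events touching the trajectory ends are censored; they are
*included* in the mean by default (plain run averaging), with a flag to
drop them, since edge handling is a matter of convention and the bias
vanishes for trajectories much longer than the lifetime. The two
formulations of the estimator — the plain average of all durations, and
the average weighted by the occurrence probability `P(t_i)` — are
algebraically identical; the tests verify this on arbitrary inputs.

**Correlation functions.** `C_HB(t)` uses every frame as a time origin
(maximal statistics) and normalises by the zero-lag value, so
`C_HB(0) = 1` exactly. The default maximum lag is half the trajectory;
longer lags average too few origins to be useful. The computation runs
through FFTs (exact integer counts recovered by rounding), verified
against a direct double loop. The integral uses the trapezoidal rule over
the available lags and reports the truncation lag; on a densely sampled
exponential it recovers the time constant within 2%. The intermittent
definition is the default because that is how the correlation-function
method is conventionally described; continuous-persistence lifetimes are
always below the intermittent ones whenever partners rebind, and this
inequality is asserted on synthetic series.

**Distance distributions.** Distances run from the site oxygen to water
hydrogens, excluding the covalent O–H, so the first shell peaks near
0.18 nm rather than 0.28 nm. Default bin width is 0.005 nm with a
collection cutoff of 0.35 nm — wide enough to cover both shells; the
cutoff is recorded on the histogram because truncation makes the
second-shell peak look artificially sharp, an artefact worth reproducing
knowingly. Raw counts are emitted, with a probability column as the
normalised view, since the normalisation of published distributions is
often unstated. `suggest_cutoff()` detects peaks on a lightly smoothed
copy of the counts (5-bin centred moving average, configurable; peaks
below 5% of the maximum are ignored as noise) and returns the centre of
the lowest bin strictly between the first two peaks, resolving ties to
the middle of a flat valley; a unimodal histogram is reported as an
explicit error, never guessed around.

## What the synthetic generator emulates — and what it does not

The generator stands in for a solvated-solute trajectory at toy scale: a
rigid six-oxygen-site solute (two hydroxyl-like sites with hydrogens, four
methoxy-like acceptors on octahedral axes) at the centre of a cubic
periodic box, surrounded by rigid 3-site waters. Production systems of
this kind use thousands of waters in 5.2–5.6 nm boxes; the defaults here
(200 waters, 3.0 nm box, 500 frames at 0.5 ps) keep every test cheap
while preserving the statistics that matter. The 4-site water models used
in production simulations differ from 3-site ones only by a massless
charge site, which no distance criterion on O and H can see, so 3-site
geometry loses nothing for these analyses.

Site occupancy evolves as a Markov chain: a bound water unbinds with
per-frame probability `p` (true mean bound time `1/p` frames — 2.5 ps at
the defaults), an empty site rebinds with probability `r = 0.9`, and a
water that stays bound swaps its pointing hydrogen with probability `q`.
The default `q = p/(1 - p)` is the *balanced* rate: it makes a bound stay
consist of exactly two hydrogen episodes in expectation, which is the
regime in which the hydrogen-mode doubling convention is exact rather
than approximate — each hydrogen interacts half of the time. Other swap
rates are available and make the two conventions disagree by a computable
factor (`1/(p + q - pq)` frames per hydrogen episode), which the tests
also exercise.

Bound waters sit with the near hydrogen at `0.18 ± 0.005` nm (Gaussian,
truncated at two standard deviations so the geometry can never cross the
0.30 nm criterion), the binding axis jittered within a 10° cone; the far
hydrogen then lies geometrically near 0.314 nm, providing the second
distance mode. Free waters are uniform outside a 0.45 nm exclusion zone
around the site oxygens, so they never form spurious bonds; they are
re-placed independently every frame. The generator therefore emulates
*occupancy statistics and first-shell geometry*, not physics: there are
no forces, no water–water hydrogen-bond network (free waters do not
cluster), no realistic diffusion, and no second hydration shell beyond
the bound water's own far hydrogen. Passing tests consequently
demonstrate that the estimators recover known truth under the stated
stochastic model — not that any particular chemical system behaves this
way.

An option (`both_hydrogens = TRUE`) parks bound waters oxygen-first so
both hydrogens fall inside the cutoff, exercising the degree-two counting
convention deterministically.

## Problem sizes

The test suite validates estimator consistency on small systems (10–50
waters, tens to a few thousand frames) and statistical recovery on one
long trajectory of 15 waters × 11,000 frames (≈ 10⁴ persistence events,
enough to pin the mean lifetime to a few per cent). The acceptance script
uses 25 waters × 8,000 frames for the residence-time quantities and a
500-frame subset for distance distributions; the end-to-end pipeline
check runs 200 waters × 500 frames. These sizes were chosen so each
statistical assertion has comfortable margin over its sampling error
while the whole suite stays quick to run.

## Known limitations

* Cubic boxes only; triclinic cells are out of scope.
* The box edge is constant across a trajectory (no per-frame box line in
  xyz input).
* Atom-to-molecule assignment is positional — templates are consumed in
  declared layout order — matching fixed-composition simulation boxes;
  no distance-based inference is attempted.
* The `.graph`/`.geopath` column layouts are documented in the writers
  but not claimed byte-compatible with any other software's files.
* Binary trajectory formats are not read; users convert to xyz upstream.
* No energetic or orbital hydrogen-bond definitions, and no
  reactive-flux lifetime estimators (velocities are never read).
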