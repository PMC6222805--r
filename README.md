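# solvgraph

Hydrogen-bond network graph analysis of molecular-dynamics trajectories.

`solvgraph` post-processes MD trajectories of a small organic solute (for
example a diol bearing hydroxyl and methoxy oxygen sites) solvated by 3-site
waters in a cubic periodic box. It converts every frame into an
intermolecular interaction graph under a geometric hydrogen-bond criterion
and analyses the resulting graph time series. It is aimed at computational
chemists who want site-resolved hydration statistics that go beyond plain
donor–acceptor hydrogen-bond counting: which site binds water, for how
long, through how many intervening waters, and at what distance.

## What it computes

**Graphs.** Each frame becomes a graph whose vertices are atom-level
interaction sites (solute oxygens and their hydroxyl hydrogens, water
O/H1/H2) and whose edges are hydrogen-bond contacts. Two criteria are
built in:

* the graph-formalism criterion *r*(O···H) < 0.30 nm with the bond angle
  unspecified (every orientation accepted), measured between an oxygen
  site and an intermolecular hydrogen;
* the donor–acceptor comparison criterion *r*(DA) ≤ 0.35 nm with
  ∠(H–D–A) ≤ 30°, the definition used by the standard GROMACS
  hydrogen-bond analysis.

Both honour periodic boundaries via the minimum-image convention, so edges
cross the box. Because the two water hydrogens are separate vertices, a
water oriented with both hydrogens inside the cutoff contributes **two**
edges to a site.

**Degree census.** For each site, *N*(*i*) counts the frames in which the
site has exactly *i* edges. The weighted mean degree is
Σᵢ *i·N*(*i*) / Σᵢ *N*(*i*); dividing by two converts the raw
hydrogen-counting degree into a water-molecule-level degree comparable to
donor–acceptor counts.

**Geodesics.** The adjacency matrix of a frame is converted to a geodesic
distance matrix with the Floyd–Warshall algorithm; entries are shortest
hydrogen-bond path lengths in edges, with path reconstruction and
`.graph`/`.geopath` output files.

**Lifetimes.** The continuous persistence *tᵢ* of every site–partner
contact is traced along the trajectory (a single absent frame ends an
event). The residence time is the average persistence weighted by the
occurrence probability *P*(*tᵢ*). Two counting conventions are provided:
*hydrogen* mode (partners are individual water hydrogens; the mean is
doubled, because a bound water alternates which hydrogen points at the
site, so each hydrogen-labelled event covers about half the stay) and
*molecule* mode (partners are water molecule identities; no correction).
The intermittent correlation function *C*\_HB(*t*) — the probability that
a pair bonded at *t₀* is bonded again at *t₀* + *t*, rebinding included —
is also computed, and its time integral gives the correlation lifetime.

**Distance distributions.** Site-resolved histograms of O(site)···H(water)
minimum-image distances show the first hydration shell near 0.18 nm and a
second mode near 0.31 nm; `suggest_cutoff()` returns the interior minimum
between the first two peaks (≈ 0.25 nm), the natural hydrogen-bond
distance cutoff that excludes second-shell waters.

**Synthetic ground truth.** `generate_trajectory()` builds a toy solvated
system whose site occupancy evolves as a Markov chain with known
parameters, so true mean lifetimes, degrees and shell positions are known
by construction and every analysis stage is testable without MD output.

## Worked example

```r
library(solvgraph)

params <- synthetic_params(n_waters = 50, n_frames = 1000, seed = 42)
traj   <- generate_trajectory(params)            # truth: 1/p = 5 frames = 2.5 ps
graphs <- build_frame_graphs(traj$frames, traj$topology)

census <- degree_census(graphs, c("O9", "O9p", "O3", "O4"))
round(weighted_mean_degree(census), 3)
#>    O9   O9p    O3    O4
#> 0.809 0.805 0.814 0.814
round(weighted_mean_degree(census, halve = TRUE), 3)
#>    O9   O9p    O3    O4
#> 0.404 0.402 0.407 0.407

ev <- trace_persistence(graphs, "O9", partner_mode = "molecule")
residence_time(ev, frame_interval = 0.5)
#>      site mean_lifetime_ps n_events correction
#> 1 LIG1:O9          2.33815      173          1

evh <- trace_persistence(graphs, "O9", partner_mode = "hydrogen")
residence_time(evh, frame_interval = 0.5)
#>      site mean_lifetime_ps n_events correction
#> 1 LIG1:O9         2.568254      315        2

hist <- distance_distribution(traj$frames, traj$topology, site = "ALL")
suggest_cutoff(hist)
#> suggested cutoff: 0.2425 nm (peaks at 0.1775 / 0.3125 nm)
```

The mean degrees sit at the generator's stationary occupancy (0.818); the
molecule-mode residence time and the doubled hydrogen-mode residence time
both recover the construction-time mean bound time of 2.5 ps; and the
distance distribution separates the two hydration shells at ≈ 0.24 nm.

For file-based workflows, `run_pipeline()` (or the thin CLI wrapper in
`inst/cli/solvgraph.R`) reads a topology/.xyz/.gro triple — or generates a
synthetic system — runs the requested stages, and writes CSV outputs plus
a deterministic `manifest.json`.

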