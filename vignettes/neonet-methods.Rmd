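---
title: "neonet: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neonet: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`neonet` analyses resting-state functional connectomes of the newborn brain
as binary graphs. The unit of analysis is a subject: a matrix of ROI
time series (frames x regions) recorded at rest, from which a Pearson
connectivity matrix `M` is built after temporal cleaning. Thresholding `M`
yields an undirected, unweighted graph per threshold, and the package then
quantifies:

* **segregation and integration** — clustering coefficient `C` and
  characteristic path length `L`, both over the largest connected component;
* **small-worldness** — `gamma = C / C_null`, `lambda = L / L_null` against
  degree-preserving rewired null ensembles, and the small-world index
  `sigma = gamma / lambda` (`sigma > 1` indicates small-world topology);
* **economy** — global and local efficiency (`Eglob`, `Eloc`) and cost
  efficiency `Eglob - cost`, with cost the fraction of possible edges;
* **degree-distribution shape** — least-squares fits of the log cumulative
  (survival) degree distribution under a power law, an exponential, and an
  exponentially truncated power law, selected by AIC;
* **hubs and modules** — degree and betweenness hubs (centrality at least
  mean + 1 SD) and Louvain community structure with modularity `Q`;
* **resilience** — largest-component and efficiency curves under random
  failure and targeted attack, and per-node efficiency loss under isolated
  removal.

# Preprocessing model

Cleaning operates on ROI-level series and supplied confounds only (no image
processing). Framewise displacement is the Power convention:
`FD[t] = sum |delta translations| + r * sum |delta rotations|` with head
radius `r = 50` mm by default (configurable; the value is the field standard
attached to the 0.3 mm censoring threshold). A frame is censored iff
`FD > 0.3` mm (strict) or its outlier-voxel fraction exceeds 10% (strict);
the union is counted once.

Censoring, nuisance regression, and band-pass filtering are performed
*simultaneously* as one least-squares projection restricted to retained
frames: the design matrix holds an intercept, the confound columns, and
sine/cosine regressors at every DFT frequency of the original frame grid
outside the 0.01–0.1 Hz pass band (band-stop by regression). This follows
the regression-based filtering approach used by AFNI-style pipelines and
avoids smearing signal across censored gaps, at the price of the pass band
being defined on the uncensored frequency grid. Residuals are orthogonal to
all regressors to machine precision, which the tests assert directly.
Subject matrices are averaged element-wise into the group matrix (no Fisher
transform, matching the original analysis).

# Thresholding

Three schemes produce graphs from `M`:

* `threshold_by_r(M, r)` — edge iff weight `> r` (strict). The grid is 0 to
  0.45 in steps of 0.025 (19 values). Strictness at the boundary is a
  convention; the grid calibration is insensitive to it, but one rule must
  be fixed, and it is documented and tested.
* `threshold_by_cost(M, cost)` — keeps the `round(cost * N(N-1)/2)`
  strongest weights. Ranking uses signed weights; ties at the cutoff break
  by node-pair lexicographic order so results are platform-independent. The
  grid is 0.02 to 0.58 in steps of 0.04 (15 values).
* `threshold_by_degree(M, k)` — cost thresholding at `k/(N-1)`; the K grid
  is 13 integers evenly spanning 9–39 (the count is fixed by the design;
  the spacing was unspecified, so an even span is used and configurable).

Negative correlations never become edges under `r >= 0`, and rank below all
positive weights under cost thresholding ("strongest correlations").

# Null and comparison graphs

* **Rewired random** — Maslov–Sneppen double-edge swaps, 10 attempted swaps
  per edge by default (standard mixing heuristic; the design is silent).
  Degrees are preserved exactly and asserted on every member. 100 nulls per
  subject and threshold is the full design; tests scale this to 20.
* **Latticized** — the same swap walk, accepting only swaps that do not
  increase total ring distance. This is the stochastic "lattice network"
  benchmark: a deterministic ring lattice cannot supply the 20 distinct
  lattice comparisons per graph the original design calls for, so the
  degree-preserving latticization is used alongside it.
* **Ring lattice** — deterministic nearest-neighbour ring fill with exactly
  `E` edges.
* **Scale-free** — Barabási–Albert growth from `m` seed nodes; `m` is the
  value whose realized edge count `(N - m) m` is nearest the target density
  (density 0.10 at `N = 90` gives `m = 5`, 425 edges). The original
  comparison network's generator is unstated; this is a documented
  interpretation.

# Metrics conventions

* `C` and `L` are computed on the largest connected component; `Eglob` is
  computed over the full node set with disconnected pairs contributing 0.
  This mirrors the stated component rule, which is explicit for `C` and `L`
  only.
* Betweenness is Brandes' algorithm, unnormalized, endpoints excluded, each
  unordered pair credited once. Hub detection uses a mean + SD rule, so the
  normalization cancels.
* An edgeless graph's largest component is a singleton at the lowest node
  index (`fraction = 1/N`); `L` of a singleton component is missing.
* `gamma`/`lambda` use the mean of the null ensemble per subject and
  threshold, not a single null.

# Degree-distribution fitting

Fitting follows the classic presentation: least squares on the **log
cumulative distribution**, not discrete MLE. All three survival forms are
linear in their parameters (power `log P = a - alpha log k`; exponential
`log P = a - rate k`; truncated `log P = a + (alpha - 1) log k - k/kc`), so
fits are exact linear solves with no convergence concerns, and the truncated
family nests both rivals. `AIC = n log(RSS/n) + 2 p` with `p` counting the
intercept (2, 2, 3); minimum AIC wins, exact ties to fewer parameters.

Two numerical choices deserve note. The truncated law is implemented with a
*decaying* cutoff `exp(-k/kc)`; the printed form with a growing exponential
is read as a typo for the standard truncated law. When the unconstrained
truncated fit returns a non-decaying cutoff (`kc <= 0`), it is refit at the
boundary `kc = Inf` (pure power law), keeping the `kc > 0` invariant.

The log-survival least-squares estimator is *biased* for the truncated
exponent: the survival function of a truncated-power pmf follows the same
functional form only asymptotically. On sequences of length 10,000 the
recovered exponent sits within about 0.45 of the truth, which is what the
parameter-recovery test asserts. At cohort-realistic n = 90 the truncated
family is confirmed in only 72–82% of draws from itself (varying with the
seed block) — both rivals are nested 2-parameter specializations, so the
AIC penalty of the third parameter frequently prefers them. The 80%
recovery criterion therefore sits right at this identifiability boundary;
the generating parameters (exponent 1.8, cutoff 10) are the
literature-canonical values for connectome degree distributions and were
not chosen to clear it.

# Hubs and communities

Hubs are nodes with centrality `>= mean + 1 * SD` (population SD). The rule
is stated in the source design as "mean ± 1 SD"; only the upper tail is
consistent with hubs being exceptional, so the upper reading is implemented.
Louvain maximizes Newman–Girvan modularity with the two-phase local-move /
aggregate scheme, restarted with random node orders (default 100 restarts;
the historical design iterated 10,000 times — the contract is identical and
the budget configurable), followed by a single-node fine-tuning pass on the
original graph until no gain remains. Local moves break ties by highest gain
then lowest community id, so partitions are deterministic under a fixed
seed. The returned `Q` always equals `modularity_q` recomputed on the
partition, exactly.

# Resilience

Targeted attacks remove nodes in descending centrality of the *intact*
graph (static ranking; adaptive re-ranking is available behind a flag —
the source wording "starting from the node with the highest degree" is read
as static). Ties break by node index. Curves report the largest-component
fraction both relative to the original N (primary) and to the remaining
nodes, plus `Eglob` absolute and as a percentage of the intact value (step
0 is exactly 100). Random failure averages independent random orders. The
isolated-removal table reports per-node `100 * (Eglob(G - i) - Eglob(G)) /
Eglob(G)`, sorted most-harmful-first, and the degree-vs-betweenness
comparison is a Welch t-test, with centrality ties straddling the top-20%
selection boundary collapsed into one averaged entry (mirroring the
tie-handling of the original analysis, where the 18th degree hub was tied
among 9 regions).

# The synthetic world

The generator emulates the study design: 60 subjects, 90 ROIs, 196 retained
frames at TR = 2 s (200 collected minus 4 stabilization volumes), four
modules of 26/26/18/20 ROIs. ROI `i` in module `m` follows

```
x_i(t) = sqrt(w - b) * s_m(t) + sqrt(b) * g(t) + noise_sd * e_i(t)
```

with unit-variance module latents `s_m`, a global latent `g`, and
independent noise. With the default `noise_sd = sqrt(1 - w)` the expected
Pearson correlation is exactly `w` within modules and `b` between modules.
Defaults `w = 0.5`, `b = 0.1` were chosen once as realistic magnitudes for
module-resolved BOLD correlations (no effect-size targets are stated in the
source design, which calibrates only to qualitative structure). A fraction
(10%) of ROIs are planted as hubs with an extra `sqrt(0.15/(M-1))` loading
on every other module's latent (noise rescaled toward unit variance); their
cross-module correlations (~0.24) sit between the background (0.1) and
within-module (0.5) levels, which makes them the inter-module bridges of
moderately thresholded graphs. By default all signals are synthesized
inside 0.01–0.1 Hz, making the band-pass stage a near-no-op on clean data
and letting the filter be tested for pass-band transparency.

Motion is zero at baseline with isolated translation spikes
(`P(spike) = 0.11` per frame, 0.5 mm), and an outlier-fraction series with
occasional excursions above 10%; jointly these reproduce the reported
censoring bookkeeping (~173 of 196 frames retained on average).

**What the synthetic world does not emulate.** Correlations within a module
are exchangeable — there is no spatial gradient, no distance-dependent
decay, no hemodynamic model, and no negative-correlation structure. Two
consequences matter for interpreting green and red tests:

* At sparse cost thresholds the ~993 within-module pairs (all near `w`)
  crowd out every cross-module edge, so 10%-density graphs fragment into
  near-cliques. Hub-recovery validation therefore thresholds at `r = 0.2`,
  between the background and hub cross-module correlation levels, where the
  planted hubs are structurally the only bridges.
* The group-average graph is an *extremum* among degree-matched graphs —
  near-maximal clustering, minimal integration — rather than intermediate.
  The economy criterion (group `Eglob`/`Eloc` strictly between matched
  lattice and rewired-random benchmarks across the cost grid) accordingly
  fails in this world and is left red. Part of that failure is
  data-independent: for cost above ~0.34 every matched graph has diameter
  2, which forces `Eglob = (1 + cost)/2` identically for group, lattice,
  and random alike, so no strict ordering can exist there for any data. The
  orderings are verified to hold for genuine Watts–Strogatz graphs at the
  operating point (E = 881) in a separate property test, isolating the
  failure to the block construction rather than the metric code.

Similarly, the scale-free-vs-small-world fragmentation comparison (largest
component after removing the top 18 of 90 nodes) holds in ~80–84% of seeds
rather than the required 90%: a density-matched Barabási–Albert graph with
`m = 5` simply remains fully connected after 18 hub removals in the
remaining seeds, tying rather than undercutting the small-world benchmark. The
original comparison network fragmented to 13% — consistent with a far more
fragile scale-free construction than density-matched BA, whose generator
was not specified.

# What a green run establishes

Green tests establish: exact agreement of every graph metric with
brute-force enumeration oracles on random graphs; exact combinatorial
anchors (4005 possible edges, 881 edges at cost 0.22, 19-value grid, cost
efficiency 0.3437 at the printed operating point); small-world structure of
the synthetic cohort (paired-t significance of `C` against rewired nulls at
all 19 thresholds after Bonferroni correction, `sigma > 1` with 99%
confidence wherever graphs stay >= 90% connected); planted-module recovery
by Louvain at >= 95% label agreement; and the resilience conventions
(exact star/complete-graph values, overlap of random-failure bands).

They do not establish that real neonatal data would reproduce the published
subject-level values (SWI range, Q = 0.6447, per-ROI efficiency losses) —
those depend on unreleased scans and are out of scope by design.
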