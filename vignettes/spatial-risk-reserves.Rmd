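---
title: "Reserve selection under spreading disturbance: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reserve selection under spreading disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firereserve)
```

## The model and its assumptions

`firereserve` solves a probabilistic maximal-covering reserve selection
problem: choose at most $m$ parcels so as to maximize the expected number of
species surviving one stochastic habitat disturbance. The stochastic
primitive is a *burn model* — a finite probability distribution over burn
patterns $b$ (sets of destroyed focal parcels) with probabilities $p_b$.
For a reserve $x$ the objective is

$$\max_x \sum_{b \in B^k} p_b \sum_{i \in I} y_{ib},
\qquad \sum_j x_j \le m,$$

where $y_{ib} = 1$ exactly when some selected, unburned parcel contains
species $i$ after pattern $b$. The behavioural assumptions are deliberately
stark, and inherited from the covering literature: presence/absence is known
with certainty; species outside the reserve do not survive; a burned parcel
loses all its species; an unburned reserve parcel keeps all of its. One
disturbance event is modelled, with no dynamics, species movement, or
partial damage — all are out of scope.

Two burn models are compared *at equal total risk*:

* **Spatially correlated.** One ignition, uniform over the ignition domain,
  spreads to every contiguous neighbour of the ignited parcel (first-order
  queen contiguity on square grids; the six adjacent cells on hexagons). On
  small landscapes the model is enumerated exactly — one pattern per
  ignition point, duplicates kept as distinct equiprobable events because
  probability mass belongs to ignitions, not to point sets. On the 5×5 grid
  with a one-parcel buffer this yields 49 patterns with burn sizes
  {1,2,3,4,6,9} and expected burned area 225/49 ≈ 4.6.
* **Spatially independent (risk-equalized null).** The burn *size* is drawn
  from the correlated model's size distribution, and conditional on size
  $n$ the burned set is a uniform $n$-subset of the $J$ focal parcels.
  Matching the size distribution makes the expected burned area equal by
  construction, so any difference between optimal reserves is attributable
  to the spatial pattern of risk alone.

### The closed-form independent model

Materializing the independent model is infeasible (already 2,235,350
patterns for $J = 25$), so it is represented implicitly. All reserve
queries reduce to hypergeometric identities: a fixed set of $r$ parcels
burns entirely with probability
$\sum_n q_n \binom{J-r}{n-r} / \binom{J}{n}$,
and the full outcome distribution over the number of surviving species is
assembled by enumerating the $2^{|x|}$ joint burn events of the reserve
parcels, whose probabilities depend only on how many reserve parcels burn.
This is exact, not approximate; the test suite certifies it against brute
force enumeration of every $n$-subset on all landscapes with $J \le 9$ at
$10^{-12}$. The $2^{|x|}$ enumeration limits full outcome distributions to
reserves of ≤ 20 parcels; expectations and per-species survival remain
available at any size (the annealer relies only on those).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `buffer_width` | 1 parcel | ring around the focal grid from which fires spread in but which cannot be selected |
| `m` | 2 (stylized) / 30 (hex) | maximum reserve size; by survival monotonicity only size-`m` reserves are searched |
| `n_sims` | 500 fires | Monte-Carlo burn sample on landscapes too large to enumerate |
| `initial_temperature` | 10 | annealing start temperature |
| `cooling_rate` | 0.995 per iteration | geometric cooling |
| `max_iterations` | 2000 | swap proposals; 10·0.995^2000 ≈ 4.4e-4 gives an effectively greedy endgame |
| `temperature_floor` | 1e-6 | early-stop threshold on temperature |

The annealer's stated schedule (T₀ = 10, cooling 0.995) is kept as the
default. Note that the floor of 1e-6 caps a run at ≈ 3200 iterations; runs
that should hill-climb longer (large hexagonal instances) profit from a
lower floor and more iterations, which is what the acceptance suite uses
(8000 iterations, floor 1e-30). The iteration count is not stated in the
source procedure (only a wall-clock figure); 2000 is our choice and is
sufficient for every stylized instance tested (20/20 seeded runs reach the
enumerative optimum).

Step 5 of the procedure re-simulates fires for each candidate reserve. The
default here instead fixes one burn model for the whole search (common
random numbers): the objective is then deterministic, runs are bit-for-bit
reproducible, and comparisons between candidates are not corrupted by
sampling noise. `resample_each_step = TRUE` restores the literal
re-simulation behaviour.

## The synthetic data generator

Two generators produce the experimental inputs.

**Stylized Monte-Carlo distributions.** Two species, each on 5 uniformly
random parcels of the 25, independently — so the number of "hotspots"
(parcels holding both) is hypergeometric with mean 1. One hundred such
distributions, solved exactly under both risk scenarios, reproduce the
published grouping by hotspot category. No degenerate draws are excluded,
since the source describes no exclusion.

**Oregon-like hexagonal matrices.** The real application uses 289 hexagons
× 424 terrestrial vertebrate species, with per-parcel richness min 165,
mean 204.11, max 264 and five rarest species on essentially single parcels.
That dataset is not shipped; the generator emulates its *published summary
statistics*, which is all a green test can establish. Design of the
generator, and why:

* **Range sizes** are beta-distributed with concentration 0.8 — a U-shaped
  occupancy distribution (many narrow endemics, many near-ubiquitous
  species), the shape real presence/absence atlases show. The mean is
  pinned by total occupancy (204.11 × 289 presences). Early versions with a
  bell-shaped size distribution made every species redundantly covered by
  any 30-parcel reserve, so fire risk was irrelevant to reserve choice —
  an unrealistic world in which the two risk scenarios are
  indistinguishable. Narrow species are what make risk bite.
* **Spatial structure.** Ranges grow as contiguous patches (seed parcel +
  frontier accretion) on the hexagon lattice; `mode = "bernoulli"` offers
  spatially unstructured ranges as a contrast. A smooth latent
  habitat-quality field (white noise averaged over neighbourhoods) gives
  each parcel a target richness on a gradient; patches are seeded and grown
  toward the remaining deficit. Without the field, realized richness was
  nearly uniform (≈179–210), far from the published 165–264 spread.
* **Hard bounds by repair + rejection.** After growth, parcels outside
  [165, 264] are repaired by contiguity-preserving moves (a deficient
  parcel joins the range of a species already on a neighbour; an overfull
  parcel leaves a range where it is a removable boundary cell), and the
  whole matrix is redrawn if bounds still fail. Bounds therefore hold
  exactly; the mean is a soft target and lands within ±1–5 of 204.11. Five
  designated rare species occupy exactly one parcel; common species are
  floored at two parcels so the rare contract is exact.

What the generator does *not* emulate: real range shapes, taxonomic
structure, environmental covariates, and the actual Oregon geometry (an
axial-coordinate rhombus of hexagons stands in; real tessellations can be
supplied as explicit adjacency lists). Conclusions from synthetic runs are
statements about the pipeline and the qualitative risk mechanism, not about
Oregon.

## Numerical choices

* Probabilities are handled as doubles; enumerated models check
  $\sum p_b = 1$ at $10^{-12}$. Exact rationals (e.g. 6/49) survive because
  the denominators are tiny powers of the pattern count.
* Ties in the exact solver are genuine: *all* maximizers within $10^{-9}$
  are returned, sorted lexicographically; downstream code uses the
  lexicographically first for determinism.
* The Metropolis rule accepts ties ($\Delta = 0$), encouraging plateau
  traversal on coverage objectives, which are piecewise constant.
* Reserve "shared borders" count rook-adjacent pairs on square grids (a
  border is an edge, distinct from queen spread contiguity) and
  edge-adjacent pairs on hexagons. "Adjacent" in the no-hotspot table
  means edge-adjacent: that convention reproduces the printed 6/49
  both-burn probability, whereas diagonal adjacency would give 4/49.
  "Separated by more than one" means Chebyshev distance ≥ 3, the smallest
  separation no single spreading fire can bridge — reproducing the printed
  0/49.
* Parcel numbering of the stylized grid is row-major, top-left to
  bottom-right. The source figure does not print its numbering; row-major
  is the only convention under which the published three-hotspot table
  (sites 7, 8, 20) is consistent with queen spread, and the tests pin it.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; child seeds are drawn below $2^{31}$.

## Monte-Carlo overfitting, and the dispersion experiment

A fixed sample of simulated fires is an objective an optimizer can *game*:
with 500 fires over 289 parcels, sampled ignition counts vary (Poisson,
cv ≈ 30%), and a fixed-sample annealer parks the reserve in regions the
sample happens to under-burn. The artifact inflates clustering precisely in
the correlated scenario (spatially independent samples have no exploitable
geography), reversing the dispersion signal the comparison is meant to
detect. The acceptance experiment therefore uses the *exact* burn models on
the hexagonal landscape — all 289 equiprobable ignitions, and the
closed-form risk-equalized null — which are cheaper than sampling and have
no noise to overfit; the annealing runs for the two scenarios are paired on
common random seeds. Under that design, correlated-risk reserves have no
more shared borders than their independent-risk counterparts on 19 of 20
seeds. Sampled models remain the right tool when enumeration is infeasible
(heterogeneous ignition rates, larger spread kernels) and are what the CLI
pipeline exercises; their risk-equalization (identical size multisets,
exactly equal expected burned area) is tested separately.

## Known limitations

* One disturbance event; no temporal dynamics, regeneration or repeated
  fires.
* Homogeneous ignition probabilities and one-step spread only.
* The annealer is a heuristic: on large instances it returns a good
  reserve, not a certified optimum, and its dispersion statistics are
  seed-dependent.
* The closed-form independent model's full outcome distribution is limited
  to reserves of ≤ 20 parcels.
* Synthetic Oregon-like matrices match published summary statistics only;
  results on them do not transfer quantitatively to the real dataset.
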