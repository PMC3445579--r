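---
title: "Methods: gape geometry, body-size scaling and morphological parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gape geometry, body-size scaling and morphological parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metriomorph)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic-data generators do and do
not emulate, and the numerical and design choices made where the published
analyses left the procedure open.

## Optimum gape

The optimum gape is a geometric proxy for biomechanically optimal prey
depth in long-jawed marine predators: the gape angle at which multiple
dentary teeth contact a prey item simultaneously. It is *not* the maximum
gape — no soft-tissue or jaw-muscle modelling is attempted here.

The construction works on 2-D landmarks in lateral view (anterior +x,
dorsal +y, coordinates in cm):

1. fit a straight line across the dentary tooth apices;
2. take the parallel line through the jaw joint (glenoid);
3. the optimum gape angle is the angle subtended at the posterior-most
   dentary tooth tip between the two lines: with `h` the perpendicular
   distance between the lines and `d` the along-line distance from the
   glenoid's projection to the posterior-most tooth tip's projection,
   `angle = atan(h / d)`.

`h` is the optimum prey depth. We report it absolutely, as a fraction of
mandible length (`h/L`), and rescaled to a reference mandible length
(default 60 cm) so that species of very different absolute size can be
compared shape-for-shape. The perpendicular-offset reading of "prey depth"
is the only length the two-parallel-lines construction defines, and it
reproduces the internal arithmetic of the published comparative table
(depth = fraction × mandible length) exactly.

Choices worth knowing:

- **Tooth line fit.** Total least squares (perpendicular residuals) over
  all tooth apices, because it is symmetric in x/y and rotation-invariant;
  a `"chord"` option uses only the first and last apex. With two points the
  two coincide.
- **Mandible length.** A measured length always takes precedence over the
  landmark-derived chord (published tables use measured lengths); the chord
  between the anterior dentary tip and posterior retroarticular landmarks
  is the fallback.
- **Rounding.** Only at the reporting boundary, and half-up (so 13.125 cm
  prints as 13.13, matching published precision; R's default half-to-even
  would print 13.12). Angles round to the nearest degree and fractions to
  the nearest 1%, the precision of the published table. All upstream
  arithmetic is full precision.
- **Degenerate input.** Coincident tooth apices raise a geometry error; a
  glenoid anterior to the posterior-most tooth along the tooth line
  (`d <= 0`) likewise — the construction is meaningless there.

The mandible generator (`sim_mandible()`) places the glenoid at the origin
and the tooth row on a line at offset `h = L (d/L) tan(angle)`, so the
noiseless pipeline is the identity on (angle, fraction) to machine
precision; Gaussian landmark noise is parameterized as a fraction of
mandible length so tests are scale-free. Its defaults emulate the
largest-gape taxon in the published table (L = 132.2 cm, 24°, 13 dentary
teeth). It does not emulate digitization bias, curved tooth rows, or
missing landmarks — a green recovery test establishes correctness of the
geometry, not robustness to malformed landmark data.

## Body-size estimation

For large geosaurines known only from mandibles, body length is estimated
in two steps. First, basicranial length = mandible length × (76.8 / 80.9),
the basicranial:mandibular ratio of the most completely preserved reference
skull; the published assumption, logged verbatim in the function
documentation, is that the target taxon's basicranium and mandible scale in
the same proportions as the reference. Second, total body length from
basicranial length. The originally cited regression equations are not
reprinted anywhere we can reach, but the three published
(basicranial, total length) pairs — (83.1 cm, 4.49 m), (100 cm, 5.42 m),
(125.5 cm, 6.83 m) — are collinear to well under 1 cm, so the package
calibrates an ordinary least-squares line on those anchors. This
reproduces every published estimate at printed precision and cross-predicts
any held-out anchor to within 0.02 m (the residual limit set by the printed
rounding of the inputs). Whether the original equations were linear is
unverifiable from the printed values alone; the linear reconstruction is an
explicit, documented assumption. No confidence intervals are produced —
no variance information is printed to calibrate them against.

## Ziphodont dentition

Denticle size separates two grades used in generic diagnoses:
macroziphodont (all three denticle dimensions strictly exceed 300 µm) and
microziphodont (no dimension exceeds 300 µm). The boundary value is
microziphodont — "do not exceed" is inclusive. A mixed pattern returns
`indeterminate` rather than a guess; no such case is described in the
diagnoses, and classification monotonicity (growing a denticle can never
move a tooth towards microziphodonty) is property-tested. One printed
occurrence of the threshold contains a typographic space ("30 0µm"); it is
read as 300 µm, consistent with every other occurrence. Densities are
reported as whole denticles/mm, the printed precision.

## Morphological maximum parsimony

**Scoring.** Unordered characters cost 1 per change between distinct
states (Fitch); ordered characters (transformational sequences) cost
`|i − j|` on the integer state scale, with no step matrices beyond that.
Missing data — both `?` and `-`, which the matrix dialect does not
distinguish — contribute the full state set, and polymorphic codings are
parsed but treated as missing with a warning (the published matrix's
polymorphism policy is not described, so nothing stronger is assumed).
The implementation runs a bit-parallel Fitch pass on binary trees and a
generalized Sankoff dynamic programme otherwise (the Sankoff pass is exact
on multifurcating trees, which is also how such trees are scored directly).
Both routes are cross-checked against each other and against an independent
implementation (phangorn) in the tests.

**Search.** Seeded stepwise random addition followed by SPR hill-climbing,
then closure of the pool of equally shortest trees under equal-length SPR
moves, deduplicated by unrooted topology and capped (default 1000, with an
explicit truncation warning reporting the count as a lower bound). The
heavyweight metaheuristics used by dedicated programs (sectorial search,
ratchet, drift, tree fusion) are deliberately out of scope: the desk-scale
contribution here is verifiable correctness, guaranteed by an exhaustive
enumeration oracle on matrices of up to 8 taxa, not raw search power.
Consequently the package does not attempt to reproduce published MPT
*counts* (22 and 195 in the two empirical analyses) or bootstrap
percentages, which are search-engine and effort dependent. Package
defaults (10 random additions; 100 bootstrap replicates) are desk-scale
stand-ins for the published effort (1000 replicates under TNT with TBR).

**Consensus and support.** Strict consensus keeps exactly the bipartitions
present in every tree; majority-rule keeps those in strictly more than 50%
(a split at exactly half is excluded — documented and tested), annotated
with frequencies. Bipartitions are canonicalized by the side away from a
fixed reference taxon, so all comparisons are unrooted; Robinson–Foulds
distance is the symmetric difference of these split sets. The bootstrap
resamples characters with replacement, reruns a reduced search per
pseudoreplicate (one fifth of the additions), and scores each clade by the
fraction of replicate majority consensuses containing it; per-replicate
seeds derive from the run seed by a fixed splitting rule, so runs are
reproducible replicate-by-replicate.

**Ensemble indices.** With `L` the tree length, `m` the per-character
minimum steps (observed states − 1 unordered; observed range ordered) and
`g` the per-character maximum steps (steps on the completely unresolved
bush): `CI = Σm/L`, `RI = (Σg − L)/(Σg − Σm)`, `RC = CI × RI`. All
characters are included by default, matching common reporting practice;
`include_uninformative = FALSE` restricts the sums (and the length) to
parsimony-informative characters, since the published convention is not
stated. The identity `RC = CI × RI` reproduces both published index
triples (0.506 × 0.860 → 0.435; 0.481 × 0.863 → 0.415) at 3-decimal
rounding.

## The character-matrix generator and what a green test means

`sim_character_matrix()` evolves each character along a known (random or
supplied) unrooted binary tree with equal branch lengths: Poisson(`rate`)
change events per branch; unordered characters jump to a uniformly random
other state, ordered characters take ±1 steps *reflected* at the ends of
the state scale (0→1, k−1→k−2). Reflection, rather than clipping in
place, keeps every Poisson event a real state change, which makes the
generator's expected-change-count calibration exact and testable. Missing
cells are masked uniformly at random. No evolutionary realism is claimed —
the published analysis is parsimony, not model-based — the generator's only
job is to produce matrices with a known generating tree and controllable
homoplasy.

Two parameter worlds are used:

- **Default** (150 characters, rate 0.1/branch on 12 taxa): produces
  ensemble CI around 0.5–0.6, the homoplasy level of the real 73 × 240
  matrix (published CI 0.506), with the real matrix's ordered fraction
  (40/240).
- **Recovery experiments** (300 characters, rate 0.03/branch): a genuinely
  low-homoplasy world (CI ≈ 0.8). At 150 characters the search finds the
  generating tree essentially always, but equal-length ties frequently
  leave one or two consensus nodes unresolved — a property of the sampling
  world, not of the search — so the strict-consensus recovery experiment
  states its world as 300 characters, where resolution is near-certain.

A green recovery test therefore establishes that scoring, search and
consensus are jointly correct under clean signal; it says nothing about
performance on matrices with correlated characters, non-uniform missing
data, or the 73-taxon scale of the empirical analysis.

## Reproducibility

Every stochastic operation takes one integer seed through
`pipeline_config()`; per-replicate seeds are derived by a fixed splitting
rule (kept below 2³¹), so the same configuration yields byte-identical
text outputs, which `run_report()` exploits to write a fully deterministic
report bundle with a JSON manifest echoing the configuration.
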