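---
title: "Generating DRM false-memory lists from vector spaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating DRM false-memory lists from vector spaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the Deese–Roediger–McDermott (DRM) paradigm, participants memorize a
list of related items (the *studied items*), then judge old/new for a probe
set containing studied items (*targets*), an unstudied item strongly related
to the list (the *critical lure*), and unrelated items (*unrelated lures*).
False recognition of the critical lure is the paradigm's signature effect.
Classically such lists are built from human free-association norms, which
exist for few languages and domains and entangle the stimulus construction
with the behavior being predicted.

`fmgen` constructs DRM lists directly from *any* vector space in which items
are represented as fixed-dimension numeric vectors — word embeddings,
visual feature spaces, sensorimotor norms, orthographic one-hot codes — by
replacing associative strength with cosine similarity,
$\cos(u, v) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}$, and the
associated cosine distance $1 - \cos(u, v)$.

## The generation procedure

Given a space of $n$ items and a configuration with $N_L$ lists, close-space
size $N_{CS}$, $N_S$ studied items, $N_T$ targets, $N_{CL}$ critical lures
and $N_{UL}$ unrelated lures per list:

1. **Seeding.** The unit-normalized space is partitioned by k-means with
   $k$ drawn uniformly from $\{N_L, \dots, N_L + 3\}$ (capped at $n$).
   Euclidean k-means on unit vectors orders pairs exactly as cosine distance
   does. We initialize with k-means++ ($D^2$ sampling), run Lloyd iterations
   (`stats::kmeans`, 300-iteration cap), take the best of 10 restarts, and
   retain the $N_L$ mutually most-separated centers (greedy farthest-first
   by cosine distance). Drawing more clusters than lists and discarding the
   surplus varies which regions become lists from run to run; retaining the
   most-separated centers (rather than an arbitrary subset) guarantees that
   two centers splitting one dense region never seed two overlapping lists.
   Each retained center maps to its nearest item, the list's starting point.

2. **Close-space construction.** Starting from the seed item, the loop
   (a) takes the $N_{CS}$ nearest eligible items to the current center,
   (b) samples $N_S$ studied items uniformly from them, (c) recomputes the
   centroid of the studied vectors, and accepts when (i) the farthest
   studied item is the centroid's neighbor number $N_{CS}$ *exactly* —
   so the close space is precisely the ball between the centroid and the
   most peripheral studied item — and (ii), when the classical-critical-lure
   option is on, the centroid's nearest neighbor is not itself studied (it
   must remain available as the critical lure). After 500 rejected
   iterations the search restarts from the next-nearest item to the original
   cluster center, then the third, and so on; after 50 starting items the
   list is declared infeasible. The cap makes failure diagnosable instead of
   unbounded.

3. **Lure selection.**
   - *Random method:* $N_{CL}$ critical lures uniformly from the non-studied
     close space; $N_{UL}$ unrelated lures uniformly from the items outside
     **every** list's close space and not otherwise used.
   - *Distributed method:* the occupied close interval (from the nearest
     available candidate at distance $d_0$ to the close radius $R$) is tiled
     by $N_{CL}$ contiguous distance bins whose widths form a geometric
     sequence $w, wr, wr^2, \dots$; the far interval $(R, d_{max}]$ is tiled
     by $N_{UL}$ further bins continuing the same progression. $(w, r)$ is
     the unique joint solution of the two tiling equations (sum of close
     widths $= R - d_0$, sum of far widths $= d_{max} - R$), found by
     root-finding on $r$; $r = 1$ is admitted when the geometry demands it.
     One lure is drawn uniformly per bin, so lure similarity is spread
     systematically across the whole range — the design that supports
     treating similarity as a continuous predictor.
   - With the classical flag on, the centroid's rank-1 neighbor is always
     included among the critical lures; under the distributed method it
     consumes its containing bin.

4. **Targets.** $N_T$ targets are sampled uniformly from the studied set
   after list acceptance, with no stratification.

Cross-list exclusivity is global: no item appears in two lists in any role.
Studied sets are committed (and, with the classical flag, each list's rank-1
neighbor reserved) for all lists before any lure is drawn, so that unrelated
lures can be restricted to the complement of *all* close spaces.

### Why bins start at the nearest candidate, not at zero

No item can lie arbitrarily close to the centroid of $N_S$ studied vectors:
the nearest candidate sits at a strictly positive distance floor $d_0$
determined by the space's local geometry. A bin tiling that starts at
distance zero therefore contains an innermost bin that is empty *by
construction* whenever $w < d_0$ — not by sampling bad luck — and the
distributed method would fail for perfectly reasonable configurations
(including $N_{CL} = 3$). Tiling $[d_0, R]$ keeps every bin satisfiable
while preserving the defining property: a single geometric width progression
across the close/far boundary (checked in the test suite to $10^{-9}$
relative tolerance).

### Degenerate inputs and numerical choices

- Distance ties in rankings are broken by label byte order, making every
  ranking, and hence every run, reproducible across platforms.
- Centroids are *not* renormalized: cosine distance is invariant to the
  scale of the reference point, so renormalization cannot change a ranking.
- The bin-ratio equation is solved by `uniroot` on
  $\log\left(r^{N_{CL}}\frac{r^{N_{UL}}-1}{r^{N_{CL}}-1}\right)$, which is
  strictly increasing in $r$; the removable singularity at $r = 1$ is
  evaluated by its limit $N_{UL}/N_{CL}$.
- An empty distributed bin triggers a full studied-set resample for that
  list (up to 20 times) before the configuration is declared infeasible,
  mirroring the 500-iteration restart philosophy of the close-space loop.
- k-means on degenerate spaces (duplicate points) falls back safely; a space
  with fewer distinct vectors than requested clusters is an error.

### Random-number discipline

One master seed expands into independent named substreams — clustering,
per-list studied-item sampling, per-list lure draws, per-list target draws,
and a dedicated feasibility stream — via a deterministic hash. Running the
feasibility simulation, or resampling one list, therefore never perturbs any
other stage: the same master seed always yields byte-identical output files.

## The feasibility check

`check_feasibility()` reports per method. Counting shortfalls
($n < N_L \times N_{CS}$, or no far items left for unrelated lures) are
detected without simulation; otherwise a capped trial generation (5 starting
items, 200 iterations per start) runs on the dedicated feasibility
substream. Failures are report content — the limiting constraint plus a
suggested parameter edit — never exceptions.

## The synthetic-space generator

`make_synthetic_space()` emulates the cluster structure of a distributional
semantic model (DSM): random unit cluster directions plus isotropic Gaussian
noise of scale `within_spread`, renormalized to the unit sphere. Throughout
the tests the noise scale is set near $1/\sqrt{d}$, which yields
within-cluster cosine similarity around 0.5–0.7 and between-cluster
similarity near 0 — the ranges typical of published word-embedding
neighborhoods.

Two emulation limits matter for interpreting the tests:

- **Effective dimensionality.** In an isotropic Gaussian cluster at large
  ambient dimension, the centroid of a studied subset is almost
  deterministically closer to its own members than to any other item (each
  member contributes $1/N_S$ of the centroid's noise), so studied and
  non-studied items stop interleaving and the rank-$N_{CS}$ acceptance
  criterion becomes unreachable. Real embedding spaces do not behave this
  way: their neighborhoods have low effective dimensionality. Fixture
  spaces therefore use moderate ambient dimension (16–24), where the
  synthetic geometry reproduces the realistic interleaving. Structural test
  fixtures use 7786 items (17 clusters × 458) to match a full-scale lexicon.
- **Homogeneity.** Synthetic clusters are exchangeable and equally sized;
  real spaces have hub words, uneven density and anisotropy. Passing tests
  certify the selection geometry (ranks, boundaries, bins, exclusivity,
  determinism), not behavioral outcomes with human participants, which
  require real stimuli and experiments.

## Validation statistics

Two closed-form quantities accompany the generator because list validation
studies use them:

- **A′ screening**: Donaldson's nonparametric discriminability
  $A' = 0.5 + \frac{(H-F)(1+H-F)}{4H(1-F)}$ for hit rate $H \ge$
  false-alarm rate $F$ (sign-reflected below chance; exactly 0.5 at
  $H = F$). Participants with $A' < 0.7$ (strict) are conventionally
  excluded; no correction is applied to rates of exactly 0 or 1.
- **AIC evidence ratios**: $\exp(\Delta AIC / 2)$, the relative likelihood
  that the lower-AIC model is closer to the data-generating process.
  Mixed-model fitting itself is out of scope — any statistics environment
  can produce the AICs.

## Problem sizes used in the test suite

Unit and property tests run on spaces of 150–720 items at dimension 8–24;
the property suite exercises 50 seeds × both selection methods on a
300-item space; full-scale structural checks use one 7786-item space. These
sizes keep the geometry checks exhaustive (brute-force re-ranking of every
list against its centroid) while the whole suite completes in well under a
minute.

## Known limitations

- Only the text dialects of word2vec/GloVe are read; binary formats are not.
- No psycholinguistic covariate matching (frequency, length) — lists are
  controlled in similarity geometry only.
- The distributed method needs enough close-space candidates per distance
  bin; small or very tight spaces may be infeasible for it while remaining
  feasible for the random method (the feasibility check reports this).
- Case- or lemma-normalization of labels is never applied; items are
  whatever strings the input space provides.
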