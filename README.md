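# fmgen — DRM false-memory lists from vector spaces

`fmgen` generates stimulus lists for the Deese–Roediger–McDermott (DRM)
false-memory paradigm directly from a vector space, instead of from
human free-association norms. Any space in which items are fixed-dimension
numeric vectors works: word embeddings (word2vec/GloVe/fastText text
formats), visual feature spaces, sensorimotor norms, orthographic codes.
It is aimed at memory researchers who need DRM materials in languages or
domains without association norms, or who want similarity controlled as a
continuous variable.

## What it builds

For each of `N_L` lists the generator selects, by cosine-distance geometry
(`cos(u,v) = u·v / (|u||v|)`, distance `1 − cos`):

- **Studied items** (`N_S`): drawn from the *close space*, the `N_CS` items
  nearest the studied set's own centroid. The centroid is re-estimated
  iteratively until the farthest studied item is the centroid's neighbor
  number `N_CS` *exactly*, so the close space is precisely the region
  between the centroid and the most peripheral studied item (500-iteration
  restart rule with progressively farther starting items).
- **Targets** (`N_T`): a random subset of studied items repeated in the
  recognition phase.
- **Critical lures** (`N_CL`): unstudied close-space items. With the
  classical option, the centroid's single nearest neighbor is forced in —
  the classical DRM critical lure.
- **Unrelated lures** (`N_UL`): items farther from the centroid than every
  studied item, drawn outside the close space of *every* list.

Lures are picked either uniformly (**random method**) or one per
logarithmically spaced distance bin spanning the close and far space with a
single geometric width ratio (**distributed method**, for designs that treat
similarity as a continuous predictor). Lists are seeded by k-means++
clustering so they occupy mutually dissimilar regions, no item serves two
lists, and a master seed makes every run byte-for-byte reproducible.

## Worked example

```r
library(fmgen)

space <- make_synthetic_space(n_clusters = 6, items_per_cluster = 50,
                              dim = 16, within_spread = 0.25, seed = 7)
cfg <- generation_config(n_lists = 3, close_space_items = 12,
                         studied_items = 6, target_items = 3,
                         critical_lures = 2, unrelated_lures = 2,
                         method = "distributed", seed = 11)
lists <- generate_lists(space, cfg)
lists
#> <fmg_lists> 3 DRM lists (method=distributed, seed=11, k_used=6)
#>   list 1: 6 studied (radius 0.1945), 2 critical, 2 unrelated
#>   list 2: 6 studied (radius 0.2079), 2 critical, 2 unrelated
#>   list 3: 6 studied (radius 0.2269), 2 critical, 2 unrelated
```

Each list reports its close radius — the cosine distance of the farthest
studied item, which by construction is also the boundary of the `N_CS`-item
close space. `write_list_output(lists, "out.tsv")` writes one row per item:

```
item       list  encoding  recognition  item_type      distance
c01_i0001  1     0         1            Critical Lure  0.064425
c01_i0035  1     1         0            Studied        0.097781
c01_i0041  1     1         1            Studied        0.114924
c01_i0015  1     1         1            Studied        0.121247
c01_i0038  1     1         1            Studied        0.150628
c01_i0017  1     1         0            Studied        0.158819
c01_i0012  1     0         1            Critical Lure  0.161451
c01_i0026  1     1         0            Studied        0.194453
c01_i0008  1     0         1            Unrelated Lure 0.357011
c02_i0030  1     0         1            Unrelated Lure 0.835796
```

Studied rows are the encoding phase (recognition = 1 marks targets); lure
rows appear only in recognition. Distances are to the list centroid: both
critical lures sit inside the 0.1945 radius — one per distance bin, the
first being the forced nearest neighbor — and both unrelated lures beyond
it. `write_close_space_report()` additionally dumps every close-space item
per list for custom resampling designs.

The companion statistics for list validation:

```r
round(aic_evidence_ratio(c(2, 16)), 1)   # 2.7  2981.0
a_prime(0.9, 0.2)                        # 0.9131944
screen_participants(data.frame(hit_rate = 0.9, fa_rate = 0.2))$keep  # TRUE
```

## Command line

```sh
fmg synth    --clusters 12 --items-per-cluster 100 --dim 50 --spread 0.14 \
             --seed 1 --out space.vec
fmg check    --space space.vec --config drm.cfg
fmg generate --space space.vec --config drm.cfg --seed 9 --out mylists
```

`drm.cfg` is flat `key = value` text (`number_of_lists`,
`close_space_items`, `studied_items`, `target_items`, `critical_lures`,
`unrelated_lures`, `method`, `classical_critical_lure`, `seed`); flags
override file values. `check` prints a per-method feasibility verdict with
suggested edits; `generate` writes `<out>_lists.tsv` and
`<out>_close_space.tsv` and logs seed, k and per-list restart counts to
standard error.

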