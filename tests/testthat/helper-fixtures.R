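# Fixtures and independent brute-force oracles shared across the test files.
# The oracles deliberately avoid the package's vectorized ranking path: plain
# loops over sum/sqrt arithmetic, so they can adjudicate it.

# small clustered space resembling a DSM neighborhood structure:
# within-cluster cosine ~0.5, between ~0.1
clustered_space <- function(n_clusters = 6, items = 50, dim = 16,
                            spread = 1 / sqrt(16), seed = 7) {
  make_synthetic_space(n_clusters, items, dim, spread, seed)
}

small_config <- function(method = "random", classical = TRUE, seed = 1,
                         n_lists = 3, ncs = 12, ns = 6, nt = 3,
                         ncl = 2, nul = 2) {
  generation_config(n_lists = n_lists, close_space_items = ncs,
                    studied_items = ns, target_items = nt,
                    critical_lures = ncl, unrelated_lures = nul,
                    method = method, classical_critical_lure = classical,
                    seed = seed)
}

# brute-force cosine similarity, one pair at a time
brute_cosine <- function(u, v) {
  num <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  num / (sqrt(nu) * sqrt(nv))
}

# brute-force ranking of all non-excluded items by cosine distance to a
# reference, ties by label order
brute_rank <- function(space, reference, excluded = character()) {
  labs <- setdiff(space$labels, excluded)
  d <- vapply(labs, function(l) {
    1 - brute_cosine(space$vectors[l, ], reference)
  }, numeric(1))
  ord <- order(d, labs, method = "radix")
  data.frame(label = labs[ord], distance = d[ord], stringsAsFactors = FALSE)
}

# distances of a set of items to a list's centroid, brute force
brute_dist_to_centroid <- function(space, items, centroid) {
  vapply(items, function(l) 1 - brute_cosine(space$vectors[l, ], centroid),
         numeric(1))
}

write_space_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
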