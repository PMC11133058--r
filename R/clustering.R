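# List seeding: partition the space into dissimilar regions with k-means and
# return one seed item (and its cluster center) per requested list.

#' Find one seed item per list by k-means clustering
#'
#' The space is partitioned with k-means on unit-normalized vectors
#' (Euclidean distance on the unit sphere orders pairs exactly as cosine
#' distance does). The number of clusters k is drawn uniformly from
#' \code{n_lists} to \code{n_lists + 3} (capped at the space size): asking
#' for a few more clusters than lists and then discarding the surplus
#' injects run-to-run variability in which regions of the space become
#' lists. The \code{n_lists} retained centers are the mutually most
#' separated ones (greedy farthest-first by cosine distance), so surplus
#' centers that split one dense region are discarded rather than seeding
#' two overlapping lists.
#' Each retained center is mapped to its nearest item by cosine distance;
#' if two centers map to the same item, the later one takes its
#' next-nearest item so that seeds stay distinct.
#'
#' @param space an \code{fmg_space} with at least \code{n_lists} items.
#' @param n_lists number of lists (and therefore seeds) required.
#' @param rng an \code{fmg_rng} stream or an integer seed.
#' @return A list of class \code{fmg_seeds}: \code{seeds} (character vector
#'   of \code{n_lists} distinct item labels), \code{centers} (matrix of the
#'   retained cluster centers, one row per seed) and \code{k_used}.
#' @export
find_list_seeds <- function(space, n_lists, rng) {
  stopifnot(inherits(space, "fmg_space"), n_lists >= 1)
  n <- length(space$labels)
  if (n < n_lists) {
    stop("infeasible: the space has ", n, " items but ", n_lists,
         " lists were requested")
  }
  rng <- as_rng_stream(rng)
  Mn <- .unit_rows(space$vectors)
  k_max <- min(n_lists + 3L, n)
  ks <- seq.int(n_lists, k_max)
  k <- if (length(ks) == 1L) ks else with_stream(rng, sample(ks, 1L))
  km <- with_stream(rng, .kmeans_safe(Mn, k))
  centers <- km$centers[.separated_order(km$centers)[seq_len(n_lists)], ,
                        drop = FALSE]

  seeds <- character(n_lists)
  for (i in seq_len(n_lists)) {
    rk <- .rank_all(Mn, space$labels, centers[i, ], rep(TRUE, n))
    pick <- rk$labels[!(rk$labels %in% seeds[seq_len(i - 1L)])][1]
    seeds[i] <- pick
  }
  structure(list(seeds = seeds, centers = centers, k_used = k),
            class = "fmg_seeds")
}

# Greedy farthest-first ordering of cluster centers by cosine distance:
# the first m centers of the ordering are mutually well separated, so when
# k > n_lists the discarded centers are the redundant ones (two centers
# splitting a single dense region sit at near-zero distance and are never
# both retained while distinct regions remain).
.separated_order <- function(centers) {
  k <- nrow(centers)
  if (k == 1L) return(1L)
  cn <- .unit_rows(centers)
  D <- 1 - cn %*% t(cn)
  chosen <- which.max(apply(D, 1L, max))  # center of the farthest pair
  left <- setdiff(seq_len(k), chosen)
  while (length(left)) {
    mind <- apply(D[left, chosen, drop = FALSE], 1L, min)
    nxt <- left[which.max(mind)]
    chosen <- c(chosen, nxt)
    left <- setdiff(left, nxt)
  }
  chosen
}

# k-means with k-means++ initialization (D^2 sampling), 10 restarts and a
# 300-iteration cap, best total within-cluster sum of squares kept. The ++
# seeding spreads initial centers across well-separated regions, which plain
# random restarts miss often enough to merge two tight clusters.
.kmeans_safe <- function(x, k, nstart = 10L) {
  if (nrow(unique(x)) < k) {
    stop("cannot form ", k, " clusters: only ", nrow(unique(x)),
         " distinct vectors in the space")
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- .kmeanspp_init(x, k)
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 300,
                      algorithm = "Lloyd")),
      error = function(e) NULL)  # e.g. a cluster emptied out mid-run
    if (!is.null(km) &&
        (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart at k = ", k)
  best
}

# k-means++ seeding: first center uniform, each further center sampled with
# probability proportional to squared Euclidean distance to the nearest
# already-chosen center
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      # fewer distinct points than remaining centers cannot happen (checked
      # by the caller); residual exact duplicates get uniform mass
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    idx[j + 1L] <- pick
    d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}
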