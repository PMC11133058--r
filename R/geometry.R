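# Cosine geometry primitives: similarity/distance, centroids, and full
# neighbor rankings. Every later stage (clustering, close-space construction,
# lure selection) is built on these.

.check_vec <- function(v, what = "vector") {
  if (!is.numeric(v) || !all(is.finite(v))) stop(what, " must be finite numeric")
  if (sqrt(sum(v^2)) == 0) stop("cosine undefined for zero-norm ", what)
  invisible(v)
}

#' Cosine similarity between two vectors
#'
#' @param u,v nonzero numeric vectors of equal dimension.
#' @return The cosine of the angle between \code{u} and \code{v}, in
#'   \eqn{[-1, 1]}; symmetric and invariant to positive rescaling of either
#'   argument.
#' @export
cosine_similarity <- function(u, v) {
  .check_vec(u, "u"); .check_vec(v, "v")
  if (length(u) != length(v)) stop("u and v must have the same dimension")
  s <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  min(1, max(-1, s))
}

#' Cosine distance between two vectors
#'
#' One minus the cosine similarity; ranges over \eqn{[0, 2]} with 0 for
#' parallel and 2 for antipodal vectors. This is the metric used everywhere
#' in list generation (item-to-centroid distances, close/far boundaries).
#'
#' @inheritParams cosine_similarity
#' @export
cosine_distance <- function(u, v) 1 - cosine_similarity(u, v)

#' Centroid of a set of vectors
#'
#' The arithmetic per-dimension mean. The centroid is deliberately not
#' renormalized: cosine distance is invariant to the scale of the reference
#' point, so renormalization could not change any ranking.
#'
#' @param vectors a numeric matrix (rows are vectors) or a list of equal
#'   length numeric vectors; at least one vector.
#' @return A numeric vector of the shared dimension.
#' @export
centroid <- function(vectors) {
  if (is.list(vectors)) {
    if (!length(vectors)) stop("centroid of an empty collection is undefined")
    d <- unique(lengths(vectors))
    if (length(d) != 1) stop("all vectors must share one dimension")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || nrow(vectors) < 1) {
    stop("centroid of an empty collection is undefined")
  }
  colMeans(vectors)
}

# Row-normalize a space's matrix once; rankings are then a single
# matrix-vector product per reference point.
.unit_rows <- function(m) m / sqrt(rowSums(m^2))

# Fast internal ranking over a precomputed unit-row matrix.
# keep: logical mask over rows. Ties broken by label byte order (radix),
# platform-independent. Returns ascending (label, distance).
.rank_all <- function(Mn, labels, reference, keep) {
  r <- reference / sqrt(sum(reference^2))
  d <- as.vector(1 - Mn[keep, , drop = FALSE] %*% r)
  labs <- labels[keep]
  ord <- order(d, labs, method = "radix")
  list(labels = labs[ord], distance = d[ord])
}

#' Rank all items of a space by cosine distance to a reference point
#'
#' @param space an \code{fmg_space}.
#' @param reference nonzero numeric vector of the space's dimensionality.
#' @param excluded character vector of labels to leave out of the ranking.
#' @return A data frame with columns \code{rank} (1-based), \code{label} and
#'   \code{distance}, ascending by distance; exact ties are ordered by label
#'   byte order so rankings are deterministic across runs and platforms. The
#'   reference vector is attached as attribute \code{"reference"}.
#' @export
rank_neighbors <- function(space, reference, excluded = character()) {
  stopifnot(inherits(space, "fmg_space"))
  .check_vec(reference, "reference")
  if (length(reference) != ncol(space$vectors)) {
    stop("reference dimension does not match the space")
  }
  unknown <- setdiff(excluded, space$labels)
  if (length(unknown)) stop("excluded label not in space: ", unknown[1])
  keep <- !(space$labels %in% excluded)
  if (!any(keep)) stop("all items excluded: empty ranking")
  rk <- .rank_all(.unit_rows(space$vectors), space$labels, reference, keep)
  out <- data.frame(rank = seq_along(rk$labels), label = rk$labels,
                    distance = rk$distance, stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  out
}
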