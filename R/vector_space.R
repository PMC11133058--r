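# Vector-space container and text-format I/O (word2vec / GloVe dialects),
# plus a synthetic clustered-space generator used throughout the test suite.

#' Construct a vector space
#'
#' A vector space is the universe of candidate items for list generation: a
#' set of uniquely labelled, fixed-dimension numeric vectors (typically word
#' embeddings, but any item representation works — images, sounds,
#' sensorimotor norms — as long as each item is a vector).
#'
#' @param vectors numeric matrix, one row per item; row names are used as
#'   labels when \code{labels} is missing.
#' @param labels character vector of unique, non-empty, whitespace-free item
#'   identifiers.
#' @return An object of class \code{fmg_space}: a list with elements
#'   \code{labels} and \code{vectors} (matrix with labels as row names).
#' @export
vector_space <- function(vectors, labels = rownames(vectors)) {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("`vectors` must be a numeric matrix")
  }
  if (is.null(labels)) stop("item labels are required (row names or `labels`)")
  labels <- as.character(labels)
  if (length(labels) != nrow(vectors)) {
    stop("length of `labels` must match the number of vector rows")
  }
  if (nrow(vectors) < 1) stop("a vector space must contain at least one item")
  if (ncol(vectors) < 2) stop("vector dimensionality must be at least 2")
  if (anyNA(labels) || any(!nzchar(labels))) stop("labels must be non-empty")
  if (any(grepl("[[:space:]]", labels))) {
    stop("labels must not contain whitespace: ",
         labels[grepl("[[:space:]]", labels)][1])
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicate label: ", dup[1])
  if (!all(is.finite(vectors))) stop("all vector values must be finite")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) {
    stop("zero-norm vector (cosine undefined) for item: ",
         labels[which(norms == 0)[1]])
  }
  rownames(vectors) <- labels
  structure(list(labels = labels, vectors = vectors), class = "fmg_space")
}

#' @export
print.fmg_space <- function(x, ...) {
  cat("<fmg_space> ", length(x$labels), " items x ", ncol(x$vectors),
      " dimensions\n", sep = "")
  invisible(x)
}

#' @export
length.fmg_space <- function(x) length(x$labels)

#' Read a vector space from a word2vec/GloVe text file
#'
#' Each line holds one item label followed by its space-separated vector
#' values. An optional leading word2vec header line (\code{"<count> <dim>"},
#' exactly two integer tokens) is detected and skipped; GloVe files have no
#' header. Tokens may be separated by any run of spaces or tabs.
#'
#' @param path path to the text file.
#' @return An \code{fmg_space}; attribute \code{"header"} records whether the
#'   file carried a word2vec header (so that [save_vector_space()] can mirror
#'   the dialect).
#' @export
load_vector_space <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bad <- which(!validUTF8(lines))
  if (length(bad)) {
    stop("invalid UTF-8 on line ", bad[1], " of ", path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty vector-space file: ", path)

  toks <- strsplit(trimws(lines), "[ \t]+")
  had_header <- FALSE
  first <- toks[[1]]
  if (length(first) == 2 && all(grepl("^[0-9]+$", first))) {
    had_header <- TRUE
    toks <- toks[-1]
    if (!length(toks)) stop("vector-space file contains only a header: ", path)
  }
  lens <- lengths(toks)
  d <- lens[1] - 1L
  off <- if (had_header) 1L else 0L
  if (d < 2) {
    stop("line ", 1L + off, ": vector dimensionality must be at least 2")
  }
  ragged <- which(lens != lens[1])
  if (length(ragged)) {
    stop("line ", ragged[1] + off, ": expected 1 label + ", d,
         " values, found ", lens[ragged[1]], " tokens")
  }
  labels <- vapply(toks, `[[`, character(1), 1L)
  vals <- vapply(toks, function(tk) {
    suppressWarnings(as.numeric(tk[-1]))
  }, numeric(d))
  vecs <- t(vals)
  badnum <- which(apply(is.na(vecs), 1L, any))
  if (length(badnum)) {
    stop("line ", badnum[1] + off, ": non-numeric vector value for item '",
         labels[badnum[1]], "'")
  }
  space <- vector_space(vecs, labels)
  attr(space, "header") <- had_header
  space
}

#' Write a vector space to a word2vec/GloVe text file
#'
#' Mirrors the dialect of the source file: a word2vec count/dimension header
#' is written when \code{header} is \code{TRUE} (the default takes the
#' space's \code{"header"} attribute, if any). Values are printed with enough
#' digits that a load/save round trip reproduces them to printed precision.
#'
#' @param space an \code{fmg_space}.
#' @param path output path.
#' @param header write a word2vec \code{"<count> <dim>"} first line?
#' @export
save_vector_space <- function(space, path, header = NULL) {
  stopifnot(inherits(space, "fmg_space"))
  if (is.null(header)) header <- isTRUE(attr(space, "header"))
  n <- length(space$labels)
  if (n < 1) stop("nothing to write: empty vector space")
  body <- paste(space$labels,
                apply(space$vectors, 1L, function(v) {
                  paste(sprintf("%.10g", v), collapse = " ")
                }))
  if (header) body <- c(paste(n, ncol(space$vectors)), body)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(body, con)
  invisible(NULL)
}

#' Generate a synthetic clustered vector space
#'
#' Emulates the cluster structure of a distributional semantic model for
#' testing: \code{n_clusters} random unit-length cluster directions are
#' drawn, then \code{items_per_cluster} items per cluster as the direction
#' plus isotropic Gaussian noise of scale \code{within_spread}, renormalized
#' to unit length. Labels encode the ground-truth cluster
#' (\code{"c<cluster>_i<item>"}) and the assignment is also returned as the
#' \code{"clusters"} attribute (a named integer vector).
#'
#' @param n_clusters number of ground-truth clusters (>= 1).
#' @param items_per_cluster items per cluster (>= 1).
#' @param dim vector dimensionality (>= 2).
#' @param within_spread standard deviation of the per-coordinate noise added
#'   to the cluster direction before renormalization; 0 collapses each
#'   cluster onto a single point.
#' @param seed integer seed; the same seed reproduces the space bit for bit.
#' @return An \code{fmg_space} of \code{n_clusters * items_per_cluster}
#'   unit-length vectors.
#' @export
make_synthetic_space <- function(n_clusters, items_per_cluster, dim,
                                 within_spread, seed) {
  stopifnot(n_clusters >= 1, items_per_cluster >= 1, dim >= 2,
            within_spread >= 0)
  stream <- new_rng_stream(seed)
  dirs <- with_stream(stream,
                      matrix(stats::rnorm(n_clusters * dim), n_clusters, dim))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- n_clusters * items_per_cluster
  noise <- with_stream(stream,
                       matrix(stats::rnorm(n * dim, sd = 1), n, dim))
  cl <- rep(seq_len(n_clusters), each = items_per_cluster)
  pts <- dirs[cl, , drop = FALSE] + within_spread * noise
  nrm <- sqrt(rowSums(pts^2))
  # with spread 0 the norm is exactly 1; guard against pathological cancels
  if (any(nrm == 0)) stop("degenerate zero vector produced; change the seed")
  pts <- pts / nrm
  labels <- sprintf("c%02d_i%04d", cl, sequence(rep(items_per_cluster,
                                                    n_clusters)))
  space <- vector_space(pts, labels)
  clusters <- stats::setNames(cl, labels)
  attr(space, "clusters") <- clusters
  space
}
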