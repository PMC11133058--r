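# The list-generation routine: per-seed close-space construction with
# iterative centroid recomputation, then lure selection by the Random or
# Distributed method, under global cross-list exclusivity.

#' Generation configuration
#'
#' Collects all user parameters of a generation run and enforces their
#' validity rules. Parameter names follow the tool's configuration window:
#' Number of Lists (N_L), Close Space Items (N_CS), Studied Items (N_S),
#' Target Items (N_T), Critical Lures (N_CL), Unrelated Lures (N_UL).
#'
#' @param n_lists number of lists N_L (>= 1).
#' @param close_space_items close-space size N_CS; must be at least
#'   \code{studied_items + critical_lures}, since both studied items and
#'   critical lures are drawn from the close space.
#' @param studied_items encoding-phase items per list N_S (>= 1).
#' @param target_items studied items repeated in the recognition phase N_T;
#'   cannot exceed \code{studied_items}.
#' @param critical_lures close-space new items per list N_CL (>= 1).
#' @param unrelated_lures far-space new items per list N_UL (>= 0).
#' @param method lure-selection method, \code{"random"} or
#'   \code{"distributed"}.
#' @param classical_critical_lure force the single nearest neighbor of the
#'   studied-set centroid to be a critical lure (the classical DRM critical
#'   lure); when \code{TRUE} the studied set is additionally constrained so
#'   that this nearest neighbor is not itself studied.
#' @param seed master integer seed; expands into independent substreams for
#'   clustering, studied-item sampling, lure draws and target draws.
#' @return An object of class \code{fmg_config}.
#' @export
generation_config <- function(n_lists, close_space_items, studied_items,
                              target_items, critical_lures,
                              unrelated_lures = 0L,
                              method = c("random", "distributed"),
                              classical_critical_lure = TRUE,
                              seed = 1L) {
  method <- match.arg(method)
  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1 || is.na(x) || x != as.integer(x) || x < min) {
      stop(name, " must be an integer >= ", min)
    }
    as.integer(x)
  }
  n_lists <- chk_count(n_lists, "Number of Lists (N_L)")
  close_space_items <- chk_count(close_space_items, "Close Space Items (N_CS)")
  studied_items <- chk_count(studied_items, "Studied Items (N_S)")
  target_items <- chk_count(target_items, "Target Items (N_T)")
  critical_lures <- chk_count(critical_lures, "Critical Lures (N_CL)")
  unrelated_lures <- chk_count(unrelated_lures, "Unrelated Lures (N_UL)", 0L)
  if (close_space_items < studied_items + critical_lures) {
    stop("Close Space Items (N_CS) must be greater than or equal to the sum ",
         "of Studied Items (N_S) and Critical Lures (N_CL)")
  }
  if (target_items > studied_items) {
    stop("Target Items (N_T) cannot exceed the number chosen for the ",
         "Studied Items (N_S)")
  }
  structure(list(n_lists = n_lists, close_space_items = close_space_items,
                 studied_items = studied_items, target_items = target_items,
                 critical_lures = critical_lures,
                 unrelated_lures = unrelated_lures, method = method,
                 classical_critical_lure = isTRUE(classical_critical_lure),
                 seed = as.integer(seed)),
            class = "fmg_config")
}

#' @export
print.fmg_config <- function(x, ...) {
  cat("<fmg_config> N_L=", x$n_lists, " N_CS=", x$close_space_items,
      " N_S=", x$studied_items, " N_T=", x$target_items,
      " N_CL=", x$critical_lures, " N_UL=", x$unrelated_lures,
      " method=", x$method,
      " classical=", x$classical_critical_lure,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# internal working context: raw vectors + unit-row matrix + labels
.make_ctx <- function(space) {
  list(labels = space$labels, V = space$vectors,
       Mn = .unit_rows(space$vectors))
}

# Close-space construction for one list.
#
# Iterative loop: take the N_CS nearest non-excluded items to the current
# center, sample N_S studied items from them, recompute the centroid, and
# accept when (i) the farthest studied item sits at neighbor rank exactly
# N_CS of that centroid and (ii), under the classical-critical-lure flag,
# the rank-1 neighbor is not itself studied. After 500 rejected iterations
# the whole selection restarts from the next-nearest item to the original
# cluster center (then the 3rd, 4th, ... up to max_starts candidates).
.build_study_set <- function(ctx, cluster_center, config, stream,
                             excluded = character(),
                             max_starts = 50L, max_iter = 500L) {
  ncs <- config$close_space_items
  ns <- config$studied_items
  keep <- !(ctx$labels %in% excluded)
  if (sum(keep) < ncs) {
    stop("infeasible: only ", sum(keep), " eligible items remain but the ",
         "Close Space Items (N_CS) setting requires ", ncs)
  }
  labels <- ctx$labels
  Mn <- ctx$Mn
  # distances of all eligible items to a center; excluded rows masked to Inf
  dist_to <- function(center) {
    d <- as.vector(1 - Mn %*% (center / sqrt(sum(center^2))))
    d[!keep] <- Inf
    d
  }
  # indices of the ncs nearest items, ascending, ties by label byte order
  close_set <- function(d) {
    kth <- sort.int(d, partial = ncs)[ncs]
    idx <- which(d <= kth)
    idx[order(d[idx], labels[idx], method = "radix")][seq_len(ncs)]
  }
  d_start <- dist_to(cluster_center)
  # excluded items carry Inf distances and sort to the tail; drop them
  start_idx <- order(d_start, labels, method = "radix")[seq_len(sum(keep))]
  n_starts <- min(max_starts, length(start_idx))
  for (s in seq_len(n_starts)) {
    d <- dist_to(ctx$V[start_idx[s], ])
    for (iter in seq_len(max_iter)) {
      close_idx <- close_set(d)
      studied_idx <- with_stream(stream, sample(close_idx, ns))
      cen <- colMeans(ctx$V[studied_idx, , drop = FALSE])
      d2 <- dist_to(cen)
      new_close <- close_set(d2)
      # criterion (i): the farthest studied item is the rank-ncs neighbor
      ok_size <- new_close[ncs] %in% studied_idx &&
        all(studied_idx %in% new_close)
      # criterion (ii): classical critical lure — nearest neighbor not studied
      ok_classical <- !config$classical_critical_lure ||
        !(new_close[1] %in% studied_idx)
      if (ok_size && ok_classical) {
        stud <- new_close[new_close %in% studied_idx]
        return(list(studied = labels[stud],
                    studied_distance = d2[stud],
                    centroid = cen,
                    close_space = labels[new_close],
                    close_distance = d2[new_close],
                    close_radius = d2[new_close[ncs]],
                    excluded = excluded,
                    start_index = s, iterations = iter))
      }
      d <- d2
    }
  }
  stop("close-space construction failed: no studied set satisfied the ",
       "rank-N_CS", if (config$classical_critical_lure)
         " and classical-critical-lure criteria" else " criterion",
       " after ", n_starts, " starting items x ", max_iter, " iterations")
}

#' Build the studied set and close space for one list
#'
#' Exposes the per-list close-space construction step on its own: starting
#' from a seed item, studied items are repeatedly sampled from the current
#' close space and the centroid re-estimated until the farthest studied item
#' is the centroid's neighbor number N_CS exactly (so the close space is the
#' region between the centroid and the most peripheral studied item), with
#' restarts from progressively farther starting items after 500 failed
#' iterations.
#'
#' @param space an \code{fmg_space}.
#' @param seed_item label of the starting item (usually from
#'   [find_list_seeds()]).
#' @param config an \code{fmg_config}.
#' @param rng an \code{fmg_rng} stream or integer seed.
#' @param excluded labels ineligible for this list (items already used by
#'   other lists).
#' @return A list with elements \code{studied} (labels, ascending distance to
#'   the final centroid), \code{studied_distance}, \code{centroid},
#'   \code{close_space} (the N_CS nearest labels), \code{close_distance},
#'   \code{close_radius} (distance of the farthest studied item),
#'   \code{excluded} (the eligibility exclusions the list was built
#'   against), \code{start_index} and \code{iterations}.
#' @export
build_study_set <- function(space, seed_item, config, rng,
                            excluded = character()) {
  stopifnot(inherits(space, "fmg_space"), inherits(config, "fmg_config"))
  if (!seed_item %in% space$labels) stop("unknown seed item: ", seed_item)
  if (seed_item %in% excluded) stop("seed item is excluded: ", seed_item)
  ctx <- .make_ctx(space)
  .build_study_set(ctx, ctx$V[seed_item, ], config, as_rng_stream(rng),
                   excluded)
}

# ---- lure selection -------------------------------------------------------

# Random method: critical lures uniform from the non-studied close space,
# unrelated lures uniform from the global far pool (items outside every
# list's close space and not otherwise used). `forced` carries the rank-1
# neighbor when the classical flag is on.
.select_lures_random <- function(lst, config, stream, far_pool, used) {
  cands <- setdiff(lst$close_space, c(lst$studied, used))
  forced <- if (config$classical_critical_lure) lst$close_space[1] else character()
  if (length(forced) && !(forced %in% cands)) {
    stop("list ", lst$list_id, ": the centroid's nearest neighbor is no ",
         "longer available as the classical critical lure")
  }
  pool <- setdiff(cands, forced)
  need <- config$critical_lures - length(forced)
  if (length(pool) < need) {
    stop("list ", lst$list_id, ": close space has only ",
         length(pool) + length(forced), " available items for ",
         config$critical_lures, " Critical Lures (N_CL)")
  }
  extra <- if (need > 0) with_stream(stream, sample(pool, need)) else character()
  critical <- c(forced, extra)
  if (length(far_pool) < config$unrelated_lures) {
    stop("list ", lst$list_id, ": far space has only ", length(far_pool),
         " available items for ", config$unrelated_lures,
         " Unrelated Lures (N_UL)")
  }
  unrelated <- if (config$unrelated_lures > 0) {
    with_stream(stream, sample(far_pool, config$unrelated_lures))
  } else character()
  list(critical = critical, unrelated = unrelated, bins = NULL)
}

# Geometric bin progression for the distributed method. The occupied close
# interval [lo, R] (nearest available candidate to close radius) is tiled by
# n_close contiguous bins whose widths form a geometric sequence w, w*r, ...;
# the far interval (R, d_max] is tiled by n_far further bins continuing the
# same progression. (w, r) is the joint solution of the two tiling
# equations, found by root-finding on r. Tiling starts at the nearest
# candidate rather than at distance zero because no item can lie arbitrarily
# close to the centroid of several studied items: a bin below that floor
# would be empty by construction, not by bad luck.
.geometric_bins <- function(lo, R, d_max, n_close, n_far) {
  stopifnot(R > lo, n_close >= 1)
  span_close <- R - lo
  span_far <- d_max - R
  gsum <- function(r, n) if (abs(r - 1) < 1e-12) n else (r^n - 1) / (r - 1)
  if (n_far == 0 || span_far <= 0) {
    r <- 1
  } else {
    q <- span_far / span_close
    # f(r) = log of (sum of far widths / sum of close widths) - log q;
    # strictly increasing in r, so a unique root exists.
    f <- function(r) log(r^n_close * gsum(r, n_far) / gsum(r, n_close)) - log(q)
    if (abs(f(1)) < 1e-13) {
      r <- 1
    } else {
      rlo <- 1e-6; rhi <- 1e6
      while (f(rlo) > 0 && rlo > 1e-12) rlo <- rlo / 10
      while (f(rhi) < 0 && rhi < 1e12) rhi <- rhi * 10
      r <- stats::uniroot(f, c(rlo, rhi), tol = 1e-15)$root
    }
  }
  w <- span_close / gsum(r, n_close)
  widths <- w * r^(seq_len(n_close + n_far) - 1)
  upper <- lo + cumsum(widths)
  upper[n_close] <- R                      # pin the boundary exactly
  if (n_far > 0) upper[n_close + n_far] <- d_max
  lower <- c(lo, upper[-length(upper)])
  data.frame(region = rep(c("close", "far"), c(n_close, n_far)),
             lower = lower, upper = upper, width = upper - lower,
             ratio = r)
}

.bin_of <- function(d, upper) {
  vapply(d, function(z) {
    i <- which(z <= upper + 1e-9)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
}

# Distributed method: one critical lure per close-space distance bin and one
# unrelated lure per far-space bin, bins logarithmically spaced (each width =
# previous * fixed ratio) across the close-far boundary. Returns NULL with
# attribute "empty_bin" when a required bin holds no candidate, signalling
# the caller to resample the studied set.
.select_lures_distributed <- function(ctx, lst, config, stream, far_pool,
                                      used) {
  ncl <- config$critical_lures
  nul <- config$unrelated_lures
  cands <- setdiff(lst$close_space, c(lst$studied, used))
  if (length(cands) < ncl) {
    stop("list ", lst$list_id, ": close space has only ", length(cands),
         " available items for ", ncl, " Critical Lures (N_CL)")
  }
  if (nul > 0 && length(far_pool) < nul) {
    stop("list ", lst$list_id, ": far space has only ", length(far_pool),
         " available items for ", nul, " Unrelated Lures (N_UL)")
  }
  cen <- lst$centroid / sqrt(sum(lst$centroid^2))
  d_close <- lst$close_distance[match(cands, lst$close_space)]
  if (nul > 0) {
    d_far <- as.vector(1 - ctx$Mn[match(far_pool, ctx$labels), ,
                                  drop = FALSE] %*% cen)
    d_max <- max(d_far)
  } else {
    d_far <- numeric(0)
    d_max <- lst$close_radius
  }
  bins <- .geometric_bins(min(d_close), lst$close_radius, d_max, ncl, nul)
  close_upper <- bins$upper[bins$region == "close"]
  far_upper <- bins$upper[bins$region == "far"]

  cand_bin <- .bin_of(d_close, close_upper)
  forced <- character()
  taken_bins <- integer(0)
  if (config$classical_critical_lure) {
    forced <- lst$close_space[1]
    if (!(forced %in% cands)) {
      stop("list ", lst$list_id, ": the centroid's nearest neighbor is no ",
           "longer available as the classical critical lure")
    }
    taken_bins <- cand_bin[match(forced, cands)]
  }
  critical <- forced
  for (b in setdiff(seq_len(ncl), taken_bins)) {
    members <- cands[cand_bin == b & !(cands %in% critical)]
    if (!length(members)) {
      return(structure(list(lower = bins$lower[b], upper = bins$upper[b]),
                       class = "fmg_empty_bin"))
    }
    pick <- if (length(members) == 1) members else
      with_stream(stream, sample(members, 1))
    critical <- c(critical, pick)
  }
  unrelated <- character()
  if (nul > 0) {
    far_bin <- .bin_of(d_far, far_upper)
    for (b in seq_len(nul)) {
      members <- far_pool[far_bin == b & !(far_pool %in% unrelated)]
      if (!length(members)) {
        i <- ncl + b
        return(structure(list(lower = bins$lower[i], upper = bins$upper[i]),
                         class = "fmg_empty_bin"))
      }
      pick <- if (length(members) == 1) members else
        with_stream(stream, sample(members, 1))
      unrelated <- c(unrelated, pick)
    }
  }
  list(critical = critical, unrelated = unrelated, bins = bins)
}

# ---- orchestration --------------------------------------------------------

#' Generate DRM lists from a vector space
#'
#' Runs the full routine: k-means seeding ([find_list_seeds()]), per-seed
#' close-space construction ([build_study_set()]), lure selection by the
#' configured method, and uniform target sampling, while maintaining a
#' global exclusion set so that no item appears in two lists in any role.
#' Unrelated lures are drawn from the items lying outside \emph{every}
#' list's close space. The whole run is deterministic given
#' \code{config$seed}.
#'
#' @param space an \code{fmg_space}.
#' @param config an \code{fmg_config}.
#' @return An object of class \code{fmg_lists}: a list of per-list records,
#'   each with \code{list_id}, \code{studied} (ascending distance to the
#'   list centroid — the encoding presentation order is its reverse,
#'   descending similarity), \code{targets}, \code{critical_lures},
#'   \code{unrelated_lures}, \code{centroid}, \code{close_space},
#'   \code{close_radius}, per-item \code{distance}s, and for the distributed
#'   method the \code{bins} table. Attributes: \code{config}, \code{k_used},
#'   \code{seeds}.
#' @param max_starts,max_iter caps on the close-space search per list:
#'   number of alternative starting items, and studied-set resamples per
#'   starting item before moving to the next one. The defaults are the
#'   routine's standard budget; [check_feasibility()] uses tighter caps for
#'   its quick trial.
#' @export
generate_lists <- function(space, config, max_starts = 50L, max_iter = 500L) {
  stopifnot(inherits(space, "fmg_space"), inherits(config, "fmg_config"))
  n <- length(space$labels)
  if (n < config$n_lists * config$close_space_items) {
    stop("infeasible: the space holds ", n, " items but ", config$n_lists,
         " lists x ", config$close_space_items,
         " Close Space Items (N_CS) require at least ",
         config$n_lists * config$close_space_items)
  }
  ctx <- .make_ctx(space)
  nl <- config$n_lists
  s_stream <- function(name) new_rng_stream(fmg_substream_seed(config$seed, name))

  seeds <- find_list_seeds(space, nl, s_stream("clustering"))
  study_streams <- lapply(seq_len(nl), function(i) s_stream(paste0("study:", i)))
  lure_streams <- lapply(seq_len(nl), function(i) s_stream(paste0("lures:", i)))
  target_streams <- lapply(seq_len(nl), function(i) s_stream(paste0("targets:", i)))

  lists <- vector("list", nl)
  reserved <- character(nl)    # per-list classical critical lure, if any
  selected <- character(0)     # every item committed to any role

  build_one <- function(i, excluded) {
    bs <- .build_study_set(ctx, seeds$centers[i, ], config,
                           study_streams[[i]], excluded,
                           max_starts = max_starts, max_iter = max_iter)
    bs$list_id <- i
    bs
  }
  for (i in seq_len(nl)) {
    bs <- build_one(i, selected)
    lists[[i]] <- bs
    if (config$classical_critical_lure) reserved[i] <- bs$close_space[1]
    selected <- c(selected, bs$studied,
                  if (config$classical_critical_lure) reserved[i])
  }

  union_close <- function() unique(unlist(lapply(lists, `[[`, "close_space")))

  for (i in seq_len(nl)) {
    attempt <- 0L
    repeat {
      far_pool <- setdiff(ctx$labels, c(union_close(), selected))
      used <- setdiff(selected, c(lists[[i]]$studied, reserved[i]))
      res <- if (config$method == "random") {
        .select_lures_random(lists[[i]], config, lure_streams[[i]],
                             far_pool, used)
      } else {
        .select_lures_distributed(ctx, lists[[i]], config, lure_streams[[i]],
                                  far_pool, used)
      }
      if (!inherits(res, "fmg_empty_bin")) {
        lst <- lists[[i]]
        cen <- lst$centroid / sqrt(sum(lst$centroid^2))
        dist_of <- function(labs) {
          if (!length(labs)) return(numeric(0))
          as.vector(1 - ctx$Mn[match(labs, ctx$labels), , drop = FALSE] %*% cen)
        }
        lst$critical_lures <- res$critical
        lst$unrelated_lures <- res$unrelated
        lst$bins <- res$bins
        lst$targets <- with_stream(target_streams[[i]],
                                   sample(lst$studied, config$target_items))
        lst$distance <- c(
          stats::setNames(lst$studied_distance, lst$studied),
          stats::setNames(dist_of(res$critical), res$critical),
          stats::setNames(dist_of(res$unrelated), res$unrelated))
        lists[[i]] <- lst
        selected <- c(selected, res$critical, res$unrelated)
        break
      }
      # distributed method hit an empty bin: resample this list's studied set
      attempt <- attempt + 1L
      if (attempt > 20L) {
        stop("list ", i, ", distributed method: distance bin [",
             format(res$lower), ", ", format(res$upper),
             "] stayed empty after 20 studied-set resamples; enlarge the ",
             "space or reduce Critical/Unrelated Lures")
      }
      drop <- c(lists[[i]]$studied,
                if (config$classical_critical_lure) reserved[i])
      selected <- setdiff(selected, drop)
      bs <- build_one(i, selected)
      lists[[i]] <- bs
      if (config$classical_critical_lure) reserved[i] <- bs$close_space[1]
      selected <- c(selected, bs$studied,
                    if (config$classical_critical_lure) reserved[i])
    }
  }

  structure(lists, class = "fmg_lists", config = config,
            k_used = seeds$k_used, seeds = seeds$seeds)
}

#' @export
print.fmg_lists <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<fmg_lists> ", length(x), " DRM lists (method=", cfg$method,
      ", seed=", cfg$seed, ", k_used=", attr(x, "k_used"), ")\n", sep = "")
  for (l in x) {
    cat(sprintf("  list %d: %d studied (radius %.4f), %d critical, %d unrelated\n",
                l$list_id, length(l$studied), l$close_radius,
                length(l$critical_lures), length(l$unrelated_lures)))
  }
  invisible(x)
}

#' Test whether a configuration can generate lists from a space
#'
#' Runs a preliminary, capped trial generation per selection method on an
#' RNG stream independent of any real run, so checking feasibility never
#' changes what [generate_lists()] later produces for the same seed.
#' Structural violations (e.g. a close space smaller than studied items plus
#' critical lures) and counting shortfalls (a vocabulary smaller than
#' \code{n_lists * close_space_items}) are reported without simulation.
#'
#' @param space an \code{fmg_space}.
#' @param config an \code{fmg_config} (its \code{method} field is ignored;
#'   both methods are always assessed).
#' @param methods which methods to assess.
#' @return A data frame of class \code{fmg_feasibility} with one row per
#'   method: \code{method}, \code{feasible}, \code{limiting_constraint} and
#'   \code{suggestion} (a human-readable parameter edit; empty when
#'   feasible).
#' @export
check_feasibility <- function(space, config,
                              methods = c("random", "distributed")) {
  stopifnot(inherits(space, "fmg_space"), inherits(config, "fmg_config"))
  n <- length(space$labels)
  need_close <- config$n_lists * config$close_space_items
  need_total <- need_close + config$n_lists * config$unrelated_lures
  one <- function(method) {
    if (n < need_close) {
      max_lists <- max(1L, n %/% (config$close_space_items +
                                    config$unrelated_lures))
      return(data.frame(
        method = method, feasible = FALSE,
        limiting_constraint = paste0(
          "vocabulary size: ", n, " items cannot host ", config$n_lists,
          " close spaces of ", config$close_space_items, " items"),
        suggestion = paste0("reduce Number of Lists (N_L) to ", max_lists,
                            " or use a larger vector space"),
        stringsAsFactors = FALSE))
    }
    if (n < need_total) {
      return(data.frame(
        method = method, feasible = FALSE,
        limiting_constraint = paste0(
          "vocabulary size: no far-space items left for ",
          config$unrelated_lures, " Unrelated Lures (N_UL) per list"),
        suggestion = "reduce Unrelated Lures (N_UL) or use a larger vector space",
        stringsAsFactors = FALSE))
    }
    trial <- config
    trial$method <- method
    ok <- tryCatch({
      .generate_trial(space, trial)
      TRUE
    }, error = function(e) e)
    if (isTRUE(ok)) {
      data.frame(method = method, feasible = TRUE, limiting_constraint = "",
                 suggestion = "", stringsAsFactors = FALSE)
    } else {
      data.frame(method = method, feasible = FALSE,
                 limiting_constraint = conditionMessage(ok),
                 suggestion = paste0(
                   "reduce Number of Lists (N_L) or Close Space Items ",
                   "(N_CS), or use a larger vector space"),
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(methods, one))
  class(out) <- c("fmg_feasibility", class(out))
  out
}

# capped trial generation on the dedicated "feasibility" substream
.generate_trial <- function(space, config) {
  trial <- config
  trial$seed <- as.integer(fmg_substream_seed(config$seed, "feasibility"))
  generate_lists(space, trial, max_starts = 5L, max_iter = 200L)
  invisible(TRUE)
}
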