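# Tab-separated output files: the per-item list file (one row per selected
# item with phase flags, type and centroid distance) and the close-space
# report (every close-space item plus the selected unrelated lures, sorted
# by distance).

.list_records <- function(lists) {
  cfg <- attr(lists, "config")
  do.call(rbind, lapply(lists, function(l) {
    items <- c(l$studied, l$critical_lures, l$unrelated_lures)
    type <- rep(c("Studied", "Critical Lure", "Unrelated Lure"),
                c(length(l$studied), length(l$critical_lures),
                  length(l$unrelated_lures)))
    enc <- type == "Studied"
    rec <- ifelse(type == "Studied", items %in% l$targets, TRUE)
    d <- unname(l$distance[items])
    out <- data.frame(item = items, list = l$list_id, encoding = enc,
                      recognition = rec, item_type = type, distance = d,
                      stringsAsFactors = FALSE)
    out[order(out$distance, out$item, method = "radix"), , drop = FALSE]
  }))
}

#' Write the generated lists to a tab-separated file
#'
#' One row per selected item: label, list id, whether the item appears in
#' the encoding phase (studied items only) and/or the recognition phase
#' (targets and all lures), its type, and its cosine distance to the list's
#' studied-set centroid (6 decimals). Within each list, rows are ordered by
#' ascending distance.
#'
#' @param lists an \code{fmg_lists} object from [generate_lists()].
#' @param path output path.
#' @export
write_list_output <- function(lists, path) {
  stopifnot(inherits(lists, "fmg_lists"), length(lists) >= 1)
  rec <- .list_records(lists)
  lines <- c(paste(c("item", "list", "encoding", "recognition", "item_type",
                     "distance"), collapse = "\t"),
             sprintf("%s\t%d\t%d\t%d\t%s\t%.6f", rec$item, rec$list,
                     rec$encoding, rec$recognition, rec$item_type,
                     rec$distance))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Read a list output file back into a data frame
#'
#' @param path a file written by [write_list_output()].
#' @return A data frame with columns \code{item}, \code{list},
#'   \code{encoding}, \code{recognition} (logical), \code{item_type} and
#'   \code{distance}.
#' @export
read_list_output <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "integer", "character", "numeric"))
  out$encoding <- as.logical(out$encoding)
  out$recognition <- as.logical(out$recognition)
  out
}

#' Write the close-space report
#'
#' For each list, reports the entire close space (all N_CS items nearest the
#' studied-set centroid, selected or not) followed by the list's unrelated
#' lures, each with its role and cosine distance to the centroid, ascending
#' within each section. This lets users resample close-space items as
#' studied items or related lures in category-length designs.
#'
#' @param lists an \code{fmg_lists} object.
#' @param space the \code{fmg_space} the lists were generated from
#'   (distances are recomputed from it).
#' @param path output path.
#' @export
write_close_space_report <- function(lists, space, path) {
  stopifnot(inherits(lists, "fmg_lists"), inherits(space, "fmg_space"),
            length(lists) >= 1)
  Mn <- .unit_rows(space$vectors)
  rows <- do.call(rbind, lapply(lists, function(l) {
    cen <- l$centroid / sqrt(sum(l$centroid^2))
    dist_of <- function(labs) {
      as.vector(1 - Mn[match(labs, space$labels), , drop = FALSE] %*% cen)
    }
    role <- function(labs) {
      ifelse(labs %in% l$studied, "Studied",
             ifelse(labs %in% l$critical_lures, "Critical Lure", "Available"))
    }
    close <- data.frame(list = l$list_id, item = l$close_space,
                        region = "close", role = role(l$close_space),
                        distance = dist_of(l$close_space),
                        stringsAsFactors = FALSE)
    close <- close[order(close$distance, close$item, method = "radix"), ,
                   drop = FALSE]
    if (length(l$unrelated_lures)) {
      far <- data.frame(list = l$list_id, item = l$unrelated_lures,
                        region = "far", role = "Unrelated Lure",
                        distance = dist_of(l$unrelated_lures),
                        stringsAsFactors = FALSE)
      far <- far[order(far$distance, far$item, method = "radix"), ,
                 drop = FALSE]
      close <- rbind(close, far)
    }
    close
  }))
  lines <- c(paste(c("list", "item", "region", "role", "distance"),
                   collapse = "\t"),
             sprintf("%d\t%s\t%s\t%s\t%.6f", rows$list, rows$item,
                     rows$region, rows$role, rows$distance))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Read a close-space report back into a data frame
#'
#' @param path a file written by [write_close_space_report()].
#' @export
read_close_space_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "character", "numeric"))
}
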