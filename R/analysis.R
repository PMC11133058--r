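# Closed-form statistics used to validate generated lists: the
# nonparametric A' discriminability index for participant screening, and
# AIC evidence ratios for model comparison. Mixed-model fitting itself is
# left to the user's statistics environment; only these closed forms are
# provided.

#' Nonparametric discriminability index A'
#'
#' Computes Donaldson's A' from a hit rate (proportion of "old" responses to
#' studied words) and a false-alarm rate (proportion of "old" responses to
#' unrelated lures). A' lies in \eqn{[0, 1]}: about 0.5 indicates chance
#' performance, values near 1 good discrimination. For \eqn{H \ge F},
#' \deqn{A' = 0.5 + \frac{(H - F)(1 + H - F)}{4H(1 - F)}}
#' and for \eqn{H < F} the sign-reflected form
#' \eqn{0.5 - ((F - H)(1 + F - H)) / (4F(1 - H))}, so the index is total on
#' the unit square; \eqn{H = F} returns exactly 0.5. No rate correction is
#' applied for rates of exactly 0 or 1.
#'
#' @param hit_rate,fa_rate proportions in \eqn{[0, 1]}; vectorized.
#' @return A' values in \eqn{[0, 1]}.
#' @export
a_prime <- function(hit_rate, fa_rate) {
  if (any(!is.finite(hit_rate)) || any(!is.finite(fa_rate)) ||
      any(hit_rate < 0 | hit_rate > 1) || any(fa_rate < 0 | fa_rate > 1)) {
    stop("hit and false-alarm rates must lie in [0, 1]")
  }
  n <- max(length(hit_rate), length(fa_rate))
  h <- rep_len(hit_rate, n)
  f <- rep_len(fa_rate, n)
  out <- numeric(n)
  eq <- h == f
  up <- h > f
  dn <- h < f
  out[eq] <- 0.5
  out[up] <- 0.5 + ((h[up] - f[up]) * (1 + h[up] - f[up])) /
    (4 * h[up] * (1 - f[up]))
  out[dn] <- 0.5 - ((f[dn] - h[dn]) * (1 + f[dn] - h[dn])) /
    (4 * f[dn] * (1 - h[dn]))
  out
}

#' Screen participants by A' discriminability
#'
#' Marks for exclusion every participant whose A' falls strictly below the
#' threshold (default 0.7, so an A' of exactly 0.7 is kept).
#'
#' @param summaries data frame with one row per participant holding either
#'   rate columns \code{hit_rate} and \code{fa_rate}, or count columns
#'   \code{hits}, \code{misses}, \code{false_alarms},
#'   \code{correct_rejections} from which the rates are computed (false
#'   alarms are to unrelated lures).
#' @param threshold exclusion threshold on A'.
#' @return The input with added columns \code{a_prime} and \code{keep}.
#' @export
screen_participants <- function(summaries, threshold = 0.7) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (!all(c("hit_rate", "fa_rate") %in% names(summaries))) {
    need <- c("hits", "misses", "false_alarms", "correct_rejections")
    if (!all(need %in% names(summaries))) {
      stop("summaries must hold hit_rate/fa_rate or ",
           paste(need, collapse = "/"))
    }
    summaries$hit_rate <- summaries$hits /
      (summaries$hits + summaries$misses)
    summaries$fa_rate <- summaries$false_alarms /
      (summaries$false_alarms + summaries$correct_rejections)
  }
  summaries$a_prime <- a_prime(summaries$hit_rate, summaries$fa_rate)
  summaries$keep <- summaries$a_prime >= threshold
  summaries
}

#' Read per-participant recognition summaries from a TSV file
#'
#' Expected columns: \code{participant}, \code{hits}, \code{misses},
#' \code{false_alarms}, \code{correct_rejections}.
#'
#' @param path path to the tab-separated file (with header).
#' @export
read_recognition_summaries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write screening decisions to a TSV file
#'
#' @param screened output of [screen_participants()].
#' @param path output path.
#' @export
write_screening <- function(screened, path) {
  utils::write.table(screened, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' AIC evidence ratio
#'
#' Converts a nonnegative AIC difference into the relative likelihood
#' \eqn{\exp(\Delta AIC / 2)} that the lower-AIC model is closer (in
#' Kullback-Leibler distance) to the data-generating process than the
#' higher-AIC model. A difference of 2 gives a ratio of about 2.7; a
#' difference of 16 about 2981.
#'
#' @param delta_aic nonnegative AIC difference(s), oriented so the better
#'   (lower-AIC) model is the reference.
#' @return Evidence ratio(s) \eqn{\ge 1}.
#' @export
aic_evidence_ratio <- function(delta_aic) {
  if (any(!is.finite(delta_aic)) || any(delta_aic < 0)) {
    stop("delta_aic must be nonnegative (orient the difference so the ",
         "lower-AIC model is the reference)")
  }
  exp(delta_aic / 2)
}
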