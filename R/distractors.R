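#' Option selection rates for one item
#'
#' Counts how many candidates chose each option and converts to a
#' percentage of the whole candidate group. Omissions are never a
#' "selection": they are excluded from every numerator but stay in the
#' denominator, so option rates plus the omission rate total 100.
#'
#' @inheritParams score_matrix
#' @param item a single item id.
#' @return data frame of class `distractor_profile` with one row per option:
#'   `option`, `count`, `rate` (percent of all candidates), `is_correct`.
#'   Attributes: `item_id`, `n_candidates`, `omit_count`.
#' @export
option_selection_rates <- function(responses, key, item) {
  opts <- key_options(key, item)
  corr <- key_correct(key, item)
  ch <- responses[, item]
  n <- length(ch)
  cnt <- vapply(opts, function(o) sum(ch == o), integer(1))
  out <- data.frame(option = opts, count = unname(cnt),
                    rate = unname(100 * cnt / n),
                    is_correct = opts == corr,
                    stringsAsFactors = FALSE)
  attr(out, "item_id") <- item
  attr(out, "n_candidates") <- n
  attr(out, "omit_count") <- sum(ch == OMIT)
  class(out) <- c("distractor_profile", "data.frame")
  out
}

#' Non-functional distractor classification
#'
#' A distractor is non-functional (NF-D) at threshold `t` when its selection
#' rate is strictly below `t` percent of the candidates; a distractor at
#' exactly the threshold is functional. The two conventional thresholds are
#' 1 and 5 percent. Strictness makes NF-D sets nested:
#' `nfd_set(<1%)` is a subset of `nfd_set(<5%)`.
#'
#' @param profile a `distractor_profile` from [option_selection_rates()].
#' @param threshold selection-rate threshold in percent (default 1).
#' @return `nfd_set()`: the NF-D option labels. `is_nfd()`: logical per
#'   profile row (always `FALSE` for the correct option).
#' @export
nfd_set <- function(profile, threshold = 1) {
  profile$option[is_nfd(profile, threshold)]
}

#' @rdname nfd_set
#' @export
is_nfd <- function(profile, threshold = 1) {
  !profile$is_correct & profile$rate < threshold
}

#' Number of non-functional distractors per item
#'
#' @inheritParams score_matrix
#' @param threshold selection-rate threshold in percent.
#' @return named integer vector, one count in `0..4` per item.
#' @export
nfd_counts <- function(responses, key, threshold = 1) {
  vapply(colnames(responses), function(it) {
    sum(is_nfd(option_selection_rates(responses, key, it), threshold))
  }, integer(1))
}

#' Distribution of items by NF-D count
#'
#' Partitions the exam's items by how many of their distractors are
#' non-functional at the threshold.
#'
#' @inheritParams nfd_counts
#' @return data frame with columns `n_nfd` (0 to the maximum distractor
#'   count), `n_items`, `pct_items`; percentages sum to 100.
#' @export
nfd_count_distribution <- function(responses, key, threshold = 1) {
  cnt <- nfd_counts(responses, key, threshold)
  max_d <- max(lengths(lapply(colnames(responses),
                              function(it) key_distractors(key, it))))
  tab <- vapply(0:max_d, function(k) sum(cnt == k), integer(1))
  data.frame(n_nfd = 0:max_d, n_items = tab,
             pct_items = 100 * tab / length(cnt))
}

#' Histogram of distractor selection rates
#'
#' Bins every distractor of the exam by its selection rate. Never-selected
#' distractors (rate exactly 0) are reported as a separate `"never"` row;
#' the remaining bins are half-open `[lo, hi)` with the last bin closed at
#' 100. The default binning uses 1-point steps up to 10 percent and wider
#' bins above, where distractor rates thin out.
#'
#' @inheritParams nfd_counts
#' @param bin_edges strictly increasing numeric vector starting at 0 and
#'   ending at 100.
#' @return data frame with columns `bin`, `lo`, `hi`, `count`, `pct`
#'   (percent of all distractors). Counts total `4 * n_items` for 5-option
#'   exams.
#' @export
selection_rate_histogram <- function(responses, key,
                                     bin_edges = c(0:10, 15, 20, 30, 50, 100)) {
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 100)
    stop("bin_edges must increase strictly from 0 to 100", call. = FALSE)
  rates <- unlist(lapply(colnames(responses), function(it) {
    prof <- option_selection_rates(responses, key, it)
    prof$rate[!prof$is_correct]
  }))
  n <- length(rates)
  never <- sum(rates == 0)
  pos <- rates[rates > 0]
  nb <- length(bin_edges) - 1L
  idx <- findInterval(pos, bin_edges, rightmost.closed = TRUE)
  cnt <- vapply(seq_len(nb), function(b) sum(idx == b), integer(1))
  lab <- sprintf("[%g,%g%s", bin_edges[-length(bin_edges)], bin_edges[-1],
                 c(rep(")", nb - 1L), "]"))
  out <- data.frame(bin = c("never", lab),
                    lo = c(0, bin_edges[-length(bin_edges)]),
                    hi = c(0, bin_edges[-1]),
                    count = c(never, cnt))
  out$pct <- 100 * out$count / n
  out
}

#' Mean difficulty and discrimination by NF-D count
#'
#' Groups items by their number of non-functional distractors and reports
#' the group mean P-value and the Fisher-Z pooled mean discrimination —
#' the gradient that links easiness to distractor dysfunction (easy items
#' leave little traffic for their distractors).
#'
#' @inheritParams nfd_counts
#' @return data frame with columns `n_nfd`, `n_items`, `mean_p`, `mean_r`,
#'   one row per NF-D count present in the exam.
#' @export
stats_by_nfd_count <- function(responses, key, threshold = 1) {
  cnt <- nfd_counts(responses, key, threshold)
  p <- item_p_value(responses, key)
  r <- item_discrimination(responses, key)
  lev <- sort(unique(cnt))
  rows <- lapply(lev, function(k) {
    sel <- cnt == k
    data.frame(n_nfd = k, n_items = sum(sel), mean_p = mean(p[sel]),
               mean_r = fisher_mean_r(r[sel]))
  })
  do.call(rbind, rows)
}

#' Delta-median of a single distractor
#'
#' How far the median total score of the candidates who selected a
#' distractor departs from the median of the whole group, in raw
#' number-correct points. Negative values mean the distractor attracts
#' below-median (low-performing) candidates. The median of an even-sized
#' set is the mean of its two central values. Defined only when at least
#' one candidate selected the option; otherwise `NULL`.
#'
#' @inheritParams option_selection_rates
#' @param option a distractor label of the item.
#' @return one-row data frame (`item_id`, `option`, `delta_median`,
#'   `n_selectors`, `rate`) or `NULL` if nobody selected the option.
#' @export
delta_median <- function(responses, key, item, option) {
  if (option == key_correct(key, item))
    stop("delta-medians are defined for distractors, not the keyed answer",
         call. = FALSE)
  tot <- total_scores(responses, key)
  sel <- responses[, item] == option
  if (!any(sel)) return(NULL)
  data.frame(item_id = item, option = option,
             delta_median = stats::median(tot[sel]) - stats::median(tot),
             n_selectors = sum(sel),
             rate = 100 * sum(sel) / length(sel),
             stringsAsFactors = FALSE)
}

#' Delta-medians for every selected distractor of an exam
#'
#' @inheritParams score_matrix
#' @return data frame with one row per (item, distractor) pair that had at
#'   least one selector; columns as in [delta_median()].
#' @export
delta_medians <- function(responses, key) {
  rows <- lapply(colnames(responses), function(it) {
    recs <- lapply(key_distractors(key, it), function(op)
      delta_median(responses, key, it, op))
    do.call(rbind, recs)
  })
  do.call(rbind, rows)
}

#' Summary of delta-medians by functional class
#'
#' Pools per-distractor delta-medians across items and summarises them
#' separately for functional (rate at or above the threshold) and
#' non-functional (rate below) distractors: the contrast showing that even
#' rarely selected distractors specifically attract low performers.
#'
#' @inheritParams nfd_counts
#' @return data frame with columns `class` (`"F-D"`, `"NF-D"`), `n`,
#'   `median`, `min`, `max`. Classes with no record are omitted.
#' @export
delta_median_summary <- function(responses, key, threshold = 1) {
  dm <- delta_medians(responses, key)
  if (is.null(dm) || !nrow(dm)) return(NULL)
  dm$class <- ifelse(dm$rate < threshold, "NF-D", "F-D")
  rows <- lapply(c("F-D", "NF-D"), function(cl) {
    d <- dm$delta_median[dm$class == cl]
    if (!length(d)) return(NULL)
    data.frame(class = cl, n = length(d), median = stats::median(d),
               min = min(d), max = max(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
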