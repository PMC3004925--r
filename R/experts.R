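#' Hit decision for one expert's marks on one item
#'
#' A hit means the expert's least-plausible mark (rank 1) lands on a
#' distractor that is truly non-functional by selection rate. When the
#' expert tied two options as equally implausible (two rank-1 marks), one
#' of them is picked uniformly at random before testing — the seed makes
#' that pick reproducible.
#'
#' @param marks data frame with columns `option`, `rank` for a single
#'   (expert, item) pair.
#' @param nfd_set character vector of the item's NF-D labels (non-empty:
#'   hit analysis is only defined for items with at least one NF-D).
#' @param seed integer seed for tie resolution.
#' @return list with `hit` (logical), `picked` (the rank-1 option tested)
#'   and `tie_resolved` (whether a random pick was needed).
#' @export
expert_hit <- function(marks, nfd_set, seed = 1) {
  if (!length(nfd_set))
    stop("hit analysis needs at least one NF-D on the item", call. = FALSE)
  rank1 <- marks$option[marks$rank == 1]
  if (!length(rank1) || length(rank1) > 2)
    stop("marks must contain one or two rank-1 options", call. = FALSE)
  tie <- length(rank1) == 2L
  picked <- if (tie) local_seed(seed, sample(rank1, 1L)) else rank1
  list(hit = picked %in% nfd_set, picked = picked, tie_resolved = tie)
}

# Stable per-(expert, item) seed offset so tie resolution is reproducible
# independently of the order ratings are processed in.
pair_seed <- function(base_seed, expert_id, item_id) {
  h <- sum(utf8ToInt(paste(expert_id, item_id, sep = "\r")) *
             seq_along(utf8ToInt(paste(expert_id, item_id, sep = "\r"))))
  (as.integer(base_seed) + (h %% 1000003L)) %% .Machine$integer.max
}

#' Individual-expert hit statistics
#'
#' Restricted to items with at least one NF-D at the threshold, computes
#' the per-item proportion of experts whose least-plausible mark hit an
#' NF-D, the overall mean and range of those proportions, and the Pearson
#' correlation between per-item hit proportion and NF-D count (experts hit
#' more easily when more distractors are non-functional).
#'
#' @param ratings an [expert_ratings()] table.
#' @inheritParams nfd_counts
#' @param seed integer seed for tie resolution (a distinct stream per
#'   expert-item pair is derived from it).
#' @return list with `per_item` (data frame: `item_id`, `n_experts`,
#'   `n_hits`, `hit_prop`, `n_nfd`), `mean_hit_prop`, `min_hit_prop`,
#'   `max_hit_prop`, `correlation` (NA when either variable is constant)
#'   and `n_items`.
#' @export
hit_statistics <- function(ratings, responses, key, threshold = 1, seed = 1) {
  cnt <- nfd_counts(responses, key, threshold)
  eligible <- names(cnt)[cnt >= 1L]
  rows <- lapply(eligible, function(it) {
    nfds <- nfd_set(option_selection_rates(responses, key, it), threshold)
    rr <- ratings[ratings$item_id == it, , drop = FALSE]
    if (!nrow(rr)) return(NULL)
    experts <- unique(rr$expert_id)
    hits <- vapply(experts, function(ex) {
      marks <- rr[rr$expert_id == ex, , drop = FALSE]
      expert_hit(marks, nfds, seed = pair_seed(seed, ex, it))$hit
    }, logical(1))
    data.frame(item_id = it, n_experts = length(experts),
               n_hits = sum(hits), hit_prop = mean(hits),
               n_nfd = unname(cnt[it]), stringsAsFactors = FALSE)
  })
  per_item <- do.call(rbind, rows)
  if (is.null(per_item) || !nrow(per_item))
    stop("no ratings on items with at least one NF-D", call. = FALSE)
  corr <- if (nrow(per_item) >= 2 &&
              stats::sd(per_item$hit_prop) > 0 &&
              stats::sd(per_item$n_nfd) > 0)
    stats::cor(per_item$hit_prop, per_item$n_nfd) else NA_real_
  list(per_item = per_item,
       mean_hit_prop = mean(per_item$hit_prop),
       min_hit_prop = min(per_item$hit_prop),
       max_hit_prop = max(per_item$hit_prop),
       correlation = corr,
       n_items = nrow(per_item))
}

#' Panel rating of one item (mode of the experts)
#'
#' Aggregates the experts' marks into a committee decision. Options are
#' scored by weighted votes — a rank-1 (least plausible) mark counts 2
#' points, a rank-2 mark 1 point — and the top two scores give the first
#' and second removal candidates. Ties are broken by option-label order and
#' flagged. With `second_from_rank2_mode = TRUE` the second removal is
#' instead the plain mode of the rank-2 marks (excluding the first
#' removal).
#'
#' @param ratings an [expert_ratings()] table (any items; only `item`'s
#'   rows are used).
#' @param key an [answer_key()].
#' @param item a single item id.
#' @param second_from_rank2_mode alternative second-removal rule.
#' @return one-row data frame: `item_id`, `first_removal`, `second_removal`,
#'   `tie_first`, `tie_second`.
#' @export
panel_mode <- function(ratings, key, item, second_from_rank2_mode = FALSE) {
  rr <- ratings[ratings$item_id == item, , drop = FALSE]
  if (!nrow(rr)) stop(sprintf("no ratings for item %s", item), call. = FALSE)
  dis <- key_distractors(key, item)
  score <- function(weights) {
    s <- vapply(dis, function(op) {
      sum(weights[rr$rank[rr$option == op]])
    }, numeric(1))
    names(s) <- dis
    s
  }
  s <- score(c(2, 1))
  ord <- order(-s, dis)
  first <- dis[ord[1]]
  tie_first <- sum(s == s[ord[1]]) > 1L
  if (second_from_rank2_mode) {
    s2 <- score(c(0, 1))
    s2 <- s2[names(s2) != first]
    rest <- names(s2)[order(-s2, names(s2))]
    second <- rest[1]
    tie_second <- sum(s2 == max(s2)) > 1L
  } else {
    rest <- dis[ord[-1]]
    second <- rest[1]
    tie_second <- sum(s == s[ord[2]]) > 1L
  }
  data.frame(item_id = item, first_removal = first, second_removal = second,
             tie_first = tie_first, tie_second = tie_second,
             stringsAsFactors = FALSE)
}

#' Panel ratings for every rated item
#'
#' @inheritParams panel_mode
#' @return data frame, one [panel_mode()] row per item present in
#'   `ratings`, in answer-key order.
#' @export
panel_ratings <- function(ratings, key, second_from_rank2_mode = FALSE) {
  items <- key$item_id[key$item_id %in% unique(ratings$item_id)]
  do.call(rbind, lapply(items, function(it)
    panel_mode(ratings, key, it, second_from_rank2_mode)))
}

#' Panel hit rate
#'
#' Proportion of items (among those with at least one NF-D at the
#' threshold) where the panel's first removal is a non-functional
#' distractor. Committees beat individual experts here: majority
#' aggregation averages out idiosyncratic misses.
#'
#' @param panel a data frame from [panel_ratings()].
#' @inheritParams nfd_counts
#' @return list with `n_hits`, `n_items`, `pct` (nearest percent).
#' @export
panel_hit_rate <- function(panel, responses, key, threshold = 1) {
  cnt <- nfd_counts(responses, key, threshold)
  eligible <- intersect(panel$item_id, names(cnt)[cnt >= 1L])
  if (!length(eligible))
    stop("no rated items with at least one NF-D", call. = FALSE)
  hits <- vapply(eligible, function(it) {
    nfds <- nfd_set(option_selection_rates(responses, key, it), threshold)
    panel$first_removal[panel$item_id == it] %in% nfds
  }, logical(1))
  list(n_hits = sum(hits), n_items = length(eligible),
       pct = percent(sum(hits), length(eligible), digits = 0))
}

#' Elimination plan from panel ratings
#'
#' Converts panel first/second removals into an `elimination_plan`
#' consumable by [eliminate()] and [run_models()], yielding the
#' expert-recommendation variant of the option-reduction comparison.
#'
#' @param panel a data frame from [panel_ratings()].
#' @param n_remove 1 (first removal only) or 2 (first and second).
#' @return an `elimination_plan` (named list item -> removal labels).
#' @export
panel_plan <- function(panel, n_remove = 2) {
  stopifnot(n_remove %in% 1:2)
  plan <- lapply(seq_len(nrow(panel)), function(i) {
    utils::head(c(panel$first_removal[i], panel$second_removal[i]), n_remove)
  })
  names(plan) <- panel$item_id
  structure(plan, class = "elimination_plan")
}
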