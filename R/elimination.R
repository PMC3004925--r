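#' Elimination models A-D
#'
#' The four option-reduction scenarios: remove the least chosen distractor
#' (leaving 3 distractors) or the two least chosen (leaving 2), and
#' reallocate the affected candidates either uniformly at random over the
#' remaining options or deterministically to the correct answer. The two
#' reallocation rules bracket the plausible range of real candidate
#' behaviour.
#'
#' * `A`: 1 removal, RANDOM reallocation (3 distractors remain)
#' * `B`: 1 removal, CORRECT reallocation
#' * `C`: 2 removals, RANDOM reallocation (2 distractors remain)
#' * `D`: 2 removals, CORRECT reallocation
#'
#' @param label one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return a list of class `elimination_model` with elements `label`,
#'   `n_removed` (1 or 2) and `reallocation` (`"RANDOM"` or `"CORRECT"`).
#' @export
elimination_model <- function(label = c("A", "B", "C", "D")) {
  label <- match.arg(label)
  spec <- list(A = list(1L, "RANDOM"),  B = list(1L, "CORRECT"),
               C = list(2L, "RANDOM"),  D = list(2L, "CORRECT"))[[label]]
  structure(list(label = label, n_removed = spec[[1]],
                 reallocation = spec[[2]]),
            class = "elimination_model")
}

#' Rank an item's distractors by selection count
#'
#' Orders the distractors by ascending selection count, so the first
#' element is the least-chosen distractor and the second the second-least.
#' Ties are broken deterministically by option-label order, making removal
#' plans reproducible.
#'
#' @param profile a `distractor_profile` from [option_selection_rates()].
#' @return character vector of distractor labels, ascending by count.
#' @export
rank_distractors <- function(profile) {
  d <- profile[!profile$is_correct, ]
  d$option[order(d$count, d$option)]
}

#' Statistics-based elimination plan
#'
#' For every item, identifies the distractors to remove from the original
#' (unmodified) selection counts: the least chosen first, then the second
#' least. With `nfd_only = TRUE` the plan is restricted to distractors
#' classified non-functional at `threshold`, so items may lose fewer than
#' `n_remove` distractors (or none) — the variant yielding variable
#' distractor counts per item.
#'
#' @inheritParams score_matrix
#' @param n_remove how many distractors to plan for removal (1 or 2).
#' @param nfd_only restrict removals to NF-Ds at `threshold`.
#' @param threshold NF-D threshold in percent, used when `nfd_only = TRUE`.
#' @return named list of class `elimination_plan`: item id -> character
#'   vector of distractor labels in removal order (length `n_remove`, or
#'   less under `nfd_only`).
#' @export
statistics_plan <- function(responses, key, n_remove = 2, nfd_only = FALSE,
                            threshold = 1) {
  stopifnot(n_remove %in% 1:2)
  plan <- lapply(colnames(responses), function(it) {
    prof <- option_selection_rates(responses, key, it)
    ranked <- rank_distractors(prof)
    if (nfd_only) ranked <- ranked[ranked %in% nfd_set(prof, threshold)]
    utils::head(ranked, n_remove)
  })
  names(plan) <- colnames(responses)
  structure(plan, class = "elimination_plan")
}

#' Apply an elimination plan to a response matrix
#'
#' Removes each planned distractor in order and reallocates the candidates
#' who had chosen it:
#'
#' * `CORRECT` mode moves every such candidate to the keyed answer.
#' * `RANDOM` mode reassigns each independently and uniformly over the
#'   options remaining after that removal (4 options after the first
#'   removal, 3 after the second).
#'
#' Removals are applied sequentially but both targets come from the
#' original matrix (see [statistics_plan()]); under RANDOM mode a candidate
#' reallocated onto the second-least distractor in step one is reallocated
#' again in step two. Removing a distractor nobody chose alters no
#' responses, so such items pass through unchanged. Candidates who chose a
#' non-removed option — and all omissions — are untouched.
#'
#' @inheritParams score_matrix
#' @param plan an `elimination_plan`; only the first `model$n_removed`
#'   entries per item are used.
#' @param model an [elimination_model()] or its label (`"A"`-`"D"`).
#' @param seed integer seed; required in RANDOM mode, where it makes the
#'   reallocation reproducible.
#' @param random_over_five if `TRUE`, RANDOM mode reproduces a literal
#'   uniform draw over all five original option codes (so a candidate can
#'   be "reallocated" onto a removed option or back onto the same one)
#'   instead of drawing over the remaining options; provided for
#'   comparison, off by default.
#' @return a new [response_matrix()]; unaffected cells are bit-identical.
#' @export
eliminate <- function(responses, key, plan, model, seed = NULL,
                      random_over_five = FALSE) {
  if (is.character(model)) model <- elimination_model(model)
  if (model$reallocation == "RANDOM" && is.null(seed))
    stop("RANDOM reallocation requires a seed", call. = FALSE)
  out <- unclass(responses)
  apply_plan <- function(out) {
    for (it in names(plan)) {
      removals <- utils::head(plan[[it]], model$n_removed)
      if (!length(removals)) next
      corr <- key_correct(key, it)
      if (any(removals == corr))
        stop(sprintf("item %s: plan removes the keyed answer", it),
             call. = FALSE)
      remaining <- key_options(key, it)
      for (d in removals) {
        remaining <- setdiff(remaining, d)
        idx <- which(out[, it] == d)
        if (!length(idx)) next   # never-chosen distractor: no-op
        if (model$reallocation == "CORRECT") {
          out[idx, it] <- corr
        } else {
          pool <- if (random_over_five) key_options(key, it) else remaining
          out[idx, it] <- pool[sample.int(length(pool), length(idx),
                                          replace = TRUE)]
        }
      }
    }
    out
  }
  out <- if (model$reallocation == "RANDOM") local_seed(seed, apply_plan(out))
         else apply_plan(out)
  response_matrix(out)
}

#' Compare exam statistics across elimination models
#'
#' Produces the comparison table at the heart of the option-reduction
#' analysis: one row for the original 5-option exam ("4 distractors") and
#' one per requested model, each with the mean item P-value, the Fisher-Z
#' pooled mean discrimination, Cronbach's alpha and the Spearman-Brown
#' reliability standardized to 100 items. The original row is computed
#' before any modification.
#'
#' @inheritParams score_matrix
#' @param models character vector of model labels to run.
#' @param seed integer seed driving the RANDOM-mode models (each model gets
#'   a distinct stream derived from it).
#' @param plan an `elimination_plan`; defaults to the statistics-based plan
#'   from the original matrix. Pass a panel-derived plan (see
#'   [panel_plan()]) for the expert-recommendation variant.
#' @return data frame with columns `model`, `pct_correct`, `discrimination`,
#'   `reliability`, `std_reliability_100`.
#' @export
run_models <- function(responses, key, models = c("A", "B", "C", "D"),
                       seed = 1, plan = NULL) {
  if (is.null(plan)) plan <- statistics_plan(responses, key, n_remove = 2)
  base <- exam_stats(responses, key)
  rows <- list(cbind(model = "4 distractors",
                     base[c("pct_correct", "discrimination", "reliability",
                            "std_reliability_100")]))
  desc <- c(A = "A) 3 distractors, random",
            B = "B) 3 distractors, right answer",
            C = "C) 2 distractors, random",
            D = "D) 2 distractors, right answer")
  for (m in models) {
    mod <- elimination_model(m)
    newr <- eliminate(responses, key, plan, mod,
                      seed = seed + match(m, LETTERS))
    st <- exam_stats(newr, key)
    rows[[length(rows) + 1L]] <-
      cbind(model = desc[[m]],
            st[c("pct_correct", "discrimination", "reliability",
                 "std_reliability_100")])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
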