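#' Configuration for the synthetic exam generator
#'
#' The generator emulates a large one-best-answer licensing examination:
#' roughly 600-650 candidates, 41-57 five-option items, a realistic spread
#' of distractor selection rates (about a third of distractors drawing
#' fewer than 1% of candidates and a fraction never selected), and
#' implausible distractors that specifically attract low-ability
#' candidates.
#'
#' Responses follow a nominal-response (softmax) choice model: candidate
#' `c` with ability `theta_c ~ N(0,1)` chooses option `k` of item `i` with
#' probability proportional to `exp(alpha_k * theta_c + beta_k)`. The
#' correct option carries a positive ability loading (slope `a_i`) and an
#' intercept `b_i` controlling easiness; distractors carry non-positive
#' loadings, so their selectors sit below the ability median — more so for
#' designed non-functional distractors, whose strongly negative loading
#' and low intercept produce both rarity and the low-ability selector
#' profile seen in delta-medians.
#'
#' @param n_candidates candidates per exam (default 620).
#' @param n_items items per exam (default 55).
#' @param difficulty_mean,difficulty_sd distribution of the correct
#'   option's intercept `b_i` (higher mean = easier exam).
#' @param slope_mean,slope_sd distribution of the correct option's ability
#'   loading `a_i` (truncated below at 0.3 to keep discrimination positive).
#' @param fd_beta_mean,fd_beta_sd intercepts of functional distractors.
#' @param fd_alpha ability loading of functional distractors (<= 0).
#' @param nfd_beta_mean,nfd_beta_sd intercepts of designed non-functional
#'   distractors (far below the functional ones).
#' @param nfd_alpha ability loading of designed NF-Ds (strongly negative:
#'   only weak candidates are drawn to them).
#' @param nfd_count_probs probabilities of an item having 0..4 designed
#'   NF-Ds; the default mirrors the mix observed in large medical exams
#'   (about 30% of items with none, a 31.5% overall NF-D fraction).
#' @param never_prob fraction of designed NF-Ds made so implausible they
#'   are never selected (intercept `never_beta`).
#' @param never_beta intercept used for never-selected distractors; -30
#'   underflows the choice probability to numerical zero.
#' @param omit_rate probability a response is replaced by an omission
#'   (default 0: items were compulsory in the emulated exams).
#' @return a list of class `exam_config`.
#' @export
exam_config <- function(n_candidates = 620,
                        n_items = 55,
                        difficulty_mean = 2.6,
                        difficulty_sd = 0.8,
                        slope_mean = 0.5,
                        slope_sd = 0.125,
                        fd_beta_mean = 0,
                        fd_beta_sd = 0.4,
                        fd_alpha = -0.15,
                        nfd_beta_mean = -4.5,
                        nfd_beta_sd = 0.4,
                        nfd_alpha = -1.0,
                        nfd_count_probs = c(0.303, 0.319, 0.231, 0.113, 0.035),
                        never_prob = 0.12,
                        never_beta = -30,
                        omit_rate = 0) {
  stopifnot(n_candidates >= 2, n_items >= 2,
            length(nfd_count_probs) == 5, all(nfd_count_probs >= 0),
            never_prob >= 0, never_prob <= 1,
            omit_rate >= 0, omit_rate < 1,
            fd_alpha <= 0, nfd_alpha <= 0)
  cfg <- as.list(environment())
  cfg$nfd_count_probs <- nfd_count_probs / sum(nfd_count_probs)
  structure(cfg, class = "exam_config")
}

# Softmax choice probabilities for one item: candidates x options.
choice_probabilities <- function(theta, alpha, beta) {
  u <- outer(theta, alpha) + matrix(beta, length(theta), length(beta),
                                    byrow = TRUE)
  u <- exp(u - apply(u, 1, max))
  u / rowSums(u)
}

#' Generate a synthetic exam
#'
#' Draws item parameters and candidate abilities per [exam_config()] and
#' simulates every response from the nominal-response choice model. The
#' returned ground truth records each option's generating parameters and
#' which distractors were designed non-functional, so recovery of the
#' design by the selection-rate analyses can be checked.
#'
#' @param config an [exam_config()].
#' @param seed integer seed; the same seed reproduces the exam exactly.
#' @return list with elements `responses` (a [response_matrix()]), `key`
#'   (an [answer_key()]) and `truth` (data frame: `item_id`, `option`,
#'   `is_correct`, `alpha`, `beta`, `designed_nfd`).
#' @export
generate_exam <- function(config = exam_config(), seed = 1) {
  local_seed(seed, {
    n <- config$n_candidates
    m <- config$n_items
    opts <- LETTERS[1:5]
    cand <- sprintf("c%04d", seq_len(n))
    items <- sprintf("i%02d", seq_len(m))
    theta <- stats::rnorm(n)
    correct <- sample(opts, m, replace = TRUE)
    key <- answer_key(items, correct)
    resp <- matrix(NA_character_, n, m, dimnames = list(cand, items))
    truth <- vector("list", m)
    for (j in seq_len(m)) {
      a <- max(stats::rnorm(1, config$slope_mean, config$slope_sd), 0.3)
      b <- stats::rnorm(1, config$difficulty_mean, config$difficulty_sd)
      n_nfd <- sample(0:4, 1, prob = config$nfd_count_probs)
      dis <- setdiff(opts, correct[j])
      nfd_flags <- c(rep(TRUE, n_nfd), rep(FALSE, 4 - n_nfd))[sample.int(4)]
      alpha <- ifelse(nfd_flags, config$nfd_alpha, config$fd_alpha)
      beta <- ifelse(nfd_flags,
                     stats::rnorm(4, config$nfd_beta_mean, config$nfd_beta_sd),
                     stats::rnorm(4, config$fd_beta_mean, config$fd_beta_sd))
      never <- nfd_flags & stats::runif(4) < config$never_prob
      beta[never] <- config$never_beta
      opt_alpha <- numeric(5); opt_beta <- numeric(5)
      names(opt_alpha) <- names(opt_beta) <- opts
      opt_alpha[correct[j]] <- a;  opt_beta[correct[j]] <- b
      opt_alpha[dis] <- alpha;     opt_beta[dis] <- beta
      pr <- choice_probabilities(theta, opt_alpha, opt_beta)
      cum <- pr %*% upper.tri(diag(5), diag = TRUE)
      pick <- rowSums(cum < stats::runif(n)) + 1L
      ch <- opts[pick]
      if (config$omit_rate > 0)
        ch[stats::runif(n) < config$omit_rate] <- OMIT
      resp[, j] <- ch
      truth[[j]] <- data.frame(
        item_id = items[j], option = opts,
        is_correct = opts == correct[j],
        alpha = unname(opt_alpha), beta = unname(opt_beta),
        designed_nfd = opts %in% dis[nfd_flags],
        stringsAsFactors = FALSE)
    }
    list(responses = response_matrix(resp, key = key), key = key,
         truth = do.call(rbind, truth))
  })
}

#' Configuration for the synthetic expert-ratings generator
#'
#' Emulates a least-plausibility survey: items are split into two blocks
#' and every expert rates one block, so each item collects
#' `n_experts_per_block` ratings. An expert of accuracy `p` marks the truly
#' least plausible distractor (lowest generating intercept `beta`) as rank
#' 1 with probability `p`, otherwise a uniformly random other distractor;
#' the rank-2 mark follows the same rule on the remaining distractors.
#' With probability `tie_prob` the two marks are declared equally
#' implausible (both rank 1).
#'
#' @param n_experts_per_block experts rating each block (default 18).
#' @param accuracy probability a mark lands on the truly least plausible
#'   remaining distractor; 0.25 is chance level over four distractors.
#' @param tie_prob probability of an equal-implausibility tie.
#' @return a list of class `rating_config`.
#' @export
rating_config <- function(n_experts_per_block = 18, accuracy = 0.7,
                          tie_prob = 0.1) {
  stopifnot(n_experts_per_block >= 1,
            accuracy >= 0, accuracy <= 1, tie_prob >= 0, tie_prob <= 1)
  structure(as.list(environment()), class = "rating_config")
}

#' Generate synthetic expert ratings
#'
#' @param truth ground-truth table from [generate_exam()] (uses the
#'   generating `beta` as the plausibility ordering).
#' @param key the matching [answer_key()].
#' @param config a [rating_config()].
#' @param seed integer seed.
#' @return an [expert_ratings()] table with a `block` column.
#' @export
generate_ratings <- function(truth, key, config = rating_config(), seed = 1) {
  local_seed(seed, {
    items <- unique(truth$item_id)
    blocks <- rep(c("A", "B"), length.out = length(items))
    blocks <- blocks[sample.int(length(items))]
    names(blocks) <- items
    nb <- config$n_experts_per_block
    experts <- list(A = sprintf("eA%02d", seq_len(nb)),
                    B = sprintf("eB%02d", seq_len(nb)))
    rows <- list()
    for (it in items) {
      tt <- truth[truth$item_id == it & !truth$is_correct, ]
      dis <- tt$option
      betas <- tt$beta
      # plausibility order: lowest beta = least plausible; label tie-break
      for (ex in experts[[blocks[[it]]]]) {
        pool <- dis; pb <- betas
        pick_one <- function() {
          truly <- pool[order(pb, pool)][1]
          if (stats::runif(1) < config$accuracy) truly
          else sample(setdiff(pool, truly), 1)
        }
        first <- pick_one()
        pb <- pb[pool != first]; pool <- pool[pool != first]
        truly2 <- pool[order(pb, pool)][1]
        second <- if (stats::runif(1) < config$accuracy) truly2
                  else sample(setdiff(pool, truly2), 1)
        ranks <- if (stats::runif(1) < config$tie_prob) c(1L, 1L) else c(1L, 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          expert_id = ex, item_id = it, option = c(first, second),
          rank = ranks, block = blocks[[it]], stringsAsFactors = FALSE)
      }
    }
    expert_ratings(do.call(rbind, rows), key = key)
  })
}
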