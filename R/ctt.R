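#' Score a response matrix against its key
#'
#' @param responses a [response_matrix()].
#' @param key an [answer_key()] covering every item of `responses`.
#' @return integer 0/1 matrix of the same shape; omissions score 0.
#' @export
score_matrix <- function(responses, key) {
  items <- colnames(responses)
  correct <- vapply(items, function(it) key_correct(key, it), character(1))
  sc <- responses == matrix(correct, nrow(responses), ncol(responses),
                            byrow = TRUE)
  storage.mode(sc) <- "integer"
  sc
}

#' Total number-correct scores per candidate
#'
#' One point per correct answer (omissions and wrong options score 0).
#'
#' @inheritParams score_matrix
#' @return named integer vector, one score per candidate, in `[0, n_items]`.
#' @export
total_scores <- function(responses, key) {
  rowSums(score_matrix(responses, key))
}

#' Item difficulty (P-value)
#'
#' Percentage of candidates answering the item correctly; higher means
#' easier. The denominator is all candidates, so omissions count as
#' incorrect.
#'
#' @inheritParams score_matrix
#' @param item a single item id, or `NULL` for all items.
#' @return percentage(s) in `[0, 100]`.
#' @export
item_p_value <- function(responses, key, item = NULL) {
  sc <- score_matrix(responses, key)
  p <- 100 * colMeans(sc)
  if (is.null(item)) p else unname(p[item])
}

#' Item discrimination (point-biserial selectivity)
#'
#' Pearson correlation between an item's 0/1 correctness vector and the
#' candidates' score on the rest of the exam. The item-rest (corrected)
#' form is the default; it avoids the self-correlation inflation of the
#' item-total form on short exams. Returns `NA` when either vector is
#' constant (e.g. an item everyone answers correctly), since the
#' correlation is then undefined.
#'
#' @inheritParams item_p_value
#' @param type `"item-rest"` (default) correlates with the total score
#'   minus the item's own point; `"item-total"` with the plain total.
#' @return correlation(s) in `[-1, 1]`, or `NA` where undefined.
#' @export
item_discrimination <- function(responses, key, item = NULL,
                                type = c("item-rest", "item-total")) {
  type <- match.arg(type)
  sc <- score_matrix(responses, key)
  tot <- rowSums(sc)
  one <- function(j) {
    x <- sc[, j]
    y <- if (type == "item-rest") tot - x else tot
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  r <- vapply(colnames(sc), one, numeric(1))
  if (is.null(item)) r else unname(r[item])
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of the exam's 0/1 item scores:
#' `alpha = k/(k-1) * (1 - sum(item variances) / total-score variance)`.
#' Population (n-denominator) variances are used throughout; the choice
#' cancels in the ratio but is fixed so intermediate outputs reproduce.
#'
#' @inheritParams score_matrix
#' @return alpha (at most 1), or `NA` when the total-score variance is zero.
#' @export
cronbach_alpha <- function(responses, key) {
  sc <- score_matrix(responses, key)
  k <- ncol(sc)
  if (k < 2L) stop("alpha needs at least 2 items", call. = FALSE)
  pvar <- function(x) mean((x - mean(x))^2)
  vt <- pvar(rowSums(sc))
  if (vt == 0) return(NA_real_)
  vi <- sum(apply(sc, 2, pvar))
  (k / (k - 1)) * (1 - vi / vt)
}

#' Fisher-Z pooled mean of correlations
#'
#' Correlations are averaged on the `atanh` scale and transformed back:
#' `tanh(mean(atanh(r)))`. Undefined entries (`NA`) and entries with
#' `|r| = 1` (where `atanh` diverges) are dropped before pooling.
#'
#' @param rs numeric vector of correlations.
#' @return the pooled correlation, or `NA` if no finite entries remain.
#' @export
fisher_mean_r <- function(rs) {
  rs <- rs[!is.na(rs) & abs(rs) < 1]
  if (!length(rs)) return(NA_real_)
  tanh(mean(atanh(rs)))
}

#' Spearman-Brown reliability standardization
#'
#' Projects a reliability to a different test length:
#' `rho_k = k * rho / (1 + (k - 1) * rho)` with
#' `k = target_items / n_items`. With the default target of 100 items this
#' gives the "standard reliability" that makes exams of different lengths
#' comparable.
#'
#' @param reliability reliability of the observed exam, in `[0, 1]`.
#' @param n_items number of items in the observed exam.
#' @param target_items projected test length (default 100).
#' @return the standardized reliability.
#' @export
spearman_brown <- function(reliability, n_items, target_items = 100) {
  if (any(is.na(reliability))) return(NA_real_)
  if (any(reliability < 0))
    stop("negative reliability cannot be standardized", call. = FALSE)
  if (n_items < 1) stop("n_items must be >= 1", call. = FALSE)
  k <- target_items / n_items
  ifelse(reliability == 1, 1, (k * reliability) / (1 + (k - 1) * reliability))
}

#' Exam-level summary statistics
#'
#' Computes the row an exam contributes to a comparison report: mean item
#' P-value (simple mean), Fisher-Z pooled mean item-rest discrimination,
#' Cronbach's alpha, and alpha standardized to 100 items.
#'
#' @inheritParams score_matrix
#' @param target_items projected length for the standardized reliability.
#' @return one-row data frame with columns `pct_correct`, `discrimination`,
#'   `reliability`, `std_reliability_100`, `n_items`, `n_candidates`.
#' @export
exam_stats <- function(responses, key, target_items = 100) {
  p <- item_p_value(responses, key)
  r <- item_discrimination(responses, key)
  a <- cronbach_alpha(responses, key)
  data.frame(
    pct_correct = mean(p),
    discrimination = fisher_mean_r(r),
    reliability = a,
    std_reliability_100 = if (is.na(a) || a < 0) NA_real_ else
      spearman_brown(a, ncol(responses), target_items),
    n_items = ncol(responses),
    n_candidates = nrow(responses))
}
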