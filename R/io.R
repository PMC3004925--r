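#' Read candidate responses from CSV
#'
#' Two layouts are accepted. Long format has columns
#' `candidate_id,item_id,choice`, one row per answered item. Wide format has
#' a `candidate_id` column followed by one column per item whose cells are
#' the chosen option labels. Both produce the identical in-memory
#' [response_matrix()].
#'
#' @param path CSV file path (UTF-8, comma-separated).
#' @param format `"auto"` (default; long is recognised by its exact column
#'   names), `"long"` or `"wide"`.
#' @param key optional [answer_key()]; cells are validated against each
#'   item's declared option set when given.
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, format = c("auto", "long", "wide"),
                           key = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  long_names <- c("candidate_id", "item_id", "choice")
  if (format == "auto")
    format <- if (identical(names(df), long_names)) "long" else "wide"
  if (format == "long") {
    if (!identical(names(df), long_names))
      stop("long format requires columns candidate_id,item_id,choice",
           call. = FALSE)
    cands <- unique(df$candidate_id)
    items <- unique(df$item_id)
    if (anyDuplicated(paste(df$candidate_id, df$item_id, sep = "\r"))) {
      dup <- df[duplicated(paste(df$candidate_id, df$item_id, sep = "\r")), ]
      stop(sprintf("duplicate entry for candidate %s, item %s",
                   dup$candidate_id[1], dup$item_id[1]), call. = FALSE)
    }
    m <- matrix(NA_character_, length(cands), length(items),
                dimnames = list(cands, items))
    m[cbind(match(df$candidate_id, cands), match(df$item_id, items))] <-
      df$choice
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("candidate %s has no entry for item %s",
                   cands[miss[1]], items[miss[2]]), call. = FALSE)
    }
  } else {
    if (names(df)[1] != "candidate_id")
      stop("wide format requires a leading candidate_id column", call. = FALSE)
    if (anyDuplicated(df$candidate_id))
      stop(sprintf("duplicate entry for candidate %s",
                   df$candidate_id[anyDuplicated(df$candidate_id)]),
           call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$candidate_id
  }
  response_matrix(m, key = key)
}

#' Write candidate responses to CSV
#'
#' @param responses a [response_matrix()].
#' @param path output file path.
#' @param format `"long"` or `"wide"` (see [read_responses()]).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    df <- data.frame(
      candidate_id = rep(rownames(responses), times = ncol(responses)),
      item_id = rep(colnames(responses), each = nrow(responses)),
      choice = as.vector(responses),
      stringsAsFactors = FALSE)
    df <- df[order(match(df$candidate_id, rownames(responses)),
                   match(df$item_id, colnames(responses))), ]
  } else {
    df <- data.frame(candidate_id = rownames(responses),
                     unclass(responses)[, , drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- c("candidate_id", colnames(responses))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an answer key from CSV
#'
#' Expects columns `item_id,correct,options` with option sets written as
#' e.g. `ABCDE`.
#'
#' @param path CSV file path.
#' @return an [answer_key()].
#' @export
read_key <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("item_id", "correct", "options")
  if (!all(need %in% names(df)))
    stop("answer key requires columns item_id,correct,options", call. = FALSE)
  answer_key(df$item_id, df$correct, df$options)
}

#' @rdname read_key
#' @param key an [answer_key()] to write.
#' @export
write_key <- function(key, path) {
  utils::write.csv(as.data.frame(key)[c("item_id", "correct", "options")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read expert least-plausibility ratings from CSV
#'
#' Expects columns `expert_id,item_id,option,rank` (optional `block`).
#' Per expert and item the marks must be one rank-1 plus one rank-2, or two
#' rank-1 marks (a tie); never more than two, never on the keyed answer.
#'
#' @param path CSV file path.
#' @param key optional [answer_key()] used to reject marks on correct answers.
#' @return an [expert_ratings()] data frame.
#' @export
read_expert_ratings <- function(path, key = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expert_ratings(df, key = key)
}

#' @rdname read_expert_ratings
#' @param ratings an [expert_ratings()] table to write.
#' @export
write_expert_ratings <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a report table to CSV with fixed formatting
#'
#' Reports are written bit-stably: column order is preserved and every
#' numeric column is printed with a fixed number of decimals so repeated
#' writes of the same table are byte-identical.
#'
#' @param report a data frame.
#' @param path output file path.
#' @param digits decimal places used for every numeric column (default 2,
#'   the precision used for percentages and reliabilities throughout).
#' @return `path`, invisibly.
#' @export
write_table <- function(report, path, digits = 2) {
  out <- report
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- sprintf(paste0("%.", digits, "f"), out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @return `read_table()` returns the table with numeric columns restored.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && all(grepl("^-?[0-9.]+$", df[[j]])))
      df[[j]] <- as.numeric(df[[j]])
  }
  df
}

# Percentage of a count over a total, rounded to `digits` decimals.
# Used everywhere a report prints a rate, so rounding is applied once,
# consistently (e.g. 929/2948 -> 31.5 at one decimal, 25/34 -> 74 at zero).
#' Format a count as a percentage
#'
#' @param count numerator.
#' @param total denominator.
#' @param digits decimals to round to (1 for selection rates, 0 for
#'   nearest-percent hit rates).
#' @return numeric percentage on the 0-100 scale.
#' @export
percent <- function(count, total, digits = 1) {
  round(100 * count / total, digits)
}
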