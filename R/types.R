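#' Reserved label for omitted answers
#'
#' Candidates occasionally leave an item blank. Omissions are accepted on
#' input under this reserved label, scored as incorrect, and excluded from
#' distractor selection-rate numerators while remaining in the denominator
#' (the denominator is always the full candidate group).
#' @export
OMIT <- "OMIT"

#' Construct a response matrix
#'
#' A response matrix is the raw input of every analysis: one chosen option
#' label per candidate and item. It is stored as a character matrix with
#' candidate ids as row names and item ids as column names; cells hold a
#' single option label (e.g. `"A"`) or [OMIT].
#'
#' @param choices character matrix, candidates in rows, items in columns.
#'   Row and column names are required and must be unique.
#' @param key optional [answer_key()]; when supplied every cell is checked
#'   against the item's declared option set.
#' @return an object of class `response_matrix`.
#' @export
response_matrix <- function(choices, key = NULL) {
  if (!is.matrix(choices) || !is.character(choices))
    stop("`choices` must be a character matrix", call. = FALSE)
  if (is.null(rownames(choices)) || is.null(colnames(choices)))
    stop("`choices` must have candidate row names and item column names",
         call. = FALSE)
  if (anyDuplicated(rownames(choices)))
    stop("duplicate candidate ids", call. = FALSE)
  if (anyDuplicated(colnames(choices)))
    stop("duplicate item ids", call. = FALSE)
  if (nrow(choices) < 2L || ncol(choices) < 2L)
    stop("a response matrix needs at least 2 candidates and 2 items",
         call. = FALSE)
  if (anyNA(choices))
    stop("every (candidate, item) pair needs exactly one entry; found NA",
         call. = FALSE)
  if (!is.null(key)) {
    for (it in colnames(choices)) {
      allowed <- c(key_options(key, it), OMIT)
      bad <- setdiff(unique(choices[, it]), allowed)
      if (length(bad))
        stop(sprintf("item %s: option label(s) %s outside declared set {%s}",
                     it, paste(bad, collapse = ", "),
                     paste(allowed, collapse = "")), call. = FALSE)
    }
  }
  structure(choices, class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d candidates x %d items\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Candidate and item identifiers of a response matrix
#' @param responses a [response_matrix()].
#' @return character vector of ids.
#' @export
candidate_ids <- function(responses) rownames(responses)

#' @rdname candidate_ids
#' @export
item_ids <- function(responses) colnames(responses)

#' Construct an answer key
#'
#' One-best-answer items carry exactly one correct option out of an ordered
#' option set (five options, `"ABCDE"`, by default).
#'
#' @param item_id character vector of item identifiers.
#' @param correct character vector of correct option labels, one per item.
#' @param options option sets, one string per item such as `"ABCDE"`;
#'   recycled if length 1.
#' @return a data frame of class `answer_key` with columns
#'   `item_id`, `correct`, `options`.
#' @export
answer_key <- function(item_id, correct, options = "ABCDE") {
  item_id <- as.character(item_id)
  correct <- as.character(correct)
  options <- rep_len(as.character(options), length(item_id))
  if (length(correct) != length(item_id))
    stop("`correct` must match `item_id` in length", call. = FALSE)
  if (anyDuplicated(item_id))
    stop("duplicate item ids in answer key", call. = FALSE)
  for (i in seq_along(item_id)) {
    opts <- strsplit(options[i], "")[[1]]
    if (anyDuplicated(opts))
      stop(sprintf("item %s: duplicated option labels", item_id[i]),
           call. = FALSE)
    if (!(correct[i] %in% opts))
      stop(sprintf("item %s: correct option %s not in option set %s",
                   item_id[i], correct[i], options[i]), call. = FALSE)
  }
  structure(data.frame(item_id = item_id, correct = correct,
                       options = options, stringsAsFactors = FALSE),
            class = c("answer_key", "data.frame"))
}

#' Option set and correct answer lookup
#' @param key an [answer_key()].
#' @param item a single item id.
#' @return `key_options()` the ordered option labels; `key_correct()` the
#'   correct label; `key_distractors()` the incorrect labels.
#' @export
key_options <- function(key, item) {
  row <- match(item, key$item_id)
  if (is.na(row)) stop(sprintf("item %s not in answer key", item), call. = FALSE)
  strsplit(key$options[row], "")[[1]]
}

#' @rdname key_options
#' @export
key_correct <- function(key, item) {
  row <- match(item, key$item_id)
  if (is.na(row)) stop(sprintf("item %s not in answer key", item), call. = FALSE)
  key$correct[row]
}

#' @rdname key_options
#' @export
key_distractors <- function(key, item) {
  setdiff(key_options(key, item), key_correct(key, item))
}

#' Construct an expert ratings table
#'
#' Each expert marks, per item, the least plausible option with rank 1 and
#' the second least plausible with rank 2; two rank-1 marks signal a tie.
#' Marks never land on the keyed correct answer (experts are shown the key).
#'
#' @param df data frame with columns `expert_id`, `item_id`, `option`,
#'   `rank` and optionally `block`.
#' @param key optional [answer_key()] for validating marks against the key.
#' @return a data frame of class `expert_ratings`.
#' @export
expert_ratings <- function(df, key = NULL) {
  need <- c("expert_id", "item_id", "option", "rank")
  if (!all(need %in% names(df)))
    stop(sprintf("expert ratings need columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df$expert_id <- as.character(df$expert_id)
  df$item_id <- as.character(df$item_id)
  df$option <- as.character(df$option)
  df$rank <- as.integer(df$rank)
  if (!all(df$rank %in% c(1L, 2L)))
    stop("ranks must be 1 or 2", call. = FALSE)
  sp <- split(df, paste(df$expert_id, df$item_id, sep = "\r"))
  for (grp in sp) {
    who <- sprintf("expert %s, item %s", grp$expert_id[1], grp$item_id[1])
    if (nrow(grp) > 2L)
      stop(sprintf("%s: more than two marks", who), call. = FALSE)
    if (nrow(grp) == 2L && !(identical(sort(grp$rank), c(1L, 2L)) ||
                             identical(grp$rank, c(1L, 1L))))
      stop(sprintf("%s: marks must be ranks {1,2} or a {1,1} tie", who),
           call. = FALSE)
    if (nrow(grp) == 1L && grp$rank != 1L)
      stop(sprintf("%s: a single mark must have rank 1", who), call. = FALSE)
    if (anyDuplicated(grp$option))
      stop(sprintf("%s: the same option marked twice", who), call. = FALSE)
    if (!is.null(key)) {
      corr <- key_correct(key, grp$item_id[1])
      if (any(grp$option == corr))
        stop(sprintf("%s: mark on the keyed correct answer", who),
             call. = FALSE)
      if (!all(grp$option %in% key_options(key, grp$item_id[1])))
        stop(sprintf("%s: mark outside the item's option set", who),
             call. = FALSE)
    }
  }
  class(df) <- c("expert_ratings", "data.frame")
  df
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
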