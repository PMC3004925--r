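# Brute-force oracles and small fixture builders shared across test files.
# The oracles deliberately use explicit textbook formulas (loops and sums),
# independent of the package's code paths.

# Pearson correlation from raw sums.
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Population variance.
bf_pvar <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

# Cronbach's alpha by explicit variance decomposition.
bf_alpha <- function(sc) {
  k <- ncol(sc)
  vi <- 0
  for (j in seq_len(k)) vi <- vi + bf_pvar(sc[, j])
  vt <- bf_pvar(rowSums(sc))
  (k / (k - 1)) * (1 - vi / vt)
}

# Median as sorted midpoint.
bf_median <- function(x) {
  s <- sort(unname(x))
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Build a response_matrix from a character matrix given as rows of strings,
# e.g. make_responses(c("AB", "AC")) -> 2 candidates x 2 items.
make_responses <- function(rows, items = NULL, cands = NULL) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), identity))
  # multi-character labels (OMIT) can be passed as a ready matrix instead
  if (is.null(items)) items <- sprintf("i%d", seq_len(ncol(m)))
  if (is.null(cands)) cands <- sprintf("c%d", seq_len(nrow(m)))
  dimnames(m) <- list(cands, items)
  response_matrix(m)
}

# Random small exam: scores spread out, occasional omissions.
rand_small_exam <- function(seed, n_cand = NULL, n_items = NULL,
                            omit_rate = 0.05) {
  withr::with_seed(seed, {
    if (is.null(n_cand)) n_cand <- sample(5:30, 1)
    if (is.null(n_items)) n_items <- sample(3:8, 1)
    items <- sprintf("i%d", seq_len(n_items))
    key <- answer_key(items, sample(LETTERS[1:5], n_items, replace = TRUE))
    m <- matrix(sample(LETTERS[1:5], n_cand * n_items, replace = TRUE),
                n_cand, n_items,
                dimnames = list(sprintf("c%d", seq_len(n_cand)), items))
    m[runif(length(m)) < omit_rate] <- OMIT
    # nudge towards realistic positive correlations: strong candidates
    ability <- rank(runif(n_cand))
    for (j in seq_len(n_items)) {
      good <- ability > n_cand / 2 & runif(n_cand) < 0.6
      m[good, j] <- key_correct(key, items[j])
    }
    list(responses = response_matrix(m), key = key)
  })
}
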