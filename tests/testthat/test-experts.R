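mk_marks <- function(options, ranks) {
  data.frame(option = options, rank = as.integer(ranks),
             stringsAsFactors = FALSE)
}

test_that("expert hits test the rank-1 mark against the NF-D set", {
  expect_true(expert_hit(mk_marks(c("E", "D"), c(1, 2)), nfd_set = "E")$hit)
  expect_false(expert_hit(mk_marks(c("B", "E"), c(1, 2)), nfd_set = "E")$hit)
  expect_error(expert_hit(mk_marks("B", 1), nfd_set = character(0)),
               "at least one NF-D")
})

test_that("tied rank-1 marks are resolved by a fair seeded coin", {
  marks <- mk_marks(c("B", "E"), c(1, 1))  # one F-D, one NF-D
  hits <- vapply(1:4000, function(s)
    expert_hit(marks, nfd_set = "E", seed = s)$hit, logical(1))
  # Bernoulli(0.5): 3 sigma over 4000 draws is ~0.024
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 4000))
  one <- expert_hit(marks, nfd_set = "E", seed = 7)
  expect_true(one$tie_resolved)
  expect_identical(one, expert_hit(marks, nfd_set = "E", seed = 7))
})

test_that("hit statistics aggregate per item and correlate with NF-D count", {
  # Exam with controlled NF-D structure: i1 has NF-Ds {D, E}, i2 has {E}.
  ch1 <- rep(c("A", "B", "C"), times = c(60, 30, 10))
  ch2 <- rep(c("B", "A", "C", "D"), times = c(55, 25, 15, 5))
  m <- cbind(i1 = ch1, i2 = ch2)
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  key <- answer_key(c("i1", "i2"), c("A", "B"))

  ratings <- expert_ratings(data.frame(
    expert_id = rep(c("e1", "e2", "e3", "e4"), each = 4),
    item_id = rep(rep(c("i1", "i2"), each = 2), times = 4),
    option = c("D", "E", "E", "A",    # e1: i1 (D1,E2), i2 (E1,A2) -> hit, hit
               "E", "D", "A", "E",    # e2: i1 (E1,D2), i2 (A1,E2) -> hit, miss
               "B", "C", "E", "C",    # e3: i1 (B1,C2), i2 (E1,C2) -> miss, hit
               "D", "C", "C", "E"),   # e4: i1 (D1,C2), i2 (C1,E2) -> hit, miss
    rank = rep(c(1L, 2L), 8)), key)
  hs <- hit_statistics(ratings, rm, key, threshold = 1)
  expect_equal(hs$per_item$n_nfd, c(2, 1))
  expect_equal(hs$per_item$hit_prop, c(0.75, 0.5))
  expect_equal(hs$n_items, 2)
  expect_equal(hs$mean_hit_prop, 0.625)
  expect_equal(hs$min_hit_prop, 0.5)
  # hit proportion here is perfectly (positively) linear in NF-D count
  expect_equal(hs$correlation, 1.0)
})

test_that("hit proportions of a guessing expert scale with the NF-D count", {
  # uniform rank-1 guess over 4 distractors hits with chance k/4
  ex <- generate_exam(exam_config(n_candidates = 400, n_items = 30), seed = 6)
  cnt <- nfd_counts(ex$responses, ex$key, 1)
  ratings <- generate_ratings(ex$truth, ex$key,
                              rating_config(n_experts_per_block = 60,
                                            accuracy = 0.25, tie_prob = 0),
                              seed = 8)
  hs <- hit_statistics(ratings, ex$responses, ex$key, threshold = 1, seed = 3)
  for (k in unique(hs$per_item$n_nfd)) {
    props <- hs$per_item$hit_prop[hs$per_item$n_nfd == k]
    n <- 60 * length(props)
    se <- sqrt((k / 4) * (1 - k / 4) / n)
    expect_lt(abs(mean(props) - k / 4), max(4 * se, 0.06))
  }
})

test_that("panel mode aggregates weighted votes with label tie-breaks", {
  key <- answer_key(c("i1", "i2"), c("A", "A"))
  unan <- expert_ratings(data.frame(
    expert_id = rep(sprintf("e%02d", 1:17), each = 2),
    item_id = "i1",
    option = rep(c("E", "D"), 17),
    rank = rep(c(1L, 2L), 17)), key)
  pm <- panel_mode(unan, key, "i1")
  expect_equal(pm$first_removal, "E")
  expect_equal(pm$second_removal, "D")
  expect_false(pm$tie_first)

  # 10 rank-1 votes for E vs 7 for D, no rank-2 marks
  votes <- expert_ratings(data.frame(
    expert_id = sprintf("e%02d", 1:17),
    item_id = "i1",
    option = c(rep("E", 10), rep("D", 7)),
    rank = 1L), key)
  pm2 <- panel_mode(votes, key, "i1")
  expect_equal(pm2$first_removal, "E")
  expect_equal(pm2$second_removal, "D")

  # engineered tie: equal weighted votes for B and C -> label order, flagged
  tie <- expert_ratings(data.frame(
    expert_id = c("e1", "e1", "e2", "e2"),
    item_id = "i1",
    option = c("B", "D", "C", "D"),
    rank = c(1L, 2L, 1L, 2L)), key)
  pm3 <- panel_mode(tie, key, "i1")
  expect_equal(pm3$first_removal, "B")
  expect_true(pm3$tie_first)
  # rank-2 mode alternative for the second removal
  pm4 <- panel_mode(tie, key, "i1", second_from_rank2_mode = TRUE)
  expect_equal(pm4$second_removal, "D")
})

test_that("panel hit rate counts first removals landing on NF-Ds", {
  ch1 <- rep(c("A", "B", "C"), times = c(60, 30, 10))   # NF-D {D, E}
  ch2 <- rep(c("B", "A", "C", "D"), times = c(55, 25, 15, 5))  # NF-D {E}
  m <- cbind(i1 = ch1, i2 = ch2)
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  key <- answer_key(c("i1", "i2"), c("A", "B"))
  panel <- data.frame(item_id = c("i1", "i2"),
                      first_removal = c("E", "C"),
                      second_removal = c("D", "E"),
                      stringsAsFactors = FALSE)
  phr <- panel_hit_rate(panel, rm, key, threshold = 1)
  expect_equal(phr$n_hits, 1L)   # i1 hit (E), i2 miss (C is functional)
  expect_equal(phr$n_items, 2L)
  expect_equal(phr$pct, 50)
})

test_that("hit percentages round to the nearest percent", {
  expect_equal(percent(25, 34, digits = 0), 74)
  expect_equal(percent(0, 34, digits = 0), 0)
})

test_that("panel plans feed elimination and never contain the key", {
  ex <- generate_exam(exam_config(n_candidates = 300, n_items = 14), seed = 5)
  ratings <- generate_ratings(ex$truth, ex$key,
                              rating_config(accuracy = 1, tie_prob = 0),
                              seed = 2)
  panel <- panel_ratings(ratings, ex$key)
  plan <- panel_plan(panel, n_remove = 2)
  for (it in names(plan)) {
    expect_false(key_correct(ex$key, it) %in% plan[[it]])
    expect_length(plan[[it]], 2)
  }
  # a perfectly informed unanimous panel marks the truly least plausible
  # distractors: its plan matches the generating plausibility order
  for (it in names(plan)) {
    tt <- ex$truth[ex$truth$item_id == it & !ex$truth$is_correct, ]
    expect_equal(plan[[it]], tt$option[order(tt$beta, tt$option)][1:2])
  }
  tab <- run_models(ex$responses, ex$key, plan = plan, seed = 11)
  expect_equal(nrow(tab), 5)
})
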