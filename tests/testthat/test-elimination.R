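test_that("model labels map to removal count and reallocation rule", {
  expect_equal(elimination_model("A")[c("n_removed", "reallocation")],
               list(n_removed = 1L, reallocation = "RANDOM"))
  expect_equal(elimination_model("B")[c("n_removed", "reallocation")],
               list(n_removed = 1L, reallocation = "CORRECT"))
  expect_equal(elimination_model("C")[c("n_removed", "reallocation")],
               list(n_removed = 2L, reallocation = "RANDOM"))
  expect_equal(elimination_model("D")[c("n_removed", "reallocation")],
               list(n_removed = 2L, reallocation = "CORRECT"))
  expect_error(elimination_model("E"))
})

test_that("distractors rank by ascending count with label tie-breaks", {
  fx_key <- answer_key(c("i1", "i2"), c("A", "A"))
  ch1 <- rep(c("A", "B", "C", "D"), times = c(50, 30, 19, 1))
  m <- cbind(i1 = ch1, i2 = rep(c("A", "B"), 50))
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  prof <- option_selection_rates(rm, fx_key, "i1")
  expect_equal(rank_distractors(prof), c("E", "D", "C", "B"))

  # all-equal counts: deterministic label order
  m2 <- cbind(i1 = rep(c("B", "C", "D", "E"), 10), i2 = rep(c("A", "B"), 20))
  rownames(m2) <- sprintf("c%02d", 1:40)
  prof2 <- option_selection_rates(response_matrix(m2), fx_key, "i1")
  expect_equal(rank_distractors(prof2), c("B", "C", "D", "E"))

  # property: the first-ranked distractor always has minimal count
  for (seed in 1:10) {
    ex <- rand_small_exam(seed)
    for (it in item_ids(ex$responses)) {
      prof <- option_selection_rates(ex$responses, ex$key, it)
      ranked <- rank_distractors(prof)
      dcounts <- prof$count[!prof$is_correct]
      expect_equal(prof$count[prof$option == ranked[1]], min(dcounts))
    }
  }
})

test_that("CORRECT-mode elimination moves removed-distractor selectors to the key", {
  # i1: 60 correct, 30 on B, 10 on E; removing E must lift P from 60 to 70
  ch1 <- rep(c("A", "B", "E"), times = c(60, 30, 10))
  m <- cbind(i1 = ch1, i2 = rep(c("A", "B"), 50))
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  key <- answer_key(c("i1", "i2"), c("A", "A"))
  plan <- structure(list(i1 = "E"), class = "elimination_plan")
  out <- eliminate(rm, key, plan, "B")
  expect_equal(item_p_value(out, key, "i1"), 70)
  expect_identical(out[, "i2"], rm[, "i2"])  # untouched item is bit-identical
  expect_identical(out[rm[, "i1"] != "E", "i1"], rm[rm[, "i1"] != "E", "i1"])
})

test_that("removing a never-chosen distractor is a no-op", {
  ch1 <- rep(c("A", "B"), times = c(60, 40))
  m <- cbind(i1 = ch1, i2 = rep(c("A", "C"), 50))
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  key <- answer_key(c("i1", "i2"), c("A", "A"))
  plan <- statistics_plan(rm, key, n_remove = 2)
  expect_equal(plan$i1, c("C", "D"))  # both never chosen on i1
  for (mod in c("A", "B", "C", "D")) {
    out <- eliminate(rm, key, plan["i1"], mod, seed = 3)
    expect_identical(unclass(out), unclass(rm))
    expect_equal(exam_stats(out, key), exam_stats(rm, key))
  }
})

test_that("plans never remove the keyed answer", {
  ex <- rand_small_exam(3)
  plan <- statistics_plan(ex$responses, ex$key)
  for (it in names(plan))
    expect_false(key_correct(ex$key, it) %in% plan[[it]])
  bad <- structure(list(i1 = key_correct(ex$key, "i1")),
                   class = "elimination_plan")
  expect_error(eliminate(ex$responses, ex$key, bad, "B"), "keyed answer")
  expect_error(eliminate(ex$responses, ex$key, plan, "A"), "requires a seed")
})

test_that("RANDOM elimination is seed-deterministic and conserves candidates", {
  ex <- rand_small_exam(5, n_cand = 30)
  plan <- statistics_plan(ex$responses, ex$key)
  o1 <- eliminate(ex$responses, ex$key, plan, "C", seed = 99)
  o2 <- eliminate(ex$responses, ex$key, plan, "C", seed = 99)
  expect_identical(o1, o2)
  o3 <- eliminate(ex$responses, ex$key, plan, "C", seed = 100)
  expect_false(identical(o1, o3))
  expect_identical(dimnames(o1), dimnames(ex$responses))
  # only candidates who chose a removed distractor changed; reallocations
  # land on remaining options only
  for (it in item_ids(ex$responses)) {
    removed <- plan[[it]]
    moved <- o1[, it] != ex$responses[, it]
    expect_true(all(ex$responses[moved, it] %in% removed))
    expect_false(any(o1[, it] %in% removed))
    expect_true(all(o1[moved, it] %in%
                      setdiff(key_options(ex$key, it), removed)))
  }
})

test_that("CORRECT-mode P-values never decrease, strictly rise iff selected", {
  for (seed in 1:5) {
    ex <- rand_small_exam(seed)
    plan <- statistics_plan(ex$responses, ex$key)
    out <- eliminate(ex$responses, ex$key, plan, "D")
    p0 <- item_p_value(ex$responses, ex$key)
    p1 <- item_p_value(out, ex$key)
    expect_true(all(p1 >= p0))
    nsel <- vapply(item_ids(ex$responses), function(it)
      sum(ex$responses[, it] %in% plan[[it]]), integer(1))
    expect_equal(unname(p1 > p0), unname(nsel > 0))
  }
})

test_that("run_models reports the original row plus one row per model", {
  ex <- rand_small_exam(8, n_cand = 50, n_items = 8)
  tab <- run_models(ex$responses, ex$key, seed = 7)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$model[1], "4 distractors")
  base <- exam_stats(ex$responses, ex$key)
  expect_equal(tab$pct_correct[1], base$pct_correct)
  # CORRECT-mode rows can only raise the mean P-value
  expect_gte(tab$pct_correct[tab$model == "B) 3 distractors, right answer"],
             tab$pct_correct[1])
  expect_gte(tab$pct_correct[tab$model == "D) 2 distractors, right answer"],
             tab$pct_correct[tab$model == "B) 3 distractors, right answer"])
})

test_that("the NF-D-restricted plan is bounded by the full plan", {
  ex <- generate_exam(exam_config(n_candidates = 200, n_items = 12), seed = 2)
  full <- statistics_plan(ex$responses, ex$key)
  nfd <- statistics_plan(ex$responses, ex$key, nfd_only = TRUE, threshold = 1)
  expect_true(all(lengths(nfd) <= lengths(full)))
  for (it in names(nfd))
    expect_true(all(nfd[[it]] %in% full[[it]]))
  p0 <- mean(item_p_value(ex$responses, ex$key))
  p_full <- mean(item_p_value(eliminate(ex$responses, ex$key, full, "D"),
                              ex$key))
  p_nfd <- mean(item_p_value(eliminate(ex$responses, ex$key, nfd, "D"),
                             ex$key))
  expect_gte(p_nfd, p0)
  expect_lte(p_nfd, p_full)
})

test_that("the literal five-code random draw can reassign onto removed options", {
  ch1 <- rep(c("A", "E"), times = c(10, 90))
  m <- cbind(i1 = ch1, i2 = rep(c("A", "B"), 50))
  rownames(m) <- sprintf("c%03d", 1:100)
  rm <- response_matrix(m)
  key <- answer_key(c("i1", "i2"), c("A", "A"))
  plan <- structure(list(i1 = "E"), class = "elimination_plan")
  out5 <- eliminate(rm, key, plan, "A", seed = 4, random_over_five = TRUE)
  expect_true(any(out5[, "i1"] == "E"))  # the removed code can reappear
  out4 <- eliminate(rm, key, plan, "A", seed = 4)
  expect_false(any(out4[, "i1"] == "E"))
})
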