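test_that("random baselines are reproducible and calibrated", {
  set.seed(51); b1 <- random_baselines(40, 6)
  set.seed(51); b2 <- random_baselines(40, 6)
  expect_identical(b1, b2)
  expect_length(b1$uniform, 40)
  expect_length(b1$agent, 40)
  # uniform tables have T-fraction 0.5 on average (+- 3 SE over all bits)
  frac <- mean(vapply(b1$uniform, mean, numeric(1)))
  se <- sqrt(0.25 / (40 * 64))
  expect_lt(abs(frac - 0.5), 3 * se)
  # agent tables come from untrained networks: diverse, rarely degenerate
  degs <- vapply(b1$agent, degeneracy, numeric(1))
  expect_lt(mean(degs == 1), 0.2)
})

test_that("classify_pattern recognizes index patterns under all polarity switches", {
  n <- 10
  for (i in c(1L, 4L, 10L)) {
    uf <- named_quantifier("ultrafilter", n, i = i)
    lab <- classify_pattern(uf)
    expect_identical(lab$label, "single_index")
    expect_identical(lab$indices, i)
    neg <- classify_pattern(as_quantifier(!uf))
    expect_identical(neg$label, "single_index")
    expect_identical(neg$indices, i)
    # switching 0/1 in the structures re-indexes by complement
    flipped <- as_quantifier(rev(as.logical(uf)))
    expect_identical(classify_pattern(flipped)$label, "single_index")
    expect_identical(classify_pattern(as_quantifier(rev(!uf)))$label,
                     "single_index")
  }
  cj <- named_quantifier("conj_ultrafilter", 6, i = 2, j = 5)
  lab <- classify_pattern(cj)
  expect_identical(lab$label, "two_index_conjunction")
  expect_identical(lab$indices, c(2L, 5L))
  expect_identical(classify_pattern(as_quantifier(!cj))$label,
                   "two_index_conjunction")
})

test_that("classify_pattern separates degenerate, threshold and other", {
  expect_identical(classify_pattern(named_quantifier("const", 5))$label,
                   "degenerate")
  thr <- classify_pattern(named_quantifier("at_least", 6, k = 3))
  expect_identical(thr$label, "threshold_like")
  expect_identical(classify_pattern(named_quantifier("some", 6))$label,
                   "threshold_like")
  expect_identical(
    classify_pattern(named_quantifier("between", 10, lo = 3, hi = 5))$label,
    "other")
  expect_identical(classify_pattern(named_quantifier("even", 6))$label,
                   "other")
  # every threshold_like table is quantitative and binary-monotone
  set.seed(52)
  for (rep in 1:40) {
    q <- as_quantifier(random_table(5))
    if (classify_pattern(q)$label == "threshold_like") {
      expect_true(is_quantitative(q))
      expect_true(is_monotone(q, "up") || is_monotone(q, "down"))
    }
  }
})

test_that("threshold profiles aggregate confidences by count class", {
  ag <- init_agent(agent_config(6), seed = 61)
  prof <- threshold_profile(ag)
  expect_identical(prof$count, 0:6)
  expect_identical(prof$n_structures, as.integer(choose(6, 0:6)))
  conf <- respond(ag, all_structures(6))
  # count-weighted profile mean equals the overall mean confidence
  expect_equal(sum(prof$mean_confidence * prof$n_structures) /
                 sum(prof$n_structures), mean(conf), tolerance = 1e-12)
  # an agent trained toward "at least 4" rises through its threshold
  set.seed(62)
  X <- all_structures(6)
  y <- as.integer(named_quantifier("at_least", 6, k = 4))
  tr <- init_agent(agent_config(6))
  for (e in 1:6) tr <- train_agent(tr, X, y, epochs = 8)
  p2 <- threshold_profile(tr)
  expect_gt(mean(p2$mean_confidence[p2$count >= 4]),
            mean(p2$mean_confidence[p2$count < 4]))
})

test_that("summarize_run reports trajectories and pattern shares that sum to 1", {
  # hand-built snapshot: 3 ultrafilters + 1 other monotone + 1 degenerate
  uf <- function(i) quantifier_to_string(named_quantifier("ultrafilter", 4, i = i))
  other_mono <- quantifier_to_string(named_quantifier("conj_ultrafilter", 4,
                                                      i = 1, j = 2))
  rows <- lapply(1:5, function(a) {
    qs <- c(uf(1), uf(2), uf(3), other_mono,
            quantifier_to_string(named_quantifier("const", 4)))[a]
    m <- quantifier_measures(as_quantifier(qs))
    tibble::tibble(generation = 0L, agent = a, parent = NA_integer_,
                   quantifier = qs, upward = m$upward, downward = m$downward,
                   monotonicity = m$monotonicity, quantity = m$quantity,
                   degeneracy = m$degeneracy)
  })
  snaps <- do.call(rbind, rows)
  out <- summarize_run(snaps)
  expect_equal(out$trajectories$prop_degenerate, 0.2)
  pooled <- out$pattern_shares_pooled
  expect_equal(sum(pooled$share), 1)
  expect_equal(pooled$share[pooled$label == "single_index"], 0.75)
  expect_equal(pooled$share[pooled$label == "two_index_conjunction"], 0.25)
  # per-generation shares sum to 1 within each generation
  for (g in unique(out$pattern_shares$generation)) {
    expect_equal(sum(out$pattern_shares$share[
      out$pattern_shares$generation == g]), 1)
  }
  # all-degenerate snapshots: degenerate share 1, no pattern rows
  snaps2 <- snaps
  snaps2$quantifier <- quantifier_to_string(named_quantifier("const", 4))
  snaps2$monotonicity <- 1; snaps2$degeneracy <- 1
  out2 <- summarize_run(snaps2)
  expect_equal(out2$trajectories$prop_degenerate, 1)
  expect_equal(nrow(out2$pattern_shares_pooled), 0)
})
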