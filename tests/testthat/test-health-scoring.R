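test_that("limitation count is the number of difficulty responses", {
  expect_equal(count_limitations(c("difficulty", "difficulty", rep("no_difficulty", 3))), 2L)
  expect_equal(count_limitations(rep("no_difficulty", 5)), 0L)
  expect_equal(count_limitations(rep("difficulty", 5)), 5L)
  expect_error(count_limitations(c("dont_know", rep("no_difficulty", 4))),
               "excluded upstream")
})

test_that("comorbidity count applies the blood-pressure hypertension rule", {
  cc <- function(dia = "no", mi = "no", st = "no", ap = "no", as_ = "no",
                 dx = "no", sbp = 120, dbp = 75) {
    count_comorbidities(dia, mi, st, ap, as_, dx, sbp, dbp)
  }
  expect_equal(cc(dia = "yes", sbp = 150, dbp = 80), 2L)  # diabetes + SBP rule
  expect_equal(cc(sbp = 138, dbp = 92), 1L)               # DBP alone suffices
  expect_equal(cc(), 0L)
  expect_equal(cc(dx = "yes", sbp = 120, dbp = 70), 1L)   # diagnosis alone
  expect_equal(cc(sbp = 139, dbp = 89), 0L)               # both just below
  expect_equal(cc(dia = "yes", mi = "yes", st = "yes", ap = "yes", as_ = "yes",
                  dx = "yes", sbp = 160, dbp = 95), 6L)
  expect_error(cc(dia = "dont_know"), "excluded upstream")
  expect_error(cc(sbp = NA), "missing")
})

test_that("cognition is recall + recall + serial 7s + graded backward counting", {
  expect_equal(score_cognition(10, 10, 5, "first_try"), 27L)
  expect_equal(score_cognition(0, 0, 0, "fail"), 0L)
  expect_equal(score_cognition(5, 3, 4, "second_try"), 13L)
  expect_error(score_cognition(11, 0, 0, "fail"), "0-10")
  expect_error(score_cognition(5, 5, 6, "fail"), "0-5")
  expect_error(score_cognition(5, 5, 5, "third_try"), "backward")
})

test_that("PSS scoring hits its printed extremes and imputes the midpoint", {
  rev_idx <- pss_reversed_items()
  worst <- ifelse(seq_len(14) %in% rev_idx, "never", "very_often")
  best <- ifelse(seq_len(14) %in% rev_idx, "very_often", "never")
  expect_equal(score_pss(worst)$pss, 56L)
  expect_equal(score_pss(best)$pss, 0L)

  mixed <- c(rep("sometimes", 13), "dont_know")
  got <- score_pss(mixed)
  expect_equal(got$pss, 28L)
  expect_equal(got$pss_dk_count, 1L)

  expect_error(score_pss(rep("dont_know", 14)), "all 14")
  expect_error(score_pss(rep("sometimes", 13)), "14 PSS responses")
})

test_that("a response scoring 2 before reversal still scores 2 after", {
  # the midpoint is the fixed point of v -> 4 - v
  all_mid <- rep("sometimes", 14)
  expect_equal(score_pss(all_mid)$pss, 28L)
  expect_equal(score_pss(all_mid, reverse_items = integer(0))$pss, 28L)
})

test_that("score_pss matches the item-wise brute-force oracle", {
  set.seed(101)
  vecs <- t(replicate(1000, random_pss_vector()))
  got <- score_pss(vecs)
  want <- apply(vecs, 1, pss_oracle)
  expect_equal(got$pss, as.integer(want))
  expect_equal(got$pss_dk_count, as.integer(rowSums(vecs == "dont_know")))
})

test_that("the HAS composite normalizes, reverses cognition, and spans 0-4", {
  expect_equal(compose_has(0, 0, 27, 0), 0)
  expect_equal(compose_has(5, 6, 0, 56), 4)
  expect_equal(compose_has(1, 3, 18, 28), 1 / 5 + 3 / 6 + (1 - 18 / 27) + 28 / 56)
  expect_error(compose_has(6, 0, 27, 0), "n_limitations")
  expect_error(compose_has(0, 0, 28, 0), "cognition")
})

test_that("HAS moves the right way under every unit perturbation", {
  base <- c(lim = 2, com = 3, cog = 14, pss = 30)
  h0 <- compose_has(base["lim"], base["com"], base["cog"], base["pss"])
  expect_gt(compose_has(base["lim"] + 1, base["com"], base["cog"], base["pss"]), h0)
  expect_gt(compose_has(base["lim"], base["com"] + 1, base["cog"], base["pss"]), h0)
  expect_lt(compose_has(base["lim"], base["com"], base["cog"] + 1, base["pss"]), h0)
  expect_gt(compose_has(base["lim"], base["com"], base["cog"], base["pss"] + 1), h0)
})

test_that("stored composites agree with recomputation from their sub-scores", {
  wx <- generate_worked_example()
  scored <- score_has(wx$surveys)
  expect_equal(scored$has,
               compose_has(scored$n_limitations, scored$n_comorbidities,
                           scored$cognition, scored$pss),
               tolerance = 1e-12)
  expect_equal(scored$has, wx$expected$has, tolerance = 1e-12)
})

test_that("component and life-quality categories follow the grouping rules", {
  wx <- generate_worked_example()
  scored <- categorize_components(score_has(wx$surveys), wx$surveys$life_quality)
  expect_equal(as.character(scored$comorbidity_cat[scored$n_comorbidities == 2]),
               rep("1-2", sum(scored$n_comorbidities == 2)))
  expect_equal(as.character(scored$limitation_cat[scored$n_limitations == 3]), ">=3")
  expect_equal(as.character(scored$limitation_cat[scored$n_limitations == 0]),
               rep("0", sum(scored$n_limitations == 0)))
  # very_bad collapses into bad; very_good into good; dont_know flagged only
  expect_equal(as.character(scored$life_quality_cat[wx$surveys$life_quality == "very_bad"]),
               "bad")
  expect_equal(as.character(scored$life_quality_cat[wx$surveys$life_quality == "very_good"]),
               rep("good", 2))
  expect_true(all(is.na(scored$life_quality_cat[wx$surveys$life_quality == "dont_know"])))
  expect_equal(sum(scored$life_quality_excluded), 1)
  expect_equal(nlevels(scored$cognition_tertile), 3)
})
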