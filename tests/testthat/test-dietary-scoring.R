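ft <- toy_food_table()

test_that("daily energy sums amount times density over the day", {
  day <- make_day("P1", 2009, 1, "pork", amount = 200)  # 200 kcal/100 g
  expect_equal(daily_energy(day, ft)$energy, 400)
  day2 <- make_day("P1", 2009, 1, c("rice", "oil"), amount = c(300, 20))
  expect_equal(daily_energy(day2, ft)$energy, 300 + 180)
  expect_warning(out <- daily_energy(make_day("P", 2009, 1, character(0)), ft),
                 "zero days")
  expect_equal(nrow(out), 0)
  expect_error(daily_energy(make_day("P", 2009, 1, "durian"), ft), "durian")
})

test_that("worked-example day energies match their stored exact values", {
  wx <- generate_worked_example()
  en <- daily_energy(wx$dietary, wx$food_table)
  # P04 ate the full eight-group menu every 2009 day
  expect_equal(en$energy[en$participant_id == "P04"],
               rep(unname(wx$day_energies["D8"]), 3))
  expect_equal(en$energy[en$participant_id == "P03"],
               rep(unname(wx$day_energies["D1"]), 3))
})

test_that("energy adjustment rescales to grams per 1000 kcal", {
  expect_equal(energy_adjust(150, 2000), 75)
  x <- c(0, 10, 250)
  expect_equal(energy_adjust(x, 1000), x)
  expect_equal(energy_adjust(0, 1700), 0)
  expect_error(energy_adjust(100, 0), "positive")
  k <- 3.7
  expect_equal(energy_adjust(k * x, k * 1500), energy_adjust(x, 1500))
})

test_that("daily DDS counts distinct scored groups and ignores salt and oil", {
  expect_equal(daily_dds(make_day("P", 2009, 1, c("rice", "cabbage", "egg")), ft)$dds, 3)
  all8 <- c("rice", "cabbage", "apple", "egg", "fish", "pork", "tofu", "milk")
  expect_equal(daily_dds(make_day("P", 2009, 1, c(all8, "oil")), ft)$dds, 8)
  expect_equal(daily_dds(make_day("P", 2009, 1, c("rice", "oil", "salt")), ft)$dds, 1)
  expect_error(daily_dds(make_day("P", 2009, 1, c("oil", "salt")), ft),
               "DDS >= 1")
  # duplicate foods in one group add nothing; zero amounts never count
  two_rice <- make_day("P", 2009, 1, c("rice", "rice", "apple"))
  expect_equal(daily_dds(two_rice, ft)$dds, 2)
  zero_apple <- make_day("P", 2009, 1, c("rice", "apple"), amount = c(100, 0))
  expect_equal(daily_dds(zero_apple, ft)$dds, 1)
})

test_that("adding a new group raises daily DDS by one, an old group by zero", {
  base <- make_day("P", 2009, 1, c("rice", "cabbage"))
  d0 <- daily_dds(base, ft)$dds
  expect_equal(daily_dds(dplyr::bind_rows(base, make_day("P", 2009, 1, "fish")), ft)$dds,
               d0 + 1)
  expect_equal(daily_dds(dplyr::bind_rows(base, make_day("P", 2009, 1, "cabbage")), ft)$dds,
               d0)
})

test_that("daily DDS equals the brute-force set-cardinality oracle", {
  set.seed(7)
  edible <- ft$food_id[!ft$food_group %in% c("salt", "oil")]
  for (i in 1:1000) {
    foods <- c(sample(edible, 1),
               sample(ft$food_id, sample(1:6, 1), replace = TRUE))
    day <- make_day("P", 2009, 1, foods,
                    amount = sample(c(0, 50, 120), length(foods), replace = TRUE))
    day$amount[1] <- 100  # guarantee one scored intake
    expect_equal(daily_dds(day, ft)$dds, dds_oracle(day, ft))
  }
})

test_that("participant averaging is nested: days within wave, then waves", {
  mk <- function(wave, day, k) {
    foods <- c("rice", "cabbage", "egg", "fish", "pork", "tofu", "milk", "apple")[1:k]
    make_day("P", wave, day, foods)
  }
  # wave 2009 daily scores {3,4,5}; wave 2011 {4,4,4} -> (4 + 4)/2
  diet <- dplyr::bind_rows(mk(2009, 1, 3), mk(2009, 2, 4), mk(2009, 3, 5),
                           mk(2011, 1, 4), mk(2011, 2, 4), mk(2011, 3, 4))
  res <- score_dds(diet, ft)
  expect_equal(res$dds, 4)
  expect_equal(res$waves_used, 2L)

  single <- dplyr::bind_rows(mk(2009, 1, 2), mk(2009, 2, 3))
  expect_equal(score_dds(single, ft)$dds, 2.5)

  # wave means {3, 5} with unequal day counts: nested 4.0, pooled 13/4
  uneq <- dplyr::bind_rows(mk(2009, 1, 3), mk(2011, 1, 5), mk(2011, 2, 5),
                           mk(2011, 3, 5))
  expect_equal(score_dds(uneq, ft)$dds, 4)
  expect_equal(score_dds(uneq, ft, averaging = "pooled")$dds, (3 + 15) / 4)

  # invariant to row, day and wave ordering
  shuffled <- uneq[sample(nrow(uneq)), ]
  expect_equal(score_dds(shuffled, ft), score_dds(uneq, ft))
})

test_that("per-group consumption averages follow the same nested scheme", {
  d1 <- make_day("P", 2009, 1, c("rice", "apple"), amount = c(500, 100))
  d2 <- make_day("P", 2009, 2, c("rice", "apple"), amount = c(500, 300))
  d3 <- make_day("P", 2011, 1, c("rice", "apple"), amount = c(500, 200))
  res <- score_dds(dplyr::bind_rows(d1, d2, d3), ft)
  # apple: 50 kcal/100g, rice 100 kcal/100g
  g <- function(apple) apple * 1000 / (500 + apple * 0.5)
  w2009 <- mean(c(g(100), g(300)))
  expect_equal(res$g_per_1000kcal_fruits, mean(c(w2009, g(200))))
  expect_equal(res$g_per_1000kcal_dairy, 0)
})

test_that("DDS tertiles split ranks into thirds with a cutpoint report", {
  tbl <- tibble::tibble(participant_id = paste0("P", 1:9), dds = as.numeric(1:9),
                        waves_used = 1L)
  out <- add_dds_tertiles(tbl)
  expect_equal(as.integer(table(out$dds_tertile)), c(3, 3, 3))
  expect_match(attr(out, "cutpoint_label"), "^T1: 1-3, T2: 4-6, T3: 7-9$")

  expect_error(add_dds_tertiles(tibble::tibble(participant_id = "a", dds = 1)),
               "at least 3")
  same <- tibble::tibble(participant_id = paste0("P", 1:5), dds = rep(4, 5))
  expect_error(add_dds_tertiles(same), "distinct")

  set.seed(1)
  big <- tibble::tibble(participant_id = paste0("P", 1:1000),
                        dds = round(runif(1000, 1, 8), 1))
  f <- add_dds_tertiles(big)$dds_tertile
  cp <- attr(add_dds_tertiles(big), "cutpoints")
  ties <- sum(big$dds == cp$max[1]) + sum(big$dds == cp$max[2])
  expect_true(all(abs(as.integer(table(f)) - c(333, 333, 334)) <= ties))
})

test_that("consumer split sends zeros to non-consumer and halves the rest", {
  x <- c(0, 0, 10, 20, 30, 40)
  f <- categorize_food_group(x, "consumer_split")
  expect_equal(as.character(f),
               c("non_consumer", "non_consumer", "low", "low", "high", "high"))
  expect_equal(attr(f, "consumer_median"), 25)
  expect_error(categorize_food_group(rep(0, 5), "consumer_split"), "no participant")
  expect_equal(as.character(categorize_food_group(as.numeric(1:9), "tertile")),
               rep(c("low", "middle", "high"), each = 3))
  # exact-median consumers fall in "low": split stays exhaustive
  f2 <- categorize_food_group(c(0, 10, 20, 30), "consumer_split")
  expect_equal(as.character(f2), c("non_consumer", "low", "low", "high"))
})
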