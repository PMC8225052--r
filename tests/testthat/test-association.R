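# A small deterministic analysis table for exact model checks.
noise_free_table <- function(n_per = 30) {
  x <- factor(rep(c("T1", "T2", "T3"), each = n_per), levels = c("T1", "T2", "T3"))
  tibble::tibble(has = 2 - 0.1 * (as.integer(x) - 1), dds_tertile = x,
                 dds = as.integer(x))
}

test_that("noise-free OLS recovers exact level contrasts", {
  tab <- noise_free_table()
  fit <- suppressWarnings(fit_linear(tab, "dds_tertile", adjust = "crude"))
  expect_equal(fit$summary$estimate[fit$summary$level == "T2"], -0.1)
  expect_equal(fit$summary$estimate[fit$summary$level == "T3"], -0.2)
  expect_true(fit$summary$reference[1])
  expect_equal(fit$summary$n, rep(30L, 3))
  expect_equal(fit$n, 90)
  td <- tidy(fit)
  expect_true(all(c("estimate", "conf.low", "conf.high", "p.value") %in% names(td)))
})

test_that("an exposure collinear with a covariate raises a named error", {
  set.seed(3)
  tab <- noise_free_table()
  tab$has <- tab$has + rnorm(90, 0, 0.1)
  # education is a deterministic recode of the exposure -> aliased dummies
  tab$age <- runif(90, 60, 80)
  tab$gender <- factor(rep(c("man", "woman"), 45))
  tab$region <- factor(rep(c("south", "north"), 45))
  tab$residency <- factor(rep(c("rural", "urban"), 45))
  tab$education <- factor(ifelse(tab$dds_tertile == "T1",
                                 "primary_or_below", "middle_or_above"))
  tab$income_tertile <- factor(tab$dds_tertile, labels = c("low", "middle", "high"))
  tab$marriage <- factor(rep(c("married", "other"), 45))
  expect_error(fit_linear(tab, "dds_tertile", adjust = "model1"),
               "collinear")
})

test_that("saturated one-way fits reproduce group mean differences exactly", {
  set.seed(5)
  tab <- noise_free_table()
  tab$has <- tab$has + rnorm(90, 0, 0.3)
  fit <- fit_linear(tab, "dds_tertile", adjust = "crude")
  means <- tapply(tab$has, tab$dds_tertile, mean)
  expect_equal(fit$summary$estimate[-1],
               as.numeric(means[2:3] - means[1]), tolerance = 1e-12)
})

test_that("the two-level proportional-odds model collapses to logistic regression", {
  set.seed(11)
  n <- 600
  x <- factor(sample(c("T1", "T2", "T3"), n, TRUE), levels = c("T1", "T2", "T3"))
  lp <- 0.6 * (as.integer(x) - 1)
  y <- factor(ifelse(runif(n) < plogis(-0.4 + lp), "high", "low"),
              levels = c("low", "high"))
  tab <- tibble::tibble(outcome = y, exposure = x)
  fit <- fit_ordinal(tab, "outcome", "exposure", adjust = "crude")
  ref <- glm(outcome ~ exposure, family = binomial, data = tab)
  expect_equal(log(fit$summary$estimate[-1]),
               unname(coef(ref)[c("exposureT2", "exposureT3")]),
               tolerance = 1e-4)
})

test_that("the proportional-odds fit recovers a planted cumulative log-odds", {
  set.seed(19)
  n <- 4000
  x <- rnorm(n)
  zeta <- c(-1, 0.8)
  eta <- 0.5 * x
  u <- runif(n)
  p1 <- plogis(zeta[1] - eta); p2 <- plogis(zeta[2] - eta)
  y <- ordered(ifelse(u < p1, "a", ifelse(u < p2, "b", "c")),
               levels = c("a", "b", "c"))
  fit <- MASS::polr(y ~ x, Hess = TRUE)
  se <- sqrt(diag(vcov(fit)))["x"]
  expect_lt(abs(coef(fit)[["x"]] - 0.5), 2.5 * se)
})

test_that("empty ordinal outcome levels are collapsed with a warning", {
  tab <- tibble::tibble(
    outcome = factor(rep(c("0", "1-2"), each = 40), levels = c("0", "1-2", ">=3")),
    exposure = factor(rep(c("T1", "T2"), 40)))
  expect_warning(fit <- fit_ordinal(tab, "outcome", "exposure", adjust = "crude"),
                 "empty")
  expect_equal(nrow(fit$summary), 2)
})

test_that("the multinomial model uses fair as baseline and recovers planted odds", {
  set.seed(23)
  n <- 4000
  has <- runif(n, 0.3, 2.5)
  w_good <- exp(0.4 - 1.0 * (has - 1.25))
  w_bad <- exp(-1.9 + 1.0 * (has - 1.25))
  tot <- 1 + w_good + w_bad
  u <- runif(n)
  lq <- ifelse(u < w_good / tot, "good",
               ifelse(u < (w_good + w_bad) / tot, "bad", "fair"))
  tab <- tibble::tibble(
    life_quality_cat = factor(lq, levels = c("fair", "good", "bad")),
    life_quality_excluded = FALSE, has = has)
  fit <- fit_multinomial(tab, adjust = "crude")
  expect_equal(fit$summary$level, c("fair", "good", "bad"))
  expect_true(fit$summary$reference[1])
  expect_true(all(fit$summary$n > 0))
  lo <- log(fit$summary$estimate[-1])
  expect_lt(abs(lo[1] - (-1.0)), 0.15)
  expect_lt(abs(lo[2] - 1.0), 0.25)

  tab2 <- tab[tab$life_quality_cat != "bad", ]
  expect_error(fit_multinomial(dplyr::mutate(tab2,
                                             life_quality_cat = droplevels(life_quality_cat)),
                               adjust = "crude"),
               "categories")
})

test_that("median-assignment trend test is exact in the noise-free case", {
  tab <- noise_free_table()
  res <- suppressWarnings(
    p_trend(tab, outcome = "has", exposure = "dds_tertile",
            continuous = "dds", adjust = "crude", family = "linear"))
  expect_equal(res$estimate, -0.1, tolerance = 1e-12)
  expect_equal(unname(res$medians), c(1, 2, 3))
  expect_lt(res$p.value, 1e-12)
})

test_that("with two categories the trend test equals the dummy-coded Wald test", {
  set.seed(31)
  n <- 200
  cont <- runif(n, 1, 8)
  cat2 <- factor(ifelse(cont <= median(cont), "lo", "hi"), levels = c("lo", "hi"))
  tab <- tibble::tibble(y = rnorm(n), g = cat2, cont = cont)
  res <- p_trend(tab, outcome = "y", exposure = "g", continuous = "cont",
                 adjust = "crude", family = "linear")
  ref <- summary(lm(y ~ g, data = tab))$coefficients["ghi", "Pr(>|t|)"]
  expect_equal(res$p.value, ref, tolerance = 1e-12)
})

test_that("a monotone planted effect gives a decisive trend p-value", {
  co <- simulate_cohort(sim_config(n_participants = 5000, seed = 41))
  tab <- build_analysis_table(apply_inclusion_rules(co))
  res <- p_trend(tab, outcome = "has", exposure = "dds_tertile",
                 continuous = "dds", adjust = "model2", family = "linear")
  expect_lt(res$p.value, 0.001)
})

test_that("interaction LRT: identical strata give a null statistic, df matches", {
  set.seed(43)
  half <- tibble::tibble(
    has = rnorm(120), dds_tertile = factor(rep(c("T1", "T2", "T3"), 40)))
  dup <- dplyr::bind_rows(dplyr::mutate(half, gender = "man"),
                          dplyr::mutate(half, gender = "woman")) |>
    dplyr::mutate(gender = factor(gender))
  res <- interaction_lrt(dup, "gender", adjust = "crude")
  expect_equal(res$lrt$statistic, 0, tolerance = 1e-8)
  expect_equal(res$lrt$df, 2)      # (3 - 1) x (2 - 1)
  expect_equal(nrow(res$strata), 2)
  expect_equal(res$strata$estimate[1], res$strata$estimate[2], tolerance = 1e-10)
})

test_that("stratified estimates drop the stratifier from the adjustment", {
  co <- simulate_cohort(sim_config(n_participants = 1200, seed = 47))
  tab <- build_analysis_table(apply_inclusion_rules(co))
  res <- interaction_lrt(tab, "gender", outcome = "has", adjust = "model2")
  expect_equal(res$strata$n, as.integer(table(tab$gender)[c("man", "woman")]))
  expect_true(all(res$strata$conf.low < res$strata$estimate &
                    res$strata$estimate < res$strata$conf.high))
  expect_true(res$lrt$p.value > 0 && res$lrt$p.value <= 1)
  # bmi_group analyses likewise drop bmi itself from the adjustment
  res2 <- interaction_lrt(tab, "bmi_group", outcome = "has", adjust = "model2")
  expect_equal(nrow(res2$strata), 2)
  expect_false("bmi" %in% adjustment_terms("model2", drop = c("bmi_group", "bmi")))
  expect_true("bmi" %in% adjustment_terms("model2"))
})

test_that("baseline table: ANOVA and chi-square behave on degenerate input", {
  g <- factor(rep(c("T1", "T2", "T3"), each = 4))
  tab <- tibble::tibble(dds_tertile = g,
                        age = rep(c(60, 62, 64, 66), 3),
                        gender = factor(rep(c("man", "woman"), 6)))
  out <- baseline_table(tab, continuous = "age", categorical = "gender")
  # identical groups: no between-group variance
  expect_equal(out$p.value[out$variable == "age"][1], 1, tolerance = 1e-12)
  # perfectly balanced 2x3 table: chi-square statistic 0, p = 1
  expect_equal(out$p.value[out$variable == "gender"][1], 1, tolerance = 1e-12)
})

test_that("baseline ANOVA matches the hand-computed F statistic", {
  tab <- tibble::tibble(
    dds_tertile = factor(rep(c("T1", "T2", "T3"), each = 3)),
    age = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  out <- baseline_table(tab, continuous = "age", categorical = character(0))
  # SSB = 6, SSW = 6 -> F = 3 on (2, 6) df
  expect_equal(out$p.value[1], pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("the full pipeline is deterministic and its sensitivity run is a subset", {
  co <- simulate_cohort(sim_config(n_participants = 500, seed = 53))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_full_pipeline(co, out_dir = d1, sensitivity = TRUE,
                          subgroup_outcomes = "has")
  r2 <- run_full_pipeline(co, out_dir = d2, sensitivity = TRUE,
                          subgroup_outcomes = "has")
  expect_equal(md5_of_dir(d1), md5_of_dir(d2))
  expect_true(file.exists(file.path(d1, "dds_models.csv")))
  expect_lte(r1$sensitivity_n, nrow(r1$table))
  expect_equal(r1$exclusions$n_remaining[6], nrow(r1$table))
  # forest plot builds from the subgroup fits
  p <- plot_forest(r1$subgroup_fits)
  expect_s3_class(p, "ggplot")
})
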