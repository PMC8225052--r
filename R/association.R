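MODEL1_TERMS <- c("age", "gender", "region", "residency", "education",
                  "income_tertile", "marriage")
MODEL2_TERMS <- c(MODEL1_TERMS, "bmi", "smoking", "alcohol")

#' Covariate sets for the adjusted models
#'
#' `crude` adjusts for nothing; `model1` for age, gender, region of
#' residence, residency, education, income tertile and marriage status;
#' `model2` additionally for BMI, smoking and alcohol use.
#'
#' @param adjust `"crude"`, `"model1"` or `"model2"`.
#' @param drop Covariates to omit (used by subgroup analyses, which adjust
#'   for all covariates other than the stratifying one).
#' @return Character vector of term names (possibly empty).
#' @export
adjustment_terms <- function(adjust = c("model2", "model1", "crude"), drop = NULL) {
  adjust <- match.arg(adjust)
  terms <- switch(adjust, crude = character(0), model1 = MODEL1_TERMS,
                  model2 = MODEL2_TERMS)
  setdiff(terms, drop)
}

build_formula <- function(outcome, rhs_terms) {
  rhs <- if (length(rhs_terms) == 0) "1" else paste(rhs_terms, collapse = " + ")
  as.formula(paste(outcome, "~", rhs))
}

new_dda_fit <- function(fit, family, outcome, exposure, adjust, summary, n,
                        p_trend = NA_real_) {
  structure(list(fit = fit, family = family, outcome = outcome,
                 exposure = exposure, adjust = adjust, summary = summary,
                 n = n, p_trend = p_trend),
            class = "dda_fit")
}

#' @export
print.dda_fit <- function(x, ...) {
  cat(sprintf("<dda_fit: %s %s ~ %s (%s), n = %d>\n",
              x$family, x$outcome, x$exposure, x$adjust, x$n))
  print(x$summary)
  if (!is.na(x$p_trend)) cat(sprintf("p-trend: %.4g\n", x$p_trend))
  invisible(x)
}

# Cumulative-logit fit that degrades gracefully: with only two observed
# outcome levels the proportional-odds model IS binary logistic regression
# (one cumulative split), which MASS::polr refuses to fit, so glm takes over
# with the same slope parameterization.
fit_cumulative <- function(formula, data, outcome) {
  if (nlevels(data[[outcome]]) >= 3) {
    MASS::polr(formula, data = data, Hess = TRUE)
  } else {
    glm(formula, data = data, family = stats::binomial())
  }
}

cumulative_coefs <- function(fit) {
  if (inherits(fit, "polr")) {
    cf <- summary(fit)$coefficients
    out <- cbind(value = cf[, "Value"], se = cf[, "Std. Error"])
  } else {
    cf <- summary(fit)$coefficients
    out <- cbind(value = cf[, "Estimate"], se = cf[, "Std. Error"])
  }
  out
}

check_full_rank <- function(fit) {
  bad <- names(coef(fit))[is.na(coef(fit))]
  if (length(bad) > 0) {
    abort(sprintf("Model is rank deficient; collinear term(s): %s.",
                  paste(bad, collapse = ", ")))
  }
}

exposure_summary <- function(data, exposure, levels, est, se, p,
                             transform = identity, z = qnorm(0.975)) {
  counts <- table(data[[exposure]])[levels]
  est <- unname(est); se <- unname(se); p <- unname(p)
  tibble::tibble(
    level = levels,
    n = as.integer(counts),
    reference = c(TRUE, rep(FALSE, length(levels) - 1L)),
    estimate = c(NA_real_, transform(est)),
    conf.low = c(NA_real_, transform(est - z * se)),
    conf.high = c(NA_real_, transform(est + z * se)),
    p.value = c(NA_real_, p))
}

#' Linear model of the healthy aging score on a categorical exposure
#'
#' Ordinary least squares with Wald 95% confidence intervals; the first
#' factor level of the exposure is the reference and is reported as such
#' with estimate `NA`.
#'
#' @param data Analysis table (one row per participant; see
#'   [build_analysis_table()]).
#' @param exposure Name of a factor column (e.g. `"dds_tertile"`).
#' @param adjust Adjustment set, see [adjustment_terms()].
#' @param outcome Numeric outcome column, default `"has"`.
#' @param trend_on Optional name of the continuous variable underlying the
#'   exposure categories; if given, the median-assignment trend test
#'   [p_trend()] is run and stored.
#' @param drop_covariates Covariates excluded from the adjustment set.
#' @return A `dda_fit`; `$summary` holds the per-level estimates,
#'   [tidy()][generics::tidy] the full coefficient table.
#' @export
fit_linear <- function(data, exposure, adjust = "model2", outcome = "has",
                       trend_on = NULL, drop_covariates = NULL) {
  if (!is.factor(data[[exposure]])) {
    abort(sprintf("`%s` must be a factor with a declared reference level.", exposure))
  }
  data <- droplevels(data)
  covars <- adjustment_terms(adjust, drop = drop_covariates)
  fit <- lm(build_formula(outcome, c(exposure, covars)), data = data)
  check_full_rank(fit)

  levels <- levels(data[[exposure]])
  cn <- paste0(exposure, levels[-1])
  cf <- summary(fit)$coefficients
  smry <- exposure_summary(data, exposure, levels,
                           est = cf[cn, "Estimate"],
                           se = cf[cn, "Std. Error"],
                           p = cf[cn, "Pr(>|t|)"])
  pt <- if (is.null(trend_on)) NA_real_ else {
    p_trend(data, outcome = outcome, exposure = exposure,
            continuous = trend_on, adjust = adjust, family = "linear",
            drop_covariates = drop_covariates)$p.value
  }
  new_dda_fit(fit, "linear", outcome, exposure, adjust, smry, nrow(data), pt)
}

#' Proportional-odds model of an ordinal healthy-aging component
#'
#' Fits a cumulative-logit (proportional-odds) model via [MASS::polr()] and
#' reports odds ratios per exposure level against the reference. The outcome
#' must be an ordered-compatible factor whose level order encodes the
#' intended direction: limitation, comorbidity and stress categories run
#' from none/low to most/high, so an OR below 1 means fewer limitations or
#' less stress at that exposure level; cognition tertiles run from low to
#' high function, so an OR above 1 means better cognition. Outcome levels
#' with zero observations are collapsed with a warning.
#'
#' @inheritParams fit_linear
#' @param outcome Name of the ordinal outcome column.
#' @return A `dda_fit` with odds ratios in `$summary`.
#' @export
fit_ordinal <- function(data, outcome, exposure, adjust = "model2",
                        trend_on = NULL, drop_covariates = NULL) {
  if (!is.factor(data[[exposure]])) {
    abort(sprintf("`%s` must be a factor with a declared reference level.", exposure))
  }
  y <- data[[outcome]]
  if (!is.factor(y)) abort(sprintf("`%s` must be an ordered factor.", outcome))
  if (any(table(y) == 0)) {
    warn(sprintf("Outcome `%s` has empty level(s); collapsing.", outcome))
  }
  data[[outcome]] <- ordered(droplevels(y))
  if (nlevels(data[[outcome]]) < 2) {
    abort(sprintf("Outcome `%s` needs at least 2 observed levels.", outcome))
  }
  data <- droplevels(data)
  covars <- adjustment_terms(adjust, drop = drop_covariates)
  f <- build_formula(outcome, c(exposure, covars))
  fit <- fit_cumulative(f, data, outcome)

  levels <- levels(data[[exposure]])
  cn <- paste0(exposure, levels[-1])
  cf <- cumulative_coefs(fit)
  est <- cf[cn, "value"]
  se <- cf[cn, "se"]
  p <- 2 * pnorm(-abs(est / se))
  smry <- exposure_summary(data, exposure, levels, est, se, p, transform = exp)
  pt <- if (is.null(trend_on)) NA_real_ else {
    p_trend(data, outcome = outcome, exposure = exposure,
            continuous = trend_on, adjust = adjust, family = "ordinal",
            drop_covariates = drop_covariates)$p.value
  }
  new_dda_fit(fit, "ordinal", outcome, exposure, adjust, smry, nrow(data), pt)
}

#' Multinomial model of self-reported life quality on the healthy aging score
#'
#' Baseline-category logit via [nnet::multinom()] with "fair" as the
#' reference category; reports the odds ratio per unit HAS of reporting
#' good and of reporting bad life quality.
#'
#' @param data Analysis table; rows flagged `life_quality_excluded` (the
#'   "don't know" answers) are dropped here.
#' @param adjust Adjustment set (the life-quality analysis conventionally
#'   uses `model1`).
#' @param exposure Numeric exposure column, default `"has"`.
#' @return A `dda_fit`; `$summary` has one row per life-quality category.
#' @export
fit_multinomial <- function(data, adjust = "model1", exposure = "has") {
  if ("life_quality_excluded" %in% names(data)) {
    data <- data[!data$life_quality_excluded, , drop = FALSE]
  }
  y <- droplevels(data$life_quality_cat)
  if (nlevels(y) < 3) {
    abort(sprintf("All three life-quality categories must be present (observed: %s).",
                  paste(levels(y), collapse = ", ")))
  }
  data$life_quality_cat <- relevel(y, ref = "fair")
  covars <- adjustment_terms(adjust)
  fit <- nnet::multinom(build_formula("life_quality_cat", c(exposure, covars)),
                        data = data, trace = FALSE, Hess = TRUE, model = TRUE)

  cats <- levels(data$life_quality_cat)
  cf <- coef(fit)
  V <- vcov(fit)
  rows <- lapply(cats[-1], function(cat) {
    par <- paste0(cat, ":", exposure)
    est <- cf[cat, exposure]
    se <- sqrt(V[par, par])
    tibble::tibble(level = cat, n = sum(data$life_quality_cat == cat),
                   reference = FALSE, estimate = exp(est),
                   conf.low = exp(est - qnorm(0.975) * se),
                   conf.high = exp(est + qnorm(0.975) * se),
                   p.value = 2 * pnorm(-abs(est / se)))
  })
  smry <- dplyr::bind_rows(
    tibble::tibble(level = "fair", n = sum(data$life_quality_cat == "fair"),
                   reference = TRUE, estimate = NA_real_,
                   conf.low = NA_real_, conf.high = NA_real_,
                   p.value = NA_real_),
    rows)
  new_dda_fit(fit, "multinomial", "life_quality_cat", exposure, adjust, smry,
              nrow(data))
}

#' Median-assignment test for linear trend across exposure categories
#'
#' Replaces each exposure category with the within-category median of the
#' underlying continuous exposure, enters that single number as a continuous
#' regressor in a separate model with the same adjustment, and returns the
#' Wald p-value of its coefficient.
#'
#' @inheritParams fit_linear
#' @param continuous Name of the continuous variable underlying the
#'   categories (e.g. `"dds"` for DDS tertiles).
#' @param family `"linear"` or `"ordinal"`, matching the main model.
#' @return List with `p.value`, `estimate` (slope per unit of the continuous
#'   exposure) and `medians` (named per category).
#' @export
p_trend <- function(data, outcome, exposure, continuous, adjust = "model2",
                    family = c("linear", "ordinal"), drop_covariates = NULL) {
  family <- match.arg(family)
  data <- droplevels(data)
  meds <- tapply(data[[continuous]], data[[exposure]], median)
  data$.trend <- as.numeric(meds[as.character(data[[exposure]])])
  covars <- adjustment_terms(adjust, drop = drop_covariates)
  f <- build_formula(outcome, c(".trend", covars))
  if (family == "linear") {
    fit <- lm(f, data = data)
    cf <- summary(fit)$coefficients
    est <- cf[".trend", "Estimate"]
    p <- cf[".trend", "Pr(>|t|)"]
  } else {
    data[[outcome]] <- ordered(droplevels(data[[outcome]]))
    fit <- fit_cumulative(f, data, outcome)
    cf <- cumulative_coefs(fit)
    est <- cf[".trend", "value"]
    p <- 2 * pnorm(-abs(est / cf[".trend", "se"]))
  }
  list(p.value = unname(p), estimate = unname(est),
       medians = setNames(as.numeric(meds), names(meds)))
}

SUBGROUP_PARENT <- c(age_group = "age", bmi_group = "bmi",
                     gender = "gender", region = "region",
                     smoking = "smoking", alcohol = "alcohol")

#' Derive the subgroup variables used in stratified analyses
#'
#' Adds `age_group` (<= 60 vs > 60 years, the conventional cut, applied as
#' stated even though the cohort window starts at 60 -- the lower stratum is
#' then exactly age 60) and `bmi_group` (< 24 vs >= 24 kg/m^2).
#'
#' @param data Analysis table with `age` and `bmi`.
#' @return `data` with the two factor columns added.
#' @export
add_subgroup_vars <- function(data) {
  data$age_group <- factor(ifelse(data$age <= 60, "le60", "gt60"),
                           levels = c("le60", "gt60"))
  data$bmi_group <- factor(ifelse(data$bmi < 24, "lt24", "ge24"),
                           levels = c("lt24", "ge24"))
  data
}

#' Subgroup analysis with a likelihood-ratio interaction test
#'
#' Compares the adjusted model with and without exposure-by-subgroup
#' interaction terms by a likelihood-ratio test, and fits the exposure model
#' within each stratum (adjusted for all covariates other than the
#' stratifying one) to report the top-versus-reference estimate per stratum
#' for a forest plot.
#'
#' @inheritParams fit_linear
#' @param subgroup Name of a two-level factor column (see
#'   [add_subgroup_vars()] for `age_group` / `bmi_group`).
#' @param family `"linear"` (HAS) or `"ordinal"` (components).
#' @param outcome Outcome column.
#' @return A `dda_subgroups` object: `$lrt` (statistic, df, p.value) and
#'   `$strata` (per-stratum n, estimate, CI for the highest exposure level
#'   vs reference). Strata too small to fit are reported as `NA` with a
#'   warning.
#' @export
interaction_lrt <- function(data, subgroup, exposure = "dds_tertile",
                            outcome = "has", adjust = "model2",
                            family = c("linear", "ordinal")) {
  family <- match.arg(family)
  data <- droplevels(data)
  sg <- data[[subgroup]]
  if (!is.factor(sg)) abort(sprintf("`%s` must be a factor.", subgroup))
  if (nlevels(sg) < 2) abort(sprintf("`%s` must have at least 2 strata.", subgroup))
  parent <- unname(SUBGROUP_PARENT[subgroup])
  drop <- c(subgroup, if (!is.na(parent)) parent)
  covars <- adjustment_terms(adjust, drop = drop)

  rhs_red <- c(exposure, subgroup, covars)
  rhs_full <- c(paste(exposure, "*", subgroup), covars)
  if (family == "linear") {
    reduced <- lm(build_formula(outcome, rhs_red), data = data)
    full <- lm(build_formula(outcome, rhs_full), data = data)
  } else {
    data[[outcome]] <- ordered(droplevels(data[[outcome]]))
    reduced <- fit_cumulative(build_formula(outcome, rhs_red), data, outcome)
    full <- fit_cumulative(build_formula(outcome, rhs_full), data, outcome)
  }
  lrt <- lmtest::lrtest(reduced, full)
  lrt_tbl <- tibble::tibble(statistic = lrt$Chisq[2], df = lrt$Df[2],
                            p.value = lrt$`Pr(>Chisq)`[2])

  strata <- purrr::map(levels(sg), function(lv) {
    sub <- data[sg == lv, , drop = FALSE]
    res <- tryCatch({
      f <- if (family == "linear") {
        fit_linear(sub, exposure, adjust = adjust, outcome = outcome,
                   drop_covariates = drop)
      } else {
        fit_ordinal(sub, outcome = outcome, exposure = exposure,
                    adjust = adjust, drop_covariates = drop)
      }
      top <- f$summary[nrow(f$summary), ]
      tibble::tibble(stratum = lv, n = nrow(sub), estimate = top$estimate,
                     conf.low = top$conf.low, conf.high = top$conf.high,
                     p.value = top$p.value)
    }, error = function(e) {
      warn(sprintf("Stratum `%s = %s` could not be fitted (%s); reported as NA.",
                   subgroup, lv, conditionMessage(e)))
      tibble::tibble(stratum = lv, n = nrow(sub), estimate = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     p.value = NA_real_)
    })
    res
  })
  structure(list(subgroup = subgroup, exposure = exposure, outcome = outcome,
                 family = family, adjust = adjust, lrt = lrt_tbl,
                 strata = dplyr::bind_rows(strata)),
            class = "dda_subgroups")
}

#' @export
print.dda_subgroups <- function(x, ...) {
  cat(sprintf("<dda_subgroups: %s ~ %s by %s (%s)>\n",
              x$outcome, x$exposure, x$subgroup, x$family))
  print(x$strata)
  cat(sprintf("Interaction LRT: chi2 = %.3f, df = %d, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p.value))
  invisible(x)
}

#' Baseline descriptive table across exposure groups
#'
#' Continuous variables are summarized as mean (SD) and compared by one-way
#' ANOVA; categorical variables as column percentages compared by the
#' chi-square test. A chi-square test whose expected counts degenerate (an
#' empty row or column) is flagged unreliable.
#'
#' @param data Analysis table.
#' @param group Grouping factor column (default `"dds_tertile"`).
#' @param continuous,categorical Character vectors of variable names.
#' @return Tibble with `variable`, `level`, one formatted column per group
#'   level, `p.value`, `test` and `reliable`.
#' @export
baseline_table <- function(data, group = "dds_tertile",
                           continuous = c("age", "bmi"),
                           categorical = c("gender", "region", "residency",
                                           "education", "income_tertile",
                                           "marriage", "smoking", "alcohol")) {
  g <- droplevels(factor(data[[group]]))
  glev <- levels(g)

  cont_rows <- purrr::map(continuous, function(v) {
    x <- data[[v]]
    cells <- vapply(glev, function(l) {
      sprintf("%.1f (%.1f)", mean(x[g == l]), sd(x[g == l])) }, character(1))
    p <- summary(aov(x ~ g))[[1]][["Pr(>F)"]][1]
    out <- tibble::tibble(variable = v, level = NA_character_)
    out[glev] <- as.list(cells)
    out$p.value <- p; out$test <- "anova"; out$reliable <- TRUE
    out
  })

  cat_rows <- purrr::map(categorical, function(v) {
    x <- droplevels(factor(data[[v]]))
    tab <- table(x, g)
    reliable <- TRUE
    p <- withCallingHandlers(
      tryCatch(chisq.test(tab)$p.value, error = function(e) NA_real_),
      warning = function(w) {
        reliable <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (is.na(p) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) reliable <- FALSE
    pct <- prop.table(tab, margin = 2) * 100
    purrr::map(levels(x), function(lv) {
      out <- tibble::tibble(variable = v, level = lv)
      out[glev] <- as.list(sprintf("%.1f", pct[lv, glev]))
      out$p.value <- p; out$test <- "chi-square"; out$reliable <- reliable
      out
    }) |> dplyr::bind_rows()
  })

  dplyr::bind_rows(dplyr::bind_rows(cont_rows), dplyr::bind_rows(cat_rows))
}
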