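#' Assemble the analysis-ready participant table
#'
#' Joins the prepared covariates, the averaged dietary exposures with DDS
#' tertiles, and the healthy-aging scores with their categorical versions
#' into one row per participant, converting the covariate strings to factors
#' with the conventional reference levels (man, south, rural, lower
#' education, low income, married, non-smoker, < 1 drink/week).
#'
#' @param cohort A filtered `dda_cohort` (see [apply_inclusion_rules()]).
#' @param averaging Passed to [score_dds()].
#' @return Tibble with one row per participant; the DDS cutpoint report is
#'   attached as attribute `"dds_cutpoints"`.
#' @export
build_analysis_table <- function(cohort, averaging = "nested") {
  stopifnot(inherits(cohort, "dda_cohort"))
  surveys <- prepare_covariates(cohort$surveys)
  dds <- add_dds_tertiles(score_dds(cohort$dietary, cohort$food_table,
                                    averaging = averaging))
  has <- categorize_components(score_has(surveys), surveys$life_quality)

  out <- surveys |>
    dplyr::select("participant_id", "age", "gender", "region", "residency",
                  "education", "income", "income_tertile", "marriage",
                  "smoking", "alcohol", "bmi", "site_id", "life_quality") |>
    dplyr::mutate(
      gender = factor(.data$gender, levels = c("man", "woman")),
      region = factor(.data$region, levels = c("south", "north")),
      residency = factor(.data$residency, levels = c("rural", "urban")),
      education = factor(.data$education,
                         levels = c("primary_or_below", "middle_or_above")),
      marriage = factor(.data$marriage, levels = c("married", "other")),
      smoking = factor(.data$smoking, levels = c("not", "current")),
      alcohol = factor(.data$alcohol, levels = c("lt1_per_week", "ge1_per_week"))) |>
    dplyr::inner_join(dds, by = "participant_id") |>
    dplyr::inner_join(has, by = "participant_id") |>
    add_subgroup_vars()
  attr(out, "dds_cutpoints") <- attr(dds, "cutpoint_label")
  out
}

COMPONENT_OUTCOMES <- c(limitation = "limitation_cat",
                        comorbidity = "comorbidity_cat",
                        cognition = "cognition_tertile",
                        stress = "pss_tertile")
CONSUMER_SPLIT_GROUPS <- c("fruits", "aquatic", "dairy")

fit_summary_row <- function(fit, label) {
  dplyr::mutate(fit$summary, outcome = fit$outcome, model = label,
                family = fit$family, p_trend = fit$p_trend,
                .before = 1)
}

#' Run the whole association pipeline
#'
#' Orchestrates the full analysis on a cohort: inclusion filtering,
#' covariate preparation, dietary and health scoring, then
#'
#' * `baseline`: descriptive table across DDS tertiles (ANOVA / chi-square);
#' * `dds_models`: DDS tertiles vs HAS (linear) and vs the four components
#'   (proportional odds), crude / model 1 / model 2, each with the
#'   median-assignment p-trend;
#' * `food_models`: each scored food group, categorized by consumer split
#'   (fruits, aquatic products, dairy) or tertiles (others), vs HAS, crude
#'   and fully adjusted;
#' * `life_quality`: multinomial model of life quality on HAS, crude and
#'   adjusted (life-quality "don't know" answers excluded there only);
#' * `subgroups`: stratified DDS-vs-outcome estimates with
#'   likelihood-ratio interaction tests for the six conventional
#'   subgroup variables;
#' * `sensitivity` (optional): the HAS and stress models refitted on
#'   participants with no "don't know" stress item.
#'
#' Every result is a plain tibble (or a list of `dda_fit` /
#' `dda_subgroups` objects alongside its tibble), so the output is
#' deterministic given the input data and can be written to CSV.
#'
#' @param cohort A `dda_cohort` (unfiltered is fine; the inclusion rules are
#'   applied first) or a directory path readable by [read_cohort()].
#' @param out_dir Optional directory; if given, each table is written there
#'   as CSV and a short text log of the exclusion flow is saved.
#' @param sensitivity If `TRUE`, also run the no-"don't know" stress subset.
#' @param subgroup_outcomes Outcomes for the subgroup/interaction analysis;
#'   defaults to HAS plus the four components.
#' @param averaging DDS averaging scheme, see [score_dds()].
#' @return Named list with the elements above plus `exclusions`,
#'   `dds_cutpoints` and the analysis `table`, invisibly when `out_dir` is
#'   given.
#' @export
run_full_pipeline <- function(cohort, out_dir = NULL, sensitivity = FALSE,
                              subgroup_outcomes = c("has", COMPONENT_OUTCOMES),
                              averaging = "nested") {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  filtered <- apply_inclusion_rules(cohort)
  data <- build_analysis_table(filtered, averaging = averaging)

  baseline <- baseline_table(data)

  dds_fits <- list()
  for (adj in c("crude", "model1", "model2")) {
    dds_fits[[paste0("has_", adj)]] <-
      fit_linear(data, "dds_tertile", adjust = adj, trend_on = "dds")
    for (comp in names(COMPONENT_OUTCOMES)) {
      dds_fits[[paste0(comp, "_", adj)]] <-
        fit_ordinal(data, COMPONENT_OUTCOMES[[comp]], "dds_tertile",
                    adjust = adj, trend_on = "dds")
    }
  }
  dds_models <- purrr::imap(dds_fits, function(f, nm) {
    fit_summary_row(f, sub("^.*_(crude|model1|model2)$", "\\1", nm))
  }) |> dplyr::bind_rows()

  food_fits <- list()
  for (grp in SCORED_GROUPS) {
    col <- paste0("g_per_1000kcal_", grp)
    scheme <- if (grp %in% CONSUMER_SPLIT_GROUPS) "consumer_split" else "tertile"
    dat <- data
    dat$food_cat <- categorize_food_group(dat[[col]], scheme = scheme)
    for (adj in c("crude", "model2")) {
      food_fits[[paste(grp, adj, sep = "_")]] <-
        fit_linear(dat, "food_cat", adjust = adj, trend_on = col)
    }
  }
  food_models <- purrr::imap(food_fits, function(f, nm) {
    dplyr::mutate(fit_summary_row(f, sub("^.*_(crude|model2)$", "\\1", nm)),
                  food_group = sub("_(crude|model2)$", "", nm), .before = 1)
  }) |> dplyr::bind_rows()

  lq_fits <- list(crude = fit_multinomial(data, adjust = "crude"),
                  adjusted = fit_multinomial(data, adjust = "model1"))
  life_quality <- purrr::imap(lq_fits, fit_summary_row) |> dplyr::bind_rows()

  subgroup_objs <- list()
  for (out in subgroup_outcomes) {
    fam <- if (out == "has") "linear" else "ordinal"
    for (sg in names(SUBGROUP_PARENT)) {
      subgroup_objs[[paste(out, sg, sep = "_")]] <-
        interaction_lrt(data, sg, outcome = out, family = fam)
    }
  }
  subgroups <- purrr::map(subgroup_objs, function(x) {
    dplyr::mutate(x$strata, outcome = x$outcome, subgroup = x$subgroup,
                  family = x$family, lrt_statistic = x$lrt$statistic,
                  lrt_df = x$lrt$df, interaction_p = x$lrt$p.value,
                  .before = 1)
  }) |> dplyr::bind_rows()

  results <- list(table = data, baseline = baseline, dds_models = dds_models,
                  food_models = food_models, life_quality = life_quality,
                  subgroups = subgroups,
                  exclusions = exclusion_counts(filtered),
                  dds_cutpoints = attr(data, "dds_cutpoints"),
                  fits = c(dds_fits, food_fits, lq_fits),
                  subgroup_fits = subgroup_objs)

  if (sensitivity) {
    sub <- data[data$pss_dk_count == 0, , drop = FALSE]
    sens <- list(
      has_model2 = fit_linear(sub, "dds_tertile", adjust = "model2",
                              trend_on = "dds"),
      stress_model2 = fit_ordinal(sub, "pss_tertile", "dds_tertile",
                                  adjust = "model2", trend_on = "dds"))
    results$sensitivity <- purrr::imap(sens, fit_summary_row) |>
      dplyr::bind_rows()
    results$sensitivity_n <- nrow(sub)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    emit <- c("baseline", "dds_models", "food_models", "life_quality",
              "subgroups", "exclusions",
              if (sensitivity) "sensitivity")
    for (nm in emit) {
      readr::write_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    writeLines(c("Exclusion flow:",
                 utils::capture.output(print(as.data.frame(results$exclusions))),
                 "", paste("DDS tertiles:", results$dds_cutpoints)),
               file.path(out_dir, "log.txt"))
    return(invisible(results))
  }
  results
}
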