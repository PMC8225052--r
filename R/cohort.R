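#' Bundle the four input tables into a cohort object
#'
#' A cohort is a light container holding the dietary records, the
#' food-composition table, the participant surveys and the site table.
#' It carries no derived quantities; scoring functions take the member
#' tibbles and return new tibbles.
#'
#' @param dietary,food_table,surveys,sites Tibbles in the schemas returned by
#'   [cohort_schemas()].
#' @param ground_truth Optional list of planted simulation parameters
#'   (attached by [simulate_cohort()]).
#' @return An object of class `dda_cohort`.
#' @export
new_cohort <- function(dietary, food_table, surveys, sites, ground_truth = NULL) {
  structure(
    list(dietary = tibble::as_tibble(dietary),
         food_table = tibble::as_tibble(food_table),
         surveys = tibble::as_tibble(surveys),
         sites = tibble::as_tibble(sites),
         ground_truth = ground_truth),
    class = "dda_cohort")
}

#' @export
print.dda_cohort <- function(x, ...) {
  cat("<dda_cohort>\n")
  cat(sprintf("  participants : %d\n", nrow(x$surveys)))
  cat(sprintf("  dietary rows : %d (waves %s)\n", nrow(x$dietary),
              paste(sort(unique(x$dietary$wave)), collapse = ", ")))
  cat(sprintf("  foods        : %d\n", nrow(x$food_table)))
  cat(sprintf("  sites        : %d\n", nrow(x$sites)))
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) {
    cat("  exclusions applied:\n")
    for (i in seq_len(nrow(excl))) {
      cat(sprintf("    %-38s -%d (remaining %d)\n",
                  excl$rule[i], excl$n_excluded[i], excl$n_remaining[i]))
    }
  }
  invisible(x)
}

#' Read a cohort from a directory of CSV tables
#'
#' Expects `dietary_records.csv`, `food_table.csv`, `surveys.csv` and
#' `sites.csv` in `dir`, validated against [cohort_schemas()]. No filtering
#' is applied; see [apply_inclusion_rules()].
#'
#' @param dir Directory containing the four CSV files.
#' @return A `dda_cohort`.
#' @export
read_cohort <- function(dir) {
  cohort <- new_cohort(
    dietary = read_dietary_records(file.path(dir, "dietary_records.csv")),
    food_table = read_food_table(file.path(dir, "food_table.csv")),
    surveys = read_surveys(file.path(dir, "surveys.csv")),
    sites = read_sites(file.path(dir, "sites.csv")))
  validate_cohort(cohort)
  cohort
}

#' Cross-table consistency checks
#'
#' Verifies that every dietary record resolves to a food in the composition
#' table and every survey site exists in the site table.
#'
#' @param cohort A `dda_cohort`.
#' @return The cohort, invisibly; aborts on inconsistency.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "dda_cohort"))
  unknown <- setdiff(unique(cohort$dietary$food_id), cohort$food_table$food_id)
  if (length(unknown) > 0) {
    abort(sprintf("Dietary records reference unknown food_id(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  unknown_site <- setdiff(unique(cohort$surveys$site_id), cohort$sites$site_id)
  if (length(unknown_site) > 0) {
    abort(sprintf("Surveys reference unknown site_id(s): %s.",
                  paste(unknown_site, collapse = ", ")))
  }
  invisible(cohort)
}

#' Write a cohort to a directory of CSV tables
#'
#' @param cohort A `dda_cohort`.
#' @param dir Output directory (created if absent). If the cohort carries
#'   simulation ground truth it is written as `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dda_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$dietary, file.path(dir, "dietary_records.csv"))
  readr::write_csv(cohort$food_table, file.path(dir, "food_table.csv"))
  readr::write_csv(cohort$surveys, file.path(dir, "surveys.csv"))
  readr::write_csv(cohort$sites, file.path(dir, "sites.csv"))
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

# Table-1 covariates that must be complete for inclusion. Income is exempt:
# it has its own imputation rule.
COVARIATE_COLS <- c("age", "gender", "weight", "height", "region", "residency",
                    "education", "marriage", "smoking", "alcohol")
LIMITATION_COLS <- paste0("limitation_", c("lift", "squat", "stand", "sit", "walk"))
DISEASE_COLS <- c("diabetes", "myocardial_infarction", "stroke", "apoplexy", "asthma")
COGNITION_COLS <- c("cog_immediate", "cog_delayed", "cog_serial7s", "cog_backward")
PSS_COLS <- sprintf("pss_%02d", 1:14)

#' Apply the cohort inclusion and exclusion rules
#'
#' Participants are filtered sequentially, in the order the criteria are
#' defined, and the count removed at each step is recorded:
#'
#' 1. age outside 60-80 years at the outcome wave;
#' 2. missing information on any baseline covariate (income exempt: it is
#'    imputed, not excluded);
#' 3. absent from the dietary survey (no recall records in either baseline
#'    wave);
#' 4. missing information on any healthy-aging index item (functional
#'    limitation, disease history, blood pressure, cognition, perceived
#'    stress);
#' 5. a "don't know" answer to any functional-limitation or comorbidity
#'    question;
#' 6. "don't know" on all 14 perceived-stress items (fewer than 14 is
#'    tolerated; those items are imputed at scoring time).
#'
#' The filter never errors on content; it only removes rows. It is
#' idempotent: re-applying it to its own output removes nobody.
#'
#' @param cohort A `dda_cohort`.
#' @return The filtered `dda_cohort` with an `"exclusions"` attribute: a
#'   tibble with `rule`, `n_excluded`, `n_remaining`. Dietary records of
#'   excluded participants are dropped too. See [exclusion_counts()].
#' @export
apply_inclusion_rules <- function(cohort) {
  stopifnot(inherits(cohort, "dda_cohort"))
  s <- cohort$surveys
  with_diet <- unique(cohort$dietary$participant_id[
    cohort$dietary$wave %in% BASELINE_WAVES & cohort$dietary$amount > 0])

  rules <- list(
    age_outside_60_80 = function(s) {
      is.na(s$age) | s$age < 60 | s$age > 80
    },
    missing_covariates = function(s) {
      !complete.cases(s[, COVARIATE_COLS])
    },
    absent_from_dietary_survey = function(s) {
      !(s$participant_id %in% with_diet)
    },
    missing_aging_indices = function(s) {
      !complete.cases(s[, c(LIMITATION_COLS, DISEASE_COLS,
                            "hypertension_diagnosed", "sbp", "dbp",
                            COGNITION_COLS, PSS_COLS)])
    },
    dont_know_limitation_or_comorbidity = function(s) {
      items <- s[, c(LIMITATION_COLS, DISEASE_COLS, "hypertension_diagnosed")]
      Reduce(`|`, lapply(items, function(v) !is.na(v) & v == "dont_know"))
    },
    all_pss_dont_know = function(s) {
      dk <- rowSums(s[, PSS_COLS] == "dont_know", na.rm = TRUE)
      dk == 14L
    })

  log <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    drop <- rules[[i]](s)
    s <- s[!drop, , drop = FALSE]
    log[[i]] <- tibble::tibble(rule = names(rules)[i],
                               n_excluded = sum(drop),
                               n_remaining = nrow(s))
  }

  keep <- s$participant_id
  out <- new_cohort(
    dietary = dplyr::filter(cohort$dietary, .data$participant_id %in% keep),
    food_table = cohort$food_table,
    surveys = s,
    sites = cohort$sites,
    ground_truth = cohort$ground_truth)
  attr(out, "exclusions") <- dplyr::bind_rows(log)
  out
}

#' Per-rule exclusion counts of a filtered cohort
#'
#' @param cohort A `dda_cohort` returned by [apply_inclusion_rules()].
#' @return Tibble with `rule`, `n_excluded`, `n_remaining`.
#' @export
exclusion_counts <- function(cohort) {
  excl <- attr(cohort, "exclusions")
  if (is.null(excl)) abort("Cohort has not been filtered; run apply_inclusion_rules().")
  excl
}
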