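#' Count physical functional limitations
#'
#' The limitation index counts the basic tasks a participant reports
#' difficulty performing: lifting a 5 kg bag, squatting down, standing up,
#' sitting continuously and walking a kilometre. Participants answering
#' "don't know" to any item are excluded before scoring, so encountering one
#' here signals a filtering bug and raises an error.
#'
#' @param items Character matrix or data frame with 5 columns of responses in
#'   `no_difficulty` / `difficulty` / `dont_know`, or a length-5 vector for a
#'   single participant.
#' @return Integer count 0-5 per row.
#' @export
count_limitations <- function(items) {
  m <- as.matrix(items)
  if (is.null(dim(m)) || ncol(m) == 1L) m <- matrix(m, nrow = 1)
  if (ncol(m) != 5) abort("Expected 5 limitation items.")
  if (any(m == "dont_know")) {
    abort("\"don't know\" limitation response found; such participants must be excluded upstream.")
  }
  bad <- !(m %in% c("no_difficulty", "difficulty"))
  if (any(bad)) abort(sprintf("Invalid limitation response `%s`.", m[bad][1]))
  as.integer(rowSums(m == "difficulty"))
}

#' Count comorbidities, applying the measured-blood-pressure hypertension rule
#'
#' Counts six chronic conditions: diabetes, myocardial infarction, stroke,
#' apoplexy and asthma from self-report, plus hypertension, which is present
#' if previously diagnosed OR systolic blood pressure >= 140 mmHg and/or
#' diastolic blood pressure >= 90 mmHg at the survey.
#'
#' @param diabetes,myocardial_infarction,stroke,apoplexy,asthma Character
#'   vectors in `yes` / `no` (`dont_know` raises an error).
#' @param hypertension_diagnosed `yes` / `no`.
#' @param sbp,dbp Measured blood pressure in mmHg, no missing values.
#' @return Integer count 0-6.
#' @export
count_comorbidities <- function(diabetes, myocardial_infarction, stroke,
                                apoplexy, asthma, hypertension_diagnosed,
                                sbp, dbp) {
  reports <- cbind(diabetes, myocardial_infarction, stroke, apoplexy, asthma,
                   hypertension_diagnosed)
  if (any(reports == "dont_know")) {
    abort("\"don't know\" disease response found; such participants must be excluded upstream.")
  }
  if (any(!(reports %in% c("yes", "no")))) abort("Disease responses must be yes/no.")
  if (anyNA(sbp) || anyNA(dbp)) abort("Blood pressure must be measured (no missing).")
  hypertension <- hypertension_diagnosed == "yes" | sbp >= 140 | dbp >= 90
  as.integer(rowSums(reports[, 1:5, drop = FALSE] == "yes") + hypertension)
}

#' Cognitive function score (0-27)
#'
#' A telephone-interview cognitive screen: immediate and delayed free recall
#' of a 10-word list (one point per word), the Serial 7s subtraction test
#' (one point per correct subtraction, up to five) and counting backward
#' from 20 (2 points if succeeded on the first try, 1 on the second, 0
#' otherwise). The four components sum to a score from 0 to 27, higher
#' meaning better function.
#'
#' @param immediate,delayed Words recalled, 0-10 each.
#' @param serial7s Correct subtractions, 0-5.
#' @param backward `first_try` / `second_try` / `fail`.
#' @return Integer score 0-27.
#' @export
score_cognition <- function(immediate, delayed, serial7s, backward) {
  if (any(is.na(immediate) | immediate < 0 | immediate > 10) ||
      any(is.na(delayed) | delayed < 0 | delayed > 10)) {
    abort("Recall counts must lie in 0-10.")
  }
  if (any(is.na(serial7s) | serial7s < 0 | serial7s > 5)) {
    abort("Serial 7s count must lie in 0-5.")
  }
  pts <- c(first_try = 2L, second_try = 1L, fail = 0L)[backward]
  if (anyNA(pts)) abort("`backward` must be first_try, second_try or fail.")
  as.integer(immediate + delayed + serial7s + pts)
}

#' Perceived Stress Scale total (0-56) with "don't know" imputation
#'
#' Responses on the 14-item PSS are coded never = 0, almost never = 1,
#' sometimes = 2, fairly often = 3, very often = 4. "Don't know" is replaced
#' by "sometimes", the neutral midpoint (which is invariant under reversal).
#' The positively-stated items are reverse-scored (value <- 4 - value) and
#' all 14 item values are summed, giving a total from 0 to 56, higher
#' meaning more perceived stress. A participant answering "don't know" to
#' all 14 items has no usable information and raises an error (such
#' participants are excluded upstream).
#'
#' @param responses Character vector of 14 responses for one participant, or
#'   a matrix / data frame with 14 columns (one row per participant).
#' @param reverse_items Positions of the positively-stated items; defaults to
#'   the instrument-standard set [pss_reversed_items()].
#' @return Tibble with columns `pss` (0-56) and `pss_dk_count` (0-13), one
#'   row per participant.
#' @export
score_pss <- function(responses, reverse_items = pss_reversed_items()) {
  m <- if (is.null(dim(responses))) matrix(responses, nrow = 1) else as.matrix(responses)
  if (ncol(m) != 14) abort(sprintf("Expected 14 PSS responses, got %d.", ncol(m)))
  valid <- c(PSS_LEVELS, LIKERT_DK)
  bad <- !(m %in% valid)
  if (any(bad)) abort(sprintf("Invalid PSS response `%s`.", m[bad][1]))

  dk <- m == LIKERT_DK
  dk_count <- as.integer(rowSums(dk))
  if (any(dk_count == 14L)) {
    abort("Participant answered \"don't know\" to all 14 PSS items; must be excluded upstream.")
  }
  m[dk] <- "sometimes"
  val <- matrix(match(m, PSS_LEVELS) - 1L, nrow = nrow(m))
  val[, reverse_items] <- 4L - val[, reverse_items]
  tibble::tibble(pss = as.integer(rowSums(val)), pss_dk_count = dk_count)
}

#' Compose the healthy aging score (0-4)
#'
#' Each of the four indices is rescaled to [0, 1] by its full score
#' (limitations / 5, comorbidities / 6, cognition / 27, stress / 56); the
#' cognition value is reversed before summation so that, for every index,
#' higher means less healthy. The composite therefore runs from 0
#' (healthiest) to 4.
#'
#' @param n_limitations 0-5.
#' @param n_comorbidities 0-6.
#' @param cognition 0-27.
#' @param pss 0-56.
#' @return Numeric HAS in [0, 4].
#' @examples
#' compose_has(1, 3, 18, 28)
#' @export
compose_has <- function(n_limitations, n_comorbidities, cognition, pss) {
  check_range <- function(x, lo, hi, what) {
    if (any(is.na(x) | x < lo | x > hi)) {
      abort(sprintf("`%s` must lie in %d-%d.", what, lo, hi))
    }
  }
  check_range(n_limitations, 0L, 5L, "n_limitations")
  check_range(n_comorbidities, 0L, 6L, "n_comorbidities")
  check_range(cognition, 0L, 27L, "cognition")
  check_range(pss, 0L, 56L, "pss")
  n_limitations / 5 + n_comorbidities / 6 + (1 - cognition / 27) + pss / 56
}

#' Score the four healthy-aging indices and their composite for a cohort
#'
#' @param surveys A filtered survey tibble (participants with "don't know"
#'   limitation/comorbidity answers or all-"don't know" stress responses must
#'   already be excluded; see [apply_inclusion_rules()]).
#' @param reverse_items Passed to [score_pss()].
#' @return Tibble with one row per participant: `n_limitations`,
#'   `n_comorbidities`, `cognition`, `pss`, `pss_dk_count`, `has`.
#' @export
score_has <- function(surveys, reverse_items = pss_reversed_items()) {
  stress <- score_pss(as.matrix(surveys[, PSS_COLS]), reverse_items)
  tibble::tibble(
    participant_id = surveys$participant_id,
    n_limitations = count_limitations(surveys[, LIMITATION_COLS]),
    n_comorbidities = count_comorbidities(
      surveys$diabetes, surveys$myocardial_infarction, surveys$stroke,
      surveys$apoplexy, surveys$asthma, surveys$hypertension_diagnosed,
      surveys$sbp, surveys$dbp),
    cognition = score_cognition(surveys$cog_immediate, surveys$cog_delayed,
                                surveys$cog_serial7s, surveys$cog_backward),
    pss = stress$pss,
    pss_dk_count = stress$pss_dk_count
  ) |>
    dplyr::mutate(has = compose_has(.data$n_limitations, .data$n_comorbidities,
                                    .data$cognition, .data$pss))
}

#' Categorical versions of the healthy-aging components and life quality
#'
#' Limitation and comorbidity counts are grouped as 0, 1-2 or >= 3;
#' cognition and stress scores into cohort-wide tertiles (low to high);
#' self-reported life quality into good (very good/good), fair and bad
#' (bad/very bad). Participants answering "don't know" on life quality are
#' not dropped from the cohort -- they are flagged for exclusion from the
#' life-quality analysis only.
#'
#' @param has_table Output of [score_has()].
#' @param life_quality Character vector aligned with `has_table` rows (the
#'   `life_quality` survey column).
#' @return `has_table` with factor columns `limitation_cat`,
#'   `comorbidity_cat` (levels `0`, `1-2`, `>=3`), `cognition_tertile`,
#'   `pss_tertile` (T1-T3) and `life_quality_cat` (good/fair/bad, `NA` for
#'   "don't know") plus logical `life_quality_excluded`.
#' @export
categorize_components <- function(has_table, life_quality) {
  cut3 <- function(n) {
    factor(ifelse(n == 0, "0", ifelse(n <= 2, "1-2", ">=3")),
           levels = c("0", "1-2", ">=3"))
  }
  lq <- dplyr::case_match(life_quality,
                          c("very_good", "good") ~ "good",
                          "fair" ~ "fair",
                          c("bad", "very_bad") ~ "bad")
  has_table |>
    dplyr::mutate(
      limitation_cat = cut3(.data$n_limitations),
      comorbidity_cat = cut3(.data$n_comorbidities),
      cognition_tertile = tertile_assign(.data$cognition),
      pss_tertile = tertile_assign(.data$pss),
      life_quality_cat = factor(lq, levels = c("fair", "good", "bad")),
      life_quality_excluded = is.na(lq))
}
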