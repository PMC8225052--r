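#' A tiny fixed cohort with hand-computed scores
#'
#' Builds a deterministic 12-participant cohort whose every dietary diversity
#' score and healthy aging score can be (and has been) computed by hand, for
#' use as an end-to-end oracle. Recall days come in five fixed menus:
#'
#' * `D1` rice + oil + salt only (480 kcal, DDS 1 -- salt and oil unscored)
#' * `D3` rice, cabbage, pork (550 kcal, DDS 3)
#' * `D4` rice, cabbage, apple, fish (600 kcal, DDS 4)
#' * `D5` rice, cabbage, egg, tofu, milk (750 kcal, DDS 5)
#' * `D8` one food from all eight scored groups plus oil and salt
#'   (1380 kcal, DDS 8)
#'
#' Food energy densities are round numbers (rice 100, cabbage 25, apple 50,
#' egg 150, fish 100, pork 200, tofu 80, milk 60, oil 900, salt 0 kcal/100 g)
#' so each day's energy is exact. Participants attend one or both baseline
#' waves; the expected DDS applies the nested day-then-wave averaging.
#'
#' @return A `dda_cohort` whose `$expected` element is a tibble of
#'   hand-computed values per participant (`dds`, `n_limitations`,
#'   `n_comorbidities`, `cognition`, `pss`, `pss_dk_count`, `has`) and whose
#'   `$day_energies` element maps the five menus to their exact kcal.
#' @export
generate_worked_example <- function() {
  food_table <- tibble::tribble(
    ~food_id,  ~energy_density, ~food_group,
    "rice",    100,             "staple",
    "cabbage", 25,              "vegetables",
    "apple",   50,              "fruits",
    "egg",     150,             "eggs",
    "fish",    100,             "aquatic",
    "pork",    200,             "meat_poultry",
    "tofu",    80,              "soy_nuts",
    "milk",    60,              "dairy",
    "oil",     900,             "oil",
    "salt",    0,               "salt")

  menus <- list(
    D1 = c(rice = 300, oil = 20, salt = 5),
    D3 = c(rice = 300, cabbage = 200, pork = 100),
    D4 = c(rice = 300, cabbage = 200, apple = 200, fish = 150),
    D5 = c(rice = 300, cabbage = 200, egg = 100, tofu = 125, milk = 250),
    D8 = c(rice = 300, cabbage = 200, apple = 200, egg = 100, fish = 150,
           pork = 100, tofu = 125, milk = 250, oil = 20, salt = 5))
  day_energies <- c(D1 = 480, D3 = 550, D4 = 600, D5 = 750, D8 = 1380)

  plans <- list(
    P01 = list(`2009` = c("D3", "D4", "D5")),
    P02 = list(`2009` = c("D3", "D3", "D3"), `2011` = c("D5", "D5", "D5")),
    P03 = list(`2011` = c("D1", "D1", "D1")),
    P04 = list(`2009` = c("D8", "D8", "D8")),
    P05 = list(`2009` = c("D1", "D3", "D5"), `2011` = c("D8", "D4", "D4")),
    P06 = list(`2011` = c("D3", "D3", "D4")),
    P07 = list(`2009` = c("D4", "D5", "D8"), `2011` = c("D5", "D5", "D8")),
    P08 = list(`2009` = c("D4", "D4", "D4")),
    P09 = list(`2011` = c("D1", "D1", "D3")),
    P10 = list(`2009` = c("D3", "D1", "D1"), `2011` = c("D3", "D3", "D3")),
    P11 = list(`2011` = c("D5", "D4", "D3")),
    P12 = list(`2009` = c("D8", "D5", "D5"), `2011` = c("D4", "D5", "D8")))

  dietary <- purrr::imap(plans, function(waves, pid) {
    purrr::imap(waves, function(menu_ids, wave) {
      purrr::imap(menu_ids, function(menu_id, day) {
        foods <- menus[[menu_id]]
        tibble::tibble(participant_id = pid, wave = as.integer(wave),
                       day = as.integer(day), food_id = names(foods),
                       amount = unname(foods))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  pss_pattern <- function(kind) {
    rev_idx <- pss_reversed_items()
    base <- switch(kind,
      mid = rep("sometimes", 14),
      best = ifelse(seq_len(14) %in% rev_idx, "very_often", "never"),
      worst = ifelse(seq_len(14) %in% rev_idx, "never", "very_often"),
      ones = ifelse(seq_len(14) %in% rev_idx, "fairly_often", "almost_never"),
      threes = ifelse(seq_len(14) %in% rev_idx, "almost_never", "fairly_often"))
    if (kind == "mid") names(base) <- NULL
    base
  }
  pss_kinds <- c("mid", "best", "worst", "ones", "mid", "threes",
                 "ones", "mid", "worst", "threes", "best", "mid")
  pss_m <- t(vapply(pss_kinds, pss_pattern, character(14)))
  pss_m[5, 1:2] <- "dont_know"   # P05: two imputed items, still scores 28
  pss_m[12, 14] <- "dont_know"   # P12: one imputed item
  colnames(pss_m) <- PSS_COLS

  n_lim <- c(1, 0, 5, 0, 2, 3, 0, 1, 4, 2, 0, 1)
  lim_m <- t(vapply(n_lim, function(k) {
    rep(c("difficulty", "no_difficulty"), c(k, 5 - k))
  }, character(5)))
  colnames(lim_m) <- LIMITATION_COLS

  yn <- function(x) ifelse(x == 1, "yes", "no")
  diseases <- tibble::tibble(
    diabetes              = yn(c(1, 0, 1, 0, 0, 1, 0, 0, 1, 1, 0, 0)),
    myocardial_infarction = yn(c(0, 0, 1, 0, 0, 0, 0, 1, 0, 1, 0, 0)),
    stroke                = yn(c(0, 0, 1, 0, 1, 0, 0, 0, 0, 1, 0, 0)),
    apoplexy              = yn(c(0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0)),
    asthma                = yn(c(0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0)),
    hypertension_diagnosed = yn(c(0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 1, 0)),
    sbp = c(150, 120, 160, 138, 118, 125, 110, 130, 145, 150, 135, 139),
    dbp = c(80, 75, 95, 92, 70, 80, 70, 85, 88, 95, 85, 89))

  surveys <- tibble::tibble(
    participant_id = names(plans),
    age = c(65, 70, 62, 75, 68, 80, 60, 77, 73, 66, 69, 71),
    gender = rep(c("man", "woman"), 6),
    weight = c(60, 55, 70, 65, 58, 72, 68, 50, 62, 75, 56, 66),
    height = c(1.65, 1.55, 1.70, 1.60, 1.58, 1.72, 1.68, 1.50, 1.62, 1.75, 1.56, 1.66),
    region = rep(c("south", "north"), each = 6),
    residency = rep(c("rural", "urban"), 6),
    education = rep(c("primary_or_below", "middle_or_above"), 6),
    income = c(3000, 12000, 4500, 20000, 6000, NA, 7000, 9000, 2500, 15000, 5500, 11000),
    income_wave = c(2009L, 2009L, 2011L, 2009L, 2009L, 2011L,
                    2009L, 2009L, 2011L, 2009L, 2011L, 2009L),
    site_id = rep(c("S1", "S2"), each = 6),
    marriage = c(rep("married", 10), "other", "married"),
    smoking = rep(c("current", "not", "not"), 4),
    alcohol = rep(c("lt1_per_week", "lt1_per_week", "ge1_per_week"), 4),
    life_quality = c("good", "very_good", "very_bad", "good", "fair", "bad",
                     "very_good", "fair", "bad", "dont_know", "good", "fair"),
    cog_immediate = c(5L, 10L, 0L, 8L, 7L, 4L, 9L, 6L, 10L, 3L, 5L, 8L),
    cog_delayed = c(3L, 10L, 0L, 6L, 5L, 2L, 8L, 4L, 9L, 1L, 5L, 7L),
    cog_serial7s = c(4L, 5L, 0L, 5L, 3L, 1L, 4L, 2L, 5L, 0L, 5L, 4L),
    cog_backward = c("second_try", "first_try", "fail", "first_try",
                     "second_try", "fail", "first_try", "second_try",
                     "first_try", "fail", "second_try", "first_try")) |>
    dplyr::bind_cols(tibble::as_tibble(lim_m), diseases,
                     tibble::as_tibble(pss_m))

  sites <- tibble::tibble(site_id = c("S1", "S2"), region = c("south", "north"))

  # Hand-computed targets. DDS: nested day-then-wave means of the menu
  # scores. HAS: lim/5 + com/6 + (1 - cog/27) + pss/56, kept as exact
  # fractions.
  expected <- tibble::tibble(
    participant_id = names(plans),
    dds = c(4, 4, 1, 8, 25 / 6, 10 / 3, 35 / 6, 4, 5 / 3, 7 / 3, 4, 35 / 6),
    n_limitations = as.integer(n_lim),
    n_comorbidities = c(2L, 0L, 6L, 1L, 1L, 2L, 0L, 1L, 3L, 4L, 2L, 0L),
    cognition = c(13L, 27L, 0L, 21L, 16L, 7L, 23L, 13L, 26L, 4L, 16L, 21L),
    pss = c(28L, 0L, 56L, 14L, 28L, 42L, 14L, 28L, 56L, 42L, 0L, 28L),
    pss_dk_count = c(0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    has = c(419 / 270, 0, 4, 23 / 36, 398 / 270, 1309 / 540, 43 / 108,
            374 / 270, 631 / 270, 1441 / 540, 20 / 27, 83 / 90))

  cohort <- new_cohort(dietary, food_table, surveys, sites)
  cohort$expected <- expected
  cohort$day_energies <- day_energies
  cohort
}
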