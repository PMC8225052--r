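resolve_foods <- function(records, food_table) {
  unknown <- setdiff(unique(records$food_id), food_table$food_id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown food_id(s): %s.", paste(unknown, collapse = ", ")))
  }
  dplyr::left_join(records,
                   dplyr::select(food_table, "food_id", "energy_density", "food_group"),
                   by = "food_id")
}

#' Daily energy intake
#'
#' Sums `amount * energy_density / 100` over the records of each recall day.
#'
#' @param records Dietary records (any subset of days/participants).
#' @param food_table Food-composition table.
#' @return Tibble with one row per participant-wave-day and an `energy`
#'   column in kcal. An empty `records` input yields an empty result with a
#'   warning, since absent days cannot be energy-adjusted later.
#' @export
daily_energy <- function(records, food_table) {
  if (nrow(records) == 0) {
    warn("No dietary records supplied; returning zero days (0 kcal).")
    return(tibble::tibble(participant_id = character(), wave = integer(),
                          day = integer(), energy = double()))
  }
  resolve_foods(records, food_table) |>
    dplyr::group_by(.data$participant_id, .data$wave, .data$day) |>
    dplyr::summarise(energy = sum(.data$amount * .data$energy_density / 100),
                     .groups = "drop")
}

#' Energy adjustment to grams per 1000 kcal
#'
#' @param amounts Gram totals (any grouping).
#' @param energy Energy of the same day in kcal; must be > 0.
#' @return `amounts * 1000 / energy`.
#' @export
energy_adjust <- function(amounts, energy) {
  if (any(energy <= 0)) abort("Day energy must be strictly positive for adjustment.")
  amounts * 1000 / energy
}

#' Daily dietary diversity score
#'
#' Counts the distinct scored food groups (staple foods, vegetables, fruits,
#' eggs, aquatic products, meat and poultry, soybeans and nuts, dairy) with
#' any positive consumption on a recall day. Salt and oil are part of the
#' guideline groups but are never scored, so a day consisting only of salt
#' and oil has no defined score (the DDS ranges from 1 to 8) and raises an
#' error.
#'
#' @param records Dietary records.
#' @param food_table Food-composition table.
#' @return Tibble with one row per participant-wave-day and an integer `dds`
#'   column in 1..8.
#' @export
daily_dds <- function(records, food_table) {
  if (nrow(records) == 0) abort("Cannot score an empty set of records.")
  days <- resolve_foods(records, food_table) |>
    dplyr::group_by(.data$participant_id, .data$wave, .data$day) |>
    dplyr::summarise(
      dds = dplyr::n_distinct(.data$food_group[.data$amount > 0 &
                                                 .data$food_group %in% SCORED_GROUPS]),
      .groups = "drop")
  if (any(days$dds == 0)) {
    bad <- days[days$dds == 0, ][1, ]
    abort(sprintf(
      "Recall day with no scored food group (participant %s, wave %d, day %d): only salt/oil or zero amounts; DDS >= 1 is violated.",
      bad$participant_id, bad$wave, bad$day))
  }
  days
}

#' Participant-level dietary diversity and food-group consumption
#'
#' For each participant, daily scores are averaged within each baseline wave
#' and wave means are then averaged (unweighted) across the one or two waves
#' attended. Per-group consumption is treated identically: grams are summed
#' per group within a day, energy-adjusted to grams per 1000 kcal, averaged
#' over the days of a wave and then across waves. Setting
#' `averaging = "pooled"` instead averages all recall days in one step
#' (offered for sensitivity use).
#'
#' @param dietary Dietary-record tibble (baseline waves).
#' @param food_table Food-composition table.
#' @param averaging `"nested"` (days, then waves; the default) or `"pooled"`.
#' @return Tibble with one row per participant: `dds`, `waves_used`, and one
#'   `g_per_1000kcal_<group>` column per scored group.
#' @export
score_dds <- function(dietary, food_table, averaging = c("nested", "pooled")) {
  averaging <- match.arg(averaging)
  dietary <- dietary[dietary$wave %in% BASELINE_WAVES, , drop = FALSE]
  if (nrow(dietary) == 0) abort("No baseline-wave dietary records to score.")
  rec <- resolve_foods(dietary, food_table)

  # Integer day index in order of first appearance; all aggregation below is
  # C-level rowsum over that index (this function sits in simulation loops).
  day_key <- paste(rec$participant_id, rec$wave, rec$day, sep = "\r")
  di <- match(day_key, unique(day_key))
  n_days <- max(di)
  first <- !duplicated(di)
  day_meta <- rec[first, c("participant_id", "wave", "day")]

  energy <- as.vector(rowsum(rec$amount * rec$energy_density / 100, di))
  if (any(energy <= 0)) {
    bad <- day_meta[which(energy <= 0)[1], ]
    abort(sprintf("Zero-energy recall day (participant %s, wave %d, day %d).",
                  bad$participant_id, bad$wave, bad$day))
  }

  gi <- match(rec$food_group, SCORED_GROUPS)   # NA for salt/oil
  keep <- !is.na(gi) & rec$amount > 0
  pair <- (di[keep] - 1L) * 8L + gi[keep]
  upair <- unique(pair)
  dds_day <- tabulate((upair - 1L) %/% 8L + 1L, nbins = n_days)
  if (any(dds_day == 0)) {
    bad <- day_meta[which(dds_day == 0)[1], ]
    abort(sprintf(
      "Recall day with no scored food group (participant %s, wave %d, day %d): only salt/oil or zero amounts; DDS >= 1 is violated.",
      bad$participant_id, bad$wave, bad$day))
  }

  grams <- matrix(0, n_days, 8L)
  for (g in seq_len(8L)) {
    sel <- keep & gi == g
    if (any(sel)) {
      s <- rowsum(rec$amount[sel], di[sel])
      grams[as.integer(rownames(s)), g] <- s
    }
  }
  g1000 <- grams * (1000 / energy)

  avg_by <- function(values, index) {
    cnt <- tabulate(index, nbins = max(index))
    rowsum(values, index) / cnt
  }
  pid_day <- day_meta$participant_id
  if (averaging == "nested") {
    pw_key <- paste(pid_day, day_meta$wave, sep = "\r")
    pwi <- match(pw_key, unique(pw_key))
    wave_vals <- avg_by(cbind(dds_day, g1000), pwi)
    pid_wave <- pid_day[!duplicated(pwi)]
    pi2 <- match(pid_wave, unique(pid_wave))
    part_vals <- avg_by(wave_vals, pi2)
    pid <- unique(pid_wave)
    waves_used <- tabulate(pi2, nbins = max(pi2))
  } else {
    pi2 <- match(pid_day, unique(pid_day))
    part_vals <- avg_by(cbind(dds_day, g1000), pi2)
    pid <- unique(pid_day)
    waves_used <- as.integer(rowsum(
      as.numeric(!duplicated(paste(pid_day, day_meta$wave, sep = "\r"))), pi2))
  }

  out <- tibble::tibble(participant_id = pid,
                        dds = unname(part_vals[, 1]),
                        waves_used = as.integer(waves_used))
  cols <- paste0("g_per_1000kcal_", SCORED_GROUPS)
  for (j in seq_along(cols)) out[[cols[j]]] <- unname(part_vals[, j + 1L])
  out
}

#' Cohort-wide DDS tertiles
#'
#' Splits the averaged DDS of a scored cohort into rank-based tertiles
#' (T1 low to T3 high) with boundary ties going to the lower group, and
#' reports the observed range of each tertile in the conventional
#' `"T1: a-b"` format.
#'
#' @param dds_table Output of [score_dds()] (needs >= 3 participants with
#'   >= 3 distinct scores).
#' @return The input with a `dds_tertile` factor column; the cutpoint report
#'   is attached as attribute `"cutpoints"` (tibble) and `"cutpoint_label"`
#'   (string).
#' @export
add_dds_tertiles <- function(dds_table) {
  if (nrow(dds_table) < 3) abort("Need at least 3 participants to form DDS tertiles.")
  if (length(unique(dds_table$dds)) < 3) {
    abort("Need at least 3 distinct DDS values to form tertiles.")
  }
  f <- tertile_assign(dds_table$dds)
  dds_table$dds_tertile <- f
  attr(dds_table, "cutpoints") <- attr(f, "cutpoints")
  attr(dds_table, "cutpoint_label") <- format_cutpoints(f)
  dds_table
}

#' Categorize a food-group consumption vector for regression
#'
#' Two schemes mirror how consumption exposures are usually coded:
#' `"tertile"` forms rank-based thirds labelled low/middle/high (used for
#' groups most people consume). `"consumer_split"` puts zero consumption in
#' `non_consumer` and splits consumers at their median, `low` for at or
#' below the consumer median, `high` above (used for fruits, aquatic
#' products and dairy, which have many non-consumers).
#'
#' @param x Numeric consumption vector (grams per 1000 kcal), no missing.
#' @param scheme `"tertile"` or `"consumer_split"`.
#' @return Factor with levels low/middle/high or non_consumer/low/high; the
#'   consumer median (if any) is attached as attribute `"consumer_median"`.
#' @export
categorize_food_group <- function(x, scheme = c("tertile", "consumer_split")) {
  scheme <- match.arg(scheme)
  if (anyNA(x)) abort("Consumption vector must not contain missing values.")
  if (scheme == "tertile") {
    return(tertile_assign(x, labels = c("low", "middle", "high")))
  }
  consumers <- x > 0
  if (!any(consumers)) {
    abort("Consumer split impossible: no participant consumes this food group.")
  }
  med <- median(x[consumers])
  lab <- ifelse(!consumers, "non_consumer", ifelse(x <= med, "low", "high"))
  f <- factor(lab, levels = c("non_consumer", "low", "high"))
  attr(f, "consumer_median") <- med
  f
}
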