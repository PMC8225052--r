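#' Body mass index
#'
#' @param weight Weight in kilograms.
#' @param height Height in metres; must be strictly positive.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(60, 1.6)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.na(height) & height <= 0)) {
    abort("`height` must be strictly positive.")
  }
  weight / height^2
}

#' Impute missing incomes by site-wave medians and assign income tertiles
#'
#' Per-capita household income is recorded once per participant at a baseline
#' wave. Missing values are replaced by the median of the non-missing incomes
#' observed at the same survey site in the same wave (midpoint convention for
#' even counts). Tertiles are then formed within each wave on the completed
#' vector, labelled low / middle / high, with boundary ties assigned to the
#' lower group (see [tertile_assign()]).
#'
#' @param data A data frame with at least the income, site and wave columns.
#' @param income,site,wave Column names (unquoted) holding the income value,
#'   the site identifier and the wave of measurement. Defaults match the
#'   `surveys` schema.
#' @return `data` with `income` completed and two added columns:
#'   `income_imputed` (logical) and `income_tertile` (factor low/middle/high).
#' @export
impute_income <- function(data, income = "income", site = "site_id",
                          wave = "income_wave") {
  inc <- data[[income]]
  st <- data[[site]]
  wv <- data[[wave]]

  key <- paste(st, wv, sep = "\r")
  med <- tapply(inc, key, function(v) median(v, na.rm = TRUE))
  all_missing <- names(med)[is.nan(med) | is.na(med)]
  if (length(all_missing) > 0) {
    bad <- strsplit(all_missing[1], "\r", fixed = TRUE)[[1]]
    abort(sprintf(
      "All incomes missing for site `%s` in wave %s; cannot impute.",
      bad[1], bad[2]))
  }
  miss <- is.na(inc)
  inc[miss] <- med[key[miss]]

  tert <- factor(rep(NA_character_, length(inc)),
                 levels = c("low", "middle", "high"))
  for (w in unique(wv)) {
    idx <- wv == w
    tert[idx] <- tertile_assign(inc[idx], labels = c("low", "middle", "high"))
  }
  data[[income]] <- inc
  data$income_imputed <- miss
  data$income_tertile <- tert
  data
}

#' Prepare analysis covariates on a survey table
#'
#' Adds BMI (weight / height^2), completes income by site-wave median
#' imputation and attaches per-wave income tertiles.
#'
#' @param surveys A survey tibble in the `surveys` schema.
#' @return The tibble with `bmi`, completed `income`, `income_imputed` and
#'   `income_tertile` columns.
#' @export
prepare_covariates <- function(surveys) {
  surveys$bmi <- compute_bmi(surveys$weight, surveys$height)
  impute_income(surveys)
}
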