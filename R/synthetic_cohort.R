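#' Default synthetic food-consumption model
#'
#' One representative food per guideline group. `energy_density` is kcal per
#' 100 g; `p_consume` is the daily probability that a participant of average
#' socioeconomic position eats from the group; raw gram amounts are
#' log-normal with the given log-scale parameters. The amounts are
#' order-of-magnitude anchors for an elderly Chinese diet (staple-heavy,
#' few dairy consumers), not calibrated marginals.
#'
#' @return Tibble with one row per food.
#' @export
default_food_model <- function() {
  tibble::tribble(
    ~food_id,           ~food_group,    ~energy_density, ~p_consume, ~meanlog,  ~sdlog,
    "mixed_cereals",    "staple",       180,             1.00,       log(400),  0.30,
    "leafy_vegetables", "vegetables",   30,              0.95,       log(240),  0.40,
    "apple",            "fruits",       52,              0.35,       log(150),  0.50,
    "hen_egg",          "eggs",         144,             0.50,       log(60),   0.40,
    "freshwater_fish",  "aquatic",      104,             0.40,       log(80),   0.50,
    "pork",             "meat_poultry", 235,             0.70,       log(80),   0.50,
    "tofu",             "soy_nuts",     98,              0.45,       log(50),   0.60,
    "milk",             "dairy",        54,              0.12,       log(180),  0.40,
    "cooking_oil",      "oil",          899,             1.00,       log(40),   0.30,
    "salt",             "salt",         0,               1.00,       log(8),    0.30
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a two-baseline-wave nutrition
#' cohort: three-day 24-hour recalls in 2009 and/or 2011 (a configurable
#' fraction attends a single wave), an outcome survey in 2015, survey sites
#' carrying income structure, and planted diet-outcome effects.
#'
#' Diet-outcome effects are planted on four latent component propensities
#' (limitation, comorbidity, cognition, stress), each linear in the realized
#' dietary diversity score and in the confounders, then discretized into the
#' questionnaire items; `beta_dds_on_has` is the total effect on the
#' composite HAS per DDS point, split equally across the four components.
#' Education and income shift both diet and outcome, so crude and adjusted
#' estimates differ by design.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the same seed reproduces identical tables.
#' @param n_sites Number of survey sites.
#' @param p_single_wave Fraction attending only one baseline dietary wave
#'   (default 0.352).
#' @param p_woman,p_south,p_urban,p_married,p_smoker,p_alcohol Covariate
#'   margins (near those of a real elderly Chinese cohort).
#' @param age_range Integer ages drawn uniformly from this range.
#' @param food_model Tibble as [default_food_model()].
#' @param diet_ses_slope Log-odds shift of non-staple consumption
#'   probabilities per SD of the latent socioeconomic factor.
#' @param edu_intercept,edu_ses_slope Logistic model of higher education on
#'   the latent socioeconomic factor.
#' @param income_meanlog,income_ses_slope,income_site_sd,income_sdlog
#'   Log-normal income model with site-level shifts.
#' @param beta_dds_on_has Planted total effect on HAS per DDS point
#'   (default -0.05).
#' @param beta_group_effects Named numeric, HAS units per 100 g/1000 kcal of
#'   a food group (centered at the cohort mean); default none.
#' @param beta_education_has,beta_income_has,beta_age_has Confounder effects
#'   on HAS (education indicator, income-tertile step, year of age from 70).
#' @param component_baselines Baseline propensities of the four components
#'   (limitation, comorbidity, cognition, stress) at reference covariates.
#' @param noise_sd SD of the per-participant, per-component propensity noise.
#' @param dds_ref DDS value at which component propensities sit at baseline.
#' @param p_income_missing,p_pss_dk,p_limitation_dk,p_disease_dk Missingness
#'   and "don't know" rates.
#' @param lq_logor_good,lq_logor_bad Planted multinomial log-odds of
#'   good/bad (vs fair) self-rated life quality per HAS unit.
#' @param p_lq_dk "Don't know" rate on the life-quality item.
#' @return Validated list of class `dda_sim_config`.
#' @export
sim_config <- function(n_participants = 2000, seed = 1, n_sites = 12,
                       p_single_wave = 0.352,
                       p_woman = 0.53, p_south = 0.64, p_urban = 0.38,
                       p_married = 0.87, p_smoker = 0.27, p_alcohol = 0.20,
                       age_range = c(60L, 80L),
                       food_model = default_food_model(),
                       diet_ses_slope = 0.35,
                       edu_intercept = -0.3, edu_ses_slope = 0.9,
                       income_meanlog = 9, income_ses_slope = 0.5,
                       income_site_sd = 0.25, income_sdlog = 0.45,
                       beta_dds_on_has = -0.05,
                       beta_group_effects = NULL,
                       beta_education_has = -0.12,
                       beta_income_has = -0.05,
                       beta_age_has = 0.008,
                       component_baselines = c(limitation = 0.25,
                                               comorbidity = 0.30,
                                               cognition = 0.55,
                                               stress = 0.30),
                       noise_sd = 0.07,
                       dds_ref = 4.5,
                       p_income_missing = 0.05, p_pss_dk = 0.02,
                       p_limitation_dk = 0, p_disease_dk = 0,
                       lq_logor_good = -1.0, lq_logor_bad = 1.4,
                       p_lq_dk = 0.002) {
  cfg <- as.list(environment())
  probs <- c(p_single_wave, p_woman, p_south, p_urban, p_married, p_smoker,
             p_alcohol, p_income_missing, p_pss_dk, p_limitation_dk,
             p_disease_dk, p_lq_dk, food_model$p_consume)
  if (any(probs < 0 | probs > 1)) abort("Config error: probabilities must lie in [0, 1].")
  if (n_participants < 1) abort("Config error: n_participants must be >= 1.")
  if (!all(FOOD_GROUPS %in% food_model$food_group)) {
    abort("Config error: food model must cover all ten food groups.")
  }
  scored_p <- food_model$p_consume[food_model$food_group %in% SCORED_GROUPS]
  if (max(scored_p) < 1) {
    abort(paste("Config error: at least one scored food group needs p_consume = 1,",
                "otherwise a recall day can violate DDS >= 1."))
  }
  if (!is.null(beta_group_effects) &&
      !all(names(beta_group_effects) %in% SCORED_GROUPS)) {
    abort("Config error: beta_group_effects must be named after scored food groups.")
  }
  if (length(component_baselines) != 4) {
    abort("Config error: component_baselines needs 4 entries.")
  }
  structure(cfg, class = "dda_sim_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

shift_logit <- function(p, shift) {
  ifelse(p >= 1, 1, ifelse(p <= 0, 0, plogis(qlogis(p) + shift)))
}

#' Generate a synthetic cohort
#'
#' Draws a complete set of input tables (dietary records, surveys, food
#' table, sites) under a [sim_config()]. All randomness flows from the
#' config seed in a fixed draw order (sites, participants, wave membership,
#' dietary records, component propensities, questionnaire items, life
#' quality), so a given config reproduces byte-identical tables. The planted
#' parameters and each participant's realized DDS and expected HAS are
#' recorded in the cohort's `ground_truth` element (written as
#' `ground_truth.json` when the cohort is saved).
#'
#' @param config A `dda_sim_config`.
#' @param out_dir Optional directory; if given, the tables are written there
#'   via [write_cohort()].
#' @return A `dda_cohort` with `ground_truth`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "dda_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  fm <- config$food_model

  ## --- sites ------------------------------------------------------------
  n_south <- round(config$p_south * config$n_sites)
  sites <- tibble::tibble(
    site_id = sprintf("S%02d", seq_len(config$n_sites)),
    region = rep(c("south", "north"),
                 c(n_south, config$n_sites - n_south)),
    income_shift = rnorm(config$n_sites, 0, config$income_site_sd))

  ## --- participants -----------------------------------------------------
  id <- sprintf("P%05d", seq_len(n))
  site_idx <- sample.int(config$n_sites, n, replace = TRUE)
  ses <- rnorm(n)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  woman <- runif(n) < config$p_woman
  urban <- runif(n) < shift_logit(rep(config$p_urban, n), 0.5 * ses)
  edu_high <- runif(n) < plogis(config$edu_intercept + config$edu_ses_slope * ses)
  married <- runif(n) < config$p_married
  smoker <- runif(n) < config$p_smoker
  alcohol <- runif(n) < config$p_alcohol
  height <- round(rnorm(n, 1.60, 0.08), 2)
  bmi_true <- clamp(rnorm(n, 23.9, 3.4), 15, 40)
  weight <- round(bmi_true * height^2, 1)
  income <- round(exp(config$income_meanlog + config$income_ses_slope * ses +
                        sites$income_shift[site_idx] +
                        rnorm(n, 0, config$income_sdlog)))

  single <- runif(n) < config$p_single_wave
  single_wave <- sample(BASELINE_WAVES, n, replace = TRUE)
  income_wave <- ifelse(single, single_wave, BASELINE_WAVES[1])
  income_obs <- ifelse(runif(n) < config$p_income_missing, NA_real_, income)
  # keep every site-wave cell imputable: restore one observed income where
  # missingness happened to wipe out a whole cell
  cell <- paste(site_idx, income_wave)
  wiped <- tapply(income_obs, cell, function(v) all(is.na(v)))
  for (k in names(wiped)[wiped]) {
    i <- which(cell == k)[1]
    income_obs[i] <- income[i]
  }

  ## --- dietary records --------------------------------------------------
  pw <- dplyr::bind_rows(
    tibble::tibble(row = which(single), wave = single_wave[single]),
    tibble::tibble(row = rep(which(!single), each = 2),
                   wave = rep(BASELINE_WAVES, sum(!single))))
  pw <- dplyr::arrange(pw, .data$row, .data$wave)

  nf <- nrow(fm)
  grid <- tibble::tibble(
    row = rep(pw$row, each = 3L * nf),
    wave = rep(pw$wave, each = 3L * nf),
    day = rep(rep(RECALL_DAYS, each = nf), times = nrow(pw)),
    food = rep(seq_len(nf), times = 3L * nrow(pw)))
  base_p <- fm$p_consume[grid$food]
  scored <- fm$food_group[grid$food] %in% setdiff(SCORED_GROUPS, "staple")
  p_eat <- ifelse(scored,
                  shift_logit(base_p, config$diet_ses_slope * ses[grid$row]),
                  base_p)
  eaten <- runif(nrow(grid)) < p_eat
  amount <- round(rlnorm(nrow(grid), fm$meanlog[grid$food], fm$sdlog[grid$food]), 1)
  dietary <- tibble::tibble(
    participant_id = id[grid$row],
    wave = as.integer(grid$wave),
    day = as.integer(grid$day),
    food_id = fm$food_id[grid$food],
    amount = pmax(amount, 0.1))[eaten, ]

  food_table <- dplyr::select(fm, "food_id", "energy_density", "food_group")

  ## --- realized diet exposures (same path the analysis uses) ------------
  dds_tbl <- score_dds(dietary, food_table)
  ord <- match(id, dds_tbl$participant_id)
  dds <- dds_tbl$dds[ord]

  ## --- income tertile as the analysis will code it ----------------------
  inc_frame <- impute_income(tibble::tibble(income = income_obs,
                                            site_id = sites$site_id[site_idx],
                                            income_wave = income_wave))
  inc_t <- as.integer(inc_frame$income_tertile)

  ## --- planted unhealth shift (HAS units) -------------------------------
  h <- config$beta_dds_on_has * (dds - config$dds_ref) +
    config$beta_education_has * edu_high +
    config$beta_income_has * (inc_t - 2) +
    config$beta_age_has * (age - 70)
  if (!is.null(config$beta_group_effects)) {
    for (g in names(config$beta_group_effects)) {
      cons <- dds_tbl[[paste0("g_per_1000kcal_", g)]][ord]
      h <- h + config$beta_group_effects[[g]] * (cons - mean(cons)) / 100
    }
  }

  bl <- config$component_baselines
  lo <- 0.005; hi <- 0.995
  p_lim <- clamp(bl[["limitation"]] + h / 4 + rnorm(n, 0, config$noise_sd), lo, hi)
  p_com <- clamp(bl[["comorbidity"]] + h / 4 + rnorm(n, 0, config$noise_sd), lo, hi)
  p_cog <- clamp(bl[["cognition"]] - h / 4 + rnorm(n, 0, config$noise_sd), lo, hi)
  p_pss <- clamp(bl[["stress"]] + (h / 4) / (1 - config$p_pss_dk) +
                   rnorm(n, 0, config$noise_sd), lo, hi)

  ## --- questionnaire items ----------------------------------------------
  lim_m <- matrix(runif(n * 5) < rep(p_lim, 5), nrow = n)
  lim_resp <- matrix(ifelse(lim_m, "difficulty", "no_difficulty"), nrow = n)
  if (config$p_limitation_dk > 0) {
    dkm <- matrix(runif(n * 5) < config$p_limitation_dk, nrow = n)
    lim_resp[dkm] <- "dont_know"
  }

  dis_m <- matrix(runif(n * 5) < rep(p_com, 5), nrow = n)
  dis_resp <- matrix(ifelse(dis_m, "yes", "no"), nrow = n)
  if (config$p_disease_dk > 0) {
    dkm <- matrix(runif(n * 5) < config$p_disease_dk, nrow = n)
    dis_resp[dkm] <- "dont_know"
  }

  htn <- runif(n) < p_com
  dx <- htn & runif(n) < 0.6
  high_bp <- htn & (!dx | runif(n) < 0.5)
  sbp_high <- pmax(140, round(rnorm(n, 152, 8)))
  sbp_norm <- clamp(round(rnorm(n, 125, 8)), 95, 139)
  sbp <- ifelse(high_bp, sbp_high, sbp_norm)
  dbp_high <- clamp(round(rnorm(n, 88, 8)), 60, sbp - 10)
  dbp_norm <- clamp(round(rnorm(n, 78, 6)), 55, 89)
  dbp <- ifelse(high_bp, dbp_high, dbp_norm)

  cog_imm <- rbinom(n, 10, p_cog)
  cog_del <- rbinom(n, 10, p_cog)
  cog_ser <- rbinom(n, 5, p_cog)
  back_pts <- rbinom(n, 2, p_cog)
  cog_back <- c("fail", "second_try", "first_try")[back_pts + 1L]

  svals <- matrix(rbinom(n * 14L, 4L, rep(p_pss, 14L)), nrow = n)
  rev_idx <- pss_reversed_items()
  pss_resp <- matrix(PSS_LEVELS[svals + 1L], nrow = n)
  pss_resp[, rev_idx] <- matrix(PSS_LEVELS[(4L - svals) + 1L],
                                nrow = n)[, rev_idx]
  dkm <- matrix(runif(n * 14L) < config$p_pss_dk, nrow = n)
  pss_resp[dkm] <- LIKERT_DK

  expected_has <- p_lim + p_com + (1 - p_cog) +
    ((1 - config$p_pss_dk) * p_pss + config$p_pss_dk * 0.5)

  # Realized HAS exactly as the scoring pipeline will compute it; life
  # quality responds to the participant's actual state, not its expectation.
  svals_imputed <- svals
  svals_imputed[dkm] <- 2L
  has_real <- rowSums(lim_m) / 5 + (rowSums(dis_m) + htn) / 6 +
    (1 - (cog_imm + cog_del + cog_ser + back_pts) / 27) +
    rowSums(svals_imputed) / 56

  w_good <- exp(log(1763 / 1148) + config$lq_logor_good * (has_real - 1.25))
  w_bad <- exp(log(168 / 1148) + config$lq_logor_bad * (has_real - 1.25))
  tot <- 1 + w_good + w_bad
  u <- runif(n)
  lq3 <- ifelse(u < w_good / tot, "good", ifelse(u < (w_good + w_bad) / tot, "bad", "fair"))
  u2 <- runif(n)
  life_quality <- dplyr::case_when(
    lq3 == "good" & u2 < 0.3 ~ "very_good",
    lq3 == "good" ~ "good",
    lq3 == "bad" & u2 < 0.3 ~ "very_bad",
    lq3 == "bad" ~ "bad",
    TRUE ~ "fair")
  life_quality[runif(n) < config$p_lq_dk] <- LIKERT_DK

  ## --- assemble ----------------------------------------------------------
  surveys <- tibble::tibble(
    participant_id = id,
    age = as.numeric(age),
    gender = ifelse(woman, "woman", "man"),
    weight = weight,
    height = height,
    region = sites$region[site_idx],
    residency = ifelse(urban, "urban", "rural"),
    education = ifelse(edu_high, "middle_or_above", "primary_or_below"),
    income = income_obs,
    income_wave = as.integer(income_wave),
    site_id = sites$site_id[site_idx],
    marriage = ifelse(married, "married", "other"),
    smoking = ifelse(smoker, "current", "not"),
    alcohol = ifelse(alcohol, "ge1_per_week", "lt1_per_week"))
  colnames(lim_resp) <- LIMITATION_COLS
  colnames(dis_resp) <- DISEASE_COLS
  colnames(pss_resp) <- PSS_COLS
  surveys <- dplyr::bind_cols(
    surveys,
    tibble::as_tibble(lim_resp),
    tibble::as_tibble(dis_resp),
    tibble::tibble(hypertension_diagnosed = ifelse(dx, "yes", "no"),
                   sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                   cog_immediate = cog_imm, cog_delayed = cog_del,
                   cog_serial7s = cog_ser, cog_backward = cog_back),
    tibble::as_tibble(pss_resp),
    tibble::tibble(life_quality = life_quality))

  ground_truth <- list(
    seed = config$seed,
    n_participants = n,
    params = list(
      beta_dds_on_has = config$beta_dds_on_has,
      beta_group_effects = as.list(config$beta_group_effects %||% list()),
      beta_education_has = config$beta_education_has,
      beta_income_has = config$beta_income_has,
      beta_age_has = config$beta_age_has,
      p_single_wave = config$p_single_wave,
      p_pss_dk = config$p_pss_dk),
    participants = data.frame(participant_id = id, dds_true = dds,
                              expected_has = expected_has,
                              has_realized = has_real))

  cohort <- new_cohort(dietary, food_table, surveys,
                       dplyr::select(sites, "site_id", "region"),
                       ground_truth = ground_truth)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
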