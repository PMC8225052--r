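# Builders for small in-code fixtures and independent brute-force oracles.

toy_food_table <- function() {
  tibble::tribble(
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
}

# One recall day eating 100 g from each named food.
make_day <- function(pid, wave, day, foods, amount = 100) {
  tibble::tibble(participant_id = pid, wave = as.integer(wave),
                 day = as.integer(day), food_id = foods,
                 amount = rep(amount, length.out = length(foods)))
}

# A complete, valid survey row; override any field by name.
make_survey <- function(participant_id, ...) {
  row <- tibble::tibble(
    participant_id = participant_id, age = 70, gender = "woman",
    weight = 60, height = 1.6, region = "south", residency = "rural",
    education = "primary_or_below", income = 5000, income_wave = 2009L,
    site_id = "S1", marriage = "married", smoking = "not",
    alcohol = "lt1_per_week",
    limitation_lift = "no_difficulty", limitation_squat = "no_difficulty",
    limitation_stand = "no_difficulty", limitation_sit = "no_difficulty",
    limitation_walk = "no_difficulty",
    diabetes = "no", myocardial_infarction = "no", stroke = "no",
    apoplexy = "no", asthma = "no", hypertension_diagnosed = "no",
    sbp = 120, dbp = 75,
    cog_immediate = 5L, cog_delayed = 5L, cog_serial7s = 3L,
    cog_backward = "first_try",
    life_quality = "fair")
  for (i in 1:14) row[[sprintf("pss_%02d", i)]] <- "sometimes"
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

make_cohort <- function(surveys, dietary = NULL, food_table = toy_food_table()) {
  if (is.null(dietary)) {
    dietary <- dplyr::bind_rows(lapply(surveys$participant_id, function(p) {
      dplyr::bind_rows(lapply(1:3, function(d) {
        make_day(p, 2009, d, c("rice", "cabbage", "pork"))
      }))
    }))
  }
  sites <- tibble::tibble(site_id = unique(surveys$site_id),
                          region = "south")
  new_cohort(dietary, food_table, surveys, sites)
}

# Brute-force PSS oracle: explicit per-item coding, imputation and reversal.
pss_oracle <- function(responses, reverse_items = pss_reversed_items()) {
  stopifnot(length(responses) == 14)
  code <- c(never = 0, almost_never = 1, sometimes = 2,
            fairly_often = 3, very_often = 4)
  total <- 0
  for (i in 1:14) {
    r <- responses[i]
    if (r == "dont_know") r <- "sometimes"
    v <- code[[r]]
    if (i %in% reverse_items) v <- 4 - v
    total <- total + v
  }
  total
}

random_pss_vector <- function() {
  resp <- sample(c("never", "almost_never", "sometimes", "fairly_often",
                   "very_often", "dont_know"), 14, replace = TRUE,
                 prob = c(rep(0.18, 5), 0.1))
  if (all(resp == "dont_know")) resp[1] <- "never"
  resp
}

# Brute-force daily DDS: set cardinality of scored groups with intake.
dds_oracle <- function(records, food_table) {
  groups <- food_table$food_group[match(records$food_id, food_table$food_id)]
  scored <- setdiff(unique(food_table$food_group), c("salt", "oil"))
  length(unique(groups[records$amount > 0 & groups %in% scored]))
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
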