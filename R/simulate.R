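# Synthetic NHANES-like cohort generator with known ground truth.
#
# Every downstream stage (exclusions, substitution, usual-intake estimation,
# HEI scoring, BRR variance, cost) is exercised against cohorts from this
# module, so the generating model mirrors the estimation model: each amount
# channel is a Box-Cox-scale linear model with a person-level random
# intercept (between-person) and a day-level residual (within-person), a
# recall-sequence shift for day 2 and a weekday (Mon-Thu) shift. Day 2 is
# observed with probability `day2_completion` (default 0.79). Protein-food
# composition is drawn from stratum-specific Dirichlet shares calibrated so
# meat contributes about half of protein-food oz equivalents.
#
# One random stream per logical purpose (demographics, amounts, groups,
# missingness, weights, food records, prices, truth), each derived from the
# master seed, so adding a stage never perturbs earlier draws.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

dirichlet1 <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

sylvester_hadamard <- function(r) {
  h <- matrix(1, 1, 1)
  while (nrow(h) < r) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

# Medians are for the NON-MEAT background of each nutrient; with
# `meat_coupling = TRUE` (default) each observed day additionally carries
# the meat composition contribution of its drawn meat oz equivalents, so
# removing meat in the substitution step can never push an intake below
# its positive background.
default_nutrient_params <- function() {
  tibble::tribble(
    ~nutrient,      ~median_adult, ~child_mult, ~male_mult, ~lambda, ~cv_between, ~cv_within,
    "energy",        1880,  0.85, 1.15, 0.25, 0.20, 0.30,
    "protein",         60,  0.82, 1.20, 0.25, 0.22, 0.32,
    "sat_fat",         23,  0.90, 1.15, 0.00, 0.25, 0.38,
    "mufa",            23,  0.88, 1.15, 0.00, 0.25, 0.38,
    "pufa",            16,  0.85, 1.10, 0.00, 0.28, 0.40,
    "ala",            1.5,  0.85, 1.10, 0.00, 0.30, 0.45,
    "la",              14,  0.85, 1.10, 0.00, 0.28, 0.42,
    "cholesterol",    220,  0.85, 1.15, 0.00, 0.30, 0.45,
    "fiber",           15,  0.85, 1.10, 0.30, 0.28, 0.40,
    "calcium",        945,  1.00, 1.10, 0.30, 0.25, 0.35,
    "iron",          11.3,  0.85, 1.15, 0.00, 0.25, 0.38,
    "magnesium",      275,  0.85, 1.10, 0.00, 0.22, 0.32,
    "potassium",     2220,  0.85, 1.10, 0.30, 0.22, 0.30,
    "sodium",        3300,  0.85, 1.15, 0.25, 0.22, 0.32,
    "copper",        1.15,  0.85, 1.10, 0.00, 0.25, 0.35,
    "zinc",           7.5,  0.85, 1.20, 0.00, 0.25, 0.38,
    "folate_dfe",     480,  0.90, 1.10, 0.00, 0.28, 0.40,
    "vitamin_e",        8,  0.85, 1.05, 0.00, 0.28, 0.42,
    "vitamin_b12",    3.0,  0.85, 1.20, 0.00, 0.35, 0.50)
}

default_hei_group_params <- function() {
  tibble::tribble(
    ~group,             ~median_adult, ~child_mult, ~male_mult,
    "total_fruit_cup",       0.85, 1.10, 0.95,
    "whole_fruit_cup",       0.40, 1.10, 0.95,
    "total_veg_cup",         1.35, 0.70, 1.10,
    "greens_beans_cup",      0.12, 0.60, 1.00,
    "whole_grain_oz",        0.80, 0.90, 1.05,
    "refined_grain_oz",      5.20, 0.95, 1.15,
    "dairy_cup",             1.50, 1.35, 1.10,
    "added_sugars_tsp",     16.00, 1.15, 1.05) %>%
    mutate(lambda = 0, cv_between = 0.35, cv_within = 0.50)
}

# Protein-food oz-eq composition targets by demographic stratum: mean total
# oz eq and source shares (%) for meats, poultry, seafood, eggs, legumes,
# soy. Calibrated to national no-nut-consumer composition (meat about half
# of animal protein).
default_protein_params <- function() {
  list(
    totals = c(boy = 4.86, girl = 3.81, man = 6.97, woman = 5.05),
    shares = rbind(
      boy   = c(50.9, 29.4, 4.5, 7.8, 6.5, 1.0),
      girl  = c(44.9, 31.7, 5.5, 9.8, 6.9, 1.3),
      man   = c(49.4, 24.5, 9.4, 8.6, 7.6, 0.6),
      woman = c(43.6, 26.2, 11.5, 10.5, 7.4, 0.8)),
    source_names = c("meats", "poultry", "seafood", "eggs", "legumes", "soy"),
    meats_split = c(meat = 0.72, cured = 0.26, organ = 0.02),
    dirichlet_conc = 25,
    sd_between = 0.30,
    sd_within = 0.35)
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults define the study conditions the package is tested under: an
#' NHANES-like two-recall cohort with 79% day-2 completion, age-gender strata
#' in nationally representative proportions, skewed positive amounts with
#' between- and within-person variation on a Box-Cox scale, protein-food
#' composition with meat near half of protein-food oz equivalents, and a
#' replicate-weight survey design with Fay coefficient 0.3.
#'
#' @param n_persons Number of sampled persons.
#' @param seed Master seed; it fully determines the cohort.
#' @param day2_completion Probability that the second recall is completed.
#' @param nutrients Which nutrient channels to simulate (default all of
#'   [nutrient_fields()]); restricting speeds up replication studies.
#' @param nutrient_params Tibble of per-nutrient generating parameters
#'   (`median_adult`, `child_mult`, `male_mult`, `lambda`, `cv_between`,
#'   `cv_within`). Transformed-scale standard deviations are
#'   `cv * median_adult^lambda`, so `cv` reads as a coefficient of variation
#'   at `lambda = 0`.
#' @param hei_group_params Same structure for HEI food-group channels.
#' @param protein_params Protein-food totals, Dirichlet share targets and
#'   two-level log-scale variances (see `default_protein_params()`).
#' @param day2_effect,weekend_effect Transformed-scale shifts for second
#'   recalls and Friday-Sunday days.
#' @param age_band_probs Sampling proportions for the six eligible age bands.
#' @param prob_male Probability of male gender.
#' @param race_probs,income_probs,education_probs Demographic category
#'   proportions.
#' @param frac_under4,frac_pregnant,frac_unreliable,frac_walnut,
#'   frac_other_nut,frac_missing_protein Fractions generating each exclusion
#'   stratum (pregnancy applies to women aged 20-44).
#' @param meat_coupling If `TRUE` (default), each day's nutrient amounts are
#'   the background channel plus the meat composition contribution of that
#'   day's meat oz equivalents, making the generated diet internally
#'   coherent (meat removal reduces B12, cholesterol, zinc, ...). `FALSE`
#'   gives pure two-level Box-Cox channels, useful for closed-form checks.
#' @param weight_log_sd Log-scale spread of the base survey weights.
#' @param n_replicates Number of BRR half-sample replicates (power of 2).
#' @param fay Fay shrinkage coefficient.
#' @param meat_price_per_oz,walnut_price_per_oz Target-year prices used to
#'   calibrate the price table.
#' @param price_base_year,price_target_year CPI base and analysis years.
#' @param truth_mc Monte-Carlo draws used for population ground truth.
#' @return A validated config object of class `nutshift_sim_config`.
#' @export
sim_config <- function(n_persons = 1500,
                       seed = 1L,
                       day2_completion = 0.79,
                       nutrients = nutrient_fields(),
                       nutrient_params = default_nutrient_params(),
                       hei_group_params = default_hei_group_params(),
                       protein_params = default_protein_params(),
                       day2_effect = -0.02,
                       weekend_effect = -0.02,
                       age_band_probs = c("4-8" = 7.36, "9-13" = 8.35,
                                          "14-18" = 9.03, "19-50" = 44.49,
                                          "51-70" = 22.79, "71+" = 7.98),
                       prob_male = 0.526,
                       race_probs = c(hispanic = 0.22, nh_white = 0.52,
                                      nh_black = 0.155, other = 0.105),
                       income_probs = c(lt20k = 0.18, i20_75k = 0.495,
                                        i75_100k = 0.11, gt100k = 0.215),
                       education_probs = c(lt9 = 0.21, g9_11 = 0.14,
                                           hs = 0.24, some_college = 0.26,
                                           college = 0.16),
                       frac_under4 = 0.02,
                       frac_pregnant = 0.02,
                       frac_unreliable = 0.02,
                       frac_walnut = 0.03,
                       frac_other_nut = 0.07,
                       frac_missing_protein = 0.005,
                       meat_coupling = TRUE,
                       weight_log_sd = 0.3,
                       n_replicates = 32L,
                       fay = 0.3,
                       meat_price_per_oz = 0.38,
                       walnut_price_per_oz = 0.26,
                       price_base_year = 2003L,
                       price_target_year = 2016L,
                       truth_mc = 60000L) {
  cfg <- as.list(environment())
  probs <- c(day2_completion, frac_under4, frac_pregnant, frac_unreliable,
             frac_walnut, frac_other_nut, frac_missing_protein, prob_male)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_persons >= 2,
            all(nutrients %in% nutrient_fields()),
            all(nutrient_params$cv_between >= 0),
            all(nutrient_params$cv_within >= 0),
            all(nutrient_params$lambda >= 0 & nutrient_params$lambda <= 1),
            fay >= 0, fay < 1, n_replicates >= 2,
            weight_log_sd >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "nutshift_sim_config")
}

#' @export
print.nutshift_sim_config <- function(x, ...) {
  cat(sprintf("<nutshift_sim_config> n = %d, seed = %d, %d nutrient channels\n",
              x$n_persons, x$seed, length(x$nutrients)))
  invisible(x)
}

sim_demographics <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_persons
  bands <- names(config$age_band_probs)
  band <- sample(bands, n, TRUE, prob = config$age_band_probs)
  lo <- c("4-8" = 4, "9-13" = 9, "14-18" = 14, "19-50" = 19,
          "51-70" = 51, "71+" = 71)
  hi <- c("4-8" = 8, "9-13" = 13, "14-18" = 18, "19-50" = 50,
          "51-70" = 70, "71+" = 90)
  age <- floor(runif(n, lo[band], hi[band] + 1))
  under4 <- runif(n) < config$frac_under4
  age[under4] <- sample(1:3, sum(under4), TRUE)
  gender <- ifelse(runif(n) < config$prob_male, "male", "female")
  preg_eligible <- gender == "female" & age >= 20 & age <= 44
  pregnant <- preg_eligible & runif(n) < config$frac_pregnant / mean(preg_eligible)
  u <- runif(n)
  nut_truth <- ifelse(u < config$frac_walnut, "walnut",
               ifelse(u < config$frac_walnut + config$frac_other_nut,
                      "other_nut", "no_nut"))
  tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    age_years = age,
    gender = gender,
    race = sample(names(config$race_probs), n, TRUE, config$race_probs),
    income_band = sample(names(config$income_probs), n, TRUE,
                         config$income_probs),
    education_band = sample(names(config$education_probs), n, TRUE,
                            config$education_probs),
    breast_milk = under4 & runif(n) < 0.5,
    pregnant_or_lactating = pregnant,
    unreliable_recall = runif(n) < config$frac_unreliable,
    missing_animal_protein = runif(n) < config$frac_missing_protein,
    nut_truth = nut_truth)
}

# Two-level Box-Cox-scale draws for one channel, returning the observed
# amounts for a person-day table plus the person-level random intercepts.
sim_channel <- function(persons_row_of_day, params, config) {
  pd <- persons_row_of_day   # one row per person-day with person index
  med <- params$median_adult *
    ifelse(pd$is_child, params$child_mult, 1) *
    ifelse(pd$gender == "male", params$male_mult, 1)
  mu <- box_cox(med, params$lambda)
  scale <- params$median_adult^params$lambda
  sigma_u <- params$cv_between * scale
  sigma_e <- params$cv_within * scale
  n_person <- max(pd$person_index)
  u <- rnorm(n_person, 0, sigma_u)
  z <- mu + u[pd$person_index] +
    config$day2_effect * (pd$day == 2) +
    config$weekend_effect * (!pd$weekday) +
    rnorm(nrow(pd), 0, sigma_e)
  list(amount = inv_box_cox(z, params$lambda), u = u,
       sigma_u = sigma_u, sigma_e = sigma_e)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws demographics, two 24-hour recall days per person (day 2 present
#' with the configured completion probability), nutrient and food-group
#' amounts from the two-level Box-Cox model, person-level food records that
#' partition each day's totals, base and BRR replicate survey weights, and a
#' ground-truth record (per-person true usual intakes and the population
#' mean/percentiles implied by the generating parameters).
#'
#' @param config A [sim_config()] object.
#' @param compute_truth If `FALSE`, skip the Monte-Carlo population truth
#'   (per-person truth is always included).
#' @return A `nutshift_cohort`: `persons`, `person_days`, `food_records`,
#'   `design`, plus `truth` and the `config` used.
#' @export
#' @examples
#' ch <- simulate_cohort(sim_config(n_persons = 50, seed = 7,
#'                                  nutrients = "magnesium"),
#'                       compute_truth = FALSE)
#' ch
simulate_cohort <- function(config = sim_config(), compute_truth = TRUE) {
  stopifnot(inherits(config, "nutshift_sim_config"))
  persons <- sim_demographics(config)
  n <- nrow(persons)

  set.seed(derive_seed(config$seed, 3))
  has_day2 <- runif(n) < config$day2_completion
  pd <- bind_rows(
    tibble(person_index = seq_len(n), day = 1L),
    tibble(person_index = which(has_day2), day = 2L)) %>%
    arrange(.data$person_index, .data$day)
  pd$weekday <- runif(nrow(pd)) < 4 / 7   # TRUE = Mon-Thu
  pd$person_id <- persons$person_id[pd$person_index]
  pd$is_child <- persons$age_years[pd$person_index] < 19
  pd$gender <- persons$gender[pd$person_index]

  # protein-food partition (drawn first: the nutrient channels add the meat
  # contribution of the drawn meat oz when meat_coupling is on)
  set.seed(derive_seed(config$seed, 8))
  pp <- config$protein_params
  demo <- ifelse(pd$is_child,
                 ifelse(pd$gender == "male", "boy", "girl"),
                 ifelse(pd$gender == "male", "man", "woman"))
  mean_tot <- pp$totals[demo]
  sig2 <- pp$sd_between^2 + pp$sd_within^2
  med_tot <- mean_tot / exp(sig2 / 2)
  u_tot <- rnorm(n, 0, pp$sd_between)
  tot <- exp(log(med_tot) + u_tot[pd$person_index] +
               rnorm(nrow(pd), 0, pp$sd_within))
  shares <- matrix(0, nrow(pd), 6)
  for (d in rownames(pp$shares)) {
    idx <- which(demo == d)
    if (length(idx) == 0) next
    alpha <- pp$shares[d, ] / sum(pp$shares[d, ]) * pp$dirichlet_conc
    shares[idx, ] <- dirichlet1(length(idx), alpha)
  }
  src <- shares * tot
  colnames(src) <- pp$source_names
  pd$meat_oz <- src[, "meats"] * pp$meats_split["meat"]
  pd$cured_meat_oz <- src[, "meats"] * pp$meats_split["cured"]
  pd$organ_meat_oz <- src[, "meats"] * pp$meats_split["organ"]
  pd$poultry_oz <- src[, "poultry"]
  pd$seafood_oz <- src[, "seafood"]
  pd$eggs_oz <- src[, "eggs"]
  pd$legumes_oz <- src[, "legumes"]
  pd$soy_oz <- src[, "soy"]
  nut_truth <- persons$nut_truth[pd$person_index]
  nuts <- numeric(nrow(pd))
  is_nutter <- nut_truth != "no_nut"
  eats_today <- is_nutter & (runif(nrow(pd)) < 0.7 | (nut_truth == "walnut" & pd$day == 1))
  nuts[eats_today] <- exp(rnorm(sum(eats_today), log(0.5), 0.5))
  pd$nuts_seeds_oz <- nuts
  pd$total_protein_oz <- pd$meat_oz + pd$cured_meat_oz + pd$organ_meat_oz +
    pd$poultry_oz + pd$seafood_oz + pd$eggs_oz + pd$legumes_oz + pd$soy_oz +
    pd$nuts_seeds_oz
  pd$seafood_plant_protein_oz <- pd$seafood_oz + pd$legumes_oz + pd$soy_oz +
    pd$nuts_seeds_oz

  # nutrient channels: non-meat background plus (optionally) the meat
  # composition contribution of the day's meat oz equivalents
  set.seed(derive_seed(config$seed, 2))
  # energy is always simulated: the kcal screen and the amount-model
  # covariate depend on it
  np <- config$nutrient_params %>%
    filter(.data$nutrient %in% union("energy", config$nutrients))
  meat_comp <- food_composition_profile()$meat_per_oz
  meat_eq_day <- pd$meat_oz + pd$cured_meat_oz + pd$organ_meat_oz
  person_u <- list()
  for (i in seq_len(nrow(np))) {
    ch <- sim_channel(pd, as.list(np[i, ]), config)
    contrib <- if (config$meat_coupling) {
      meat_comp[[np$nutrient[i]]] * meat_eq_day
    } else 0
    pd[[np$nutrient[i]]] <- ch$amount + contrib
    person_u[[np$nutrient[i]]] <- ch$u
  }
  for (f in setdiff(nutrient_fields(), np$nutrient)) pd[[f]] <- 0

  # HEI food-group channels
  set.seed(derive_seed(config$seed, 7))
  gp <- config$hei_group_params
  for (i in seq_len(nrow(gp))) {
    pd[[gp$group[i]]] <- sim_channel(pd, as.list(gp[i, ]), config)$amount
  }

  person_days <- pd %>%
    select("person_id", "day", "weekday", all_of(nutrient_fields()),
           all_of(food_group_fields()))

  food_records <- build_food_records(person_days, persons, config)

  # survey weights and BRR replicates
  set.seed(derive_seed(config$seed, 4))
  w <- rlnorm(n, meanlog = 0, sdlog = config$weight_log_sd)
  R <- as.integer(2^ceiling(log2(config$n_replicates)))
  strat <- (sample(seq_len(n)) - 1L) %% R + 1L
  psu <- integer(n)
  for (h in seq_len(R)) {
    idx <- which(strat == h)
    psu[idx] <- rep_len(c(1L, 2L), length(idx))[sample(length(idx))]
  }
  H <- sylvester_hadamard(R)
  f <- config$fay
  rep_weights <- matrix(0, n, R)
  for (r in seq_len(R)) {
    up <- H[r, strat] == 1L
    sel <- (up & psu == 1L) | (!up & psu == 2L)
    rep_weights[, r] <- w * ifelse(sel, 2 - f, f)
  }
  design <- new_survey_design(
    tibble(person_id = persons$person_id, weight = w), rep_weights, f)

  truth <- build_truth(persons, person_u, np, config, u_tot = u_tot,
                       compute_population = compute_truth)

  persons <- persons %>%
    select(-"nut_truth") %>%
    mutate(n_days = 1L + has_day2)

  out <- new_cohort(persons, person_days, food_records, design)
  out$truth <- truth
  out$config <- config
  out
}

# Person-level ground truth: usual intake T_i is the long-run expectation
# over days of the observed amount at day-1 covariate values - the
# background channel E_e[g^{-1}(mu_i + weekday-mix shift + u_i + e)] plus,
# under meat coupling, the meat composition contribution of the person's
# expected daily meat oz eq. Population mean/percentiles by Monte Carlo
# over strata and random intercepts.
build_truth <- function(persons, person_u, np, config, u_tot,
                        compute_population) {
  rule <- gh_rule(9)
  p_weekday <- 4 / 7
  pp <- config$protein_params
  meat_comp <- food_composition_profile()$meat_per_oz
  share_meats <- pp$shares[, 1] / rowSums(pp$shares)
  usual_meat_for <- function(demo, u) {
    med_tot <- pp$totals[demo] / exp((pp$sd_between^2 + pp$sd_within^2) / 2)
    unname(share_meats[demo] * med_tot * exp(u + pp$sd_within^2 / 2))
  }
  demo_of <- function(is_child, male) {
    ifelse(is_child, ifelse(male, "boy", "girl"),
           ifelse(male, "man", "woman"))
  }
  person_demo <- demo_of(persons$age_years < 19, persons$gender == "male")
  person_meat <- usual_meat_for(person_demo, u_tot)

  person_truth <- list()
  for (i in seq_len(nrow(np))) {
    pars <- as.list(np[i, ])
    med <- pars$median_adult *
      ifelse(persons$age_years < 19, pars$child_mult, 1) *
      ifelse(persons$gender == "male", pars$male_mult, 1)
    mu <- box_cox(med, pars$lambda)
    scale <- pars$median_adult^pars$lambda
    sigma_e <- pars$cv_within * scale
    u <- person_u[[pars$nutrient]]
    # background usual intake averages over the weekday mix of recall days
    t_wd <- gh_expect_inv(mu + u, sigma_e, pars$lambda, rule)
    t_we <- gh_expect_inv(mu + u + config$weekend_effect, sigma_e,
                          pars$lambda, rule)
    tt <- p_weekday * t_wd + (1 - p_weekday) * t_we
    if (config$meat_coupling) {
      tt <- tt + meat_comp[[pars$nutrient]] * person_meat
    }
    person_truth[[pars$nutrient]] <- tt
  }
  person_tbl <- as_tibble(c(list(person_id = persons$person_id), person_truth))

  population <- NULL
  if (compute_population) {
    set.seed(derive_seed(config$seed, 6))
    m <- config$truth_mc
    band <- sample(names(config$age_band_probs), m, TRUE,
                   config$age_band_probs)
    is_child <- band %in% c("4-8", "9-13", "14-18")
    male <- runif(m) < config$prob_male
    weekend <- runif(m) >= p_weekday
    mc_meat <- usual_meat_for(demo_of(is_child, male),
                              rnorm(m, 0, pp$sd_between))
    pop <- list()
    for (i in seq_len(nrow(np))) {
      pars <- as.list(np[i, ])
      med <- pars$median_adult * ifelse(is_child, pars$child_mult, 1) *
        ifelse(male, pars$male_mult, 1)
      mu <- box_cox(med, pars$lambda)
      scale <- pars$median_adult^pars$lambda
      u <- rnorm(m, 0, pars$cv_between * scale)
      tt <- gh_expect_inv(mu + u + config$weekend_effect * weekend,
                          pars$cv_within * scale, pars$lambda, rule)
      if (config$meat_coupling) {
        tt <- tt + meat_comp[[pars$nutrient]] * mc_meat
      }
      qs <- quantile(tt, probs = (1:99) / 100, names = FALSE)
      pop[[pars$nutrient]] <- tibble(
        nutrient = pars$nutrient, mean = mean(tt),
        percentile = list(tibble(p = 1:99, value = qs)))
    }
    population <- bind_rows(pop)
  }
  list(person = person_tbl, population = population)
}

# Partition each person-day's totals into food-level records. Records carry
# grams, a WWEIA-style category, a food code, and grams-proportional shares
# of the day's nutrients, so summing records reproduces the person-day.
build_food_records <- function(person_days, persons, config) {
  set.seed(derive_seed(config$seed, 9))
  pd <- person_days
  idx <- match(pd$person_id, persons$person_id)
  nut_truth <- persons$nut_truth[idx]
  variant <- (as.integer(sub("^P", "", pd$person_id)) %% 3L) + 1L

  # grams per category; simple food-pattern-to-gram factors
  g <- list(
    meats = (pd$meat_oz + pd$organ_meat_oz) * 28.35,
    cured = pd$cured_meat_oz * 28.35,
    poultry = pd$poultry_oz * 28.35,
    seafood_eggs_plant = (pd$seafood_oz + pd$eggs_oz + pd$legumes_oz +
                            pd$soy_oz) * 28.35,
    nuts = pd$nuts_seeds_oz * 14.175,   # 0.5 oz food per oz eq
    fruit = pd$total_fruit_cup * 150,
    veg = pd$total_veg_cup * 120 + pd$greens_beans_cup * 120,
    grains = (pd$whole_grain_oz + pd$refined_grain_oz) * 28.35,
    dairy = pd$dairy_cup * 245,
    sweets = pd$added_sugars_tsp * 4.2 + 150,
    other = rep(350, nrow(pd)))
  cat_label <- c(
    meats = "Protein Foods-Meats",
    cured = "Protein Foods-Cured Meats/Poultry",
    poultry = "Protein Foods-Cured Meats/Poultry",
    seafood_eggs_plant = "Protein Foods-Seafood Eggs Plant",
    nuts = "Nuts and Seeds",
    fruit = "Fruits", veg = "Vegetables", grains = "Grains",
    dairy = "Milk and Dairy", sweets = "Sweets and Beverages",
    other = "Other")
  code_prefix <- c(meats = "M1", cured = "C2", poultry = "Y3",
                   seafood_eggs_plant = "S4", nuts = "N5", fruit = "F6",
                   veg = "V7", grains = "G8", dairy = "D9", sweets = "B0",
                   other = "O1")

  total_g <- Reduce(`+`, g)
  recs <- list()
  for (cat in names(g)) {
    keep <- g[[cat]] > 0
    if (!any(keep)) next
    share <- g[[cat]][keep] / total_g[keep]
    r <- pd[keep, c("person_id", "day")]
    r$food_code <- paste0(code_prefix[cat], "0", variant[keep])
    r$walnut_flag <- cat == "nuts" & nut_truth[keep] == "walnut"
    if (cat == "nuts") {
      r$food_code <- ifelse(r$walnut_flag, "N5W1", paste0("N50", variant[keep]))
    }
    r$grams <- g[[cat]][keep]
    r$wweia_category <- cat_label[cat]
    for (f in nutrient_fields()) r[[f]] <- pd[[f]][keep] * share
    grp <- matrix(0, sum(keep), length(food_group_fields()),
                  dimnames = list(NULL, food_group_fields()))
    grp_cols <- switch(cat,
      meats = c("meat_oz", "organ_meat_oz"),
      cured = "cured_meat_oz",
      poultry = "poultry_oz",
      seafood_eggs_plant = c("seafood_oz", "eggs_oz", "legumes_oz", "soy_oz"),
      nuts = "nuts_seeds_oz",
      fruit = c("total_fruit_cup", "whole_fruit_cup"),
      veg = c("total_veg_cup", "greens_beans_cup"),
      grains = c("whole_grain_oz", "refined_grain_oz"),
      dairy = "dairy_cup",
      sweets = "added_sugars_tsp",
      other = character(0))
    for (col in grp_cols) grp[, col] <- pd[[col]][keep]
    # derived totals follow their constituents' records
    grp[, "total_protein_oz"] <- rowSums(grp[, c("meat_oz", "cured_meat_oz",
      "organ_meat_oz", "poultry_oz", "seafood_oz", "eggs_oz", "legumes_oz",
      "soy_oz", "nuts_seeds_oz"), drop = FALSE])
    grp[, "seafood_plant_protein_oz"] <- rowSums(grp[, c("seafood_oz",
      "legumes_oz", "soy_oz", "nuts_seeds_oz"), drop = FALSE])
    recs[[cat]] <- bind_cols(r, as_tibble(as.data.frame(grp)))
  }
  bind_rows(recs) %>% arrange(.data$person_id, .data$day)
}

#' Generate a price table and CPI series for the cohort's food codes
#'
#' Base-year prices per 100 g for every food code the generator emits, with
#' food-category CPI series from the base to the target year. Meat and
#' walnut prices are calibrated so that after inflation adjustment to the
#' target year they equal the configured per-ounce prices exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list: `prices` (food_code, category, price_per_100g, imputed),
#'   `cpi` (category, year, index), and the configured `meat_price_per_oz`
#'   and `walnut_price_per_oz`.
#' @export
simulate_prices <- function(config = sim_config()) {
  stopifnot(inherits(config, "nutshift_sim_config"))
  set.seed(derive_seed(config$seed, 5))
  cats <- tibble::tribble(
    ~prefix, ~category,                            ~price100, ~infl,
    "M1", "Protein Foods-Meats",                   NA,    0.025,
    "C2", "Protein Foods-Cured Meats/Poultry",     NA,    0.025,
    "Y3", "Protein Foods-Cured Meats/Poultry",     1.10,  0.025,
    "S4", "Protein Foods-Seafood Eggs Plant",      1.60,  0.022,
    "N5", "Nuts and Seeds",                        NA,    0.018,
    "F6", "Fruits",                                0.45,  0.020,
    "V7", "Vegetables",                            0.40,  0.020,
    "G8", "Grains",                                0.55,  0.019,
    "D9", "Milk and Dairy",                        0.38,  0.017,
    "B0", "Sweets and Beverages",                  0.30,  0.016,
    "O1", "Other",                                 0.60,  0.020)
  years <- config$price_base_year:config$price_target_year
  cpi <- cats %>%
    distinct(.data$category, .data$infl) %>%
    tidyr::crossing(year = years) %>%
    mutate(index = 100 * (1 + .data$infl)^(.data$year - config$price_base_year)) %>%
    select("category", "year", "index")
  ratio <- function(cat_name) {
    i <- cpi[cpi$category == cat_name, ]
    i$index[i$year == config$price_target_year] /
      i$index[i$year == config$price_base_year]
  }
  # calibrate meat/cured and walnut codes to the configured target-year
  # per-oz (of food) prices: price per 100 g = per-oz price / 28.35 * 100
  meat100 <- config$meat_price_per_oz / 28.35 * 100
  waln100 <- config$walnut_price_per_oz / 28.35 * 100
  prices <- purrr::map_dfr(seq_len(nrow(cats)), function(i) {
    pre <- cats$prefix[i]
    codes <- if (pre == "N5") c("N5W1", "N501", "N502", "N503") else
      paste0(pre, "0", 1:3)
    base <- if (pre %in% c("M1", "C2")) meat100 / ratio(cats$category[i])
    else if (pre == "N5") waln100 / ratio(cats$category[i])
    else cats$price100[i] / ratio(cats$category[i]) *
      exp(rnorm(length(codes), 0, 0.08))
    tibble(food_code = codes, category = cats$category[i],
           price_per_100g = base, imputed = FALSE)
  })
  list(prices = prices, cpi = cpi,
       meat_price_per_oz = config$meat_price_per_oz,
       walnut_price_per_oz = config$walnut_price_per_oz,
       base_year = config$price_base_year,
       target_year = config$price_target_year)
}
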