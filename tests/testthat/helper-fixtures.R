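# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A mid-sized default-condition cohort with exclusions applied.
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    ch <- simulate_cohort(sim_config(n_persons = 300, seed = 42))
    ex <- apply_exclusions(ch$persons, ch$person_days, ch$food_records)
    inc <- assign_groups(ex$included)
    .fixtures$cohort <- list(
      cohort = ch,
      included = inc,
      excluded = ex$excluded,
      pd = dplyr::filter(ch$person_days,
                         person_id %in% inc$person_id),
      design = subset_design(ch$design, inc$person_id))
  }
  .fixtures$cohort
}

# One person-day with plenty of meat, for substitution arithmetic.
high_meat_day <- function() {
  pd <- nutrient_vector(energy = 2200, protein = 90, sat_fat = 28,
                        mufa = 25, pufa = 17, ala = 1.6, la = 15,
                        cholesterol = 300, fiber = 16, calcium = 900,
                        iron = 13, magnesium = 300, potassium = 2500,
                        sodium = 3400, copper = 1.2, zinc = 11,
                        folate_dfe = 500, vitamin_e = 8, vitamin_b12 = 5)
  pd$person_id <- "X1"
  pd$day <- 1L
  pd$weekday <- TRUE
  pd$meat_oz <- 3
  pd$cured_meat_oz <- 1.5
  pd$organ_meat_oz <- 0.5
  pd$poultry_oz <- 1
  pd$seafood_oz <- 0.5
  pd$eggs_oz <- 0.5
  pd$legumes_oz <- 0.3
  pd$soy_oz <- 0.1
  pd$nuts_seeds_oz <- 0
  pd$total_protein_oz <- 7.4
  pd$seafood_plant_protein_oz <- 0.9
  pd$total_fruit_cup <- 0.8
  pd$whole_fruit_cup <- 0.4
  pd$total_veg_cup <- 1.4
  pd$greens_beans_cup <- 0.2
  pd$whole_grain_oz <- 0.9
  pd$refined_grain_oz <- 5
  pd$dairy_cup <- 1.5
  pd$added_sugars_tsp <- 15
  pd
}

# Tiny equal-structure survey design for hand-arithmetic tests.
toy_design <- function(ids, weights = rep(1, length(ids)), fay = 0,
                       n_rep = 2) {
  new_survey_design(
    tibble::tibble(person_id = ids, weight = weights),
    matrix(rep(weights, n_rep), ncol = n_rep), fay = fay)
}
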