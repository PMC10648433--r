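# Healthy Eating Index 2015: 13 components with piecewise-linear
# density-based standards (9 adequacy, 4 moderation; 100 points total),
# the population-ratio method on day-1 intakes, and the printed
# addition/subtraction adjustment for the walnut-for-meat substitution.

#' HEI-2015 component standards
#'
#' Each component is scored piecewise-linearly between its zero-score and
#' full-score standards and clamped to `[0, max_points]`:
#' `score = max_points * clamp((density - zero_std) / (full_std - zero_std), 0, 1)`.
#' Adequacy components have `zero_std = 0`; moderation components have
#' `zero_std > full_std` so the score falls as the density rises. Densities
#' are per 1000 kcal (cup or oz eq), percent of energy (added sugars at
#' 16 kcal/tsp, saturated fat at 9 kcal/g), or the unitless fatty-acid
#' ratio (MUFA + PUFA) / SFA. The standards live in data, not code, so a
#' revised index (e.g. HEI-2020) can be swapped in.
#'
#' @return Tibble: `component`, `max_points`, `basis`, `direction`,
#'   `full_std`, `zero_std`.
#' @export
hei_standards <- function() {
  tibble::tribble(
    ~component,                 ~max_points, ~basis,         ~direction,   ~full_std, ~zero_std,
    "total_fruit",               5, "density_1000",  "adequacy",    0.8,  0,
    "whole_fruit",               5, "density_1000",  "adequacy",    0.4,  0,
    "total_veg",                 5, "density_1000",  "adequacy",    1.1,  0,
    "greens_beans",              5, "density_1000",  "adequacy",    0.2,  0,
    "whole_grains",             10, "density_1000",  "adequacy",    1.5,  0,
    "dairy",                    10, "density_1000",  "adequacy",    1.3,  0,
    "total_protein",             5, "density_1000",  "adequacy",    2.5,  0,
    "seafood_plant_protein",     5, "density_1000",  "adequacy",    0.8,  0,
    "fatty_acid_ratio",         10, "fa_ratio",      "adequacy",    2.5,  1.2,
    "refined_grains",           10, "density_1000",  "moderation",  1.8,  4.3,
    "sodium",                   10, "density_1000",  "moderation",  1.1,  2.0,
    "added_sugars",             10, "pct_energy",    "moderation",  6.4, 26,
    "sat_fat",                  10, "pct_energy",    "moderation",  8,   16)
}

#' Extract the HEI constituent amounts from person-days
#'
#' Pulls the raw totals all 13 components need: energy, the food-pattern
#' amounts, MUFA/PUFA/SFA grams, sodium (converted mg to g here, the only
#' place it happens), and added-sugars tsp equivalents.
#'
#' @param person_days Person-day tibble.
#' @return Tibble keyed by `person_id`, `day` with one column per
#'   constituent.
#' @export
hei_constituents <- function(person_days) {
  person_days %>%
    mutate(sodium_g = .data$sodium / 1000) %>%
    select("person_id", "day", "energy",
           total_fruit = "total_fruit_cup", whole_fruit = "whole_fruit_cup",
           total_veg = "total_veg_cup", greens_beans = "greens_beans_cup",
           whole_grains = "whole_grain_oz", refined_grains = "refined_grain_oz",
           dairy = "dairy_cup", total_protein = "total_protein_oz",
           seafood_plant_protein = "seafood_plant_protein_oz",
           mufa = "mufa", pufa = "pufa", sfa = "sat_fat",
           sodium_g = "sodium_g", added_sugars = "added_sugars_tsp")
}

hei_densities <- function(amounts) {
  e <- amounts$energy
  if (any(e <= 0)) stop("HEI densities undefined at energy <= 0", call. = FALSE)
  dens1000 <- function(x) 1000 * x / e
  tibble(
    total_fruit = dens1000(amounts$total_fruit),
    whole_fruit = dens1000(amounts$whole_fruit),
    total_veg = dens1000(amounts$total_veg),
    greens_beans = dens1000(amounts$greens_beans),
    whole_grains = dens1000(amounts$whole_grains),
    dairy = dens1000(amounts$dairy),
    total_protein = dens1000(amounts$total_protein),
    seafood_plant_protein = dens1000(amounts$seafood_plant_protein),
    fatty_acid_ratio = ifelse(amounts$sfa > 0,
                              (amounts$mufa + amounts$pufa) / amounts$sfa,
                              Inf),
    refined_grains = dens1000(amounts$refined_grains),
    sodium = dens1000(amounts$sodium_g),
    added_sugars = 100 * amounts$added_sugars * 16 / e,
    sat_fat = 100 * amounts$sfa * 9 / e)
}

#' Score the 13 HEI-2015 components from constituent amounts
#'
#' Converts amounts to densities and applies the piecewise-linear
#' standards. Vectorized over rows, so it scores one population-level mean
#' amount vector or many per-person rows alike.
#'
#' @param amounts Tibble of constituent amounts as from
#'   [hei_constituents()] (id columns optional).
#' @param standards Standards tibble, default [hei_standards()].
#' @return Tibble with one column per component score plus `hei_total`.
#' @export
#' @examples
#' amt <- hei_constituents(simulate_cohort(sim_config(n_persons = 20, seed = 1),
#'                                         compute_truth = FALSE)$person_days)
#' score_hei(dplyr::summarise(amt, dplyr::across(-c(person_id, day), mean)))
score_hei <- function(amounts, standards = hei_standards()) {
  dens <- hei_densities(amounts)
  out <- list()
  for (i in seq_len(nrow(standards))) {
    s <- standards[i, ]
    frac <- (dens[[s$component]] - s$zero_std) / (s$full_std - s$zero_std)
    # Inf density (zero SFA) scores full points for an adequacy ratio
    frac[is.infinite(dens[[s$component]]) & dens[[s$component]] > 0] <- 1
    out[[s$component]] <- s$max_points * pmin(pmax(frac, 0), 1)
  }
  res <- as_tibble(out)
  res$hei_total <- rowSums(as.matrix(res))
  res
}

#' The printed walnut-addition / meat-subtraction adjustment values
#'
#' Per-ounce constituent changes used for diet-quality scoring of the
#' modeled diets: adding 1 oz of walnuts contributes 2.53 g MUFA, 13.4 g
#' PUFA, 1.74 g SFA, 185 kcal, 2 oz eq total protein, 2 oz eq seafood and
#' plant proteins, and 0.567 mg sodium; subtracting 1 oz eq of meat removes
#' 0.87 g MUFA, 0.12 g PUFA, 0.76 g SFA, 49 kcal, 1 oz eq total protein,
#' 1 oz eq seafood and plant proteins, and 127 mg sodium. The values are
#' kept exactly as published, including the meat entry for seafood and
#' plant proteins (see `literal_seafood_plant` in [adjust_hei_amounts()])
#' and the mg-scale walnut sodium.
#'
#' @return List with named vectors `walnut_add_per_oz` and
#'   `meat_subtract_per_oz` (sodium in mg; protein entries in oz eq).
#' @export
hei_adjustment_profile <- function() {
  list(
    walnut_add_per_oz = c(mufa = 2.53, pufa = 13.4, sfa = 1.74,
                          energy = 185, total_protein = 2,
                          seafood_plant_protein = 2, sodium_mg = 0.567),
    meat_subtract_per_oz = c(mufa = 0.87, pufa = 0.12, sfa = 0.76,
                             energy = 49, total_protein = 1,
                             seafood_plant_protein = 1, sodium_mg = 127))
}

#' Adjust HEI constituent amounts for a walnut-for-meat substitution
#'
#' Applies `amounts + w * walnut_add - r * meat_subtract` with
#' `w = 0.5 * r` ounces of walnuts per `r` oz eq of meat removed, clipping
#' at zero. With `literal_seafood_plant = TRUE` (default) the published
#' meat subtraction of 1 oz eq from the seafood-and-plant-proteins
#' constituent is applied literally even though meat is not normally part
#' of that component; set it to `FALSE` to leave that constituent's
#' subtraction out.
#'
#' @param amounts Constituent tibble from [hei_constituents()].
#' @param r Meat oz eq removed; scalar or one value per row.
#' @param profile A [hei_adjustment_profile()].
#' @param literal_seafood_plant Apply the printed seafood-and-plant
#'   subtraction for meat (default `TRUE`).
#' @return The adjusted amounts tibble.
#' @export
adjust_hei_amounts <- function(amounts, r, profile = hei_adjustment_profile(),
                               literal_seafood_plant = TRUE) {
  stopifnot(all(r >= 0), length(r) %in% c(1L, nrow(amounts)))
  w <- 0.5 * r
  add <- profile$walnut_add_per_oz
  sub <- profile$meat_subtract_per_oz
  if (!literal_seafood_plant) sub[["seafood_plant_protein"]] <- 0
  delta <- function(field, add_name = field, sub_name = field) {
    w * add[[add_name]] - r * sub[[sub_name]]
  }
  amounts %>%
    mutate(
      energy = pmax(.data$energy + delta("energy"), 0),
      mufa = pmax(.data$mufa + delta("mufa"), 0),
      pufa = pmax(.data$pufa + delta("pufa"), 0),
      sfa = pmax(.data$sfa + delta("sfa"), 0),
      sodium_g = pmax(.data$sodium_g + delta("sodium_mg") / 1000, 0),
      total_protein = pmax(.data$total_protein + delta("total_protein"), 0),
      seafood_plant_protein = pmax(
        .data$seafood_plant_protein + delta("seafood_plant_protein"), 0))
}

#' Population-ratio HEI-2015 score with BRR confidence interval
#'
#' The population score is the score of the weighted mean constituent
#' amounts (ratio of means), not the mean of per-person scores: day-1
#' amounts are averaged across persons with survey weights first, and the
#' piecewise-linear scoring is applied to those mean amounts. Under a
#' substitution dose, each person's day-1 amounts are first adjusted by
#' their own capped meat removal `r_i = min(dose, day-1 meat oz eq)`. The
#' 95% interval re-computes the whole ratio-then-score pipeline under every
#' BRR replicate weight vector.
#'
#' @param person_days Person-day tibble (day 1 is used).
#' @param design Survey design covering the persons.
#' @param dose Meat-replacement dose in oz eq; 0 scores the current diet.
#' @param standards Standards tibble, default [hei_standards()].
#' @param profile Adjustment values, default [hei_adjustment_profile()].
#' @param literal_seafood_plant See [adjust_hei_amounts()].
#' @return A `hei_result` list: `total` (one-row tibble with `estimate`,
#'   `se`, `lower`, `upper`), `components` (scores at the point estimate),
#'   `dose`, `n`.
#' @export
hei_population_ratio <- function(person_days, design, dose = 0,
                                 standards = hei_standards(),
                                 profile = hei_adjustment_profile(),
                                 literal_seafood_plant = TRUE) {
  day1 <- person_days %>% filter(.data$day == 1L)
  amounts <- hei_constituents(day1)
  if (dose > 0) {
    r <- pmin(dose, meat_oz_equivalents(day1))
    amounts <- adjust_hei_amounts(amounts, r, profile, literal_seafood_plant)
  }
  design <- subset_design(design, amounts$person_id)
  ord <- match(design$weights$person_id, amounts$person_id)
  amounts <- amounts[ord, ]
  value_cols <- setdiff(names(amounts), c("person_id", "day"))
  score_with <- function(w) {
    if (sum(w) <= 0 || weighted_mean(amounts$energy, pmax(w, 1e-12)) <= 0) {
      stop("zero weighted energy", call. = FALSE)
    }
    mean_amt <- as_tibble(lapply(amounts[value_cols], function(x) {
      sum(w * x) / sum(w)
    }))
    score_hei(mean_amt, standards)
  }
  total <- brr_interval(design, function(w) score_with(w)$hei_total)
  structure(
    list(total = total,
         components = score_with(design$weights$weight),
         dose = dose, n = nrow(amounts)),
    class = "nutshift_hei")
}

#' @export
print.nutshift_hei <- function(x, ...) {
  cat(sprintf("<HEI-2015 population-ratio score> dose %s oz: %.1f (%.1f-%.1f), n = %d\n",
              format(x$dose), x$total$estimate, x$total$lower, x$total$upper,
              x$n))
  invisible(x)
}

#' HEI dose-response table across substitution doses
#'
#' Scores the current diet and each modeled dose for one or more reporting
#' groups, flagging doses whose 95% CI does not overlap the current diet's
#' (the non-overlap significance rule).
#'
#' @param person_days Person-day tibble.
#' @param persons Persons tibble (for group assignment).
#' @param design Survey design.
#' @param doses Dose levels, default 1-4.
#' @param groups Reporting group labels, default all elementary groups and
#'   roll-ups.
#' @param ... Passed to [hei_population_ratio()].
#' @return Tibble: `group`, `dose`, `estimate`, `lower`, `upper`,
#'   `significant` (`NA` for the current diet row).
#' @export
hei_dose_table <- function(person_days, persons, design, doses = 1:4,
                           groups = NULL, ...) {
  if (!"group" %in% names(persons)) persons <- assign_groups(persons)
  if (is.null(groups)) {
    groups <- c(age_gender_groups()$group, names(group_rollups()))
  }
  purrr::map_dfr(groups, function(gl) {
    ids <- group_members(persons, gl)$person_id
    pdg <- person_days %>% filter(.data$person_id %in% ids)
    if (nrow(pdg) == 0) return(NULL)
    dg <- subset_design(design, ids)
    rows <- purrr::map_dfr(c(0, doses), function(d) {
      h <- hei_population_ratio(pdg, dg, dose = d, ...)
      tibble(group = gl, dose = d, estimate = h$total$estimate,
             lower = h$total$lower, upper = h$total$upper)
    })
    cur <- rows %>% filter(.data$dose == 0)
    rows %>% mutate(significant = ifelse(
      .data$dose == 0, NA,
      nonoverlap_significant(cur$lower, cur$upper, .data$lower, .data$upper)))
  })
}
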