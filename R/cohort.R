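# Sample construction: walnut/other-nut/no-nut classification, ordered
# exclusion rules, age-gender grouping and the survey-weighted protein-food
# composition summary.

#' Classify each person's nut-consumption status
#'
#' A person is a `walnut` consumer if any food record is flagged as
#' containing walnuts (ingredient-level identification), an `other_nut`
#' consumer if any recall day has non-zero nuts-and-seeds oz equivalents
#' without a walnut food, and a `no_nut` consumer otherwise.
#'
#' @param food_records Food-record tibble (needs `person_id`, `walnut_flag`).
#' @param person_days Person-day tibble (needs `person_id`, `nuts_seeds_oz`).
#' @return Tibble with `person_id` and `nut_status`.
#' @export
classify_nut_status <- function(food_records, person_days) {
  walnut <- food_records %>%
    group_by(.data$person_id) %>%
    summarise(any_walnut = any(.data$walnut_flag), .groups = "drop")
  nuts <- person_days %>%
    group_by(.data$person_id) %>%
    summarise(any_nuts = any(.data$nuts_seeds_oz > 0), .groups = "drop")
  nuts %>%
    left_join(walnut, by = "person_id") %>%
    mutate(any_walnut = dplyr::coalesce(.data$any_walnut, FALSE),
           nut_status = dplyr::case_when(
             .data$any_walnut ~ "walnut",
             .data$any_nuts ~ "other_nut",
             TRUE ~ "no_nut")) %>%
    select("person_id", "nut_status")
}

#' Apply the study exclusion rules in order
#'
#' Rules are applied in a fixed order and each excluded person carries the
#' first matching reason: (1) younger than 4 years or consuming breast milk;
#' (2) pregnant or lactating women aged 20-44; (3) unreliable recall;
#' (4) day-1 energy below 500 or above 5000 kcal (both bounds themselves
#' are retained); (5) missing animal-protein food-pattern data; (6) nut
#' consumer (walnut or other nut). The included set therefore contains only
#' no-nut consumers aged 4 and older with plausible day-1 energy.
#'
#' @param persons Person tibble with the flag columns `breast_milk`,
#'   `pregnant_or_lactating`, `unreliable_recall`, `missing_animal_protein`.
#' @param person_days Person-day tibble (for day-1 energy).
#' @param food_records Food-record tibble (for walnut identification).
#' @return List with `included` (persons tibble plus `nut_status`) and
#'   `excluded` (tibble of `person_id`, `reason`).
#' @export
apply_exclusions <- function(persons, person_days, food_records) {
  required <- c("breast_milk", "pregnant_or_lactating", "unreliable_recall",
                "missing_animal_protein")
  missing_cols <- setdiff(required, names(persons))
  if (length(missing_cols) > 0) {
    stop("persons table lacks required flag(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  day1 <- person_days %>% filter(.data$day == 1L) %>%
    select("person_id", day1_energy = "energy")
  status <- classify_nut_status(food_records, person_days)
  p <- persons %>%
    left_join(day1, by = "person_id") %>%
    left_join(status, by = "person_id")

  reason <- rep(NA_character_, nrow(p))
  hit <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- hit(p$age_years < 4 | p$breast_milk, "too_young_or_breastfed")
  reason <- hit(p$pregnant_or_lactating & p$gender == "female" &
                  p$age_years >= 20 & p$age_years <= 44, "pregnant_lactating")
  reason <- hit(p$unreliable_recall, "unreliable_recall")
  reason <- hit(p$day1_energy < 500 | p$day1_energy > 5000,
                "implausible_energy")
  reason <- hit(p$missing_animal_protein, "missing_protein_data")
  reason <- hit(p$nut_status != "no_nut", "nut_consumer")

  p$exclusion_reason <- reason
  list(
    included = p %>% filter(is.na(.data$exclusion_reason)) %>%
      select(-"exclusion_reason", -"day1_energy"),
    excluded = p %>% filter(!is.na(.data$exclusion_reason)) %>%
      select("person_id", reason = "exclusion_reason"))
}

#' Elementary age-gender group definitions
#'
#' Ten gender-specific bands (male/female by 4-8, 9-13, 14-18, 19-50,
#' 51-70) plus a combined `Adult 71+` group, forming a partition of the
#' included sample.
#'
#' @return Tibble with `group`, `gender` (`NA` = both), `age_min`, `age_max`.
#' @export
age_gender_groups <- function() {
  tibble::tribble(
    ~group,          ~gender,  ~age_min, ~age_max,
    "Male 4-8",      "male",    4,  8,
    "Male 9-13",     "male",    9, 13,
    "Male 14-18",    "male",   14, 18,
    "Female 4-8",    "female",  4,  8,
    "Female 9-13",   "female",  9, 13,
    "Female 14-18",  "female", 14, 18,
    "Male 19-50",    "male",   19, 50,
    "Male 51-70",    "male",   51, 70,
    "Female 19-50",  "female", 19, 50,
    "Female 51-70",  "female", 51, 70,
    "Adult 71+",     NA,       71, Inf)
}

#' Reporting roll-ups of the elementary groups
#'
#' @return Named list mapping each roll-up label to its elementary groups.
#' @export
group_rollups <- function() {
  list(
    "Male 4-18" = c("Male 4-8", "Male 9-13", "Male 14-18"),
    "Female 4-18" = c("Female 4-8", "Female 9-13", "Female 14-18"),
    "Child 4-18" = c("Male 4-8", "Male 9-13", "Male 14-18",
                     "Female 4-8", "Female 9-13", "Female 14-18"),
    "Adult 19-50" = c("Male 19-50", "Female 19-50"),
    "Adult 51-70" = c("Male 51-70", "Female 51-70"),
    "Male 19-71+" = c("Male 19-50", "Male 51-70", "Adult 71+"),
    "Female 19-71+" = c("Female 19-50", "Female 51-70", "Adult 71+"),
    "Adult 19-71+" = c("Male 19-50", "Male 51-70", "Female 19-50",
                       "Female 51-70", "Adult 71+"))
}

#' Assign every person to exactly one elementary age-gender group
#'
#' @param persons Person tibble with `age_years` and `gender`.
#' @return `persons` with an added `group` column.
#' @export
assign_groups <- function(persons) {
  defs <- age_gender_groups()
  grp <- rep(NA_character_, nrow(persons))
  for (i in seq_len(nrow(defs))) {
    m <- persons$age_years >= defs$age_min[i] &
      persons$age_years <= defs$age_max[i] &
      (is.na(defs$gender[i]) | persons$gender == defs$gender[i])
    grp[is.na(grp) & m] <- defs$group[i]
  }
  if (any(is.na(grp))) {
    stop("person(s) with age outside all group bands: ",
         paste(utils::head(persons$person_id[is.na(grp)], 5), collapse = ", "),
         call. = FALSE)
  }
  persons %>% mutate(group = grp)
}

# membership helper: persons belonging to a reporting group (elementary or
# roll-up label)
group_members <- function(persons_with_group, label) {
  elem <- group_rollups()[[label]]
  if (is.null(elem)) elem <- label
  persons_with_group %>% filter(.data$group %in% elem)
}

#' Survey-weighted protein-food composition summary
#'
#' For each reporting group: the weighted mean protein-food oz equivalents
#' per day (averaged over a person's recall days, then weighted across
#' persons) for the total and for each source - meats (meat + cured +
#' organ), poultry, seafood, eggs, legumes, soy - plus each source's
#' percent share of the total, `100 * source / total`.
#'
#' @param persons Included persons (a `group` column is added if absent).
#' @param person_days Person-day tibble for those persons.
#' @param design Survey design; only base weights are used here.
#' @param groups Reporting group labels (default: gender-by-age roll-ups
#'   used for composition reporting).
#' @return Tibble: `group`, `source`, `mean_oz`, `share_pct` (share is `NA`
#'   for the `total` row denominator when the weighted total is 0).
#' @export
protein_food_summary <- function(persons, person_days, design,
                                 groups = c("Male 4-18", "Female 4-18",
                                            "Child 4-18", "Male 19-71+",
                                            "Female 19-71+", "Adult 19-71+")) {
  if (!"group" %in% names(persons)) persons <- assign_groups(persons)
  per_person <- person_days %>%
    mutate(meats = .data$meat_oz + .data$cured_meat_oz + .data$organ_meat_oz) %>%
    group_by(.data$person_id) %>%
    summarise(across(c("total_protein_oz", "meats", "poultry_oz",
                       "seafood_oz", "eggs_oz", "legumes_oz", "soy_oz"),
                     mean),
              .groups = "drop") %>%
    left_join(design$weights, by = "person_id")
  sources <- c(total = "total_protein_oz", meats = "meats",
               poultry = "poultry_oz", seafood = "seafood_oz",
               eggs = "eggs_oz", legumes = "legumes_oz", soy = "soy_oz")
  purrr::map_dfr(groups, function(gl) {
    ids <- group_members(persons, gl)$person_id
    sub <- per_person %>% filter(.data$person_id %in% ids)
    if (nrow(sub) == 0) return(NULL)
    means <- vapply(sources, function(col) weighted_mean(sub[[col]], sub$weight),
                    numeric(1))
    share <- if (means[["total"]] > 0) {
      100 * unname(means) / means[["total"]]
    } else {
      rep(NA_real_, length(means))
    }
    share[names(sources) == "total"] <- NA_real_
    tibble(group = gl, source = names(sources), mean_oz = unname(means),
           share_pct = share)
  })
}
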