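# Dose-escalation replacement engine: remove meat oz equivalents (meat +
# cured + organ; poultry excluded), add walnuts at 0.5 oz of nuts per 1 oz
# eq of meat (both are 1 oz eq of Protein Foods), and apply the per-ounce
# nutrient deltas.

#' The four escalating replacement doses
#'
#' @return Tibble with `dose` (the meat target in oz eq, 1-4) and
#'   `walnut_oz` (ounces of walnuts added at full replacement,
#'   `0.5 * dose`).
#' @export
dose_levels <- function() {
  tibble(dose = 1:4, walnut_oz = 0.5 * (1:4))
}

#' Meat oz equivalents of a person-day
#'
#' Meat is the sum of the meat, cured-meat and organ-meat food-pattern
#' categories; poultry is explicitly excluded.
#'
#' @param person_days Person-day tibble (or any tibble with the three
#'   columns).
#' @return Numeric vector of meat oz equivalents, one per row.
#' @export
#' @examples
#' meat_oz_equivalents(tibble::tibble(meat_oz = 1, cured_meat_oz = 0.5,
#'                                    organ_meat_oz = 0.2, poultry_oz = 3))
meat_oz_equivalents <- function(person_days) {
  person_days$meat_oz + person_days$cured_meat_oz + person_days$organ_meat_oz
}

#' Replace meat with walnuts on each person-day at a given dose
#'
#' For each row, removes `r = min(dose, available meat oz eq)` of meat and
#' adds `w = 0.5 * r` ounces of walnuts (`r` oz eq), so a day reporting
#' less meat than the dose is only modified up to its reported level and a
#' zero-meat day is returned unchanged. Nutrient changes are
#' `w * walnut_per_oz - r * meat_per_oz`, clipped at zero (clipping is
#' flagged per row). Food groups: the meat, cured and organ categories are
#' reduced proportionally; nuts-and-seeds gains `r` oz eq (the oz-eq value
#' of `w` oz of walnuts), so `total_protein_oz` is unchanged and
#' `seafood_plant_protein_oz` gains `r`.
#'
#' @param person_days Person-day tibble.
#' @param dose Meat replacement target in oz eq (typically 1-4).
#' @param profile A [food_composition_profile()].
#' @param cap If `TRUE` (default), replacement is capped at reported meat.
#' @return The modified tibble with added columns `dose`,
#'   `meat_removed_oz`, `walnut_added_oz` (ounces of walnuts) and `clipped`.
#' @export
substitute_meat <- function(person_days, dose,
                            profile = food_composition_profile(),
                            cap = TRUE) {
  stopifnot(length(dose) == 1, dose >= 0)
  check_nutrient_cols(person_days, "person_days")
  avail <- meat_oz_equivalents(person_days)
  r <- if (cap) pmin(dose, avail) else rep(dose, nrow(person_days))
  w <- 0.5 * r
  out <- person_days
  clipped <- rep(FALSE, nrow(out))
  for (f in nutrient_fields()) {
    delta <- w * profile$walnut_per_oz[[f]] - r * profile$meat_per_oz[[f]]
    v <- out[[f]] + delta
    clipped <- clipped | v < -1e-6
    out[[f]] <- pmax(v, 0)
  }
  shrink <- ifelse(avail > 0, (avail - r) / avail, 1)
  out$meat_oz <- out$meat_oz * shrink
  out$cured_meat_oz <- out$cured_meat_oz * shrink
  out$organ_meat_oz <- out$organ_meat_oz * shrink
  out$nuts_seeds_oz <- out$nuts_seeds_oz + r
  out$seafood_plant_protein_oz <- out$seafood_plant_protein_oz + r
  out$dose <- dose
  out$meat_removed_oz <- r
  out$walnut_added_oz <- w
  out$clipped <- clipped
  out
}

#' Apply the full dose series to a cohort's person-days
#'
#' Runs [substitute_meat()] independently on every recall day at each dose
#' and stacks the results with the unmodified diet as `dose = 0`.
#'
#' @param person_days Person-day tibble.
#' @param doses Dose levels (default 1-4 oz of meat).
#' @param profile A [food_composition_profile()].
#' @param cap Cap replacement at reported meat (default `TRUE`).
#' @return Long tibble with a `dose` column; `dose = 0` rows carry
#'   `meat_removed_oz = walnut_added_oz = 0`.
#' @export
apply_dose_series <- function(person_days, doses = 1:4,
                              profile = food_composition_profile(),
                              cap = TRUE) {
  base <- person_days %>%
    mutate(dose = 0, meat_removed_oz = 0, walnut_added_oz = 0,
           clipped = FALSE)
  bind_rows(base,
            purrr::map_dfr(doses, function(d) {
              substitute_meat(person_days, d, profile, cap = cap)
            }))
}

#' Nutrient deltas between a modified and an original person-day table
#'
#' Convenience accessor for the substitution result: the component-wise
#' difference of the nutrient columns, aligned on `person_id` and `day`.
#'
#' @param modified,original Person-day tibbles with identical rows.
#' @return Tibble of `person_id`, `day` and per-nutrient deltas.
#' @export
substitution_deltas <- function(modified, original) {
  stopifnot(nrow(modified) == nrow(original),
            all(modified$person_id == original$person_id),
            all(modified$day == original$day))
  out <- modified[, c("person_id", "day")]
  for (f in nutrient_fields()) out[[f]] <- modified[[f]] - original[[f]]
  out
}
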