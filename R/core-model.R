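#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols across all_of n row_number if_else rename
#'   relocate pull distinct count inner_join anti_join
#' @importFrom rlang .data
#' @importFrom stats rnorm rbinom runif rlnorm quantile sd var setNames
#'   model.matrix as.formula logLik qnorm
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# ---------------------------------------------------------------------------
# Field registries: the closed component sets shared by every stage.
# Units are fixed here and never converted downstream: energy kcal; protein,
# sat_fat, mufa, pufa, ala, la, fiber g; cholesterol, calcium, iron,
# magnesium, potassium, sodium, copper, zinc, vitamin_e mg; folate_dfe,
# vitamin_b12 ug. Food groups are USDA food-pattern equivalents (oz eq, cup
# eq, tsp eq).
# ---------------------------------------------------------------------------

#' Names of the nutrient components tracked per person-day
#'
#' The component set is closed: every nutrient table in the package carries
#' exactly these columns, and constructors reject unknown names. Units are
#' fixed (kcal for energy; g for protein, fats, ALA, LA and fiber; mg for
#' cholesterol, minerals and vitamin E; ug for folate DFE and vitamin B12)
#' and all unit conversion happens at data ingest, never downstream.
#'
#' @return Character vector of nutrient column names.
#' @export
#' @examples
#' nutrient_fields()
nutrient_fields <- function() {
  c("energy", "protein", "sat_fat", "mufa", "pufa", "ala", "la",
    "cholesterol", "fiber", "calcium", "iron", "magnesium", "potassium",
    "sodium", "copper", "zinc", "folate_dfe", "vitamin_e", "vitamin_b12")
}

#' Names of the food-pattern (FPED-style) group components
#'
#' Protein-food groups in oz equivalents, HEI constituents in their native
#' food-pattern units (cup eq, oz eq, tsp eq). `total_protein_oz` is the sum
#' of the named protein sub-groups; `seafood_plant_protein_oz` is seafood +
#' soy + legumes + nuts and seeds.
#'
#' @return Character vector of food-group column names.
#' @export
food_group_fields <- function() {
  c("meat_oz", "cured_meat_oz", "organ_meat_oz", "poultry_oz", "seafood_oz",
    "eggs_oz", "legumes_oz", "soy_oz", "nuts_seeds_oz", "total_protein_oz",
    "seafood_plant_protein_oz",
    "total_fruit_cup", "whole_fruit_cup", "total_veg_cup",
    "greens_beans_cup", "whole_grain_oz", "refined_grain_oz", "dairy_cup",
    "added_sugars_tsp")
}

#' Construct a one-row nutrient tibble
#'
#' Unnamed components default to 0; unknown component names are rejected so
#' that the component set stays closed across the pipeline.
#'
#' @param ... Named scalar nutrient amounts, e.g. `energy = 185, fiber = 1.9`.
#' @return A one-row tibble with all columns of [nutrient_fields()].
#' @export
#' @examples
#' nutrient_vector(energy = 185, protein = 4.32)
nutrient_vector <- function(...) {
  vals <- list(...)
  fields <- nutrient_fields()
  if (length(vals) > 0) {
    if (is.null(names(vals)) || any(names(vals) == "")) {
      stop("all nutrient components must be named", call. = FALSE)
    }
    bad <- setdiff(names(vals), fields)
    if (length(bad) > 0) {
      stop("unknown nutrient component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- as.list(setNames(rep(0, length(fields)), fields))
  out[names(vals)] <- vals
  as_tibble(out)
}

check_nutrient_cols <- function(x, where = "input") {
  missing <- setdiff(nutrient_fields(), names(x))
  if (length(missing) > 0) {
    stop(where, " is missing nutrient column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-ounce composition of the swap foods (USDA values).
# ---------------------------------------------------------------------------

#' Per-ounce nutrient composition of the substitution foods
#'
#' `food_composition_profile()` returns the per-ounce nutrient vectors used
#' by the substitution engine: walnuts per 1 oz of nuts, and meat (beef,
#' veal, pork, lamb, game plus cured and organ meat; poultry excluded) per
#' 1 oz eq. Components not listed in the source composition data are 0 —
#' in particular the meat vector carries no fiber, copper, folate,
#' vitamin E or LA, so those nutrients are only ever added by walnuts. The
#' PUFA sub-components ALA and LA carry the polyunsaturated-fat change in
#' these vectors; total MUFA/PUFA adjustments for diet-quality scoring use
#' the separate [hei_adjustment_profile()].
#'
#' @param walnut_per_oz,meat_per_oz Optional one-row nutrient tibbles (see
#'   [nutrient_vector()]) overriding the built-in USDA composition.
#' @return A list with elements `walnut_per_oz` and `meat_per_oz`.
#' @export
#' @examples
#' food_composition_profile()$walnut_per_oz$energy  # 185 kcal
food_composition_profile <- function(walnut_per_oz = NULL, meat_per_oz = NULL) {
  if (is.null(walnut_per_oz)) {
    walnut_per_oz <- nutrient_vector(
      energy = 185, protein = 4.32, sat_fat = 1.74, ala = 2.57, la = 10.8,
      calcium = 27.8, iron = 0.825, magnesium = 44.8, potassium = 125,
      copper = 0.451, zinc = 0.876, folate_dfe = 27.8, vitamin_e = 0.198,
      fiber = 1.9)
  }
  if (is.null(meat_per_oz)) {
    meat_per_oz <- nutrient_vector(
      energy = 49, protein = 7.1, sat_fat = 0.76, cholesterol = 20,
      ala = 0.01, calcium = 2, iron = 0.5, magnesium = 6, potassium = 93,
      zinc = 1.2, vitamin_b12 = 0.6)
  }
  check_nutrient_cols(walnut_per_oz, "walnut_per_oz")
  check_nutrient_cols(meat_per_oz, "meat_per_oz")
  list(walnut_per_oz = walnut_per_oz, meat_per_oz = meat_per_oz)
}

#' Component-wise scaled addition of nutrient tables
#'
#' Computes `base + factor * delta` column by column over the nutrient
#' components. `delta` may have one row (recycled against every row of
#' `base`) or as many rows as `base`. Both inputs must carry exactly the
#' same nutrient columns; unknown or missing components are an error, so a
#' malformed delta can never silently drop a nutrient.
#'
#' @param base Data frame with the [nutrient_fields()] columns (extra
#'   non-nutrient columns are passed through untouched).
#' @param delta Data frame with the same nutrient columns.
#' @param factor Finite scalar multiplier applied to `delta`.
#' @param clip If `TRUE`, negative results are clipped to 0 (used after
#'   substitution, where a removal can exceed a small observed amount).
#' @return `base` with updated nutrient columns.
#' @export
#' @examples
#' scale_and_add(nutrient_vector(), food_composition_profile()$walnut_per_oz, 2)
scale_and_add <- function(base, delta, factor = 1, clip = FALSE) {
  stopifnot(is.data.frame(base), is.data.frame(delta),
            length(factor) == 1, is.finite(factor))
  check_nutrient_cols(base, "base")
  check_nutrient_cols(delta, "delta")
  extra <- setdiff(names(delta), nutrient_fields())
  if (length(extra) > 0) {
    stop("delta carries non-nutrient column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!nrow(delta) %in% c(1L, nrow(base))) {
    stop("delta must have 1 row or nrow(base) rows", call. = FALSE)
  }
  for (f in nutrient_fields()) {
    v <- base[[f]] + factor * delta[[f]]
    base[[f]] <- if (clip) pmax(v, 0) else v
  }
  base
}

# ---------------------------------------------------------------------------
# Cohort container and delimited-text I/O
# ---------------------------------------------------------------------------

new_cohort <- function(persons, person_days, food_records, design) {
  structure(
    list(persons = persons, person_days = person_days,
         food_records = food_records, design = design),
    class = "nutshift_cohort")
}

#' @export
print.nutshift_cohort <- function(x, ...) {
  cat("<nutshift_cohort>\n")
  cat("  persons:      ", nrow(x$persons), "\n")
  cat("  person-days:  ", nrow(x$person_days), "\n")
  cat("  food records: ", nrow(x$food_records), "\n")
  cat("  replicates:   ", ncol(x$design$rep_weights),
      sprintf(" (Fay %.2f)\n", x$design$fay))
  invisible(x)
}

#' Write a cohort to a directory of delimited text files
#'
#' Serializes the cohort as plain CSV (`persons.csv`, `person_days.csv`,
#' `food_records.csv`, `weights.csv`, `rep_weights.csv`) plus a small
#' `design.json` holding the Fay coefficient. Numeric values are written at
#' full round-trip precision, so [read_cohort()] reproduces every field
#' exactly.
#'
#' @param cohort A cohort as returned by [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nutshift_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$persons, file.path(dir, "persons.csv"))
  readr::write_csv(cohort$person_days, file.path(dir, "person_days.csv"))
  readr::write_csv(cohort$food_records, file.path(dir, "food_records.csv"))
  readr::write_csv(cohort$design$weights, file.path(dir, "weights.csv"))
  rw <- as_tibble(as.data.frame(cohort$design$rep_weights),
                  .name_repair = "minimal")
  names(rw) <- paste0("rep_", seq_len(ncol(rw)))
  rw$person_id <- cohort$design$weights$person_id
  readr::write_csv(rw, file.path(dir, "rep_weights.csv"))
  jsonlite::write_json(list(fay = cohort$design$fay),
                       file.path(dir, "design.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Enforces referential integrity (every person-day and food record must
#' belong to a listed person) and the recall-day domain (`day` in 1, 2).
#'
#' @param dir Directory containing the cohort CSV files.
#' @return A cohort object (list of tibbles plus survey design).
#' @export
read_cohort <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE, progress = FALSE)
  persons <- read1("persons.csv")
  person_days <- read1("person_days.csv")
  food_records <- read1("food_records.csv")
  weights <- read1("weights.csv")
  rw <- read1("rep_weights.csv")
  for (tab in list(pd = person_days, fr = food_records)) {
    bad <- setdiff(unique(tab$person_id), persons$person_id)
    if (length(bad) > 0) {
      stop("linkage error: person_id not in persons table: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (!all(tab$day %in% c(1L, 2L))) {
      stop("parse error: day must be 1 or 2", call. = FALSE)
    }
  }
  fay <- jsonlite::read_json(file.path(dir, "design.json"))$fay
  rep_weights <- as.matrix(rw[, setdiff(names(rw), "person_id")])
  dimnames(rep_weights) <- NULL
  design <- new_survey_design(weights, rep_weights, fay)
  new_cohort(persons, person_days, food_records, design)
}
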