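# Food-cost model: price assignment with category-median imputation, CPI
# inflation adjustment by food category, day-1 daily cost, replacement cost
# under the cap-at-reported-meat rule, and survey-weighted group summaries.

#' Inflate a price table from a base year to a target year
#'
#' Each food's price is scaled by its category's CPI ratio
#' `index(target) / index(base)`, so categories inflate independently.
#'
#' @param prices Tibble: `food_code`, `category`, `price_per_100g`,
#'   `imputed`.
#' @param cpi Tibble: `category`, `year`, `index` (> 0).
#' @param base_year,target_year Years present in `cpi` for every category.
#' @return `prices` with `price_per_100g` inflation-adjusted.
#' @export
#' @examples
#' inflation_adjust(
#'   tibble::tibble(food_code = "A", category = "Fruits",
#'                  price_per_100g = 2, imputed = FALSE),
#'   tibble::tibble(category = "Fruits", year = c(2003, 2016),
#'                  index = c(200, 250)),
#'   2003, 2016)
inflation_adjust <- function(prices, cpi, base_year, target_year) {
  if (base_year == target_year) {
    missing <- setdiff(unique(prices$category),
                       cpi$category[cpi$year == base_year])
    if (length(missing) > 0) {
      stop("CPI lookup failed for category-year: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(prices)
  }
  ratio <- cpi %>%
    filter(.data$year %in% c(base_year, target_year)) %>%
    tidyr::pivot_wider(names_from = "year", values_from = "index",
                       names_prefix = "y") %>%
    rename(base = paste0("y", base_year), target = paste0("y", target_year))
  missing <- setdiff(unique(prices$category), ratio$category)
  if (length(missing) > 0 || anyNA(ratio$base) || anyNA(ratio$target)) {
    stop("CPI lookup failed for category-year: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prices %>%
    left_join(ratio %>% select("category", "base", "target"),
              by = "category") %>%
    mutate(price_per_100g = .data$price_per_100g * .data$target / .data$base) %>%
    select(-"base", -"target")
}

#' Impute prices for unpriced food codes from their category median
#'
#' @param food_codes Tibble: `food_code`, `category` for every code that
#'   needs a price.
#' @param prices Price table covering at least some codes per category.
#' @return A price table covering all requested codes; borrowed prices are
#'   flagged `imputed = TRUE`.
#' @export
impute_prices <- function(food_codes, prices) {
  need <- food_codes %>% distinct(.data$food_code, .data$category) %>%
    anti_join(prices, by = "food_code")
  if (nrow(need) == 0) return(prices)
  med <- prices %>% group_by(.data$category) %>%
    summarise(med = stats::median(.data$price_per_100g), .groups = "drop")
  filled <- need %>% inner_join(med, by = "category") %>%
    mutate(price_per_100g = .data$med, imputed = TRUE) %>%
    select("food_code", "category", "price_per_100g", "imputed")
  bind_rows(prices, filled)
}

#' Daily food cost from day-1 food records
#'
#' `sum(grams / 100 * price_per_100g)` over each person's day-1 records.
#' Every food code must be priced (imputed prices allowed); unpriced codes
#' are an error listing the offenders.
#'
#' @param food_records Food-record tibble.
#' @param prices Price table (already inflation-adjusted).
#' @return Tibble: `person_id`, `daily_cost`.
#' @export
daily_cost <- function(food_records, prices) {
  day1 <- food_records %>% filter(.data$day == 1L)
  unpriced <- setdiff(unique(day1$food_code), prices$food_code)
  if (length(unpriced) > 0) {
    stop("unpriced food code(s): ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  }
  costs <- day1 %>%
    left_join(prices %>% select("food_code", "price_per_100g"),
              by = "food_code") %>%
    group_by(.data$person_id) %>%
    summarise(daily_cost = sum(.data$grams / 100 * .data$price_per_100g),
              .groups = "drop")
  # persons with records but nothing on day 1 spent nothing that day
  tibble(person_id = unique(food_records$person_id)) %>%
    left_join(costs, by = "person_id") %>%
    mutate(daily_cost = dplyr::coalesce(.data$daily_cost, 0))
}

#' Daily cost change under a walnut-for-meat replacement dose
#'
#' Removes `r = min(dose, reported day-1 meat oz eq)` of meat at the meat
#' price per ounce and adds `0.5 * r` ounces of walnuts at the walnut price
#' per ounce (walnuts are priced per ounce of food, not per oz eq). A
#' zero-meat day keeps its expenses unchanged.
#'
#' @param person_days Person-day tibble (day 1 used for meat amounts).
#' @param base_cost Tibble from [daily_cost()].
#' @param dose Meat-replacement dose in oz eq.
#' @param meat_price_per_oz,walnut_price_per_oz Per-ounce prices.
#' @return Tibble: `person_id`, `daily_cost` (original), `meat_removed_oz`,
#'   `cost_delta`, `new_cost`.
#' @export
#' @examples
#' # removing 1 oz meat at 0.38/oz, adding 0.5 oz walnuts at 0.26/oz: -0.25
replacement_cost <- function(person_days, base_cost, dose,
                             meat_price_per_oz = 0.38,
                             walnut_price_per_oz = 0.26) {
  stopifnot(dose >= 0)
  day1 <- person_days %>% filter(.data$day == 1L)
  r <- pmin(dose, meat_oz_equivalents(day1))
  tibble(person_id = day1$person_id, meat_removed_oz = r) %>%
    inner_join(base_cost, by = "person_id") %>%
    mutate(cost_delta = -.data$meat_removed_oz * meat_price_per_oz +
             0.5 * .data$meat_removed_oz * walnut_price_per_oz,
           new_cost = .data$daily_cost + .data$cost_delta) %>%
    select("person_id", "daily_cost", "meat_removed_oz", "cost_delta",
           "new_cost")
}

#' Survey-weighted daily food cost by group and dose
#'
#' Weighted mean daily expenses for the current diet and each replacement
#' dose, by reporting group, with BRR confidence intervals, percent change
#' versus the current diet, and the non-overlapping-CI significance flag.
#'
#' @param persons Persons tibble.
#' @param person_days Person-day tibble.
#' @param food_records Food-record tibble.
#' @param prices Inflation-adjusted price table.
#' @param design Survey design.
#' @param doses Dose levels, default 1-4.
#' @param groups Reporting groups, default the cost-reporting age bands by
#'   gender.
#' @param meat_price_per_oz,walnut_price_per_oz Per-ounce prices.
#' @return Tibble: `group`, `dose`, `estimate`, `lower`, `upper`,
#'   `pct_change`, `significant`.
#' @export
group_cost_summary <- function(persons, person_days, food_records, prices,
                               design, doses = 1:4,
                               groups = c("Child 4-18", "Adult 19-50",
                                          "Adult 51-70", "Adult 71+",
                                          "Male 19-71+", "Female 19-71+"),
                               meat_price_per_oz = 0.38,
                               walnut_price_per_oz = 0.26) {
  if (!"group" %in% names(persons)) persons <- assign_groups(persons)
  base <- daily_cost(food_records, prices)
  costs <- bind_rows(
    base %>% mutate(dose = 0, cost = .data$daily_cost),
    purrr::map_dfr(doses, function(d) {
      replacement_cost(person_days, base, d, meat_price_per_oz,
                       walnut_price_per_oz) %>%
        mutate(dose = d, cost = .data$new_cost) %>%
        select("person_id", "dose", "cost")
    }))
  purrr::map_dfr(groups, function(gl) {
    ids <- intersect(group_members(persons, gl)$person_id, base$person_id)
    if (length(ids) == 0) {
      warning("empty cost group: ", gl)
      return(NULL)
    }
    dg <- subset_design(design, ids)
    rows <- purrr::map_dfr(c(0, doses), function(d) {
      cc <- costs %>% filter(.data$dose == d, .data$person_id %in% ids)
      cc <- cc[match(dg$weights$person_id, cc$person_id), ]
      est <- brr_interval(dg, function(w) weighted_mean(cc$cost, w))
      tibble(group = gl, dose = d, estimate = est$estimate,
             lower = est$lower, upper = est$upper)
    })
    cur <- rows %>% filter(.data$dose == 0)
    rows %>% mutate(
      pct_change = 100 * (.data$estimate - cur$estimate) / cur$estimate,
      significant = ifelse(.data$dose == 0, NA,
                           nonoverlap_significant(cur$lower, cur$upper,
                                                  .data$lower, .data$upper)))
  })
}
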