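toy_prices <- function() {
  tibble::tibble(food_code = c("A", "B", "C"),
                 category = c("Fruits", "Fruits", "Grains"),
                 price_per_100g = c(2.00, 4.00, 1.00),
                 imputed = FALSE)
}

toy_cpi <- function() {
  tidyr::crossing(category = c("Fruits", "Grains"),
                  year = c(2003, 2016)) |>
    dplyr::mutate(index = dplyr::case_when(
      category == "Fruits" & year == 2003 ~ 200,
      category == "Fruits" & year == 2016 ~ 250,
      category == "Grains" & year == 2003 ~ 100,
      category == "Grains" & year == 2016 ~ 110))
}

test_that("inflation adjustment scales per category", {
  adj <- inflation_adjust(toy_prices(), toy_cpi(), 2003, 2016)
  expect_equal(adj$price_per_100g[adj$food_code == "A"], 2.50)
  expect_equal(adj$price_per_100g[adj$food_code == "B"], 5.00)
  expect_equal(adj$price_per_100g[adj$food_code == "C"], 1.10)
  # identical years leave prices untouched
  same <- inflation_adjust(toy_prices(), toy_cpi(), 2003, 2003)
  expect_equal(same$price_per_100g, toy_prices()$price_per_100g)
  # a category missing from the CPI is an error
  expect_error(
    inflation_adjust(dplyr::mutate(toy_prices(), category = "Unknown"),
                     toy_cpi(), 2003, 2016),
    "CPI")
})

test_that("daily cost multiplies grams by adjusted prices", {
  fr <- tibble::tibble(
    person_id = c("p1", "p1", "p2", "p3"),
    day = c(1L, 1L, 1L, 2L),
    food_code = c("A", "C", "A", "A"),
    grams = c(150, 200, 50, 500),
    wweia_category = "x")
  cost <- daily_cost(fr, toy_prices())
  expect_equal(cost$daily_cost[cost$person_id == "p1"],
               150 / 100 * 2 + 200 / 100 * 1)   # 5.00
  expect_equal(cost$daily_cost[cost$person_id == "p2"], 1.00)
  # additivity over records
  expect_equal(cost$daily_cost[cost$person_id == "p1"],
               daily_cost(fr[1, ], toy_prices())$daily_cost +
                 daily_cost(fr[2, ], toy_prices())$daily_cost)
  # a person with no day-1 records spends nothing that day
  expect_equal(cost$daily_cost[cost$person_id == "p3"], 0)
  fr_bad <- dplyr::mutate(fr, food_code = c("A", "ZZZ", "A", "A"))
  expect_error(daily_cost(fr_bad, toy_prices()), "ZZZ")
})

test_that("price imputation borrows the category median and flags it", {
  codes <- tibble::tibble(food_code = c("A", "B", "C", "D"),
                          category = c("Fruits", "Fruits", "Grains",
                                       "Fruits"))
  full <- impute_prices(codes, toy_prices())
  d <- full[full$food_code == "D", ]
  expect_equal(d$price_per_100g, 3.00)   # median of 2 and 4
  expect_true(d$imputed)
  expect_false(any(full$imputed[full$food_code != "D"]))
})

test_that("replacement cost follows the per-ounce price arithmetic", {
  day <- high_meat_day()   # 5 oz eq meat on day 1
  base <- tibble::tibble(person_id = "X1", daily_cost = 10)
  r1 <- replacement_cost(day, base, 1)
  expect_equal(r1$cost_delta, -0.38 + 0.5 * 0.26)   # -0.25
  expect_equal(r1$new_cost, 10 - 0.25)
  # capped at reported meat
  r9 <- replacement_cost(day, base, 9)
  expect_equal(r9$meat_removed_oz, 5)
  # zero-meat day held constant
  none <- dplyr::mutate(day, meat_oz = 0, cured_meat_oz = 0,
                        organ_meat_oz = 0)
  expect_equal(replacement_cost(none, base, 4)$cost_delta, 0)
})

test_that("cost delta is monotone non-increasing when walnuts are cheaper", {
  set.seed(31)
  day <- high_meat_day()
  base <- tibble::tibble(person_id = "X1", daily_cost = 12)
  for (i in 1:20) {
    pm <- runif(1, 0.1, 1)
    pw <- runif(1, 0.05, 2 * pm * 0.99)   # pw / 2 < pm
    deltas <- vapply(1:4, function(d) {
      replacement_cost(day, base, d, pm, pw)$cost_delta
    }, numeric(1))
    expect_true(all(diff(deltas) <= 1e-12))
  }
})

test_that("group cost summary matches hand arithmetic on a uniform cohort", {
  fx <- fixture_cohort()
  ids <- fx$included$person_id
  fr <- dplyr::filter(fx$cohort$food_records, person_id %in% ids)
  # flat price of 1.00 per 100 g for every code
  prices <- tibble::tibble(food_code = unique(fr$food_code),
                           category = "all", price_per_100g = 1,
                           imputed = FALSE)
  tab <- group_cost_summary(fx$included, fx$pd, fr, prices, fx$design,
                            doses = 1:2, groups = "Adult 19-71+")
  day1 <- dplyr::filter(fr, day == 1) |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(cost = sum(grams) / 100, .groups = "drop")
  adults <- fx$included$person_id[fx$included$age_years >= 19]
  sub <- day1[day1$person_id %in% adults, ]
  w <- fx$design$weights$weight[match(sub$person_id,
                                      fx$design$weights$person_id)]
  expect_equal(tab$estimate[tab$dose == 0], weighted_mean(sub$cost, w))
  expect_equal(tab$pct_change[tab$dose == 0], 0)
  # interval geometry and the significance flag are consistent
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  cur <- tab[tab$dose == 0, ]
  expect_equal(tab$significant[tab$dose == 2],
               nonoverlap_significant(cur$lower, cur$upper,
                                      tab$lower[tab$dose == 2],
                                      tab$upper[tab$dose == 2]))
  # zero prices give zero means
  zero <- dplyr::mutate(prices, price_per_100g = 0)
  tz <- group_cost_summary(fx$included, fx$pd, fr, zero, fx$design,
                           doses = integer(0), groups = "Adult 19-71+")
  expect_equal(tz$estimate, 0)
})

test_that("cost delta ignores non-meat records entirely", {
  day <- high_meat_day()
  base <- tibble::tibble(person_id = "X1", daily_cost = 10)
  more_veg <- dplyr::mutate(day, total_veg_cup = 99)
  expect_equal(replacement_cost(day, base, 3)$cost_delta,
               replacement_cost(more_veg, base, 3)$cost_delta)
})
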