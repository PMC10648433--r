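make_pd_row <- function(id, day = 1L, energy = 2000, nuts = 0) {
  pd <- nutrient_vector(energy = energy)
  pd$person_id <- id
  pd$day <- day
  pd$weekday <- TRUE
  for (f in food_group_fields()) pd[[f]] <- 0
  pd$nuts_seeds_oz <- nuts
  pd
}

make_person <- function(id, age = 30, gender = "male", preg = FALSE,
                        unreliable = FALSE, missing = FALSE, bm = FALSE) {
  tibble::tibble(person_id = id, age_years = age, gender = gender,
                 race = "nh_white", income_band = "i20_75k",
                 education_band = "hs", breast_milk = bm,
                 pregnant_or_lactating = preg,
                 unreliable_recall = unreliable,
                 missing_animal_protein = missing)
}

make_fr_row <- function(id, walnut = FALSE) {
  tibble::tibble(person_id = id, day = 1L, food_code = "F001",
                 walnut_flag = walnut, grams = 100,
                 wweia_category = "Other")
}

test_that("nut status follows walnut codes first, then nuts-and-seeds", {
  fr <- dplyr::bind_rows(make_fr_row("A", walnut = TRUE),
                         make_fr_row("B"), make_fr_row("C"))
  pdays <- dplyr::bind_rows(
    make_pd_row("A"), make_pd_row("B"),
    make_pd_row("B", day = 2L, nuts = 0.3), make_pd_row("C"))
  st <- classify_nut_status(fr, pdays)
  expect_equal(st$nut_status[st$person_id == "A"], "walnut")
  expect_equal(st$nut_status[st$person_id == "B"], "other_nut")
  expect_equal(st$nut_status[st$person_id == "C"], "no_nut")
})

test_that("exclusions fire in order with first-match reasons", {
  persons <- dplyr::bind_rows(
    make_person("low", age = 30),
    make_person("edge500", age = 30),
    make_person("edge5000", age = 30),
    make_person("high", age = 30),
    make_person("nutty", age = 30),
    make_person("multi", age = 30, unreliable = TRUE),   # also a nut eater
    make_person("preg", age = 25, gender = "female", preg = TRUE),
    make_person("pregold", age = 50, gender = "female", preg = TRUE),
    make_person("baby", age = 2),
    make_person("nodata", age = 30, missing = TRUE),
    make_person("ok", age = 30))
  pdays <- dplyr::bind_rows(
    make_pd_row("low", energy = 400),
    make_pd_row("edge500", energy = 500),
    make_pd_row("edge5000", energy = 5000),
    make_pd_row("high", energy = 5001),
    make_pd_row("nutty", nuts = 0.4),
    make_pd_row("multi", nuts = 0.4),
    make_pd_row("preg"), make_pd_row("pregold"), make_pd_row("baby"),
    make_pd_row("nodata"), make_pd_row("ok"))
  fr <- dplyr::bind_rows(lapply(persons$person_id, make_fr_row))
  ex <- apply_exclusions(persons, pdays, fr)
  reason <- function(id) ex$excluded$reason[ex$excluded$person_id == id]
  expect_equal(reason("low"), "implausible_energy")
  expect_equal(reason("high"), "implausible_energy")
  expect_equal(reason("nutty"), "nut_consumer")
  expect_equal(reason("multi"), "unreliable_recall")  # earlier rule wins
  expect_equal(reason("preg"), "pregnant_lactating")
  expect_equal(reason("baby"), "too_young_or_breastfed")
  expect_equal(reason("nodata"), "missing_protein_data")
  # 500 and 5000 kcal are retained; pregnancy rule stops at 44
  expect_setequal(ex$included$person_id,
                  c("edge500", "edge5000", "pregold", "ok"))
  # partition: included + excluded covers the input exactly once
  expect_setequal(c(ex$included$person_id, ex$excluded$person_id),
                  persons$person_id)
  expect_equal(nrow(ex$included) + nrow(ex$excluded), nrow(persons))
})

test_that("apply_exclusions demands the flag columns", {
  p <- make_person("a")
  p$unreliable_recall <- NULL
  expect_error(apply_exclusions(p, make_pd_row("a"), make_fr_row("a")),
               "unreliable_recall")
})

test_that("age-gender groups partition the included sample", {
  expect_equal(assign_groups(make_person("x", 18, "female"))$group,
               "Female 14-18")
  expect_equal(assign_groups(make_person("x", 19, "male"))$group,
               "Male 19-50")
  expect_equal(assign_groups(make_person("x", 85, "female"))$group,
               "Adult 71+")
  expect_error(assign_groups(make_person("x", 2)), "outside")

  fx <- fixture_cohort()
  counts <- table(fx$included$group)
  expect_equal(sum(counts), nrow(fx$included))
  expect_true(all(fx$included$group %in% age_gender_groups()$group))
})

test_that("protein food summary matches hand-computed weighted means", {
  # two adults, weights 1 and 3; all protein as plain meat and eggs
  pdays <- dplyr::bind_rows(make_pd_row("a"), make_pd_row("b"))
  pdays$meat_oz <- c(2, 4)
  pdays$eggs_oz <- c(1, 0)
  pdays$total_protein_oz <- c(3, 4)
  persons <- dplyr::bind_rows(make_person("a", 30), make_person("b", 40))
  des <- toy_design(c("a", "b"), weights = c(1, 3))
  tab <- protein_food_summary(persons, pdays, des,
                              groups = "Male 19-71+")
  total <- tab$mean_oz[tab$source == "total"]
  meats <- tab$mean_oz[tab$source == "meats"]
  expect_equal(total, (1 * 3 + 3 * 4) / 4)     # 3.75
  expect_equal(meats, (1 * 2 + 3 * 4) / 4)     # 3.5
  expect_equal(tab$share_pct[tab$source == "meats"], 100 * 3.5 / 3.75)
  expect_equal(tab$share_pct[tab$source == "eggs"], 100 * 0.25 / 3.75)

  # single person with all protein from eggs
  solo_pd <- make_pd_row("solo")
  solo_pd$eggs_oz <- 1.5
  solo_pd$total_protein_oz <- 1.5
  solo <- protein_food_summary(make_person("solo", 30), solo_pd,
                               toy_design("solo"), groups = "Male 19-71+")
  expect_equal(solo$share_pct[solo$source == "eggs"], 100)
})

test_that("source shares sum to 100 on generated cohorts", {
  fx <- fixture_cohort()
  tab <- protein_food_summary(fx$included, fx$pd, fx$design)
  sums <- tab |>
    dplyr::filter(source != "total") |>
    dplyr::group_by(group) |>
    dplyr::summarise(s = sum(share_pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 0.3))
})
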