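amounts_row <- function(energy = 2000, total_fruit = 0, whole_fruit = 0,
                        total_veg = 0, greens_beans = 0, whole_grains = 0,
                        refined_grains = 0, dairy = 0, total_protein = 0,
                        seafood_plant_protein = 0, mufa = 0, pufa = 0,
                        sfa = 1, sodium_g = 0, added_sugars = 0) {
  tibble::tibble(energy = energy, total_fruit = total_fruit,
                 whole_fruit = whole_fruit, total_veg = total_veg,
                 greens_beans = greens_beans, whole_grains = whole_grains,
                 refined_grains = refined_grains, dairy = dairy,
                 total_protein = total_protein,
                 seafood_plant_protein = seafood_plant_protein,
                 mufa = mufa, pufa = pufa, sfa = sfa, sodium_g = sodium_g,
                 added_sugars = added_sugars)
}

test_that("boundary densities score exactly at the standards", {
  # fatty-acid ratio at the zero and full standards
  a <- amounts_row(mufa = 0.6, pufa = 0.6, sfa = 1)        # ratio 1.2
  expect_equal(score_hei(a)$fatty_acid_ratio, 0)
  b <- amounts_row(mufa = 1.5, pufa = 1.0, sfa = 1)        # ratio 2.5
  expect_equal(score_hei(b)$fatty_acid_ratio, 10)
  # whole grains halfway to the 1.5 oz/1000 kcal standard
  c <- amounts_row(whole_grains = 1.5)                     # 0.75 / 1000
  expect_equal(score_hei(c)$whole_grains, 5)
  # zero SFA yields an infinite ratio and full points
  d <- amounts_row(sfa = 0, mufa = 1)
  expect_equal(score_hei(d)$fatty_acid_ratio, 10)
  expect_error(score_hei(amounts_row(energy = 0)), "energy")
})

test_that("a diet at every standard scores the full 100 points", {
  best <- amounts_row(
    energy = 2000,
    total_fruit = 2 * 0.8, whole_fruit = 2 * 0.4, total_veg = 2 * 1.1,
    greens_beans = 2 * 0.2, whole_grains = 2 * 1.5, dairy = 2 * 1.3,
    total_protein = 2 * 2.5, seafood_plant_protein = 2 * 0.8,
    mufa = 50, pufa = 50, sfa = 2000 * 0.05 / 9,   # ratio >= 2.5, SFA 5%E
    refined_grains = 2 * 1.0, sodium_g = 2 * 1.0,
    added_sugars = 2000 * 0.05 / 16)               # 5% of energy
  s <- score_hei(best)
  expect_equal(s$hei_total, 100)
  expect_equal(sum(hei_standards()$max_points), 100)
})

test_that("scores match a brute-force interpolation oracle", {
  set.seed(77)
  std <- hei_standards()
  for (i in 1:200) {
    a <- amounts_row(
      energy = runif(1, 1200, 3200),
      total_fruit = runif(1, 0, 4), whole_fruit = runif(1, 0, 2),
      total_veg = runif(1, 0, 5), greens_beans = runif(1, 0, 1.5),
      whole_grains = runif(1, 0, 6), refined_grains = runif(1, 0, 12),
      dairy = runif(1, 0, 5), total_protein = runif(1, 0, 12),
      seafood_plant_protein = runif(1, 0, 4),
      mufa = runif(1, 5, 60), pufa = runif(1, 5, 60),
      sfa = runif(1, 5, 60), sodium_g = runif(1, 0.5, 8),
      added_sugars = runif(1, 0, 40))
    got <- score_hei(a)
    dens <- list(
      total_fruit = 1000 * a$total_fruit / a$energy,
      whole_fruit = 1000 * a$whole_fruit / a$energy,
      total_veg = 1000 * a$total_veg / a$energy,
      greens_beans = 1000 * a$greens_beans / a$energy,
      whole_grains = 1000 * a$whole_grains / a$energy,
      dairy = 1000 * a$dairy / a$energy,
      total_protein = 1000 * a$total_protein / a$energy,
      seafood_plant_protein = 1000 * a$seafood_plant_protein / a$energy,
      fatty_acid_ratio = (a$mufa + a$pufa) / a$sfa,
      refined_grains = 1000 * a$refined_grains / a$energy,
      sodium = 1000 * a$sodium_g / a$energy,
      added_sugars = 100 * a$added_sugars * 16 / a$energy,
      sat_fat = 100 * a$sfa * 9 / a$energy)
    for (comp in std$component) {
      row <- std[std$component == comp, ]
      xs <- sort(c(row$zero_std, row$full_std))
      ys <- if (row$zero_std < row$full_std) c(0, row$max_points) else
        c(row$max_points, 0)
      oracle <- stats::approx(xs, ys, xout = dens[[comp]], rule = 2)$y
      expect_equal(got[[comp]], oracle, tolerance = 1e-12)
    }
    expect_equal(got$hei_total, sum(unlist(got[1, std$component])))
  }
})

test_that("adequacy scores rise and moderation scores fall with density", {
  lo <- amounts_row(total_veg = 1, sodium_g = 2)
  hi <- amounts_row(total_veg = 2, sodium_g = 4)
  expect_gte(score_hei(hi)$total_veg, score_hei(lo)$total_veg)
  expect_lte(score_hei(hi)$sodium, score_hei(lo)$sodium)
})

test_that("substitution adjustment applies the published values", {
  a <- amounts_row(energy = 2000, mufa = 20, pufa = 15, sfa = 25,
                   sodium_g = 3.4, total_protein = 6,
                   seafood_plant_protein = 1)
  adj <- adjust_hei_amounts(a, r = 4)
  expect_equal(adj$energy - a$energy, 2 * 185 - 4 * 49)      # +174
  expect_equal(adj$pufa - a$pufa, 2 * 13.4 - 4 * 0.12)       # +26.32
  expect_equal(adj$mufa - a$mufa, 2 * 2.53 - 4 * 0.87)
  expect_equal(adj$sfa - a$sfa, 2 * 1.74 - 4 * 0.76)
  # walnut sodium is printed in mg while meat sodium removes 127 mg per oz
  expect_equal(adj$sodium_g - a$sodium_g,
               (2 * 0.567 - 4 * 127) / 1000)
  expect_lt(adjust_hei_amounts(a, r = 1)$sodium_g, a$sodium_g)
  # the printed "1 oz eq seafood and plant proteins" subtraction for meat
  # exactly cancels the walnut addition (w * 2 = r)
  expect_equal(adj$seafood_plant_protein, a$seafood_plant_protein)
  off <- adjust_hei_amounts(a, r = 4, literal_seafood_plant = FALSE)
  expect_equal(off$seafood_plant_protein, a$seafood_plant_protein + 4)
  expect_equal(adjust_hei_amounts(a, r = 0), a)
})

test_that("population-ratio scoring is a ratio of means, not mean of ratios", {
  fx <- fixture_cohort()
  # single-person population equals that person's own score
  one <- fx$included$person_id[1]
  pd1 <- dplyr::filter(fx$pd, person_id == one, day == 1)
  h1 <- hei_population_ratio(pd1, toy_design(one))
  own <- score_hei(dplyr::select(hei_constituents(pd1), -person_id, -day))
  expect_equal(h1$total$estimate, own$hei_total)

  # two equal-weight persons: score of the mean amounts, by hand
  ids <- fx$included$person_id[1:2]
  pd2 <- dplyr::filter(fx$pd, person_id %in% ids, day == 1)
  h2 <- hei_population_ratio(pd2, toy_design(ids))
  amt <- hei_constituents(pd2) |>
    dplyr::summarise(dplyr::across(-c(person_id, day), mean))
  expect_equal(h2$total$estimate, score_hei(amt)$hei_total)

  # Jensen gap: population-ratio differs from the mean of per-person scores
  pdall <- dplyr::filter(fx$pd, day == 1)
  hall <- hei_population_ratio(pdall, fx$design)
  per_person <- score_hei(hei_constituents(pdall))$hei_total
  expect_gt(abs(hall$total$estimate -
                  weighted_mean(per_person, fx$design$weights$weight)), 0.1)
})

test_that("HEI rises monotonically with dose on a high-meat cohort", {
  fx <- fixture_cohort()
  rich_ids <- fx$pd |>
    dplyr::filter(day == 1) |>
    dplyr::filter(meat_oz_equivalents(dplyr::pick(dplyr::everything())) >= 2) |>
    dplyr::pull(person_id)
  pdr <- dplyr::filter(fx$pd, person_id %in% rich_ids)
  des <- subset_design(fx$design, rich_ids)
  totals <- vapply(0:4, function(d) {
    hei_population_ratio(pdr, des, dose = d)$total$estimate
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})
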