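# Direct two-level lognormal draws used by several oracles below.
simulate_lognormal_panel <- function(n, mu = 5, sigma_u = 0.3,
                                     sigma_e = 0.5, seed = 1,
                                     p_day2 = 1) {
  set.seed(seed)
  u <- rnorm(n, 0, sigma_u)
  pd <- dplyr::bind_rows(
    tibble::tibble(person_id = sprintf("p%04d", 1:n), day = 1L),
    tibble::tibble(person_id = sprintf("p%04d", which(runif(n) < p_day2)),
                   day = 2L))
  idx <- as.integer(sub("p", "", pd$person_id))
  pd$weekday <- TRUE
  pd$energy <- 2000
  pd$y <- exp(mu + u[idx] + rnorm(nrow(pd), 0, sigma_e))
  pd
}

panel_persons <- function(pd) {
  tibble::tibble(person_id = unique(pd$person_id), age_years = 30,
                 gender = "male", race = "nh_white")
}

test_that("lambda = 1 fit matches ordinary least squares on balanced data", {
  pd <- simulate_lognormal_panel(80, seed = 4)
  pd$y <- 100 + 5 * (pd$day == 2) + log(pd$y)   # linear-scale outcome
  m <- fit_amount_model(pd, "y", panel_persons(pd),
                        lambda_grid = 1, energy_covariate = FALSE)
  # balanced two-day data: GLS for the sequence contrast reduces to OLS
  # (the lambda = 1 transform shifts the intercept by exactly 1)
  ols <- stats::lm(y ~ I(day == 2), data = pd)
  expect_equal(unname(m$beta[1]) + 1, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(m$beta[2]), unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(m$lambda, 1)
})

test_that("the profile likelihood selects the generating exponent", {
  pd <- simulate_lognormal_panel(1000, seed = 8)
  m <- fit_amount_model(pd, "y", panel_persons(pd),
                        energy_covariate = FALSE)
  expect_lte(m$lambda, 0.05)
  # components are reported on the selected transformed scale; compare on
  # the scale-free (squared CV) normalization
  nv <- normalized_variance_components(m)
  expect_lt(abs(nv[["cv2_between"]] - 0.09) / 0.09, 0.2)
  expect_lt(abs(nv[["cv2_within"]] - 0.25) / 0.25, 0.2)
  expect_true(m$converged)
  g <- glance(m)
  expect_true(g$icc > 0 && g$icc < 1)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
})

test_that("a zero between-person variance is recovered as (near) zero", {
  pd <- simulate_lognormal_panel(400, sigma_u = 0, sigma_e = 0.4, seed = 5)
  m <- fit_amount_model(pd, "y", panel_persons(pd),
                        lambda_grid = 0, energy_covariate = FALSE)
  expect_lt(m$sigma_u2, 0.01 * m$sigma_e2)
})

test_that("single-day data and non-positive amounts are rejected", {
  pd <- simulate_lognormal_panel(50, seed = 6) |> dplyr::filter(day == 1)
  expect_error(fit_amount_model(pd, "y", panel_persons(pd)),
               "two recall days")
  pd2 <- simulate_lognormal_panel(50, seed = 6)
  pd2$y[1] <- 0
  expect_error(fit_amount_model(pd2, "y", panel_persons(pd2)),
               "positive")
})

test_that("usual-intake mean matches the lognormal closed form", {
  pd <- simulate_lognormal_panel(800, mu = 5, sigma_u = 0.3, sigma_e = 0.5,
                                 seed = 10)
  m <- fit_amount_model(pd, "y", panel_persons(pd), lambda_grid = 0,
                        energy_covariate = FALSE)
  des <- toy_design(unique(pd$person_id))
  ui <- estimate_usual_intake(m, des, n_pseudo = 100, seed = 2)
  # at the fitted parameters the estimator must reproduce the lognormal
  # closed form exp(xb + sigma_u^2/2 + sigma_e^2/2) up to Monte-Carlo error
  # in the random-intercept draws
  xb1 <- m$beta[["(Intercept)"]]
  fitted_form <- exp(xb1 + m$sigma_u2 / 2 + m$sigma_e2 / 2)
  expect_lt(abs(ui$mean$estimate - fitted_form) / fitted_form, 0.01)
  # and the generating parameters within sampling error
  closed_form <- exp(5 + 0.3^2 / 2 + 0.5^2 / 2)
  expect_lt(abs(ui$mean$estimate - closed_form) / closed_form, 0.05)
  # degenerate model: zero variances collapse onto the linear predictor
  m0 <- m
  m0$sigma_u2 <- 0
  m0$sigma_e2 <- 0
  ui0 <- estimate_usual_intake(m0, des, n_pseudo = 5, seed = 2)
  expect_lt(stats::sd(ui0$t), 1e-9)
  expect_equal(ui0$percentiles$value[1], ui0$percentiles$value[99])
})

test_that("usual intake shrinks toward the center relative to single days", {
  fx <- fixture_cohort()
  m <- fit_amount_model(fx$pd, "magnesium", fx$included)
  ui <- estimate_usual_intake(m, fx$design, n_pseudo = 50, seed = 3)
  day1 <- dplyr::filter(fx$pd, day == 1)
  expect_lt(stats::var(as.numeric(ui$t)), stats::var(day1$magnesium))
  # percentile curve is non-decreasing and brackets the mean
  expect_true(all(diff(ui$percentiles$value) >= 0))
  expect_gt(ui$mean$estimate, ui$percentiles$value[1])
  expect_lt(ui$mean$estimate, ui$percentiles$value[99])
  expect_true(ui$mean$lower <= ui$mean$estimate &
                ui$mean$estimate <= ui$mean$upper)

  # an unconverged fit refuses to simulate
  m_bad <- m
  m_bad$converged <- FALSE
  expect_error(estimate_usual_intake(m_bad, fx$design), "unconverged")
})

test_that("threshold fractions behave like tail probabilities", {
  fx <- fixture_cohort()
  m <- fit_amount_model(fx$pd, "magnesium", fx$included)
  ui <- estimate_usual_intake(m, fx$design, n_pseudo = 50, seed = 3)
  below <- threshold_fraction(ui, 300, "below")
  above <- threshold_fraction(ui, 300, "above")
  expect_equal(below$estimate + above$estimate, 1, tolerance = 1e-12)
  expect_lt(threshold_fraction(ui, ui$percentiles$value[1] * 0.5,
                               "below")$estimate, 0.02)
  expect_error(threshold_fraction(ui, 300, person_ids = "nobody"),
               "no persons")

  adequacy <- adequacy_table(ui, fx$included)
  expect_true(all(adequacy$estimate >= 0 & adequacy$estimate <= 1))
  expect_true(all(adequacy$kind == "ear"))
  expect_gt(nrow(adequacy), 3)
})

test_that("fraction below the known generator median is one half", {
  cfg <- sim_config(n_persons = 1200, seed = 31, nutrients = "magnesium",
                    meat_coupling = FALSE)
  ch <- simulate_cohort(cfg)
  ex <- apply_exclusions(ch$persons, ch$person_days, ch$food_records)
  pd <- dplyr::filter(ch$person_days, person_id %in% ex$included$person_id)
  m <- fit_amount_model(pd, "magnesium", ex$included)
  ui <- estimate_usual_intake(m, subset_design(ch$design,
                                               ex$included$person_id),
                              n_pseudo = 50, seed = 4)
  pop <- ch$truth$population
  med_true <- pop$percentile[[which(pop$nutrient == "magnesium")]]$value[50]
  fr <- threshold_fraction(ui, med_true, "below")
  expect_lt(abs(fr$estimate - 0.5), 0.05)
})

test_that("percentile curves agree across independent pseudo-draw seeds", {
  fx <- fixture_cohort()
  m <- fit_amount_model(fx$pd, "fiber", fx$included)
  u1 <- estimate_usual_intake(m, fx$design, n_pseudo = 100, seed = 11)
  u2 <- estimate_usual_intake(m, fx$design, n_pseudo = 100, seed = 99)
  mid <- 10:90
  expect_lt(max(abs(u1$percentiles$value[mid] - u2$percentiles$value[mid]) /
                  u1$percentiles$value[mid]), 0.03)
})
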