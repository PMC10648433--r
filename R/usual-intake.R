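# Usual-intake estimation for daily-consumed nutrients: a Box-Cox
# transformed linear mixed model with a person-level random intercept
# separates within- from between-person variation in short-term recalls;
# the population distribution of usual intake is recovered by simulating
# person random effects and back-transforming with Gauss-Hermite
# integration over the within-person residual.

age7_categories <- function(age) {
  cut(age, breaks = c(4, 9, 14, 19, 31, 51, 71, Inf), right = FALSE,
      labels = c("4-8", "9-13", "14-18", "19-30", "31-50", "51-70", "71+"))
}

build_model_data <- function(person_days, persons, nutrient) {
  idx <- match(person_days$person_id, persons$person_id)
  if (anyNA(idx)) stop("person_days refer to unknown persons", call. = FALSE)
  tibble(
    person_id = person_days$person_id,
    y = person_days[[nutrient]],
    day2 = person_days$day == 2L,
    weekday = person_days$weekday,
    age_cat = age7_categories(persons$age_years[idx]),
    gender = persons$gender[idx],
    race = persons$race[idx],
    energy_k = person_days$energy / 1000)
}

#' Fit the Box-Cox amount model for one nutrient
#'
#' For each exponent in `lambda_grid`, transforms the positive daily
#' amounts by `g(y; lambda) = (y^lambda - 1) / lambda` (log at
#' `lambda = 0`), fits a linear mixed model with a person random intercept
#' by maximum likelihood (covariates: recall sequence, weekday Mon-Thu
#' indicator, 7-level age category, gender, 4-level race, energy in 1000
#' kcal; covariates constant in the data are dropped automatically), and
#' selects the exponent maximizing the profile likelihood including the
#' Jacobian term `(lambda - 1) * sum(log y)`.
#'
#' @param person_days Person-day tibble (each row one recall day).
#' @param nutrient Name of the nutrient column to model.
#' @param persons Persons tibble supplying the covariates.
#' @param lambda_grid Candidate Box-Cox exponents in `[0, 1]`.
#' @param energy_covariate Include daily energy as a covariate (default
#'   `TRUE`; under substitution the modified diet's energy is what the
#'   person-day table carries).
#' @return An object of class `nutshift_amount_model` with the selected
#'   `lambda`, fixed effects, variance components `sigma_u2` (between) and
#'   `sigma_e2` (within), the profile-likelihood trace, and the fitted
#'   `lme4` model.
#' @export
fit_amount_model <- function(person_days, nutrient, persons,
                             lambda_grid = seq(0, 1, by = 0.05),
                             energy_covariate = TRUE) {
  dat <- build_model_data(person_days, persons, nutrient)
  if (any(!is.finite(dat$y)) || any(dat$y <= 0)) {
    stop("Box-Cox transform requires strictly positive, finite amounts",
         call. = FALSE)
  }
  if (!any(duplicated(dat$person_id))) {
    stop("no person contributes two recall days; the within-person variance ",
         "is not estimable", call. = FALSE)
  }
  terms <- c("day2", "weekday", "age_cat", "gender", "race",
             if (energy_covariate) "energy_k")
  varying <- terms[vapply(terms,
                          function(t) length(unique(dat[[t]])) > 1,
                          logical(1))]
  rhs <- paste(c("1", varying, "(1 | person_id)"), collapse = " + ")
  form <- as.formula(paste("z ~", rhs))
  log_jac <- sum(log(dat$y))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fits <- vector("list", length(lambda_grid))
  ll <- rep(-Inf, length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    dat$z <- box_cox(dat$y, lambda_grid[i])
    fit <- suppressWarnings(suppressMessages(
      try(lme4::lmer(form, data = dat, REML = FALSE, control = ctrl),
          silent = TRUE)))
    if (inherits(fit, "try-error")) next
    fits[[i]] <- fit
    ll[i] <- as.numeric(logLik(fit)) + (lambda_grid[i] - 1) * log_jac
  }
  if (all(!is.finite(ll))) stop("amount model failed at every lambda",
                                call. = FALSE)
  best <- which.max(ll)
  fit <- fits[[best]]
  vc <- lme4::VarCorr(fit)
  converged <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  structure(
    list(nutrient = nutrient,
         lambda = lambda_grid[best],
         beta = lme4::fixef(fit),
         sigma_u2 = as.numeric(vc$person_id[1, 1]),
         sigma_e2 = stats::sigma(fit)^2,
         log_lik = ll[best],
         profile = tibble(lambda = lambda_grid, log_lik = ll),
         converged = converged,
         fit = fit,
         data = dat %>% select(-"z"),
         n_persons = length(unique(dat$person_id)),
         n_days = nrow(dat)),
    class = "nutshift_amount_model")
}

#' @export
print.nutshift_amount_model <- function(x, ...) {
  cat(sprintf(
    "<amount model: %s> lambda = %.2f, sigma_u^2 = %.4g, sigma_e^2 = %.4g, %d persons / %d days\n",
    x$nutrient, x$lambda, x$sigma_u2, x$sigma_e2, x$n_persons, x$n_days))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of an amount model
#'
#' @param x A `nutshift_amount_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @export
tidy.nutshift_amount_model <- function(x, ...) {
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std_error = unname(se))
}

#' One-row summary of an amount model fit
#'
#' @param x A `nutshift_amount_model`.
#' @param ... Unused.
#' @return Tibble with `nutrient`, `lambda`, `sigma_u2`, `sigma_e2`,
#'   `icc`, `log_lik`, `converged`, `n_persons`, `n_days`.
#' @export
glance.nutshift_amount_model <- function(x, ...) {
  tibble(nutrient = x$nutrient, lambda = x$lambda, sigma_u2 = x$sigma_u2,
         sigma_e2 = x$sigma_e2,
         icc = x$sigma_u2 / (x$sigma_u2 + x$sigma_e2),
         log_lik = x$log_lik, converged = x$converged,
         n_persons = x$n_persons, n_days = x$n_days)
}

#' Scale-free variance components of an amount model
#'
#' Variance components live on the selected Box-Cox scale, so fits with
#' different exponents are not directly comparable. Dividing by the squared
#' local derivative of the transform at the typical intake - the geometric
#' mean `G` of the amounts, giving `sigma^2 / G^(2 lambda)` - expresses both
#' components as squared coefficients of variation, comparable across
#' exponents (and equal to `sigma^2` itself at `lambda = 0`).
#'
#' @param model A `nutshift_amount_model`.
#' @return Named vector: `cv2_between`, `cv2_within`.
#' @export
normalized_variance_components <- function(model) {
  stopifnot(inherits(model, "nutshift_amount_model"))
  g <- exp(mean(log(model$data$y)))
  c(cv2_between = model$sigma_u2 / g^(2 * model$lambda),
    cv2_within = model$sigma_e2 / g^(2 * model$lambda))
}

#' Estimate the population distribution of usual intake
#'
#' For every person, sets covariates to their day-1 values (recall
#' sequence at the day-1 level), draws `n_pseudo` person random effects
#' `u ~ N(0, sigma_u^2)`, and computes each pseudo-person's usual intake
#' `T = E_e[g^{-1}(x'beta + u + e)]` by 9-point Gauss-Hermite quadrature
#' over the within-person residual. The population distribution of usual
#' intake is the survey-weighted distribution of `T` over all
#' pseudo-persons; its mean carries a BRR confidence interval.
#'
#' @param model A converged [fit_amount_model()] result.
#' @param design Survey design covering the modeled persons.
#' @param n_pseudo Pseudo-persons (random-effect draws) per person.
#' @param seed Seed for the random-effect draws.
#' @param gh_points Gauss-Hermite nodes for the residual integral.
#' @return An object of class `nutshift_usual_intake`: `mean` (tibble with
#'   `estimate`, `se`, `lower`, `upper`), `percentiles` (1-99), the
#'   pseudo-person draws, and the design used.
#' @export
estimate_usual_intake <- function(model, design, n_pseudo = 100, seed = 1,
                                  gh_points = 9) {
  stopifnot(inherits(model, "nutshift_amount_model"))
  if (!model$converged) {
    stop("refusing to simulate from an unconverged amount model",
         call. = FALSE)
  }
  day1 <- model$data %>% filter(!.data$day2)
  xb <- as.numeric(stats::predict(model$fit,
                                  newdata = transform(day1, z = 0),
                                  re.form = NA))
  design <- subset_design(design, day1$person_id)
  ord <- match(design$weights$person_id, day1$person_id)
  day1 <- day1[ord, ]
  xb <- xb[ord]
  n <- length(xb)
  set.seed(as.integer(seed))
  u <- matrix(rnorm(n * n_pseudo, 0, sqrt(model$sigma_u2)), n, n_pseudo)
  rule <- gh_rule(gh_points)
  tmat <- matrix(0, n, n_pseudo)
  sigma_e <- sqrt(model$sigma_e2)
  for (q in seq_along(rule$z)) {
    tmat <- tmat + rule$w[q] *
      inv_box_cox(xb + u + sigma_e * rule$z[q], model$lambda)
  }
  w <- design$weights$weight
  mean_tbl <- brr_interval(design, function(wr) {
    weighted_mean(rowMeans(tmat), wr)
  })
  wq <- rep(w, times = n_pseudo)
  pct <- tibble(p = 1:99,
                value = weighted_quantile(as.numeric(tmat), wq, (1:99) / 100))
  structure(
    list(nutrient = model$nutrient, mean = mean_tbl, percentiles = pct,
         t = tmat, person_id = day1$person_id, design = design,
         n_pseudo = n_pseudo, lambda = model$lambda),
    class = "nutshift_usual_intake")
}

#' @export
print.nutshift_usual_intake <- function(x, ...) {
  cat(sprintf(
    "<usual intake: %s> mean %.3g (95%% CI %.3g-%.3g), %d persons x %d pseudo\n",
    x$nutrient, x$mean$estimate, x$mean$lower, x$mean$upper,
    length(x$person_id), x$n_pseudo))
  invisible(x)
}

#' Fraction of the usual-intake distribution beyond a threshold
#'
#' EAR cut-point (`direction = "below"`): the survey-weighted fraction of
#' pseudo-persons whose usual intake falls below the threshold; the AI
#' check uses `direction = "above"`. Confidence intervals by BRR.
#'
#' @param ui A [estimate_usual_intake()] result.
#' @param threshold DRI threshold value in the nutrient's units.
#' @param direction `"below"` (EAR) or `"above"` (AI).
#' @param person_ids Optional subset of persons (e.g. one age-gender group).
#' @return One-row tibble: `estimate`, `se`, `lower`, `upper`.
#' @export
threshold_fraction <- function(ui, threshold, direction = c("below", "above"),
                               person_ids = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(ui, "nutshift_usual_intake"), threshold > 0)
  keep <- if (is.null(person_ids)) seq_along(ui$person_id) else
    which(ui$person_id %in% person_ids)
  if (length(keep) == 0) stop("no persons in the requested subset",
                              call. = FALSE)
  ind <- if (direction == "below") ui$t[keep, , drop = FALSE] < threshold
  else ui$t[keep, , drop = FALSE] > threshold
  frac_by_person <- rowMeans(ind)
  d <- subset_design(ui$design, ui$person_id[keep])
  brr_interval(d, function(w) weighted_mean(frac_by_person, w)) %>%
    select(-"n_replicates")
}

#' Reference intake thresholds by nutrient, gender and age
#'
#' Estimated Average Requirements (EAR, adequacy assessed as the fraction
#' below) for magnesium, vitamin B12 and iron, and Adequate Intakes (AI,
#' fraction above) for potassium, fiber and ALA, in the package's fixed
#' units, by gender and age band. `gender = NA` applies to both.
#'
#' @return Tibble: `nutrient`, `kind`, `gender`, `age_min`, `age_max`,
#'   `value`.
#' @export
dri_reference <- function() {
  tibble::tribble(
    ~nutrient,      ~kind,  ~gender,  ~age_min, ~age_max, ~value,
    "magnesium",    "ear",  NA,        4,  8,   110,
    "magnesium",    "ear",  NA,        9, 13,   200,
    "magnesium",    "ear",  "male",   14, 18,   340,
    "magnesium",    "ear",  "female", 14, 18,   300,
    "magnesium",    "ear",  "male",   19, 30,   330,
    "magnesium",    "ear",  "female", 19, 30,   255,
    "magnesium",    "ear",  "male",   31, Inf,  350,
    "magnesium",    "ear",  "female", 31, Inf,  265,
    "vitamin_b12",  "ear",  NA,        4,  8,   1.0,
    "vitamin_b12",  "ear",  NA,        9, 13,   1.5,
    "vitamin_b12",  "ear",  NA,       14, Inf,  2.0,
    "iron",         "ear",  NA,        4,  8,   4.1,
    "iron",         "ear",  "male",    9, 13,   5.9,
    "iron",         "ear",  "female",  9, 13,   5.7,
    "iron",         "ear",  "male",   14, 18,   7.7,
    "iron",         "ear",  "female", 14, 18,   7.9,
    "iron",         "ear",  "male",   19, 50,   6.0,
    "iron",         "ear",  "female", 19, 50,   8.1,
    "iron",         "ear",  "male",   51, Inf,  6.0,
    "iron",         "ear",  "female", 51, Inf,  5.0,
    "potassium",    "ai",   NA,        4,  8,  2300,
    "potassium",    "ai",   "male",    9, 13,  2500,
    "potassium",    "ai",   "female",  9, 13,  2300,
    "potassium",    "ai",   "male",   14, 18,  3000,
    "potassium",    "ai",   "female", 14, 18,  2300,
    "potassium",    "ai",   "male",   19, Inf, 3400,
    "potassium",    "ai",   "female", 19, Inf, 2600,
    "fiber",        "ai",   NA,        4,  8,    25,
    "fiber",        "ai",   "male",    9, 13,    31,
    "fiber",        "ai",   "female",  9, 13,    26,
    "fiber",        "ai",   "male",   14, 18,    38,
    "fiber",        "ai",   "female", 14, 18,    26,
    "fiber",        "ai",   "male",   19, 50,    38,
    "fiber",        "ai",   "female", 19, 50,    25,
    "fiber",        "ai",   "male",   51, Inf,   30,
    "fiber",        "ai",   "female", 51, Inf,   21,
    "ala",          "ai",   NA,        4,  8,   0.9,
    "ala",          "ai",   "male",    9, 13,   1.2,
    "ala",          "ai",   "female",  9, 13,   1.0,
    "ala",          "ai",   "male",   14, Inf,  1.6,
    "ala",          "ai",   "female", 14, Inf,  1.1)
}

#' Adequacy fractions against all matching DRI rows
#'
#' Looks up every DRI band for the nutrient of a usual-intake distribution
#' and computes the fraction of that band's population below the EAR or
#' above the AI, with BRR intervals.
#'
#' @param ui A [estimate_usual_intake()] result.
#' @param persons Persons tibble (for gender and age matching).
#' @param dri DRI table, default [dri_reference()].
#' @return Tibble: one row per matching DRI band with `kind`, `value`,
#'   `n`, `estimate`, `se`, `lower`, `upper`.
#' @export
adequacy_table <- function(ui, persons, dri = dri_reference()) {
  rows <- dri %>% filter(.data$nutrient == ui$nutrient)
  if (nrow(rows) == 0) {
    stop("no DRI reference rows for nutrient ", ui$nutrient, call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    ids <- persons %>%
      filter(.data$age_years >= r$age_min, .data$age_years <= r$age_max,
             is.na(r$gender) | .data$gender == r$gender) %>%
      pull("person_id")
    ids <- intersect(ids, ui$person_id)
    if (length(ids) == 0) return(NULL)
    fr <- threshold_fraction(ui, r$value,
                             if (r$kind == "ear") "below" else "above",
                             person_ids = ids)
    bind_cols(r %>% select("nutrient", "kind", "gender", "age_min",
                           "age_max", "value"),
              tibble(n = length(ids)), fr)
  })
}
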