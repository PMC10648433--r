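# Survey-weighted estimation with balanced repeated replication (BRR)
# variance. The design holds one base weight per person plus R replicate
# weight vectors built by Fay's method: in replicate r the selected
# half-sample is scaled by (2 - F) and the complement by F, and
#   Var(theta) = 1 / (R (1-F)^2) * sum_r (theta_r - theta)^2.

#' Construct a replicate-weight survey design
#'
#' @param weights Tibble with columns `person_id` and `weight` (> 0).
#' @param rep_weights Numeric matrix, one row per person (in the order of
#'   `weights`), one column per replicate.
#' @param fay Fay shrinkage coefficient F in `[0, 1)`; `F = 0` is classic BRR.
#' @return An object of class `nutshift_design`.
#' @export
new_survey_design <- function(weights, rep_weights, fay = 0.3) {
  stopifnot(is.data.frame(weights),
            all(c("person_id", "weight") %in% names(weights)),
            all(weights$weight > 0),
            is.matrix(rep_weights),
            nrow(rep_weights) == nrow(weights),
            ncol(rep_weights) >= 2,
            fay >= 0, fay < 1)
  structure(list(weights = as_tibble(weights), rep_weights = rep_weights,
                 fay = fay),
            class = "nutshift_design")
}

#' @export
print.nutshift_design <- function(x, ...) {
  cat(sprintf("<nutshift_design> %d persons, %d BRR replicates, Fay %.2f\n",
              nrow(x$weights), ncol(x$rep_weights), x$fay))
  invisible(x)
}

#' Restrict a survey design to a subset of persons
#'
#' @param design A [new_survey_design()] object.
#' @param person_ids Person identifiers to keep.
#' @return A design containing only the requested persons, in `person_ids`
#'   order where present.
#' @export
subset_design <- function(design, person_ids) {
  idx <- match(intersect(person_ids, design$weights$person_id),
               design$weights$person_id)
  new_survey_design(design$weights[idx, ], design$rep_weights[idx, , drop = FALSE],
                    design$fay)
}

#' Survey-weighted mean
#'
#' @param x Numeric values.
#' @param w Non-negative weights of the same length with a positive sum
#'   (classic BRR replicates zero out half the sample, so zeros are legal).
#' @return The scalar weighted mean `sum(w * x) / sum(w)`.
#' @export
#' @examples
#' weighted_mean(c(0, 4), c(1, 3))  # 3
weighted_mean <- function(x, w) {
  if (length(x) == 0) stop("weighted_mean of empty input", call. = FALSE)
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  sum(w * x) / sum(w)
}

#' Weighted quantiles of a sample
#'
#' Inverse of the weighted empirical CDF: the smallest observed value whose
#' cumulative normalized weight reaches the requested probability.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Point estimate and BRR confidence interval for any weighted statistic
#'
#' Evaluates `statistic` under the base weights and under every replicate
#' weight vector, and forms the Fay-adjusted BRR variance
#' `Var = sum_r (theta_r - theta)^2 / (R (1 - F)^2)`. The 95% interval uses
#' the normal multiplier 1.96.
#'
#' @param design A [new_survey_design()] object.
#' @param statistic Function taking one argument, a weight vector aligned
#'   with `design$weights`, and returning a scalar.
#' @return One-row tibble: `estimate`, `se`, `lower`, `upper`, `n_replicates`.
#' @export
#' @examples
#' d <- new_survey_design(tibble::tibble(person_id = c("a", "b"),
#'                                       weight = c(1, 1)),
#'                        matrix(c(2, 0, 0, 2), nrow = 2), fay = 0)
#' brr_interval(d, function(w) weighted_mean(c(1, 3), w))
brr_interval <- function(design, statistic) {
  stopifnot(inherits(design, "nutshift_design"), is.function(statistic))
  point <- statistic(design$weights$weight)
  R <- ncol(design$rep_weights)
  reps <- vapply(seq_len(R), function(r) {
    out <- tryCatch(statistic(design$rep_weights[, r]), error = function(e) {
      stop("statistic failed on replicate ", r, ": ", conditionMessage(e),
           call. = FALSE)
    })
    out
  }, numeric(1))
  v <- sum((reps - point)^2) / (R * (1 - design$fay)^2)
  se <- sqrt(v)
  tibble(estimate = point, se = se,
         lower = point - 1.96 * se, upper = point + 1.96 * se,
         n_replicates = R)
}

#' Significance by the non-overlapping confidence interval rule
#'
#' Two estimates are declared significantly different when their 95%
#' intervals do not overlap at all: `upper_a < lower_b` or
#' `upper_b < lower_a` (strict, so intervals sharing a boundary are not
#' significant). Vectorized over all four arguments.
#'
#' @param lower_a,upper_a First interval.
#' @param lower_b,upper_b Second interval.
#' @return Logical vector.
#' @export
#' @examples
#' nonoverlap_significant(47.9, 50.4, 53.8, 56.2)  # TRUE
#' nonoverlap_significant(51.1, 57.0, 54.6, 60.0)  # FALSE
nonoverlap_significant <- function(lower_a, upper_a, lower_b, upper_b) {
  stopifnot(all(lower_a <= upper_a), all(lower_b <= upper_b))
  upper_a < lower_b | upper_b < lower_a
}
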