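# Published NHANES-derived reference values used as desk-check inputs:
# the protein-food composition table (oz-eq means with percent shares) and
# the HEI-2015 dose-response table (population-ratio totals with 95% CIs
# and the non-overlap significance marks). The package cannot reproduce
# the underlying survey estimates without the survey microdata; these
# tables verify the share arithmetic and the CI-overlap rule themselves.

#' Published protein-food composition reference table
#'
#' Survey-weighted usual protein-food intake of no-nut consumers: total oz
#' equivalents per day and per-source means with percent shares
#' (`meats` = meat + cured + organ), as printed to 2 (means) and 1 (shares)
#' decimals.
#'
#' @return Tibble: `group`, `total_oz`, `source`, `mean_oz`, `share_pct`.
#' @export
reference_protein_food_table <- function() {
  rows <- tibble::tribble(
    ~group,     ~total_oz, ~meats, ~meats_s, ~poultry, ~poultry_s, ~seafood, ~seafood_s, ~eggs, ~eggs_s, ~legumes, ~legumes_s, ~soy, ~soy_s,
    "Boys",      4.86, 2.47, 50.9, 1.43, 29.4, 0.22,  4.5, 0.38,  7.8, 0.32, 6.5, 0.05, 1.0,
    "Girls",     3.81, 1.71, 44.9, 1.21, 31.7, 0.21,  5.5, 0.37,  9.8, 0.26, 6.9, 0.05, 1.3,
    "Children",  4.36, 2.11, 48.4, 1.32, 30.3, 0.21,  4.9, 0.38,  8.6, 0.29, 6.7, 0.05, 1.1,
    "Men",       6.97, 3.44, 49.4, 1.71, 24.5, 0.65,  9.4, 0.60,  8.6, 0.53, 7.6, 0.04, 0.6,
    "Women",     5.05, 2.20, 43.6, 1.32, 26.2, 0.58, 11.5, 0.53, 10.5, 0.38, 7.4, 0.04, 0.8,
    "Adults",    6.06, 2.85, 47.1, 1.53, 25.2, 0.62, 10.2, 0.57,  9.3, 0.46, 7.5, 0.04, 0.6)
  purrr::map_dfr(c("meats", "poultry", "seafood", "eggs", "legumes", "soy"),
                 function(src) {
                   tibble(group = rows$group, total_oz = rows$total_oz,
                          source = src, mean_oz = rows[[src]],
                          share_pct = rows[[paste0(src, "_s")]])
                 }) %>%
    arrange(match(.data$group, rows$group))
}

#' Published HEI-2015 dose-response reference table
#'
#' Population-ratio HEI-2015 totals with 95% confidence intervals for the
#' current diet (`dose = 0`) and the four walnut-for-meat replacement
#' doses, for all 19 reporting rows, with the published non-overlapping-CI
#' significance marks (`NA` for the current diet).
#'
#' @return Tibble: `group`, `dose`, `estimate`, `lower`, `upper`,
#'   `significant`.
#' @export
reference_hei_dose_table <- function() {
  raw <- list(
    list("Male 4-8",     c(51.4, 48.9, 53.8), c(57.4, 54.9, 59.8, TRUE),  c(60.1, 57.7, 62.6, TRUE),  c(62.7, 60.2, 65.2, TRUE), c(64.7, 62.4, 67.0, TRUE)),
    list("Male 9-13",    c(46.8, 44.3, 49.3), c(52.4, 49.8, 54.8, TRUE),  c(55.3, 52.8, 57.7, TRUE),  c(57.7, 55.3, 60.0, TRUE), c(59.8, 57.4, 62.1, TRUE)),
    list("Male 14-18",   c(44.6, 42.4, 46.8), c(49.8, 47.6, 51.9, TRUE),  c(52.6, 50.5, 54.8, TRUE),  c(54.9, 52.7, 57.1, TRUE), c(57.1, 54.9, 59.2, TRUE)),
    list("Male 4-18",    c(47.3, 45.7, 48.9), c(52.8, 51.1, 54.5, TRUE),  c(55.6, 54.0, 57.2, TRUE),  c(58.0, 56.3, 59.7, TRUE), c(60.2, 58.6, 61.7, TRUE)),
    list("Female 4-8",   c(54.1, 52.2, 56.0), c(60.8, 58.8, 62.7, TRUE),  c(63.8, 61.8, 65.8, TRUE),  c(66.8, 64.7, 68.7, TRUE), c(67.6, 65.8, 69.5, TRUE)),
    list("Female 9-13",  c(51.6, 49.1, 54.2), c(57.3, 54.9, 59.7, TRUE),  c(59.9, 57.6, 62.3, TRUE),  c(62.5, 60.1, 64.8, TRUE), c(63.4, 61.4, 65.4, TRUE)),
    list("Female 14-18", c(48.7, 45.9, 51.5), c(54.4, 51.8, 57.1, TRUE),  c(57.3, 54.7, 60.1, TRUE),  c(59.6, 57.1, 62.1, TRUE), c(60.2, 57.9, 62.7, TRUE)),
    list("Female 4-18",  c(51.5, 50.1, 53.1), c(57.4, 56.1, 58.8, TRUE),  c(60.2, 58.9, 61.6, TRUE),  c(62.9, 61.6, 64.2, TRUE), c(63.6, 62.4, 64.8, TRUE)),
    list("Child 4-18",   c(49.1, 47.9, 50.4), c(55.0, 53.8, 56.2, TRUE),  c(57.6, 56.5, 58.8, TRUE),  c(60.2, 59.0, 61.3, TRUE), c(61.8, 60.8, 62.8, TRUE)),
    list("Male 19-50",   c(49.7, 47.9, 51.7), c(53.7, 52.1, 55.3, TRUE),  c(55.9, 54.3, 57.5, TRUE),  c(58.1, 56.5, 59.7, TRUE), c(59.9, 58.4, 61.3, TRUE)),
    list("Female 19-50", c(50.7, 48.4, 53.0), c(55.3, 53.1, 57.5, TRUE),  c(58.1, 56.0, 60.3, TRUE),  c(60.7, 58.7, 62.6, TRUE), c(61.4, 59.5, 63.2, TRUE)),
    list("Adult 19-50",  c(50.1, 48.4, 51.9), c(54.3, 52.8, 55.8, TRUE),  c(56.8, 55.3, 58.3, TRUE),  c(59.2, 57.7, 60.7, TRUE), c(60.5, 59.2, 61.8, TRUE)),
    list("Male 51-70",   c(54.0, 51.1, 57.0), c(57.3, 54.6, 60.0, FALSE), c(59.5, 56.8, 62.3, FALSE), c(61.8, 59.0, 64.6, TRUE), c(63.2, 60.8, 65.6, TRUE)),
    list("Female 51-70", c(56.4, 54.7, 58.1), c(60.7, 58.9, 62.5, TRUE),  c(63.7, 61.9, 65.5, TRUE),  c(65.6, 63.9, 67.2, TRUE), c(66.2, 64.5, 67.8, TRUE)),
    list("Adult 51-70",  c(55.0, 53.0, 56.9), c(58.7, 56.7, 60.7, FALSE), c(61.3, 59.3, 63.3, TRUE),  c(63.7, 61.8, 65.6, TRUE), c(64.4, 62.7, 66.2, TRUE)),
    list("Adult 71+",    c(59.6, 56.4, 62.7), c(63.6, 60.8, 66.3, FALSE), c(66.5, 63.7, 69.2, TRUE),  c(68.7, 66.0, 71.2, TRUE), c(69.2, 66.6, 71.7, TRUE)),
    list("Male 19-71+",  c(51.7, 50.1, 53.2), c(55.4, 54.0, 56.8, TRUE),  c(57.6, 56.2, 59.0, TRUE),  c(59.9, 58.5, 61.3, TRUE), c(61.5, 60.2, 62.8, TRUE)),
    list("Female 19-71+", c(53.5, 51.9, 55.2), c(58.0, 56.3, 59.7, TRUE), c(60.9, 59.2, 62.6, TRUE),  c(63.2, 61.8, 64.7, TRUE), c(63.8, 62.4, 65.3, TRUE)),
    list("Adult 19-71+", c(52.4, 51.0, 53.8), c(56.4, 55.1, 57.8, TRUE),  c(59.0, 57.6, 60.3, TRUE),  c(61.5, 60.1, 62.8, TRUE), c(62.4, 61.2, 63.6, TRUE)))
  purrr::map_dfr(raw, function(row) {
    cur <- row[[2]]
    bind_rows(
      tibble(group = row[[1]], dose = 0, estimate = cur[1], lower = cur[2],
             upper = cur[3], significant = NA),
      purrr::map_dfr(1:4, function(d) {
        v <- row[[d + 2]]
        tibble(group = row[[1]], dose = d, estimate = v[1], lower = v[2],
               upper = v[3], significant = as.logical(v[4]))
      }))
  })
}
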