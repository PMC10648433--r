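# Box-Cox machinery shared by the generator and the usual-intake model.
# g(y; lambda) = (y^lambda - 1) / lambda for lambda > 0, log(y) at lambda = 0.

box_cox <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox transform requires strictly positive amounts",
                        call. = FALSE)
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

inv_box_cox <- function(z, lambda) {
  if (lambda == 0) return(exp(z))
  base <- pmax(lambda * z + 1, 0)  # outside the image of g; clamp to 0 intake
  base^(1 / lambda)
}

# Nodes/weights for E[f(mu + sigma*Z)], Z ~ N(0,1), via Gauss-Hermite:
# E = sum_q w_q / sqrt(pi) * f(mu + sqrt(2) * sigma * t_q)
gh_rule <- function(n = 9) {
  gh <- pracma::gaussHermite(n)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# E_e[ g^{-1}(mu + e) ] with e ~ N(0, sigma_e^2), vectorized over mu.
gh_expect_inv <- function(mu, sigma_e, lambda, rule = gh_rule(9)) {
  out <- numeric(length(mu))
  for (q in seq_along(rule$z)) {
    out <- out + rule$w[q] * inv_box_cox(mu + sigma_e * rule$z[q], lambda)
  }
  out
}
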