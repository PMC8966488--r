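#' Optimal breeding date in environment n
#'
#' The optimum depends linearly on nutritional condition: `theta = A + B * n`.
#'
#' @param n Nutritional condition (vectorized).
#' @param params A [model_params()] object.
#' @return Optimal breeding date(s), in days.
#' @examples
#' optimal_breeding_date(c(-1, 0, 2), model_params(A = 0, B = -1))
#' @export
optimal_breeding_date <- function(n, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  params$A + params$B * n
}

#' Absolute fitness of an individual
#'
#' `W = exp(alpha n - (theta - y)^2 / (2 omega_y2) - b^2 / (2 omega_b2))`:
#' a log-linear direct effect of nutrition, Gaussian stabilizing selection of
#' breeding date `y` around the nutrition-dependent optimum, and a Gaussian
#' cost of the plastic slope `b` around zero. All arguments are vectorized.
#'
#' @param y Breeding date (days).
#' @param b Plastic slope of the individual.
#' @param n Nutritional condition.
#' @param params A [model_params()] object.
#' @return Absolute fitness, strictly positive.
#' @examples
#' p <- model_params()
#' individual_fitness(optimal_breeding_date(1, p), b = 0, n = 1, p)  # exp(1)
#' @export
individual_fitness <- function(y, b, n, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  theta <- params$A + params$B * n
  exp(params$alpha * n -
        (theta - y)^2 / (2 * params$omega_y2) -
        b^2 / (2 * params$omega_b2))
}

#' Phenotypic variance of breeding date in environment n
#'
#' Exactly, `sigma_y2(n) = sigma_i2 + 2 sigma_ib n + sigma_b2 n^2`, a
#' quadratic in nutrition. The companion [constant_phenotypic_variance()]
#' returns its average over the nutrition distribution,
#' `sigma_i2 + sigma_b2 sigma_n2`, used by the constant-variance
#' approximation.
#'
#' @param n Nutritional condition (vectorized).
#' @param params A [model_params()] object.
#' @return Phenotypic variance of `y` at `n`.
#' @examples
#' phenotypic_variance(2, model_params())
#' constant_phenotypic_variance(model_params())
#' @export
phenotypic_variance <- function(n, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  params$sigma_i2 + 2 * params$sigma_ib * n + params$sigma_b2 * n^2
}

#' @rdname phenotypic_variance
#' @export
constant_phenotypic_variance <- function(params) {
  stopifnot(inherits(params, "plastinorm_params"))
  params$sigma_i2 + params$sigma_b2 * params$sigma_n2
}

# Second-moment structure of (y, b) joined with the selection widths, per
# environment n, for the requested variance mode. Returns the components of
# M = Sigma + diag(omega_y2, omega_b2) and its determinant.
#
# mode "exact": M11 = sigma_y2(n) + omega_y2, M12 = sigma_ib + sigma_b2 n,
#   det = M11 M22 - M12^2, all n-dependent.
# mode "constant": the variance-order n^2 terms are replaced by their
#   expectation sigma_n2 (so M11 and det become constant in n) while the
#   n-linear y-b covariance is retained. This is the "constant phenotypic
#   variance" approximation; dropping the covariance as well would lose the
#   alpha-dependence of the weak-mismatch equilibrium slope.
.m_terms <- function(n, params, mode = c("exact", "constant")) {
  mode <- match.arg(mode)
  p <- params
  M22 <- p$sigma_b2 + p$omega_b2
  M12 <- p$sigma_ib + p$sigma_b2 * n
  if (mode == "exact") {
    M11 <- phenotypic_variance(n, p) + p$omega_y2
    det <- M11 * M22 - M12^2
  } else {
    M11 <- constant_phenotypic_variance(p) + p$omega_y2
    det <- (constant_phenotypic_variance(p) + p$omega_y2) * M22 -
      (p$sigma_ib^2 + p$sigma_b2^2 * p$sigma_n2)
    M11 <- rep_len(M11, length(n))
    det <- rep_len(det, length(n))
  }
  list(M11 = M11, M12 = M12, M22 = M22, det = det)
}

#' Mean fitness within an environment
#'
#' Expected fitness `Wbar(n)` over the Gaussian joint distribution of
#' breeding date and slope with means taken from `state` and (co)variances
#' from `params`. Computed in closed form as a bivariate Gaussian integral;
#' supports nonzero intercept-slope correlation.
#'
#' @param n Nutritional condition (vectorized).
#' @param state A [population_state()] (or `c(mu_i, mu_b)`).
#' @param params A [model_params()] object.
#' @param mode `"exact"` uses the full environment-dependent phenotypic
#'   variance; `"constant"` applies the constant-variance approximation (see
#'   [phenotypic_variance()]).
#' @param log If `TRUE` return `log(Wbar(n))`.
#' @return Mean fitness (strictly positive), or its log.
#' @examples
#' p <- model_params()
#' env_mean_fitness(0, population_state(0, 0), p)
#' @export
env_mean_fitness <- function(n, state, params,
                             mode = c("exact", "constant"), log = FALSE) {
  stopifnot(inherits(params, "plastinorm_params"))
  mode <- match.arg(mode)
  st <- .as_state(state)
  p <- params
  mt <- .m_terms(n, p, mode)
  # deviation of the mean phenotype from the optimum, and the mean slope
  d1 <- st$mu_i + st$mu_b * n - (p$A + p$B * n)
  d2 <- st$mu_b
  q <- mt$M22 * d1^2 - 2 * mt$M12 * d1 * d2 + mt$M11 * d2^2
  lw <- p$alpha * n + 0.5 * log(p$omega_y2 * p$omega_b2) -
    0.5 * log(mt$det) - q / (2 * mt$det)
  if (log) lw else exp(lw)
}
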