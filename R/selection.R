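#' Selection gradients on the mean intercept and slope within an environment
#'
#' The gradient is the derivative of `log Wbar(n)` with respect to the trait
#' mean. With zero intercept-slope correlation the closed forms are
#' \deqn{\beta_{\mu_i}(n) = \frac{(A + Bn - \mu_i - n\mu_b)(\sigma_b^2 +
#'   \omega_b^2) + n\mu_b\sigma_b^2}{D(n)}}
#' \deqn{\beta_{\mu_b}(n) = \frac{(A + Bn - \mu_i - n\mu_b)\,n\,\omega_b^2 -
#'   \mu_b(\sigma_i^2 + \omega_y^2)}{D(n)}}
#' with `D(n) = (sigma_i2 + omega_y2)(sigma_b2 + omega_b2) +
#' sigma_b2 omega_b2 n^2` in the exact mode, and `n^2` replaced by `sigma_n2`
#' in the constant-variance mode. The slope gradient carries a direct cost
#' term proportional to `-mu_b (sigma_i2 + omega_y2)`, so it is nonzero even
#' at `n = 0` whenever `mu_b != 0`.
#'
#' With nonzero `rho_ib` the closed forms do not apply and the gradient is
#' computed by central finite differences of `log` [env_mean_fitness()]
#' (which handles correlation exactly); `method = "auto"` selects the path.
#'
#' @param n Nutritional condition (vectorized).
#' @param state A [population_state()] (or `c(mu_i, mu_b)`).
#' @param params A [model_params()] object.
#' @param mode Variance mode, `"exact"` or `"constant"`.
#' @param method `"auto"`, `"closed_form"` or `"finite_difference"`.
#' @param h Step for the finite-difference path.
#' @return The selection gradient(s) at `n`.
#' @examples
#' p <- model_params()
#' selection_gradient_intercept(1, population_state(0, 0), p)
#' selection_gradient_slope(0, population_state(0, 1), p)  # pure cost, < 0
#' @export
selection_gradient_intercept <- function(n, state, params,
                                         mode = c("exact", "constant"),
                                         method = c("auto", "closed_form",
                                                    "finite_difference"),
                                         h = 1e-6) {
  mode <- match.arg(mode)
  method <- .grad_method(match.arg(method), params)
  st <- .as_state(state)
  if (method == "finite_difference") {
    up <- population_state(st$mu_i + h, st$mu_b)
    dn <- population_state(st$mu_i - h, st$mu_b)
    return((env_mean_fitness(n, up, params, mode, log = TRUE) -
              env_mean_fitness(n, dn, params, mode, log = TRUE)) / (2 * h))
  }
  p <- params
  mt <- .m_terms(n, p, mode)
  m <- (p$A + p$B * n) - st$mu_i - n * st$mu_b
  (m * mt$M22 + n * st$mu_b * p$sigma_b2) / mt$det
}

#' @rdname selection_gradient_intercept
#' @export
selection_gradient_slope <- function(n, state, params,
                                     mode = c("exact", "constant"),
                                     method = c("auto", "closed_form",
                                                "finite_difference"),
                                     h = 1e-6) {
  mode <- match.arg(mode)
  method <- .grad_method(match.arg(method), params)
  st <- .as_state(state)
  if (method == "finite_difference") {
    up <- population_state(st$mu_i, st$mu_b + h)
    dn <- population_state(st$mu_i, st$mu_b - h)
    return((env_mean_fitness(n, up, params, mode, log = TRUE) -
              env_mean_fitness(n, dn, params, mode, log = TRUE)) / (2 * h))
  }
  p <- params
  mt <- .m_terms(n, p, mode)
  m <- (p$A + p$B * n) - st$mu_i - n * st$mu_b
  (m * n * p$omega_b2 - st$mu_b * (p$sigma_i2 + p$omega_y2)) / mt$det
}

.grad_method <- function(method, params) {
  if (method == "auto")
    return(if (params$rho_ib == 0) "closed_form" else "finite_difference")
  if (method == "closed_form" && params$rho_ib != 0)
    stop("closed-form gradients assume rho_ib = 0; ",
         "use method = \"finite_difference\"")
  method
}

# both gradients at once, vectorized over n (internal)
.gradients <- function(n, st, params, mode) {
  if (params$rho_ib == 0) {
    mt <- .m_terms(n, params, mode)
    m <- (params$A + params$B * n) - st$mu_i - n * st$mu_b
    list(bi = (m * mt$M22 + n * st$mu_b * params$sigma_b2) / mt$det,
         bb = (m * n * params$omega_b2 -
                 st$mu_b * (params$sigma_i2 + params$omega_y2)) / mt$det)
  } else {
    list(bi = selection_gradient_intercept(n, st, params, mode,
                                           method = "finite_difference"),
         bb = selection_gradient_slope(n, st, params, mode,
                                       method = "finite_difference"))
  }
}

# genetic covariance matrix entries
.g_matrix <- function(params) {
  c(gii = params$sigma_ai2, gbb = params$sigma_ab2, gib = params$sigma_aib)
}

#' Response to selection within an environment
#'
#' The multivariate breeder's equation applied per environment:
#' `d_mu_i(n) = sigma_ai2 * beta_i(n) + sigma_aib * beta_b(n)` and
#' `d_mu_b(n) = sigma_ab2 * beta_b(n) + sigma_aib * beta_i(n)`.
#'
#' @inheritParams selection_gradient_intercept
#' @return A list with vectors `d_mu_i` and `d_mu_b` (per-generation changes).
#' @examples
#' response_in_environment(1, population_state(0, 0), model_params())
#' @export
response_in_environment <- function(n, state, params,
                                    mode = c("exact", "constant")) {
  mode <- match.arg(mode)
  st <- .as_state(state)
  g <- .gradients(n, st, params, mode)
  G <- .g_matrix(params)
  list(d_mu_i = G["gii"] * g$bi + G["gib"] * g$bb,
       d_mu_b = G["gbb"] * g$bb + G["gib"] * g$bi)
}

#' Global mean fitness
#'
#' `Wbar = Integral of Wbar(n) f(n) dn` over the Gaussian nutrition density,
#' by Gauss-Hermite quadrature. The result is checked by node doubling and an
#' error is raised if the two rules disagree by more than `1e-8` relative.
#'
#' @param state A [population_state()] (or `c(mu_i, mu_b)`).
#' @param params A [model_params()] object.
#' @param quad A [quadrature_spec()].
#' @param mode Variance mode, `"exact"` or `"constant"`.
#' @param check If `TRUE` (default) perform the node-doubling accuracy check.
#' @return Global mean fitness, a positive scalar.
#' @examples
#' global_mean_fitness(population_state(0, -0.5), model_params())
#' @export
global_mean_fitness <- function(state, params, quad = quadrature_spec(),
                                mode = c("exact", "constant"), check = TRUE) {
  stopifnot(inherits(quad, "plastinorm_quadrature"))
  mode <- match.arg(mode)
  st <- .as_state(state)
  val <- .wbar_global(st, params, quad, mode)
  if (check) {
    q2 <- quadrature_spec(2 * quad$nodes, quad$range_sd)
    val2 <- .wbar_global(st, params, q2, mode)
    if (abs(val2 - val) > 1e-8 * abs(val2))
      stop("quadrature not converged: node doubling changed the result by ",
           format(abs(val2 - val) / abs(val2)), " relative")
  }
  val
}

.wbar_global <- function(st, params, quad, mode) {
  n <- sqrt(params$sigma_n2) * quad$x
  sum(quad$w * env_mean_fitness(n, st, params, mode))
}

# fitness-weighted mean gradients over environments: the left-hand sides of
# the equilibrium conditions (zero at equilibrium)
.weighted_gradients <- function(st, params, quad, mode) {
  n <- sqrt(params$sigma_n2) * quad$x
  Wn <- env_mean_fitness(n, st, params, mode)
  wt <- quad$w * Wn
  wt <- wt / sum(wt)
  g <- .gradients(n, st, params, mode)
  c(beta_i = sum(wt * g$bi), beta_b = sum(wt * g$bb))
}

#' Fitness-weighted total response to selection
#'
#' Under hard selection each environment contributes in proportion to its
#' frequency times its relative mean fitness, so the total per-generation
#' change of the trait means is
#' `d_mu = Integral of d_mu(n) * (Wbar(n) / Wbar) * f(n) dn`. When `Wbar(n)`
#' is constant in `n` this reduces to the unweighted (soft-selection) average
#' of the per-environment responses.
#'
#' @inheritParams global_mean_fitness
#' @return A named numeric vector `c(d_mu_i, d_mu_b)`; both components are
#'   zero at an equilibrium state.
#' @examples
#' total_response(population_state(0, -0.5), model_params())
#' @export
total_response <- function(state, params, quad = quadrature_spec(),
                           mode = c("exact", "constant")) {
  stopifnot(inherits(quad, "plastinorm_quadrature"))
  mode <- match.arg(mode)
  st <- .as_state(state)
  wg <- .weighted_gradients(st, params, quad, mode)
  G <- .g_matrix(params)
  c(d_mu_i = unname(G["gii"] * wg["beta_i"] + G["gib"] * wg["beta_b"]),
    d_mu_b = unname(G["gbb"] * wg["beta_b"] + G["gib"] * wg["beta_i"]))
}
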