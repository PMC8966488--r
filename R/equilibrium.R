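#' Closed-form equilibrium approximations for the mean intercept and slope
#'
#' Four analytic approximations to the joint equilibrium of the fitness-
#' weighted selection responses, each valid in a stated regime:
#'
#' * `approx_intercept_cv(mu_b, params)` — equilibrium intercept under the
#'   constant-phenotypic-variance approximation, conditional on a mean slope
#'   `mu_b`:
#'   \deqn{\mu_i^* = A + \sigma_n^2\alpha\, D\,\frac{B(\sigma_b^2 +
#'     \omega_b^2) - \omega_b^2\mu_b}{(\sigma_b^2+\omega_b^2)D -
#'     \sigma_n^2\sigma_b^4\mu_b^2}}
#'   with `D = (sigma_i2 + omega_y2)(sigma_b2 + omega_b2) +
#'   sigma_b2 omega_b2 sigma_n2`. The mean breeding date exceeds the optimum
#'   (`mu_i* > A`) exactly when `B > mu_b omega_b2 / (sigma_b2 + omega_b2)`;
#'   notably the intercept depends on the cost of plasticity even
#'   conditionally on the mean slope.
#' * `approx_intercept_ssv(mu_b, params)` — little slope variance
#'   (`sigma_b2 ~ 0`): `mu_i* = A + sigma_n2 alpha (B - mu_b)`. The same form
#'   holds under weak mismatch with little slope variance.
#' * `approx_slope_ssv(params)` — little slope variance: the admissible real
#'   root of the cubic
#'   \deqn{x^3 - 2Bx^2 + (B^2 + K)x - \omega_b^2 B = 0,\quad
#'     K = \frac{\sigma_i^2 + \omega_y^2 + \sigma_n^2\omega_b^2}{\sigma_n^2},}
#'   selected as the branch continuous in `B` with root 0 at `B = 0`. It does
#'   not depend on `alpha`, and its magnitude is maximized at intermediate
#'   `|B|`: past that point stronger environmental dependence of the optimum
#'   selects *against* plasticity, because badly mismatched extreme
#'   environments stop contributing to the response under hard selection.
#' * `approx_slope_wm_cv(params)` — weak mismatch (variation in mean fitness
#'   across environments dominated by `alpha`) with constant variance:
#'   \deqn{\mu_b^* = \frac{B\sigma_n^2\omega_b^2}{\sigma_n^2\omega_b^2\left(1 +
#'     \frac{\sigma_b^2\sigma_n^2\alpha^2}{\sigma_b^2+\omega_b^2}\right) +
#'     \sigma_i^2 + \omega_y^2}}
#'   — the only approximation whose slope depends on `alpha` (decreasing in
#'   magnitude as `alpha^2` grows).
#' * `approx_slope_wm_ssv(params)` — weak mismatch with little slope
#'   variance: `mu_b* = B sigma_n2 omega_b2 / (sigma_n2 omega_b2 + sigma_i2 +
#'   omega_y2)`, the classic soft-selection result.
#' * `approx_intercept_wm_cv(mu_b, params)` — weak mismatch with constant
#'   variance: `mu_i* = A + sigma_n2 alpha (B - mu_b omega_b2 / (sigma_b2 +
#'   omega_b2))`.
#'
#' All slope approximations are hypoplastic: `mu_b*` lies between 0 and `B`.
#'
#' @param mu_b Mean slope to condition on.
#' @param params A [model_params()] object.
#' @param method For `approx_slope_ssv`: `"cardano"` evaluates the closed-form
#'   radical expression (trigonometric branch when all three roots are real);
#'   `"polyroot"` solves the monic cubic numerically. The two agree to 1e-9
#'   and the admissible root is always verified against the hypoplasticity
#'   bound.
#' @return The approximate equilibrium mean (`mu_i*` or `mu_b*`).
#' @examples
#' p <- model_params()
#' mb <- approx_slope_ssv(p)
#' approx_intercept_ssv(mb, p)
#' approx_slope_wm_ssv(p)  # -20/41
#' @name equilibrium_approximations
NULL

#' @rdname equilibrium_approximations
#' @export
approx_intercept_cv <- function(mu_b, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  p <- params
  P <- p$sigma_b2 + p$omega_b2
  D <- (p$sigma_i2 + p$omega_y2) * P + p$sigma_b2 * p$omega_b2 * p$sigma_n2
  num <- p$B * P - p$omega_b2 * mu_b
  den <- P * D - p$sigma_n2 * p$sigma_b2^2 * mu_b^2
  p$A + p$sigma_n2 * p$alpha * D * num / den
}

#' @rdname equilibrium_approximations
#' @export
approx_intercept_ssv <- function(mu_b, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  params$A + params$sigma_n2 * params$alpha * (params$B - mu_b)
}

#' @rdname equilibrium_approximations
#' @export
approx_slope_ssv <- function(params, method = c("cardano", "polyroot")) {
  stopifnot(inherits(params, "plastinorm_params"))
  method <- match.arg(method)
  p <- params
  B <- p$B
  if (B == 0) return(0)
  K <- (p$sigma_i2 + p$omega_y2 + p$sigma_n2 * p$omega_b2) / p$sigma_n2
  # monic cubic x^3 + a2 x^2 + a1 x + a0
  a2 <- -2 * B
  a1 <- B^2 + K
  a0 <- -p$omega_b2 * B
  roots <- if (method == "cardano") {
    .cardano_roots(a2, a1, a0)
  } else {
    r <- polyroot(c(a0, a1, a2, 1))
    Re(r[abs(Im(r)) < 1e-7 * max(1, Mod(r))])
  }
  lo <- min(B, 0) - 1e-9
  hi <- max(B, 0) + 1e-9
  adm <- roots[roots >= lo & roots <= hi]
  if (!length(adm))
    stop("no admissible real root of the equilibrium-slope cubic in [",
         min(B, 0), ", ", max(B, 0), "] for B = ", B)
  # continuity with the B = 0 branch: take the root nearest zero
  x <- adm[which.min(abs(adm))]
  resid <- x^3 + a2 * x^2 + a1 * x + a0
  if (abs(resid) > 1e-6 * max(1, abs(a0)))
    stop("equilibrium-slope cubic root failed verification (residual ",
         format(resid), ")")
  x
}

# real roots of x^3 + a2 x^2 + a1 x + a0 via Cardano / Viete
.cardano_roots <- function(a2, a1, a0) {
  p <- a1 - a2^2 / 3
  q <- 2 * a2^3 / 27 - a2 * a1 / 3 + a0
  disc <- (q / 2)^2 + (p / 3)^3
  shift <- -a2 / 3
  if (disc >= 0) {
    s <- sqrt(disc)
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    t <- cbrt(-q / 2 + s) + cbrt(-q / 2 - s)
    return(t + shift)
  }
  # three real roots: trigonometric form
  r <- 2 * sqrt(-p / 3)
  phi <- acos(pmin(1, pmax(-1, 3 * q / (p * r))))
  t <- r * cos(phi / 3 - 2 * pi * (0:2) / 3)
  t + shift
}

#' @rdname equilibrium_approximations
#' @export
approx_slope_wm_cv <- function(params) {
  stopifnot(inherits(params, "plastinorm_params"))
  p <- params
  P <- p$sigma_b2 + p$omega_b2
  den <- p$sigma_n2 * p$omega_b2 *
    (1 + p$sigma_b2 * p$sigma_n2 * p$alpha^2 / P) +
    p$sigma_i2 + p$omega_y2
  p$B * p$sigma_n2 * p$omega_b2 / den
}

#' @rdname equilibrium_approximations
#' @export
approx_slope_wm_ssv <- function(params) {
  stopifnot(inherits(params, "plastinorm_params"))
  p <- params
  p$B * p$sigma_n2 * p$omega_b2 /
    (p$sigma_n2 * p$omega_b2 + p$sigma_i2 + p$omega_y2)
}

#' @rdname equilibrium_approximations
#' @export
approx_intercept_wm_cv <- function(mu_b, params) {
  stopifnot(inherits(params, "plastinorm_params"))
  p <- params
  p$A + p$sigma_n2 * p$alpha *
    (p$B - mu_b * p$omega_b2 / (p$sigma_b2 + p$omega_b2))
}

#' Numeric solution of the joint equilibrium conditions
#'
#' Finds the state where both fitness-weighted mean selection gradients
#' vanish, by damped fixed-point iteration of [total_response()] (mimicking
#' the evolutionary dynamics, so the stable equilibrium is reached) followed
#' by Newton polishing on the weighted gradients.
#'
#' Traits without genetic variance do not evolve: if `sigma_ab2 = 0` the
#' slope is held at its initial value and only the intercept condition is
#' solved (and vice versa). `B = 0` short-circuits to the known exact answer
#' `(A, 0)`; `alpha = 0` (with `rho_ib = 0`) pins the intercept at `A`, where
#' the weighted intercept gradient is an odd integral over the symmetric
#' nutrition density. Residuals are still computed honestly in these cases.
#'
#' @param params A [model_params()] object.
#' @param quad A [quadrature_spec()].
#' @param mode Variance mode, `"exact"` or `"constant"`.
#' @param init Initial state: a [population_state()], `c(mu_i, mu_b)`, or
#'   `"auto"` (the weak-mismatch closed forms).
#' @param damping Step factor of the fixed-point iteration.
#' @param grad_tol Convergence tolerance on the weighted gradients.
#' @param max_iter Iteration cap.
#' @return An object of class `plastinorm_equilibrium` with fields
#'   `mu_i_star`, `mu_b_star`, `method` (`"numeric_full"` or
#'   `"numeric_constant_variance"`), `converged`, `residual` (max absolute
#'   component of [total_response()] at the solution) and `iterations`.
#' @examples
#' solve_equilibrium_numeric(model_params(B = 0))
#' @export
solve_equilibrium_numeric <- function(params, quad = quadrature_spec(),
                                      mode = c("exact", "constant"),
                                      init = "auto", damping = 0.5,
                                      grad_tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(params, "plastinorm_params"))
  mode <- match.arg(mode)
  p <- params
  evolve_i <- p$sigma_ai2 > 0
  evolve_b <- p$sigma_ab2 > 0
  if (!evolve_i && !evolve_b)
    stop("no genetic variance in either trait; nothing evolves")
  if (evolve_i && evolve_b && abs(p$rho_ib) >= 1)
    stop("|genetic correlation| must be < 1 for a joint equilibrium")

  if (identical(init, "auto")) {
    mb0 <- if (evolve_b) approx_slope_wm_cv(p) else 0
    st <- c(approx_intercept_wm_cv(mb0, p), mb0)
  } else {
    s <- .as_state(init)
    st <- c(s$mu_i, s$mu_b)
  }

  # exact short-circuits (starting points only; residuals verified below)
  if (p$B == 0 && p$rho_ib == 0) {
    st <- c(p$A, if (evolve_b) 0 else st[2])
  }
  fix_i <- FALSE
  if (p$alpha == 0 && p$rho_ib == 0 && evolve_i) {
    st[1] <- p$A
    fix_i <- TRUE   # exact: odd integrand over symmetric f(n)
  }

  mask <- c(evolve_i && !fix_i, evolve_b)
  iter <- 0L
  if (any(mask)) {
    for (iter in seq_len(max_iter)) {
      state <- population_state(st[1], st[2])
      wg <- .weighted_gradients(state, p, quad, mode)
      if (max(abs(wg[mask])) < grad_tol) break
      resp <- c(p$sigma_ai2 * wg[1] + p$sigma_aib * wg[2],
                p$sigma_ab2 * wg[2] + p$sigma_aib * wg[1])
      st[mask] <- st[mask] + damping * resp[mask]
      if (iter %% 50 == 0 && any(!is.finite(st)))
        stop("equilibrium iteration diverged at iteration ", iter)
    }
    st <- .newton_polish(st, mask, p, quad, mode, grad_tol)
  }

  state <- population_state(st[1], st[2])
  wg <- .weighted_gradients(state, p, quad, mode)
  resp <- total_response(state, p, quad, mode)
  residual <- max(abs(resp))
  converged <- max(abs(wg[mask]), 0) < 1e-8 && residual < 1e-8
  if (!converged && any(mask))
    warning("equilibrium solver did not reach tolerance; residual = ",
            format(residual), " after ", iter, " iterations")
  structure(list(mu_i_star = st[1], mu_b_star = st[2],
                 method = if (mode == "exact") "numeric_full"
                          else "numeric_constant_variance",
                 converged = converged, residual = residual,
                 iterations = iter),
            class = "plastinorm_equilibrium")
}

# a few Newton steps on the weighted gradients, restricted to evolving traits
.newton_polish <- function(st, mask, p, quad, mode, tol, steps = 8,
                           h = 1e-7) {
  idx <- which(mask)
  for (k in seq_len(steps)) {
    g0 <- .weighted_gradients(population_state(st[1], st[2]), p, quad, mode)
    if (max(abs(g0[idx])) < tol / 10) break
    J <- matrix(0, length(idx), length(idx))
    for (j in seq_along(idx)) {
      stp <- st; stp[idx[j]] <- stp[idx[j]] + h
      gp <- .weighted_gradients(population_state(stp[1], stp[2]), p, quad,
                                mode)
      J[, j] <- (gp[idx] - g0[idx]) / h
    }
    step <- tryCatch(solve(J, -g0[idx]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    st[idx] <- st[idx] + step
  }
  st
}

#' @export
print.plastinorm_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (%s): mu_i* = %.8g, mu_b* = %.8g\n",
              x$method, x$mu_i_star, x$mu_b_star))
  cat(sprintf("  converged: %s, residual %.3g, %d iterations\n",
              x$converged, x$residual, x$iterations))
  invisible(x)
}

#' Equilibrium estimates along a parameter grid
#'
#' Evaluate one or more equilibrium methods across a sweep of `B` or `alpha`,
#' e.g. to regenerate the analytic curves of the B-sweep figure. Closed-form
#' labels: `"ssv"` (small-slope-variance cubic plus its intercept), `"wm_cv"`
#' and `"wm_ssv"` (weak-mismatch forms), `"cv"` (constant-variance intercept
#' conditioned on the ssv slope), and `"numeric"`
#' (full numeric solve). Failures at individual grid points are recorded
#' (`converged = FALSE`) rather than aborting the sweep.
#'
#' @param params A [model_params()] object (the non-swept values).
#' @param grid Numeric vector of swept values.
#' @param variable `"B"` or `"alpha"`.
#' @param methods Character vector of method labels (see Details).
#' @param quad Quadrature used by the `"numeric"` method.
#' @return A data frame with columns `method`, `B`, `alpha`, `mu_i_star`,
#'   `mu_b_star`, `residual`, `converged`.
#' @examples
#' equilibrium_curve(model_params(), grid = c(-2, -1, 0), methods = "ssv")
#' @export
equilibrium_curve <- function(params, grid, variable = c("B", "alpha"),
                              methods = c("ssv", "wm_cv", "wm_ssv"),
                              quad = quadrature_spec()) {
  stopifnot(inherits(params, "plastinorm_params"), length(grid) >= 1)
  variable <- match.arg(variable)
  known <- c("ssv", "wm_cv", "wm_ssv", "cv", "numeric")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (m in methods) {
    for (v in grid) {
      p <- if (variable == "B") update_params(params, B = v)
           else update_params(params, alpha = v)
      row <- data.frame(method = m, B = p$B, alpha = p$alpha,
                        mu_i_star = NA_real_, mu_b_star = NA_real_,
                        residual = NA_real_, converged = FALSE)
      ok <- tryCatch({
        if (m == "ssv") {
          mb <- approx_slope_ssv(p)
          row$mu_b_star <- mb
          row$mu_i_star <- approx_intercept_ssv(mb, p)
        } else if (m == "wm_cv") {
          mb <- approx_slope_wm_cv(p)
          row$mu_b_star <- mb
          row$mu_i_star <- approx_intercept_wm_cv(mb, p)
        } else if (m == "wm_ssv") {
          mb <- approx_slope_wm_ssv(p)
          row$mu_b_star <- mb
          row$mu_i_star <- approx_intercept_ssv(mb, p)
        } else if (m == "cv") {
          mb <- approx_slope_ssv(p)
          row$mu_b_star <- mb
          row$mu_i_star <- approx_intercept_cv(mb, p)
        } else {
          sol <- solve_equilibrium_numeric(p, quad)
          row$mu_b_star <- sol$mu_b_star
          row$mu_i_star <- sol$mu_i_star
          row$residual <- sol$residual
          row$converged <- sol$converged
        }
        TRUE
      }, error = function(e) FALSE)
      if (ok && m != "numeric") row$converged <- TRUE
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
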