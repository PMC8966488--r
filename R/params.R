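#' Model parameters
#'
#' Bundle and validate the fixed constants of the reaction-norm model. An
#' individual's breeding date is `y = i + b * n` where the intercept
#' `i = a_i + e_i` and plastic slope `b = a_b + e_b` each split into additive
#' genetic and environmental parts, and `n` is nutritional condition with mean
#' zero and variance `sigma_n2`. The optimal breeding date is `A + B * n` and
#' fitness is Gaussian around it with width `omega_y2`, multiplied by a
#' Gaussian cost of plasticity of width `omega_b2` and a log-linear direct
#' effect `exp(alpha * n)` of nutrition on fitness.
#'
#' @param A Optimal breeding date at `n = 0` (days).
#' @param B Slope of the optimum on nutrition (days per nutrition unit).
#' @param alpha Effect of nutrition on log fitness (per nutrition unit).
#' @param omega_y2 Width of stabilizing selection on breeding date (days^2);
#'   larger values mean weaker selection.
#' @param omega_b2 Width of direct selection against plasticity (slope
#'   units^2); larger values mean a cheaper plasticity. Use a large finite
#'   value such as `1e12` to represent "no cost".
#' @param sigma_n2 Variance of nutritional condition.
#' @param sigma_ai2,sigma_ei2 Additive-genetic and environmental variance of
#'   the intercept.
#' @param sigma_ab2,sigma_eb2 Additive-genetic and environmental variance of
#'   the slope.
#' @param rho_ib Correlation between intercept and slope, applied identically
#'   to the genetic and environmental parts.
#'
#' @return An object of class `plastinorm_params`: a list with the arguments
#'   plus the derived phenotypic variances `sigma_i2 = sigma_ai2 + sigma_ei2`,
#'   `sigma_b2 = sigma_ab2 + sigma_eb2` and covariances `sigma_aib`,
#'   `sigma_eib`, `sigma_ib`.
#'
#' @details The defaults are the reference parameterization used throughout
#'   the package's validation experiments: unit variances placed entirely on
#'   the genetic components (heritability one), `A = 0`, `B = -1`,
#'   `alpha = 1` and selection widths of 20.
#'
#' @examples
#' p <- model_params()
#' p$sigma_i2
#' model_params(B = 0, alpha = 0)
#' @export
model_params <- function(A = 0, B = -1, alpha = 1,
                         omega_y2 = 20, omega_b2 = 20,
                         sigma_n2 = 1,
                         sigma_ai2 = 1, sigma_ei2 = 0,
                         sigma_ab2 = 1, sigma_eb2 = 0,
                         rho_ib = 0) {
  p <- list(A = A, B = B, alpha = alpha,
            omega_y2 = omega_y2, omega_b2 = omega_b2,
            sigma_n2 = sigma_n2,
            sigma_ai2 = sigma_ai2, sigma_ei2 = sigma_ei2,
            sigma_ab2 = sigma_ab2, sigma_eb2 = sigma_eb2,
            rho_ib = rho_ib)
  for (nm in c("A", "B", "alpha", "omega_y2", "omega_b2", "sigma_n2",
               "sigma_ai2", "sigma_ei2", "sigma_ab2", "sigma_eb2", "rho_ib")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (omega_y2 <= 0 || omega_b2 <= 0)
    stop("selection widths omega_y2 and omega_b2 must be strictly positive")
  if (sigma_n2 <= 0)
    stop("sigma_n2 must be strictly positive")
  if (min(sigma_ai2, sigma_ei2, sigma_ab2, sigma_eb2) < 0)
    stop("variance components must be non-negative")
  if (abs(rho_ib) >= 1)
    stop("|rho_ib| must be < 1")
  p$sigma_i2 <- sigma_ai2 + sigma_ei2
  p$sigma_b2 <- sigma_ab2 + sigma_eb2
  p$sigma_aib <- rho_ib * sqrt(sigma_ai2 * sigma_ab2)
  p$sigma_eib <- rho_ib * sqrt(sigma_ei2 * sigma_eb2)
  p$sigma_ib <- p$sigma_aib + p$sigma_eib
  class(p) <- "plastinorm_params"
  p
}

#' @export
print.plastinorm_params <- function(x, ...) {
  cat("Reaction-norm model parameters\n")
  cat(sprintf("  optimum:    theta(n) = %g %+g n   (omega_y2 = %g)\n",
              x$A, x$B, x$omega_y2))
  cat(sprintf("  plasticity cost width omega_b2 = %g\n", x$omega_b2))
  cat(sprintf("  nutrition:  sigma_n2 = %g, alpha = %g\n", x$sigma_n2, x$alpha))
  cat(sprintf("  intercept:  sigma_i2 = %g (genetic %g, environmental %g)\n",
              x$sigma_i2, x$sigma_ai2, x$sigma_ei2))
  cat(sprintf("  slope:      sigma_b2 = %g (genetic %g, environmental %g)\n",
              x$sigma_b2, x$sigma_ab2, x$sigma_eb2))
  cat(sprintf("  intercept-slope correlation rho_ib = %g\n", x$rho_ib))
  invisible(x)
}

#' Update a parameter set
#'
#' Return a copy of `params` with the named fields replaced and all derived
#' quantities recomputed.
#'
#' @param params A [model_params()] object.
#' @param ... Named primary fields to change (e.g. `B = -2`, `alpha = 0`).
#' @return A new `plastinorm_params` object.
#' @examples
#' update_params(model_params(), B = -2, alpha = 0)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "plastinorm_params"))
  repl <- list(...)
  keep <- c("A", "B", "alpha", "omega_y2", "omega_b2", "sigma_n2",
            "sigma_ai2", "sigma_ei2", "sigma_ab2", "sigma_eb2", "rho_ib")
  bad <- setdiff(names(repl), keep)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  args <- unclass(params)[keep]
  args[names(repl)] <- repl
  do.call(model_params, args)
}

#' Read model parameters from a flat key-value config file
#'
#' The file holds one `key = value` (or `key value`, `key: value`) pair per
#' line; `#` starts a comment. Recognised keys are exactly the primary
#' arguments of [model_params()]; missing keys take their defaults.
#'
#' @param path Path to the config file.
#' @return A `plastinorm_params` object.
#' @examples
#' cfg <- system.file("extdata", "reference-params.cfg", package = "plastinorm")
#' read_params_config(cfg)
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:[:space:]]+")[[1]]
    kv <- kv[nzchar(kv)]
    if (length(kv) != 2L)
      stop("cannot parse config line: '", ln, "'")
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val)) stop("non-numeric value in config line: '", ln, "'")
    args[[kv[1]]] <- val
  }
  known <- c("A", "B", "alpha", "omega_y2", "omega_b2", "sigma_n2",
             "sigma_ai2", "sigma_ei2", "sigma_ab2", "sigma_eb2", "rho_ib")
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(model_params, args)
}

#' Population state: the evolving trait means
#'
#' @param mu_i Mean reaction-norm intercept (days).
#' @param mu_b Mean reaction-norm slope (days per nutrition unit).
#' @return An object of class `plastinorm_state`.
#' @examples
#' population_state(0, -0.5)
#' @export
population_state <- function(mu_i = 0, mu_b = 0) {
  if (!is.finite(mu_i) || !is.finite(mu_b))
    stop("state means must be finite")
  structure(list(mu_i = mu_i, mu_b = mu_b), class = "plastinorm_state")
}

#' @export
print.plastinorm_state <- function(x, ...) {
  cat(sprintf("Population state: mu_i = %g, mu_b = %g\n", x$mu_i, x$mu_b))
  invisible(x)
}

#' Quadrature rule for expectations over the nutrition distribution
#'
#' Integrals over environments weight by the Gaussian nutrition density
#' `f(n) ~ N(0, sigma_n2)`. They are evaluated by Gauss-Hermite quadrature;
#' the rule is built once and reused.
#'
#' @param nodes Number of Gauss-Hermite nodes (>= 16; default 64).
#' @param range_sd Minimum span of the node range, in standard deviations of
#'   `n` (>= 6). The rule is rejected if its outermost nodes cover less.
#' @return An object of class `plastinorm_quadrature` carrying standardized
#'   nodes `x` (multiply by `sqrt(sigma_n2)` for nutrition values) and
#'   normalized weights `w` summing to one.
#' @examples
#' q <- quadrature_spec(64)
#' sum(q$w)
#' @export
quadrature_spec <- function(nodes = 64, range_sd = 8) {
  if (nodes < 16) stop("quadrature needs at least 16 nodes")
  gh <- pracma::gaussHermite(nodes)
  # transform from weight exp(-x^2) to the standard normal density
  x <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  if (max(x) < range_sd)
    stop("quadrature rule spans only ", round(max(x), 2),
         " SD; need at least ", range_sd,
         " (increase 'nodes' or lower 'range_sd')")
  structure(list(scheme = "gauss-hermite", nodes = nodes,
                 range_sd = range_sd, x = x, w = w),
            class = "plastinorm_quadrature")
}

#' @export
print.plastinorm_quadrature <- function(x, ...) {
  cat(sprintf("%s quadrature: %d nodes spanning %.1f SD\n",
              x$scheme, x$nodes, max(x$x)))
  invisible(x)
}

# coerce a state argument that may be given as c(mu_i, mu_b)
.as_state <- function(state) {
  if (inherits(state, "plastinorm_state")) return(state)
  if (is.numeric(state) && length(state) == 2L)
    return(population_state(state[1], state[2]))
  stop("'state' must be a population_state or a numeric vector c(mu_i, mu_b)")
}
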