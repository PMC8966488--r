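#' Simulation configuration
#'
#' Settings for the individual-based Wright-Fisher simulation. The defaults
#' are the full validation protocol: 10,000 individuals (equal sexes) evolved
#' for 10,000 generations, with the equilibrium estimated as the average
#' intercept and slope over the final 5,000 generations. Heritabilities are
#' carried by the variance split in [model_params()] (the defaults put all
#' variance on the genetic components, i.e. heritability one, which speeds up
#' equilibration without changing the equilibrium, since only the phenotypic
#' (co)variances matter there).
#'
#' @param pop_size Number of individuals (even; half female, half male).
#' @param generations Number of generations to evolve.
#' @param window Number of final generations averaged for the equilibrium
#'   estimate (<= `generations`).
#' @param seed Master RNG seed (integer).
#' @param init Initial means: `"auto"` (the small-slope-variance analytic
#'   equilibrium) or `c(mu_i, mu_b)`.
#' @param block_size Block length (generations) for the block-bootstrap
#'   Monte-Carlo standard errors, chosen to exceed the autocorrelation time
#'   of the trait means.
#' @return An object of class `plastinorm_sim_config`.
#' @examples
#' sim_config(pop_size = 2000, generations = 3000, window = 1500)
#' @export
sim_config <- function(pop_size = 10000, generations = 10000,
                       window = 5000, seed = 1, init = "auto",
                       block_size = 100) {
  if (pop_size %% 2 != 0 || pop_size < 4)
    stop("pop_size must be an even number >= 4")
  if (window > generations)
    stop("averaging window cannot exceed the number of generations")
  if (!identical(init, "auto")) {
    init <- as.numeric(init)
    if (length(init) != 2L || any(!is.finite(init)))
      stop("init must be \"auto\" or c(mu_i, mu_b)")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 window = as.integer(window),
                 seed = as.integer(seed), init = init,
                 block_size = as.integer(block_size)),
            class = "plastinorm_sim_config")
}

# closed-form 2x2 Cholesky draw; tolerates zero variances (which chol() does
# not), as needed for configurations with a fixed slope
.rbvn <- function(n, mean1, mean2, v1, v2, cv) {
  if (v1 < 0 || v2 < 0 || (v1 * v2 > 0 && cv^2 >= v1 * v2))
    stop("covariance matrix is not positive semi-definite")
  l11 <- sqrt(v1)
  l21 <- if (l11 > 0) cv / l11 else 0
  l22 <- sqrt(max(v2 - l21^2, 0))
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  list(x = mean1 + l11 * z1, y = mean2 + l21 * z1 + l22 * z2)
}

.init_means <- function(params, config) {
  if (identical(config$init, "auto")) {
    mb <- if (params$sigma_b2 > 0 || params$B != 0)
      approx_slope_ssv(params) else 0
    c(approx_intercept_ssv(mb, params), mb)
  } else config$init
}

#' Initialize a population
#'
#' Breeding values of intercept and slope are drawn from a bivariate normal
#' with means equal to the initial means and covariance equal to the genetic
#' (co)variances; environmental deviations and nutritional condition are
#' drawn from independent zero-mean normals with the configured variances.
#' Sexes are split exactly 50/50 (the first half of each array is female).
#'
#' @param params A [model_params()] object.
#' @param config A [sim_config()]. Its `seed` is *not* applied here; callers
#'   that need reproducibility should set the RNG state (as
#'   [run_simulation()] does) before calling.
#' @return An object of class `plastinorm_population`: parallel vectors
#'   `a_i`, `a_b`, `e_i`, `e_b`, `n`, `female`, derived phenotypes `i`, `b`,
#'   `y` (with `y = i + b * n` holding exactly), and a `generation` counter.
#' @examples
#' set.seed(1)
#' pop <- initialize_population(model_params(), sim_config(pop_size = 100,
#'   generations = 10, window = 5))
#' mean(pop$y)
#' @export
initialize_population <- function(params, config) {
  stopifnot(inherits(params, "plastinorm_params"),
            inherits(config, "plastinorm_sim_config"))
  N <- config$pop_size
  mu <- .init_means(params, config)
  a <- .rbvn(N, mu[1], mu[2], params$sigma_ai2, params$sigma_ab2,
             params$sigma_aib)
  e <- .rbvn(N, 0, 0, params$sigma_ei2, params$sigma_eb2, params$sigma_eib)
  n <- rnorm(N, 0, sqrt(params$sigma_n2))
  pop <- list(a_i = a$x, a_b = a$y, e_i = e$x, e_b = e$y, n = n,
              female = rep(c(TRUE, FALSE), each = N / 2L),
              generation = 0L)
  .derive_phenotypes(pop)
}

.derive_phenotypes <- function(pop) {
  pop$i <- pop$a_i + pop$e_i
  pop$b <- pop$a_b + pop$e_b
  pop$y <- pop$i + pop$b * pop$n
  pop
}

#' Advance the population by one generation
#'
#' Fitness is computed for every individual from its breeding date, slope and
#' nutrition. Each of the N offspring draws one mother from the females and
#' one father from the males, with replacement and probability proportional
#' to absolute fitness. Offspring breeding values are normal around the
#' midparent value with covariance equal to half the genetic (co)variances
#' (infinitesimal model; inbreeding ignored). Environmental deviations and
#' nutrition are drawn fresh, and sexes are reassigned as an exact 50/50
#' split.
#'
#' @param pop A `plastinorm_population`.
#' @param params A [model_params()] object.
#' @return The next-generation `plastinorm_population`.
#' @examples
#' set.seed(1)
#' p <- model_params()
#' pop <- initialize_population(p, sim_config(pop_size = 200,
#'   generations = 10, window = 5))
#' pop2 <- advance_generation(pop, p)
#' pop2$generation
#' @export
advance_generation <- function(pop, params) {
  N <- length(pop$a_i)
  half <- N %/% 2L
  w <- individual_fitness(pop$y, pop$b, pop$n, params)
  if (!any(w > 0))
    stop("all fitnesses are zero (numerical underflow) at generation ",
         pop$generation, "; mean phenotype may have diverged")
  mothers <- sample.int(half, N, replace = TRUE, prob = w[seq_len(half)])
  fathers <- half + sample.int(half, N, replace = TRUE,
                               prob = w[half + seq_len(half)])
  seg <- .rbvn(N, 0, 0, params$sigma_ai2 / 2, params$sigma_ab2 / 2,
               params$sigma_aib / 2)
  e <- .rbvn(N, 0, 0, params$sigma_ei2, params$sigma_eb2, params$sigma_eib)
  pop$a_i <- (pop$a_i[mothers] + pop$a_i[fathers]) / 2 + seg$x
  pop$a_b <- (pop$a_b[mothers] + pop$a_b[fathers]) / 2 + seg$y
  pop$e_i <- e$x
  pop$e_b <- e$y
  pop$n <- rnorm(N, 0, sqrt(params$sigma_n2))
  pop$generation <- pop$generation + 1L
  .derive_phenotypes(pop)
}

#' Block-bootstrap standard error of a time-series mean
#'
#' Standard error of `mean(x)` for an autocorrelated series, by resampling
#' contiguous blocks with replacement. Used for the Monte-Carlo error of
#' window-averaged trait means.
#'
#' @param x Numeric series (e.g. per-generation trait means over the
#'   averaging window).
#' @param block_size Block length; should exceed the autocorrelation time.
#' @param n_boot Number of bootstrap resamples.
#' @return Estimated standard error of `mean(x)`.
#' @examples
#' set.seed(1)
#' block_bootstrap_se(arima.sim(list(ar = 0.9), 2000), block_size = 100)
#' @export
block_bootstrap_se <- function(x, block_size = 100, n_boot = 1000) {
  nb <- length(x) %/% block_size
  if (nb < 2) stop("need at least two full blocks")
  bm <- colMeans(matrix(x[seq_len(nb * block_size)], nrow = block_size))
  boots <- vapply(seq_len(n_boot), function(k)
    mean(bm[sample.int(nb, nb, replace = TRUE)]), numeric(1))
  stats::sd(boots)
}

#' Run an individual-based simulation
#'
#' Evolves a population under the model for `config$generations` generations
#' and estimates the equilibrium means as the average intercept and slope
#' over the final `config$window` generations. Fully deterministic given
#' `config$seed`.
#'
#' @param params A [model_params()] object.
#' @param config A [sim_config()].
#' @param trajectory If `TRUE` (default) return the per-generation means.
#' @return A list of class `plastinorm_sim` with elements `mu_i`, `mu_b`
#'   (window-averaged equilibrium estimates), `se_mu_i`, `se_mu_b`
#'   (block-bootstrap Monte-Carlo SEs), `trajectory` (data frame
#'   `generation`, `mu_i`, `mu_b`, or `NULL`), `params` and `config`.
#' @examples
#' res <- run_simulation(model_params(),
#'   sim_config(pop_size = 200, generations = 200, window = 100, seed = 1))
#' res$mu_b
#' @export
run_simulation <- function(params, config, trajectory = TRUE) {
  stopifnot(inherits(params, "plastinorm_params"),
            inherits(config, "plastinorm_sim_config"))
  set.seed(config$seed)
  pop <- initialize_population(params, config)
  G <- config$generations
  mi <- numeric(G)
  mb <- numeric(G)
  for (g in seq_len(G)) {
    pop <- advance_generation(pop, params)
    mi[g] <- mean(pop$i)
    mb[g] <- mean(pop$b)
  }
  win <- seq.int(G - config$window + 1L, G)
  bs <- min(config$block_size, config$window %/% 2L)
  out <- list(mu_i = mean(mi[win]), mu_b = mean(mb[win]),
              se_mu_i = block_bootstrap_se(mi[win], bs),
              se_mu_b = block_bootstrap_se(mb[win], bs),
              trajectory = if (trajectory)
                data.frame(generation = seq_len(G), mu_i = mi, mu_b = mb),
              params = params, config = config)
  class(out) <- "plastinorm_sim"
  out
}

#' @export
print.plastinorm_sim <- function(x, ...) {
  cat(sprintf(paste0("Simulation (N = %d, %d generations, window %d):\n",
                     "  mu_i = %.4f (MC-SE %.4f)\n",
                     "  mu_b = %.4f (MC-SE %.4f)\n"),
              x$config$pop_size, x$config$generations, x$config$window,
              x$mu_i, x$se_mu_i, x$mu_b, x$se_mu_b))
  invisible(x)
}

# deterministic per-replicate seed from (master seed, grid value, replicate),
# independent of execution order; stays below 2^31 - 1
.derive_seed <- function(master, value, replicate) {
  s <- paste(master, format(value, digits = 12), replicate, sep = "|")
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(s)) {
    h <- (h * 16777 + code) %% 2147483647
  }
  as.integer(max(h, 1))
}

#' Sweep a model parameter across a grid of simulations
#'
#' Runs [run_simulation()] for every combination of grid value and replicate,
#' deriving a deterministic per-run seed from the master seed, the grid value
#' and the replicate index (so results do not depend on execution order).
#' Failures at individual points are recorded and the sweep continues.
#'
#' @param params A [model_params()] object; the swept field is overwritten
#'   per grid point.
#' @param config A [sim_config()] shared by all runs (its `seed` is the
#'   master seed).
#' @param variable `"B"` or `"alpha"`.
#' @param grid Numeric vector of swept values.
#' @param replicates Replicate runs per grid value.
#' @return A data frame with one row per (grid value, replicate): `variable`,
#'   `value`, `replicate`, `seed`, `mu_i`, `mu_b`, `se_mu_i`, `se_mu_b`,
#'   `ok`.
#' @examples
#' sweep_simulation(model_params(), sim_config(pop_size = 100,
#'   generations = 50, window = 20, block_size = 10), "B", c(0, -1), 1)
#' @export
sweep_simulation <- function(params, config, variable = c("B", "alpha"),
                             grid, replicates = 1) {
  stopifnot(inherits(params, "plastinorm_params"),
            inherits(config, "plastinorm_sim_config"), length(grid) >= 1)
  variable <- match.arg(variable)
  rows <- vector("list", length(grid) * replicates)
  k <- 0L
  for (v in grid) {
    p <- if (variable == "B") update_params(params, B = v)
         else update_params(params, alpha = v)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      seed <- .derive_seed(config$seed, v, r)
      cfg <- config
      cfg$seed <- seed
      row <- data.frame(variable = variable, value = v, replicate = r,
                        seed = seed, mu_i = NA_real_, mu_b = NA_real_,
                        se_mu_i = NA_real_, se_mu_b = NA_real_, ok = FALSE)
      res <- tryCatch(run_simulation(p, cfg, trajectory = FALSE),
                      error = function(e) e)
      if (!inherits(res, "error")) {
        row$mu_i <- res$mu_i; row$mu_b <- res$mu_b
        row$se_mu_i <- res$se_mu_i; row$se_mu_b <- res$se_mu_b
        row$ok <- TRUE
      } else {
        warning("sweep point ", variable, " = ", v, ", replicate ", r,
                " failed: ", conditionMessage(res))
      }
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
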