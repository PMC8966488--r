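# Independent numerical oracles used across the test files.

ref_params <- function(...) model_params(...)  # defaults = reference set

# Brute-force mean fitness in environment n: 2-D Gauss-Hermite integration of
# the fitness function over the bivariate Gaussian phenotype distribution
# (intercept, slope), supporting correlation. Independent of the closed form.
wbar_2d_oracle <- function(n, state, params, nodes = 80) {
  p <- params
  gh <- pracma::gaussHermite(nodes)
  si <- sqrt(p$sigma_i2); sb <- sqrt(p$sigma_b2)
  rho <- if (si > 0 && sb > 0) p$sigma_ib / (si * sb) else 0
  total <- 0
  for (k in seq_along(gh$x)) {
    z1 <- sqrt(2) * gh$x[k]
    z2 <- sqrt(2) * gh$x
    i <- state$mu_i + si * z1
    b <- state$mu_b + sb * (rho * z1 + sqrt(1 - rho^2) * z2)
    y <- i + b * n
    theta <- p$A + p$B * n
    w <- exp(p$alpha * n - (theta - y)^2 / (2 * p$omega_y2) -
               b^2 / (2 * p$omega_b2))
    total <- total + gh$w[k] * sum(gh$w * w)
  }
  total / pi
}

# Central finite difference of log mean fitness wrt a state mean.
fd_gradient <- function(n, state, params, wrt = c("mu_i", "mu_b"),
                        mode = "exact", h = 1e-6) {
  wrt <- match.arg(wrt)
  bump <- function(s) {
    st <- state
    st[[wrt]] <- st[[wrt]] + s
    population_state(st$mu_i, st$mu_b)
  }
  (env_mean_fitness(n, bump(h), params, mode, log = TRUE) -
     env_mean_fitness(n, bump(-h), params, mode, log = TRUE)) / (2 * h)
}

# Fitness-weighted mean gradients via explicit Gauss-Hermite sums over the
# nutrition density, assembled from exported pieces only.
weighted_gradient_oracle <- function(state, params, mode = "exact",
                                     nodes = 200) {
  q <- quadrature_spec(nodes)
  n <- sqrt(params$sigma_n2) * q$x
  Wn <- env_mean_fitness(n, state, params, mode)
  wt <- q$w * Wn / sum(q$w * Wn)
  c(bi = sum(wt * selection_gradient_intercept(n, state, params, mode)),
    bb = sum(wt * selection_gradient_slope(n, state, params, mode)))
}

# Weak-mismatch joint solve: weight environments by exp(alpha*n) f(n) only,
# with the constant-variance gradient numerators; independent oracle for the
# weak-mismatch closed forms.
wm_oracle <- function(params, nodes = 200) {
  p <- params
  q <- quadrature_spec(nodes)
  n <- sqrt(p$sigma_n2) * q$x
  wt <- q$w * exp(p$alpha * n)
  wt <- wt / sum(wt)
  P <- p$sigma_b2 + p$omega_b2
  mu_i_of <- function(mu_b) {
    # E_w[(A + Bn - mu_i - mu_b n) P + sigma_b2 mu_b n] = 0, linear in mu_i
    En <- sum(wt * n)
    p$A + (p$B - mu_b) * En + p$sigma_b2 * mu_b * En / P
  }
  slope_cond <- function(mu_b) {
    mu_i <- mu_i_of(mu_b)
    m <- (p$A + p$B * n) - mu_i - mu_b * n
    sum(wt * (m * n * p$omega_b2 - mu_b * (p$sigma_i2 + p$omega_y2)))
  }
  mu_b <- uniroot(slope_cond, c(min(p$B, 0) - 1, max(p$B, 0) + 1),
                  tol = 1e-13)$root
  c(mu_i = mu_i_of(mu_b), mu_b = mu_b)
}

# Average one-generation change of mean breeding values across simulator
# replicates started from the same displaced state.
one_generation_mc <- function(params, init, n_reps, pop_size = 10000,
                              seed = 1) {
  cfg <- sim_config(pop_size = pop_size, generations = 1, window = 1,
                    init = init, seed = seed)
  out <- matrix(NA_real_, n_reps, 2)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    pop <- initialize_population(params, cfg)
    m0 <- c(mean(pop$a_i), mean(pop$a_b))
    pop <- advance_generation(pop, params)
    out[r, ] <- c(mean(pop$a_i), mean(pop$a_b)) - m0
  }
  list(mean = colMeans(out), se = apply(out, 2, sd) / sqrt(n_reps))
}

# Aggregate simulation sweep rows per grid value: replicate-mean and pooled SE.
aggregate_cells <- function(tab) {
  vals <- unique(tab$value)
  do.call(rbind, lapply(vals, function(v) {
    sel <- tab$ok & tab$value == v
    data.frame(value = v, mu_i = mean(tab$mu_i[sel]),
               mu_b = mean(tab$mu_b[sel]),
               se_mu_i = sqrt(sum(tab$se_mu_i[sel]^2)) / sum(sel),
               se_mu_b = sqrt(sum(tab$se_mu_b[sel]^2)) / sum(sel))
  }))
}

# Random moderate-regime parameter draws (weak-to-moderate selection, the
# regime of the model's validation experiments).
random_params <- function(n_draws, seed, B_range = c(-4, -0.1),
                          alpha_range = c(0.1, 1)) {
  set.seed(seed)
  lapply(seq_len(n_draws), function(k) {
    model_params(
      A = runif(1, -2, 2),
      B = runif(1, B_range[1], B_range[2]),
      alpha = runif(1, alpha_range[1], alpha_range[2]),
      omega_y2 = runif(1, 10, 50),
      omega_b2 = runif(1, 10, 50),
      sigma_n2 = runif(1, 0.5, 2),
      sigma_ai2 = runif(1, 0.25, 2),
      sigma_ab2 = runif(1, 0.25, 2))
  })
}
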