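test_that("parameter construction validates inputs and derives variances", {
  p <- model_params(sigma_ai2 = 0.6, sigma_ei2 = 0.4,
                    sigma_ab2 = 0.5, sigma_eb2 = 0.5, rho_ib = 0.3)
  expect_equal(p$sigma_i2, 1)
  expect_equal(p$sigma_b2, 1)
  expect_equal(p$sigma_ib, 0.3 * (sqrt(0.6 * 0.5) + sqrt(0.4 * 0.5)))
  expect_error(model_params(omega_y2 = 0), "positive")
  expect_error(model_params(sigma_n2 = -1), "positive")
  expect_error(model_params(rho_ib = 1), "rho_ib")
  expect_error(model_params(sigma_ab2 = -0.1), "non-negative")
})

test_that("config files round-trip into parameter objects", {
  cfg <- system.file("extdata", "reference-params.cfg",
                     package = "plastinorm")
  p <- read_params_config(cfg)
  expect_equal(p$B, -1)
  expect_equal(p$omega_y2, 20)
  expect_equal(p$sigma_i2, 1)
  tmp <- tempfile()
  writeLines(c("A = 1", "bogus = 2"), tmp)
  expect_error(read_params_config(tmp), "unknown config key")
})

test_that("quadrature rule is normalized and guards its range", {
  q <- quadrature_spec(64)
  expect_equal(sum(q$w), 1, tolerance = 1e-12)
  expect_equal(sum(q$w * q$x^2), 1, tolerance = 1e-10)  # unit variance
  expect_error(quadrature_spec(8), "at least 16")
  expect_error(quadrature_spec(16, range_sd = 10), "spans only")
})

test_that("optimum and individual fitness follow their defining formulas", {
  p <- model_params(A = 0, B = -1)
  expect_equal(optimal_breeding_date(0, p), 0)
  expect_equal(optimal_breeding_date(2, p), -2)
  expect_equal(optimal_breeding_date(-1, model_params(A = 5, B = -3)), 8)

  expect_equal(individual_fitness(optimal_breeding_date(0, p), 0, 0, p), 1)
  expect_equal(individual_fitness(optimal_breeding_date(1, p), 0, 1, p),
               exp(1))
  # mismatch of 2 days under width 20 costs a factor exp(-0.1)
  expect_equal(individual_fitness(2, 0, 0, model_params(A = 0, B = 0)),
               exp(-0.1))
})

test_that("environment mean fitness matches brute-force 2-D integration", {
  cases <- list(
    list(p = ref_params(), st = population_state(0, 0), n = 0),
    list(p = ref_params(), st = population_state(0.3, -0.4), n = 0.7),
    list(p = ref_params(B = -2, alpha = 0.5),
         st = population_state(-0.5, -0.8), n = -1.6),
    list(p = ref_params(sigma_ai2 = 0.7, sigma_ei2 = 0.3,
                        sigma_ab2 = 0.4, sigma_eb2 = 0.6, rho_ib = 0.5),
         st = population_state(0.2, -0.3), n = 1.1))
  for (cs in cases) {
    expect_equal(env_mean_fitness(cs$n, cs$st, cs$p),
                 wbar_2d_oracle(cs$n, cs$st, cs$p),
                 tolerance = 1e-8)
  }
})

test_that("mean fitness has the expected degenerate limits", {
  # flat optimum, population exactly on it, no plasticity, no direct effect
  p0 <- model_params(B = 0, alpha = 0, sigma_ai2 = 0, sigma_ab2 = 0)
  expect_equal(env_mean_fitness(1.7, population_state(p0$A, 0), p0), 1)
  # only the alpha*n term survives when the phenotype tracks the optimum
  p1 <- model_params(B = -1, alpha = 1, sigma_ai2 = 0, sigma_ab2 = 0,
                     omega_b2 = 1e12)
  expect_equal(env_mean_fitness(1, population_state(p1$A + p1$B, 0), p1),
               exp(1), tolerance = 1e-10)
  expect_true(all(env_mean_fitness(c(-3, 0, 3),
                                   population_state(5, -2),
                                   ref_params()) > 0))
})

test_that("closed-form gradients agree with finite differences of log mean fitness", {
  set.seed(42)
  for (k in 1:100) {
    p <- model_params(A = runif(1, -2, 2), B = runif(1, -4, 0),
                      alpha = runif(1, 0, 1),
                      omega_y2 = runif(1, 5, 50),
                      omega_b2 = runif(1, 5, 50),
                      sigma_n2 = runif(1, 0.5, 2),
                      sigma_ai2 = runif(1, 0.2, 2),
                      sigma_ab2 = runif(1, 0.2, 2))
    st <- population_state(runif(1, -2, 2), runif(1, -1.5, 0.5))
    n <- runif(1, -2.5, 2.5)
    expect_lt(abs(selection_gradient_intercept(n, st, p) -
                    fd_gradient(n, st, p, "mu_i")), 1e-6)
    expect_lt(abs(selection_gradient_slope(n, st, p) -
                    fd_gradient(n, st, p, "mu_b")), 1e-6)
  }
})

test_that("gradients vanish and sign correctly in the anchor cases", {
  p <- ref_params()
  # population mean at the optimum of the average environment
  expect_equal(selection_gradient_intercept(0, population_state(p$A, 0.3), p),
               0)
  expect_equal(selection_gradient_slope(0, population_state(p$A, 0), p), 0)
  # pure cost of plasticity: negative slope gradient at n = 0
  expect_lt(selection_gradient_slope(0, population_state(p$A, 1), p), 0)
  # univariate Gaussian-fitness limit: (theta - mu)/(sigma^2 + omega^2)
  pu <- model_params(A = 0, B = 0, sigma_ab2 = 0, sigma_eb2 = 0,
                     omega_b2 = 1e12)
  expect_equal(selection_gradient_intercept(0, population_state(-1, 0), pu),
               1 / (pu$sigma_i2 + pu$omega_y2), tolerance = 1e-9)
})

test_that("closed-form gradients refuse nonzero correlation but the finite-difference path handles it", {
  p <- model_params(rho_ib = 0.5)
  st <- population_state(0.4, -0.3)
  expect_error(selection_gradient_slope(1, st, p, method = "closed_form"),
               "rho_ib")
  # auto path falls back to finite differences and matches the oracle
  expect_equal(selection_gradient_intercept(1.2, st, p),
               fd_gradient(1.2, st, p, "mu_i"), tolerance = 1e-8)
})

test_that("per-environment response is the G-matrix product of the gradients", {
  p <- model_params(sigma_ai2 = 0.8, sigma_ab2 = 0.5, rho_ib = 0.4)
  st <- population_state(0.3, -0.6)
  n <- c(-1.5, 0, 2)
  r <- response_in_environment(n, st, p)
  bi <- selection_gradient_intercept(n, st, p)
  bb <- selection_gradient_slope(n, st, p)
  G <- matrix(c(p$sigma_ai2, p$sigma_aib, p$sigma_aib, p$sigma_ab2), 2)
  for (k in seq_along(n)) {
    expect_equal(c(r$d_mu_i[k], r$d_mu_b[k]),
                 as.numeric(G %*% c(bi[k], bb[k])), tolerance = 1e-12)
  }
  # no genetic variance, no response
  p0 <- model_params(sigma_ai2 = 0, sigma_ei2 = 1, sigma_ab2 = 0,
                     sigma_eb2 = 1)
  r0 <- response_in_environment(1, st, p0)
  expect_equal(unname(r0$d_mu_i), 0)
  expect_equal(unname(r0$d_mu_b), 0)
})

test_that("global mean fitness matches closed limits and adaptive integration", {
  # with selection off, Wbar is the lognormal mean of exp(alpha n)
  poff <- model_params(omega_y2 = 1e12, omega_b2 = 1e12, alpha = 1)
  expect_equal(global_mean_fitness(population_state(0, 0), poff),
               exp(0.5), tolerance = 1e-8)
  # neutral degenerate population has fitness exactly one everywhere
  p0 <- model_params(B = 0, alpha = 0, sigma_ai2 = 0, sigma_ab2 = 0)
  expect_equal(global_mean_fitness(population_state(p0$A, 0), p0), 1,
               tolerance = 1e-10)
  # adaptive quadrature oracle
  p <- ref_params()
  st <- population_state(0, -0.5)
  oracle <- integrate(function(n)
    env_mean_fitness(n, st, p) * dnorm(n, 0, sqrt(p$sigma_n2)),
    -12 * sqrt(p$sigma_n2), 12 * sqrt(p$sigma_n2), rel.tol = 1e-12)$value
  expect_equal(global_mean_fitness(st, p), oracle, tolerance = 1e-9)
})

test_that("hard-selection weights integrate to one", {
  set.seed(7)
  q <- quadrature_spec(64)
  for (k in 1:20) {
    p <- ref_params(B = runif(1, -4, 0), alpha = runif(1, 0, 1))
    st <- population_state(runif(1, -2, 2), runif(1, -1, 0.5))
    n <- sqrt(p$sigma_n2) * q$x
    Wn <- env_mean_fitness(n, st, p)
    Wg <- global_mean_fitness(st, p, q, check = FALSE)
    expect_equal(sum(q$w * Wn / Wg), 1, tolerance = 1e-8)
  }
})

test_that("total response reduces to the soft-selection average when mean fitness is flat", {
  # alpha = 0 and a perfectly tracking mean make Wbar(n) constant in the
  # constant-variance mode
  p <- model_params(alpha = 0)
  st <- population_state(p$A, p$B)
  q <- quadrature_spec(64)
  n <- sqrt(p$sigma_n2) * q$x
  lw <- env_mean_fitness(n, st, p, mode = "constant", log = TRUE)
  expect_lt(diff(range(lw)), 1e-12)
  tr <- total_response(st, p, q, mode = "constant")
  r <- response_in_environment(n, st, p, mode = "constant")
  expect_equal(unname(tr["d_mu_i"]), sum(q$w * r$d_mu_i), tolerance = 1e-8)
  expect_equal(unname(tr["d_mu_b"]), sum(q$w * r$d_mu_b), tolerance = 1e-8)
})

test_that("with symmetric selection the intercept response is odd in the displacement", {
  p <- model_params(B = 0, alpha = 0)
  up <- total_response(population_state(p$A + 0.8, 0), p)
  dn <- total_response(population_state(p$A - 0.8, 0), p)
  at <- total_response(population_state(p$A, 0), p)
  expect_lt(up["d_mu_i"], 0)
  expect_gt(dn["d_mu_i"], 0)
  expect_equal(unname(up["d_mu_i"]), -unname(dn["d_mu_i"]),
               tolerance = 1e-10)
  expect_equal(unname(at["d_mu_i"]), 0, tolerance = 1e-12)
})

test_that("phenotypic variance is quadratic in nutrition with the stated average", {
  expect_equal(phenotypic_variance(0, ref_params()), 1)
  expect_equal(phenotypic_variance(2, ref_params()), 5)  # 1 + 1 * 4
  expect_equal(constant_phenotypic_variance(ref_params()), 2)
  p <- model_params(sigma_ai2 = 0.5, sigma_ab2 = 2, rho_ib = 0.6,
                    sigma_n2 = 1.5)
  expect_equal(phenotypic_variance(1.2, p),
               p$sigma_i2 + 2 * p$sigma_ib * 1.2 + p$sigma_b2 * 1.2^2)
  expect_equal(constant_phenotypic_variance(p),
               p$sigma_i2 + p$sigma_b2 * 1.5)
})

test_that("weighted one-generation response from a displaced state matches the analytic prediction at the ssv point", {
  # the expected per-generation movement away from the approximate (ssv)
  # equilibrium is nonzero and equals the fitness-weighted response
  p <- ref_params()
  mb <- approx_slope_ssv(p)
  st <- population_state(approx_intercept_ssv(mb, p), mb)
  pred <- total_response(st, p)
  expect_gt(pred["d_mu_b"], 0)   # slope relaxes back toward zero
})
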