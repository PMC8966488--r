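#' Reproduce the B-sweep validation experiment
#'
#' Runs the individual-based simulation across a grid of optimum slopes `B`
#' and intercept-slope correlations, and attaches the analytic equilibrium
#' curves (small-slope-variance, weak-mismatch constant-variance,
#' weak-mismatch small-slope-variance, and the full numeric solution) for
#' comparison. The summary reports, per run, the deviation of the simulated
#' slope from each analytic reference in units of the run's Monte-Carlo SE.
#'
#' `scale = "full"` is the complete validation protocol (B from -40 to 0 in
#' 0.4 steps, 10,000 individuals, 10,000 generations, one run per point) and
#' takes hours; `scale = "reduced"` (default) uses B in \{-0.4, -1, -2\},
#' 2,000 individuals, 3,000 generations, window 1,500, three replicates, and
#' runs in about a minute.
#'
#' @param params Baseline [model_params()] (its `B` and `rho_ib` are swept).
#' @param scale `"reduced"` or `"full"`.
#' @param B_grid,correlations,replicates,pop_size,generations,window Override
#'   the scale defaults.
#' @param seed Master seed.
#' @return A list of class `plastinorm_experiment`: `table` (one row per run
#'   with simulated and analytic values), `summary` (max |sim - analytic| in
#'   MC-SE units per method), and `meta` (scale and sizes).
#' @examples
#' \donttest{
#' fig3 <- run_figure3(seed = 1)
#' fig3$summary
#' }
#' @export
run_figure3 <- function(params = model_params(),
                        scale = c("reduced", "full"),
                        B_grid = NULL, correlations = 0,
                        replicates = NULL, pop_size = NULL,
                        generations = NULL, window = NULL, seed = 1) {
  scale <- match.arg(scale)
  d <- .scale_defaults(scale)
  if (is.null(B_grid))
    B_grid <- if (scale == "full") seq(-40, 0, by = 0.4) else c(-0.4, -1, -2)
  cfg <- sim_config(pop_size = pop_size %||% d$pop_size,
                    generations = generations %||% d$generations,
                    window = window %||% d$window, seed = seed)
  replicates <- replicates %||% d$replicates
  rows <- list()
  for (rho in correlations) {
    p <- update_params(params, rho_ib = rho)
    tab <- sweep_simulation(p, cfg, "B", B_grid, replicates)
    tab$rho_ib <- rho
    tab$ssv_mu_b <- tab$ssv_mu_i <- tab$wm_cv_mu_b <- tab$wm_cv_mu_i <-
      tab$wm_ssv_mu_b <- tab$wm_ssv_mu_i <- tab$numeric_mu_b <-
      tab$numeric_mu_i <- NA_real_
    for (j in seq_len(nrow(tab))) {
      pb <- update_params(p, B = tab$value[j])
      mb_ssv <- tryCatch(approx_slope_ssv(pb), error = function(e) NA_real_)
      tab$ssv_mu_b[j] <- mb_ssv
      tab$ssv_mu_i[j] <- approx_intercept_ssv(mb_ssv, pb)
      tab$wm_cv_mu_b[j] <- approx_slope_wm_cv(pb)
      tab$wm_cv_mu_i[j] <- approx_intercept_wm_cv(tab$wm_cv_mu_b[j], pb)
      tab$wm_ssv_mu_b[j] <- approx_slope_wm_ssv(pb)
      tab$wm_ssv_mu_i[j] <- approx_intercept_ssv(tab$wm_ssv_mu_b[j], pb)
      num <- tryCatch(solve_equilibrium_numeric(pb), error = function(e) NULL)
      tab$numeric_mu_b[j] <- if (is.null(num)) NA_real_ else num$mu_b_star
      tab$numeric_mu_i[j] <- if (is.null(num)) NA_real_ else num$mu_i_star
    }
    rows[[length(rows) + 1L]] <- tab
  }
  tab <- do.call(rbind, rows)
  ok <- tab$ok
  dev <- function(ref) max(abs(tab$mu_b[ok] - ref[ok]) / tab$se_mu_b[ok])
  summary <- data.frame(
    method = c("ssv", "wm_cv", "wm_ssv", "numeric"),
    max_abs_dev_se = c(dev(tab$ssv_mu_b), dev(tab$wm_cv_mu_b),
                       dev(tab$wm_ssv_mu_b), dev(tab$numeric_mu_b)))
  structure(list(table = tab, summary = summary,
                 meta = list(experiment = "figure3_B_sweep", scale = scale,
                             pop_size = cfg$pop_size,
                             generations = cfg$generations,
                             window = cfg$window, replicates = replicates,
                             seed = seed)),
            class = "plastinorm_experiment")
}

.scale_defaults <- function(scale) {
  if (scale == "full")
    list(pop_size = 10000L, generations = 10000L, window = 5000L,
         replicates = 1L)
  else
    list(pop_size = 2000L, generations = 3000L, window = 1500L,
         replicates = 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproduce the alpha-sweep experiment
#'
#' Holds `B` fixed (at the baseline value of `params`, -1 by default) and
#' sweeps the direct nutrition-fitness effect `alpha`, then reports the
#' relative change of the simulated equilibrium slope between the smallest
#' and largest `alpha` on the grid:
#' `100 * |mu_b(alpha_max) - mu_b(alpha_min)| / |mu_b(alpha_min)|`, with a
#' Monte-Carlo SE propagated from the block-bootstrap SEs of the two window
#' means. The analytic columns show that the small-slope-variance slope is
#' exactly constant in `alpha` while the weak-mismatch constant-variance
#' slope shrinks with `alpha^2`.
#'
#' @param params Baseline [model_params()].
#' @param scale `"reduced"` (N = 2,000, 3,000 generations) or `"full"` (the
#'   complete protocol, N = 10,000, 10,000 generations).
#' @param alphas Swept values; default the endpoints `c(0, 1)`. Use
#'   `seq(0, 1, by = 0.01)` for the full grid.
#' @param replicates,pop_size,generations,window Overrides of the scale
#'   defaults (default one run per grid value).
#' @param seed Master seed.
#' @return A `plastinorm_experiment` list: `table` (per-run estimates plus
#'   analytic `ssv_mu_b` and `wm_cv_mu_b` columns), `relative_change_pct`,
#'   `relative_change_se`, and `meta`. If the slope at the smallest alpha is
#'   indistinguishable from zero the statistic is flagged and omitted.
#' @examples
#' \donttest{
#' sw <- run_alpha_sweep(scale = "reduced", seed = 1)
#' sw$relative_change_pct
#' }
#' @export
run_alpha_sweep <- function(params = model_params(),
                            scale = c("reduced", "full"),
                            alphas = c(0, 1), replicates = 1,
                            pop_size = NULL, generations = NULL,
                            window = NULL, seed = 1) {
  scale <- match.arg(scale)
  d <- .scale_defaults(scale)
  cfg <- sim_config(pop_size = pop_size %||% d$pop_size,
                    generations = generations %||% d$generations,
                    window = window %||% d$window, seed = seed)
  tab <- sweep_simulation(params, cfg, "alpha", alphas, replicates)
  tab$ssv_mu_b <- tab$wm_cv_mu_b <- NA_real_
  for (j in seq_len(nrow(tab))) {
    pa <- update_params(params, alpha = tab$value[j])
    tab$ssv_mu_b[j] <- approx_slope_ssv(pa)
    tab$wm_cv_mu_b[j] <- approx_slope_wm_cv(pa)
  }
  agg <- function(a) {
    sel <- tab$ok & tab$value == a
    c(mean(tab$mu_b[sel]), sqrt(sum(tab$se_mu_b[sel]^2)) / sum(sel))
  }
  lo <- agg(min(alphas)); hi <- agg(max(alphas))
  flagged <- !is.finite(lo[1]) || abs(lo[1]) < 5 * lo[2]
  if (flagged) {
    rel <- NA_real_; rel_se <- NA_real_
  } else {
    rel <- 100 * abs(hi[1] - lo[1]) / abs(lo[1])
    # delta method on (hi - lo) / lo with independent runs
    rel_se <- 100 * sqrt((hi[2] / lo[1])^2 +
                           ((hi[1] - lo[1]) * lo[2] / lo[1]^2)^2)
  }
  structure(list(table = tab, relative_change_pct = rel,
                 relative_change_se = rel_se, flagged = flagged,
                 meta = list(experiment = "alpha_sweep", scale = scale,
                             B = params$B, pop_size = cfg$pop_size,
                             generations = cfg$generations,
                             window = cfg$window, replicates = replicates,
                             seed = seed)),
            class = "plastinorm_experiment")
}

#' Recover the fixed-slope displacement of the mean breeding date
#'
#' With a flat optimum (`B = 0`), no slope variation, and every individual's
#' plastic slope fixed at -1, the equilibrium mean breeding date exceeds the
#' optimum by `sigma_n2 * alpha`: individuals in good nutritional
#' environments breed earlier *and* contribute more offspring, dragging the
#' mean away from the optimum. The simulation starts at `mu_i = A` and the
#' window-averaged displacement is compared with the analytic value.
#'
#' @param params Baseline [model_params()]; `B`, the slope variances and the
#'   correlation are overridden to the fixed-slope configuration.
#' @param slope The fixed plastic slope (default -1).
#' @param pop_size,generations,window Simulation size (reduced-scale
#'   defaults).
#' @param seed Master seed.
#' @return A list of class `plastinorm_experiment`: simulated displacement
#'   `displacement` with `se`, `analytic` displacement, and their difference
#'   in MC-SE units (`z`).
#' @examples
#' \donttest{
#' run_price_recovery(seed = 1)$z
#' }
#' @export
run_price_recovery <- function(params = model_params(), slope = -1,
                               pop_size = 2000, generations = 3000,
                               window = 1500, seed = 1) {
  p <- update_params(params, B = 0, sigma_ab2 = 0, sigma_eb2 = 0,
                     rho_ib = 0)
  cfg <- sim_config(pop_size = pop_size, generations = generations,
                    window = window, seed = seed, init = c(p$A, slope))
  res <- run_simulation(p, cfg, trajectory = FALSE)
  analytic <- approx_intercept_ssv(slope, p) - p$A   # sigma_n2*alpha*(0 - slope)
  disp <- res$mu_i - p$A
  structure(list(displacement = disp, se = res$se_mu_i,
                 analytic = analytic,
                 z = (disp - analytic) / res$se_mu_i,
                 meta = list(experiment = "price_recovery", slope = slope,
                             pop_size = cfg$pop_size,
                             generations = cfg$generations,
                             window = cfg$window, seed = seed)),
            class = "plastinorm_experiment")
}

#' @export
print.plastinorm_experiment <- function(x, ...) {
  cat("Experiment:", x$meta$experiment, "\n")
  str(x$meta, give.attr = FALSE, no.list = TRUE)
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$relative_change_pct))
    cat(sprintf("relative slope change: %.2f%% (MC-SE %.2f)\n",
                x$relative_change_pct, x$relative_change_se))
  if (!is.null(x$displacement))
    cat(sprintf("displacement: %.4f (MC-SE %.4f), analytic %.4f, z = %.2f\n",
                x$displacement, x$se, x$analytic, x$z))
  invisible(x)
}

#' Write and read result tables
#'
#' CSV round-trip that is lossless for numeric fields (written with 17
#' significant digits) and carries provenance as `#`-prefixed header
#' comments: package version, a hash of the metadata, and the master seed.
#'
#' @param table A data frame of results.
#' @param path Output path.
#' @param seed Master seed to record.
#' @param meta Named list of extra metadata to record in the header.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   the data frame with the parsed header in `attr(, "meta")`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_results(data.frame(B = -1, mu_b = -0.45), f, seed = 1)
#' read_results(f)
#' @export
write_results <- function(table, path, seed = NA, meta = list()) {
  stopifnot(is.data.frame(table))
  ver <- as.character(utils::packageVersion("plastinorm"))
  meta_str <- paste(names(meta), unlist(lapply(meta, format)),
                    sep = "=", collapse = ";")
  header <- c(paste0("# package_version=", ver),
              paste0("# config_hash=", .derive_seed(0, meta_str, 0)),
              paste0("# seed=", seed),
              if (length(meta)) paste0("# ", names(meta), "=",
                                       unlist(lapply(meta, format))))
  tab <- table
  for (j in seq_along(tab))
    if (is.numeric(tab[[j]])) tab[[j]] <- sprintf("%.17g", tab[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (!length(body)) stop("malformed results file '", path, "': no header row")
  tab <- tryCatch(
    utils::read.csv(text = paste(lines[body], collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop("malformed results file '", path, "' near line ",
                             body[1], ": ", conditionMessage(e)))
  meta <- sub("^#\\s*", "", hdr)
  attr(tab, "meta") <- meta
  tab
}
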