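RATE_MIN <- 1e-8
RATE_MAX <- 1e3

#' Initialise per-origin firing rates from experimental timing
#'
#' The starting point of the fit converts each origin's experimentally
#' measured replication time T_i into a firing-factor association rate
#' \deqn{f_{i,0} = \frac{1}{F}\frac{1}{T_i}}
#' so that at full factor availability the realised initial firing rate is
#' 1/T_i per minute.
#'
#' @param timing a [timing_profile()] of experimental times (minutes).
#' @param origins data frame with `origin_id`, `chrom`, `bin`.
#' @param n_factors number of firing factors `F` (>= 1).
#' @return `origins` with a `rate` column added (per minute per free factor).
#' @export
initialize_rates <- function(timing, origins, n_factors) {
  stopifnot(n_factors >= 1)
  t_i <- timing_at_origins(timing, origins)
  if (any(t_i <= 0))
    stop("experimental replication time is <= 0 at origin(s) ",
         paste(origins$origin_id[t_i <= 0], collapse = ", "),
         "; rates would be infinite")
  origins$rate <- clamp_rates(1 / (n_factors * t_i))
  origins
}

#' Multiplicative firing-rate update
#'
#' One fitting step rescales each origin's rate by a power of the ratio of
#' its simulated to its experimental replication timing,
#' \deqn{f_{i,n+1} = f_{i,n}\,(\tilde T_{i,n}/T_i)^{\alpha},}
#' raising rates where the simulation replicates too late and lowering them
#' where it replicates too early. Rates are clamped to \[1e-8, 1e3\] to keep
#' the multiplicative update numerically sane; clamping is reported.
#'
#' @param rates data frame with `origin_id`, `chrom`, `bin`, `rate`.
#' @param simulated simulated mean [timing_profile()].
#' @param experimental experimental [timing_profile()].
#' @param alpha update exponent; 1.2 balances speed against stability.
#' @return `rates` with updated `rate` column.
#' @export
update_rates <- function(rates, simulated, experimental, alpha = 1.2) {
  t_sim <- timing_at_origins(simulated, rates)
  t_exp <- timing_at_origins(experimental, rates)
  if (any(t_sim <= 0) || any(t_exp <= 0))
    stop("nonpositive replication time at an origin; cannot form timing ratio")
  rates$rate <- clamp_rates(rates$rate * (t_sim / t_exp)^alpha)
  rates
}

clamp_rates <- function(r) {
  n_clamped <- sum(r < RATE_MIN | r > RATE_MAX)
  if (n_clamped > 0)
    warning(sprintf("%d rate(s) clamped to [%g, %g]", n_clamped,
                    RATE_MIN, RATE_MAX), call. = FALSE)
  pmin(pmax(r, RATE_MIN), RATE_MAX)
}

#' Timing-error summaries between two profiles
#'
#' The fitting objective is the mean absolute error over all 1-kb bins
#' genome-wide; root-mean-square error and the coefficient of determination
#' (squared Pearson correlation) are reported alongside as diagnostics.
#'
#' @param simulated,experimental [timing_profile()]s on the same grid.
#' @return List with `mae`, `rmse` (minutes) and `r_squared`.
#' @export
compute_mae <- function(simulated, experimental) {
  if (!identical(simulated$grid$chrom, experimental$grid$chrom) ||
      !identical(simulated$grid$length_bins, experimental$grid$length_bins))
    stop("timing profiles are on different grids")
  s <- timing_values(simulated)
  e <- timing_values(experimental)
  list(mae = mean(abs(s - e)),
       rmse = sqrt(mean((s - e)^2)),
       r_squared = if (stats::sd(s) == 0 || stats::sd(e) == 0) {
         if (all(s == e)) 1 else NA_real_
       } else stats::cor(s, e)^2)
}

#' Fitting configuration
#'
#' @param alpha exponent of the multiplicative rate update (> 0).
#' @param n_iterations number of fitting iterations; 15 is enough for the
#'   MAE's rate of change to approach zero on yeast-scale problems.
#' @param n_sims ensemble size per iteration.
#' @param sim a [sim_config()].
#' @param base_seed master seed; each iteration draws a fresh ensemble seed
#'   from it so Monte-Carlo noise is not correlated across iterations.
#' @return A `fit_config` list.
#' @export
fit_config <- function(alpha = 1.2, n_iterations = 15, n_sims = 500,
                       sim = sim_config(), base_seed = 1) {
  stopifnot(alpha >= 0, n_iterations >= 1, n_sims >= 1,
            inherits(sim, "sim_config"))
  structure(list(alpha = alpha, n_iterations = as.integer(n_iterations),
                 n_sims = as.integer(n_sims), sim = sim,
                 base_seed = as.integer(base_seed)), class = "fit_config")
}

#' Fit per-origin firing rates to a replication-timing profile
#'
#' Iterates simulate-compare-update: rates start at f_{i,0} = 1/(F T_i);
#' each iteration simulates an ensemble, takes the per-bin mean replication
#' time over completed replicates, records the genome-wide MAE against the
#' experimental profile, and updates each origin's rate by
#' (simulated/experimental timing at the origin)^alpha. The iteration with
#' the lowest MAE is selected as the fitted model.
#'
#' @param config a [fit_config()].
#' @param origins data frame with `origin_id`, `chrom`, `bin`.
#' @param grid a [genome_grid()].
#' @param experimental experimental [timing_profile()] covering all bins.
#' @return A `fit_trace`: per-iteration rate tables, mean profiles and error
#'   summaries (`$summary` data frame with iteration, mae, rmse, r_squared,
#'   n_completed), plus `$best` (iteration index, 1-based over recorded
#'   iterations 0..n-1), `$best_rates` and `$best_profile`.
#' @export
fit_rates <- function(config, origins, grid, experimental) {
  stopifnot(inherits(config, "fit_config"))
  rates <- initialize_rates(experimental, origins, config$sim$n_factors)
  set.seed(config$base_seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, config$n_iterations)

  iters <- vector("list", config$n_iterations)
  for (n in seq_len(config$n_iterations)) {
    ens <- run_ensemble(config$sim, rates, grid, n_sims = config$n_sims,
                        base_seed = iter_seeds[n])
    n_done <- attr(ens, "n_completed")
    if (n_done < config$n_sims / 2)
      stop(sprintf(paste0("iteration %d: only %d/%d replicates completed; ",
                          "rates are pathological"),
                   n - 1L, n_done, config$n_sims))
    prof <- timing_profiles(ens)$mean
    err <- compute_mae(prof, experimental)
    iters[[n]] <- list(iteration = n - 1L, rates = rates, profile = prof,
                       mae = err$mae, rmse = err$rmse,
                       r_squared = err$r_squared, n_completed = n_done)
    message(sprintf("iteration %2d: MAE %.4f min, RMSE %.4f, R2 %.4f (%d/%d complete)",
                    n - 1L, err$mae, err$rmse, err$r_squared, n_done,
                    config$n_sims))
    if (n < config$n_iterations)
      rates <- update_rates(rates, prof, experimental, alpha = config$alpha)
  }
  summary_df <- data.frame(
    iteration = vapply(iters, `[[`, integer(1), "iteration"),
    mae = vapply(iters, `[[`, numeric(1), "mae"),
    rmse = vapply(iters, `[[`, numeric(1), "rmse"),
    r_squared = vapply(iters, `[[`, numeric(1), "r_squared"),
    n_completed = vapply(iters, `[[`, numeric(1), "n_completed"))
  best <- which.min(summary_df$mae)
  structure(list(iterations = iters, summary = summary_df, best = best,
                 best_rates = iters[[best]]$rates,
                 best_profile = iters[[best]]$profile,
                 config = config), class = "fit_trace")
}

#' @export
print.fit_trace <- function(x, ...) {
  cat(sprintf("fit_trace: %d iterations; best iteration %d with MAE %.4f min (RMSE %.4f, R2 %.4f)\n",
              nrow(x$summary), x$summary$iteration[x$best],
              x$summary$mae[x$best], x$summary$rmse[x$best],
              x$summary$r_squared[x$best]))
  invisible(x)
}

#' Write a fit-trace summary and per-iteration rate snapshots
#'
#' @param trace a `fit_trace`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(trace$summary, file.path(dir, "fit_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (it in trace$iterations)
    write_rate_table(it$rates,
                     file.path(dir, sprintf("rates_iter%02d.tsv", it$iteration)))
  write_rate_table(trace$best_rates, file.path(dir, "rates_best.tsv"))
  invisible(dir)
}
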