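#' Simulation configuration
#'
#' Parameters of the stochastic S-phase model: a finite pool of `F` firing
#' factors shared by all origins, an exponential recycling delay with rate
#' `recycle_rate` after each firing, and forks advancing at `fork_speed`.
#' Defaults follow the fitted budding-yeast configuration: F = 200 (the
#' copy number of Dpb11, taken as the rate-limiting pre-initiation factor),
#' recycling at 0.05 per minute (expected recycling time about a third of
#' S phase) and a fork speed of 1.4 kb per minute.
#'
#' @param n_factors number of firing factors `F` (>= 0).
#' @param recycle_rate recycling rate `r` per minute per inactive factor.
#' @param fork_speed fork speed `v` in kb/min.
#' @param fork_mode `"stochastic_steps"` (1-kb steps with Exponential(v)
#'   waits) or `"deterministic"` (a step exactly every 1/v minutes).
#' @param max_time safety cap in minutes; a simulation still incomplete at
#'   `max_time` is returned with `completed = FALSE`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_factors = 200, recycle_rate = 0.05, fork_speed = 1.4,
                       fork_mode = c("stochastic_steps", "deterministic"),
                       max_time = 500) {
  fork_mode <- match.arg(fork_mode)
  stopifnot(n_factors >= 0, recycle_rate >= 0, fork_speed > 0, max_time > 0)
  structure(list(n_factors = as.integer(n_factors),
                 recycle_rate = recycle_rate, fork_speed = fork_speed,
                 fork_mode = fork_mode, max_time = max_time),
            class = "sim_config")
}

validate_origins <- function(origins, grid) {
  need <- c("origin_id", "chrom", "bin", "rate")
  if (!all(need %in% names(origins)))
    stop("origins must have columns: ", paste(need, collapse = ", "))
  len <- grid_chrom_length(grid, origins$chrom)
  if (any(origins$bin < 1) || any(origins$bin > len))
    stop("origin bin outside chromosome grid")
  if (anyDuplicated(paste(origins$chrom, origins$bin)))
    stop("duplicate origin bins; resolve collisions first")
  if (any(!is.finite(origins$rate)) || any(origins$rate <= 0))
    stop("origin firing rates must be finite and > 0")
  no_origin <- setdiff(grid$chrom, origins$chrom)
  if (length(no_origin) > 0)
    stop("chromosome(s) without any origin can never replicate: ",
         paste(no_origin, collapse = ", "))
  invisible(origins)
}

#' Event propensities of a simulation state
#'
#' Exposes the kinetic Monte Carlo rate book-keeping for inspection: each
#' pending origin can fire at `rate * n_free` (mass action against the free
#' firing-factor pool), each active fork steps at the fork speed, and the
#' recycling pool returns factors at `recycle_rate * n_recycling`.
#'
#' @param state list with elements `pending` (data frame with `origin_id`,
#'   `rate`), `n_free`, `n_forks`, `n_recycling`, and `config`
#'   (a [sim_config()]).
#' @return Data frame with columns `event`, `id`, `rate`; the summed total
#'   is in attribute `"total"`.
#' @export
compute_propensities <- function(state) {
  cfg <- state$config
  if (state$n_free < 0 || state$n_forks < 0 || state$n_recycling < 0)
    stop("corrupt state: negative counts")
  rows <- list()
  if (nrow(state$pending) > 0)
    rows$fire <- data.frame(event = "fire", id = state$pending$origin_id,
                            rate = state$pending$rate * state$n_free,
                            stringsAsFactors = FALSE)
  if (state$n_forks > 0)
    rows$fork <- data.frame(event = "fork_step",
                            id = paste0("fork_", seq_len(state$n_forks)),
                            rate = cfg$fork_speed, stringsAsFactors = FALSE)
  rows$recycle <- data.frame(event = "recycle", id = "pool",
                             rate = cfg$recycle_rate * state$n_recycling,
                             stringsAsFactors = FALSE)
  out <- do.call(rbind, unname(rows))
  if (any(out$rate < 0)) stop("corrupt state: negative propensity")
  attr(out, "total") <- sum(out$rate)
  out
}

#' Simulate one S phase
#'
#' Runs the event-driven model on a genome grid: origins fire by capturing a
#' free firing factor (propensity `rate * n_free`), each firing replicates
#' the origin's own bin and launches a leftward and a rightward fork, forks
#' replicate one 1-kb bin per step and terminate at chromosome ends or on
#' already-replicated DNA, pending origins overrun by a fork are passivated,
#' and factors return to the free pool after an exponential recycling delay.
#'
#' @param config a [sim_config()].
#' @param origins data frame with columns `origin_id`, `chrom`, `bin`,
#'   `rate` (per minute per free factor); bins must be distinct.
#' @param grid a [genome_grid()].
#' @param seed integer seed; identical seeds give identical results.
#' @param keep_events keep the full event log (needed for time-resolved
#'   curves and the conservation checks).
#' @return A `sim_result` list: per-chromosome `time`, `direction`
#'   (-1 left, 0 origin, +1 right) and `parent` (origin index) vectors;
#'   `origins` with per-origin `fate` (fired/passivated/pending) and
#'   `fate_time`; a `forks` table (parent, dir, born, terminated, last_bin);
#'   `events` (time-ordered log) if kept; `completed`, `completion_time`.
#' @export
simulate_s_phase <- function(config, origins, grid, seed = NULL,
                             keep_events = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "genome_grid"))
  validate_origins(origins, grid)
  if (!is.null(seed)) set.seed(seed)
  res <- sim_core(grid$length_bins, match(origins$chrom, grid$chrom),
                  as.integer(origins$bin), as.numeric(origins$rate),
                  config$n_factors, config$recycle_rate, config$fork_speed,
                  config$fork_mode == "stochastic_steps", config$max_time,
                  keep_events)

  split_by_chrom <- function(v) {
    ends <- cumsum(grid$length_bins)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    out <- mapply(function(s, e) v[s:e], starts, ends, SIMPLIFY = FALSE)
    names(out) <- grid$chrom
    out
  }
  ori <- origins
  ori$fate <- c("pending", "fired", "passivated")[res$ori_state + 1L]
  ori$fate_time <- res$ori_time

  structure(list(
    grid = grid, origins = ori,
    time = split_by_chrom(res$rep_time),
    direction = split_by_chrom(res$rep_dir),
    parent = split_by_chrom(res$rep_parent),
    forks = as.data.frame(res$forks),
    events = if (is.null(res$events) || length(res$events) == 0) NULL
             else as.data.frame(res$events),
    completed = res$completed,
    completion_time = res$completion_time,
    stalled = res$stalled, t_end = res$t_end,
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %s at t = %.2f min; %d/%d origins fired\n",
              if (x$completed) "completed" else
                if (x$stalled) "stalled (no possible events)" else "timed out",
              if (x$completed) x$completion_time else x$t_end,
              sum(x$origins$fate == "fired"), nrow(x$origins)))
  invisible(x)
}

#' Run an ensemble of independent S-phase simulations
#'
#' Each replicate is seeded deterministically from (`base_seed`, replicate
#' index), so the ensemble is reproducible and replicate contents do not
#' depend on execution order. Population statistics are conventionally
#' averaged over 500 replicates.
#'
#' @inheritParams simulate_s_phase
#' @param n_sims number of replicates (>= 1).
#' @param base_seed integer master seed.
#' @return A `sim_ensemble`: list of `sim_result`s with the shared inputs
#'   attached as attributes.
#' @export
run_ensemble <- function(config, origins, grid, n_sims = 500, base_seed = 1,
                         keep_events = FALSE) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  validate_origins(origins, grid)
  set.seed(base_seed %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  sims <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sims[[i]] <- tryCatch(
      simulate_s_phase(config, origins, grid, seed = rep_seeds[i],
                       keep_events = keep_events),
      error = function(e) stop("replicate ", i, ": ", conditionMessage(e)))
  }
  n_done <- sum(vapply(sims, `[[`, logical(1), "completed"))
  if (n_done < n_sims)
    message(sprintf("ensemble: %d/%d replicates completed within max_time",
                    n_done, n_sims))
  structure(sims, class = "sim_ensemble", config = config, origins = origins,
            grid = grid, base_seed = base_seed, n_completed = n_done)
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("sim_ensemble: %d replicates (%d completed), %d origins, %d kb\n",
              length(x), attr(x, "n_completed"),
              nrow(attr(x, "origins")), n_bins(attr(x, "grid"))))
  invisible(x)
}

completed_sims <- function(ensemble) {
  Filter(function(s) isTRUE(s$completed), ensemble)
}

#' Write a per-replicate event log as JSONL
#'
#' One JSON object per line with fields `time`, `type`, `chrom`, `bin`,
#' `id`; event types are `fire`, `fork_step`, `terminate`, `passivate`,
#' `recycle`.
#'
#' @param sim a `sim_result` run with `keep_events = TRUE`.
#' @param path output path.
#' @export
write_event_log <- function(sim, path) {
  if (is.null(sim$events))
    stop("simulation was run without keep_events = TRUE")
  ev <- sim$events
  types <- c("fire", "fork_step", "terminate", "passivate", "recycle")
  chrom <- ifelse(is.na(ev$chrom), NA, sim$grid$chrom[ev$chrom])
  lines <- sprintf(
    '{"time": %.6f, "type": "%s", "chrom": %s, "bin": %s, "id": %s}',
    ev$time, types[ev$type],
    ifelse(is.na(chrom), "null", paste0('"', chrom, '"')),
    ifelse(is.na(ev$bin), "null", ev$bin),
    ifelse(is.na(ev$id), "null", ev$id))
  writeLines(lines, path)
  invisible(path)
}
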