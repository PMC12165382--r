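#' Ensemble mean and SD replication-timing profiles
#'
#' Per-bin mean and sample standard deviation of replication time over the
#' completed replicates of an ensemble. This is the same mean profile the
#' fitting loop compares against experimental timing.
#'
#' @param ensemble a `sim_ensemble` from [run_ensemble()].
#' @return List with `mean` and `sd` [timing_profile()]s and `n_completed`.
#' @export
timing_profiles <- function(ensemble) {
  sims <- completed_sims(ensemble)
  if (length(sims) < 2 && length(ensemble) >= 2)
    stop("need >= 2 completed replicates for mean/SD profiles")
  if (length(sims) < 1)
    stop("no completed replicates")
  grid <- sims[[1]]$grid
  mean_t <- list(); sd_t <- list()
  for (ch in grid$chrom) {
    mat <- vapply(sims, function(s) s$time[[ch]],
                  numeric(grid_chrom_length(grid, ch)))
    mat <- matrix(mat, ncol = length(sims))
    mean_t[[ch]] <- rowMeans(mat)
    sd_t[[ch]] <- if (ncol(mat) >= 2) apply(mat, 1, stats::sd)
                  else rep(NA_real_, nrow(mat))
  }
  list(mean = timing_profile(grid, mean_t),
       sd = if (length(sims) >= 2)
         timing_profile(grid, sd_t) else NULL,
       n_completed = length(sims))
}

#' S-phase lengths across an ensemble
#'
#' S-phase duration of a replicate is the time, from the start of the
#' simulation, at which the last bin of the genome replicates.
#'
#' @param ensemble a `sim_ensemble`.
#' @return List with `lengths` (minutes, completed replicates only), `mean`,
#'   `sd`, and `n_incomplete`.
#' @export
s_phase_lengths <- function(ensemble) {
  sims <- completed_sims(ensemble)
  lens <- vapply(sims, `[[`, numeric(1), "completion_time")
  if (length(lens) == 0)
    warning("no completed replicates; empty S-phase summary", call. = FALSE)
  if (length(lens) == 1)
    warning("single completed replicate; SD undefined", call. = FALSE)
  list(lengths = lens,
       mean = if (length(lens)) mean(lens) else NA_real_,
       sd = if (length(lens) >= 2) stats::sd(lens) else NA_real_,
       n_incomplete = length(ensemble) - length(lens))
}

#' Inter-origin distances
#'
#' The IOD sample pools, over completed replicates and chromosomes, the
#' distances between successive origins that both fired in the same
#' simulated S phase (sorted fired-origin bins, successive differences,
#' times 1 kb). Chromosomes with fewer than two fired origins in a
#' replicate contribute nothing.
#'
#' @param ensemble a `sim_ensemble`.
#' @return List with `iods` (kb), `mean`, `sd`.
#' @export
iod_distribution <- function(ensemble) {
  sims <- completed_sims(ensemble)
  iods <- unlist(lapply(sims, function(s) {
    fired <- s$origins[s$origins$fate == "fired", ]
    unlist(lapply(split(fired$bin, fired$chrom), function(b) {
      if (length(b) < 2) numeric(0) else diff(sort(b))
    }), use.names = FALSE)
  }), use.names = FALSE)
  list(iods = iods,
       mean = if (length(iods)) mean(iods) else NA_real_,
       sd = if (length(iods) >= 2) stats::sd(iods) else NA_real_)
}

#' Per-origin efficiency and mean firing time
#'
#' Origin efficiency is the percentage of completed simulations in which the
#' origin fired (rather than being passively replicated); passivation
#' percentage is its complement.
#'
#' @param ensemble a `sim_ensemble`.
#' @return Data frame per origin: `origin_id`, `chrom`, `bin`, `n_fired`,
#'   `efficiency_pct`, `passivated_pct`, `mean_firing_time`.
#' @export
origin_efficiency <- function(ensemble) {
  sims <- completed_sims(ensemble)
  if (length(sims) < 1) stop("need >= 1 completed replicate")
  ori <- sims[[1]]$origins[c("origin_id", "chrom", "bin")]
  fired <- vapply(sims, function(s) s$origins$fate == "fired",
                  logical(nrow(ori)))
  fired <- matrix(fired, ncol = length(sims))
  ftime <- vapply(sims, function(s) ifelse(s$origins$fate == "fired",
                                           s$origins$fate_time, NA_real_),
                  numeric(nrow(ori)))
  ftime <- matrix(ftime, ncol = length(sims))
  ori$n_fired <- rowSums(fired)
  ori$efficiency_pct <- 100 * ori$n_fired / length(sims)
  ori$passivated_pct <- 100 - ori$efficiency_pct
  ori$mean_firing_time <- rowMeans(ftime, na.rm = TRUE)
  ori$mean_firing_time[ori$n_fired == 0] <- NA_real_
  ori
}

#' Replication fork directionality profile
#'
#' Per bin, RFD = (n_right - n_left) / (n_right + n_left) over completed
#' replicates, counting only fork-replicated passages: in replicates where a
#' bin is replicated at origin firing it contributes to neither count. Bins
#' never replicated by a fork across the ensemble get `NA`.
#'
#' @param ensemble a `sim_ensemble`.
#' @return Named list (per chromosome) of numeric RFD vectors in \[-1, 1\].
#' @export
rfd_profile <- function(ensemble) {
  sims <- completed_sims(ensemble)
  if (length(sims) < 1) stop("need >= 1 completed replicate")
  grid <- sims[[1]]$grid
  out <- list()
  for (ch in grid$chrom) {
    nr <- nl <- numeric(grid_chrom_length(grid, ch))
    for (s in sims) {
      d <- s$direction[[ch]]
      nr <- nr + (!is.na(d) & d == 1L)
      nl <- nl + (!is.na(d) & d == -1L)
    }
    rfd <- (nr - nl) / (nr + nl)
    rfd[nr + nl == 0] <- NA_real_
    out[[ch]] <- rfd
  }
  out
}

#' Mean replicon length per origin
#'
#' A replicon is the contiguous segment replicated from one fired origin:
#' its own bin plus every bin its two forks replicated. Within a completed
#' replicate, replicon lengths over fired origins tile the genome exactly.
#'
#' @param ensemble a `sim_ensemble`.
#' @return Data frame per origin: `origin_id`, `chrom`, `bin`, `n_fired`,
#'   `mean_replicon_kb` (mean over replicates in which the origin fired).
#' @export
replicon_lengths <- function(ensemble) {
  sims <- completed_sims(ensemble)
  if (length(sims) < 1) stop("need >= 1 completed replicate")
  ori <- sims[[1]]$origins[c("origin_id", "chrom", "bin")]
  tot <- numeric(nrow(ori)); n_fired <- integer(nrow(ori))
  for (s in sims) {
    parent <- unlist(s$parent, use.names = FALSE)
    cnt <- tabulate(parent, nbins = nrow(ori))
    fired <- s$origins$fate == "fired"
    tot <- tot + ifelse(fired, cnt, 0)
    n_fired <- n_fired + fired
  }
  ori$n_fired <- n_fired
  ori$mean_replicon_kb <- ifelse(n_fired > 0, tot / n_fired, NA_real_)
  ori
}

#' Per-replicate replicon partition
#'
#' @param sim a completed `sim_result`.
#' @return Named integer vector: bins replicated from each fired origin
#'   (1 kb each); sums to the genome size.
#' @export
replicon_partition <- function(sim) {
  parent <- unlist(sim$parent, use.names = FALSE)
  cnt <- tabulate(parent, nbins = nrow(sim$origins))
  names(cnt) <- sim$origins$origin_id
  cnt[sim$origins$fate == "fired"]
}

#' Per-origin firing-time samples
#'
#' @param ensemble a `sim_ensemble`.
#' @return Named list (per origin id) of firing times in minutes, from the
#'   replicates in which that origin fired; passivated replicates excluded.
#' @export
firing_time_distributions <- function(ensemble) {
  sims <- completed_sims(ensemble)
  ori <- attr(ensemble, "origins")
  out <- lapply(seq_len(nrow(ori)), function(i) {
    t_i <- vapply(sims, function(s)
      if (s$origins$fate[i] == "fired") s$origins$fate_time[i] else NA_real_,
      numeric(1))
    t_i[!is.na(t_i)]
  })
  names(out) <- ori$origin_id
  out
}

#' Time-resolved ensemble curves
#'
#' Reconstructs, from event logs, the ensemble-mean time courses of: active
#' replication forks, free firing factors, cumulative fired origins, origins
#' still available to fire, the fraction of the genome unreplicated, and the
#' instantaneous origin-firing rate (events per minute smoothed over one
#' grid step). Curves are evaluated on a uniform grid and reported up to the
#' latest replicate end; for cross-replicate means each finished replicate
#' holds its final state.
#'
#' @param ensemble a `sim_ensemble` run with `keep_events = TRUE`.
#' @param grid_step time-grid spacing in minutes.
#' @param t_max optional truncation time (default: latest replicate end).
#' @return Data frame: `time`, `active_forks`, `free_factors`,
#'   `fired_origins`, `available_origins`, `fraction_unreplicated`,
#'   `firing_rate`.
#' @export
time_curves <- function(ensemble, grid_step = 1, t_max = NULL) {
  sims <- completed_sims(ensemble)
  if (length(sims) < 1) stop("need >= 1 completed replicate")
  if (is.null(sims[[1]]$events))
    stop("event logs missing: rerun the ensemble with keep_events = TRUE")
  total_bins <- n_bins(sims[[1]]$grid)
  n_ori <- nrow(sims[[1]]$origins)
  n_fac <- sims[[1]]$config$n_factors
  if (is.null(t_max))
    t_max <- max(vapply(sims, `[[`, numeric(1), "completion_time"))
  tgrid <- unique(c(seq(0, t_max, by = grid_step), t_max))

  step_count <- function(ev_t, tg) findInterval(tg, sort(ev_t))
  acc <- matrix(0, nrow = length(tgrid), ncol = 6)
  for (s in sims) {
    ev <- s$events
    fires <- ev$time[ev$type == 1]
    terms <- ev$time[ev$type == 3]
    recyc <- ev$time[ev$type == 5]
    pass <- ev$time[ev$type == 4]
    repl <- ev$time[ev$type %in% c(1, 2)]
    n_fire <- step_count(fires, tgrid)
    n_term <- step_count(terms, tgrid)
    n_rec <- step_count(recyc, tgrid)
    n_pass <- step_count(pass, tgrid)
    n_repl <- step_count(repl, tgrid)
    rate <- (step_count(fires, tgrid + grid_step / 2) -
               step_count(fires, tgrid - grid_step / 2)) / grid_step
    acc <- acc + cbind(2 * n_fire - n_term,          # active forks
                       n_fac - n_fire + n_rec,       # free factors
                       n_fire,                       # fired origins
                       n_ori - n_fire - n_pass,      # available origins
                       1 - n_repl / total_bins,      # fraction unreplicated
                       rate)                         # firing rate
  }
  acc <- acc / length(sims)
  data.frame(time = tgrid, active_forks = acc[, 1], free_factors = acc[, 2],
             fired_origins = acc[, 3], available_origins = acc[, 4],
             fraction_unreplicated = acc[, 5], firing_rate = acc[, 6])
}

#' Sweep the firing-factor copy number
#'
#' Re-simulates a fitted model across a range of firing-factor pool sizes F
#' with the per-origin rates and the recycling rate held fixed, recording
#' the genome-wide timing MAE against the experimental profile at each F;
#' the (F, MAE) points are summarised by a least-squares fifth-degree
#' polynomial when at least six F values are available. Ensembles are run
#' with paired seeds so F values differ only through the factor pool.
#'
#' @param rates fitted rate table (`origin_id`, `chrom`, `bin`, `rate`).
#' @param grid a [genome_grid()].
#' @param experimental experimental [timing_profile()].
#' @param f_values integer vector of firing-factor counts to test.
#' @param n_sims replicates per F.
#' @param config a [sim_config()] supplying the recycling rate, fork speed
#'   and max time (its `n_factors` is overridden per sweep point).
#' @param base_seed shared ensemble seed (paired across F values).
#' @return List with `table` (data frame F, mae, rmse, r_squared,
#'   mean_completion, n_completed), `poly` (lm fit of mae on F, degree 5,
#'   or NULL), and `profiles` (per-F mean timing profiles).
#' @export
firing_factor_sweep <- function(rates, grid, experimental,
                                f_values = c(25, 50, 100, 200, 400, 800),
                                n_sims = 500, config = sim_config(),
                                base_seed = 1) {
  stopifnot(all(f_values >= 1))
  rows <- list(); profiles <- list()
  for (f in f_values) {
    cfg <- config
    cfg$n_factors <- as.integer(f)
    ens <- run_ensemble(cfg, rates, grid, n_sims = n_sims,
                        base_seed = base_seed)
    n_done <- attr(ens, "n_completed")
    if (n_done < n_sims / 2) {
      warning(sprintf("F = %d: only %d/%d replicates completed; MAE missing",
                      f, n_done, n_sims), call. = FALSE)
      rows[[as.character(f)]] <- data.frame(
        F = f, mae = NA_real_, rmse = NA_real_, r_squared = NA_real_,
        mean_completion = NA_real_, n_completed = n_done)
      next
    }
    prof <- timing_profiles(ens)$mean
    err <- compute_mae(prof, experimental)
    sp <- s_phase_lengths(ens)
    profiles[[as.character(f)]] <- prof
    rows[[as.character(f)]] <- data.frame(
      F = f, mae = err$mae, rmse = err$rmse, r_squared = err$r_squared,
      mean_completion = sp$mean, n_completed = n_done)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$mae)
  poly_fit <- NULL
  if (sum(ok) >= 6) {
    poly_fit <- stats::lm(mae ~ poly(F, 5, raw = TRUE), data = tab[ok, ])
  } else {
    warning("fewer than 6 usable F values; degree-5 polynomial fit skipped",
            call. = FALSE)
  }
  list(table = tab, poly = poly_fit, profiles = profiles)
}
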