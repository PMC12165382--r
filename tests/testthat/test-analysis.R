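# two hand-built replicates on a 4-bin chromosome with one origin at bin 2
fake_pair <- function() {
  grid <- genome_grid("c1", 4)
  base_ori <- data.frame(origin_id = c("o1", "o2"), chrom = "c1",
                         bin = c(2, 4), stringsAsFactors = FALSE)
  o1 <- base_ori; o1$fate <- c("fired", "passivated"); o1$fate_time <- c(1, 3)
  o2 <- base_ori; o2$fate <- c("fired", "fired"); o2$fate_time <- c(2, 4)
  s1 <- fake_sim(grid, o1,
                 time = list(c1 = c(2, 1, 2.5, 3)),
                 direction = list(c1 = c(-1L, 0L, 1L, 1L)),
                 parent = list(c1 = c(1L, 1L, 1L, 1L)))
  s2 <- fake_sim(grid, o2,
                 time = list(c1 = c(4, 2, 3, 4)),
                 direction = list(c1 = c(-1L, 0L, 1L, 0L)),
                 parent = list(c1 = c(1L, 1L, 1L, 2L)))
  fake_ensemble(list(s1, s2), base_ori, grid)
}

test_that("timing mean/SD profiles follow per-bin sample statistics", {
  ens <- fake_pair()
  tp <- timing_profiles(ens)
  expect_equal(tp$mean$time$c1, c(3, 1.5, 2.75, 3.5))
  expect_equal(tp$sd$time$c1[1], sd(c(2, 4)))
  expect_equal(tp$sd$time$c1[1], sqrt(2), tolerance = 1e-12)
  expect_equal(tp$n_completed, 2)

  # identical replicates have zero SD
  ens2 <- fake_ensemble(list(ens[[1]], ens[[1]]),
                        attr(ens, "origins"), attr(ens, "grid"))
  expect_true(all(timing_values(timing_profiles(ens2)$sd) == 0))
})

test_that("S-phase lengths summarise completion times of finished runs", {
  ens <- fake_pair()
  sp <- s_phase_lengths(ens)
  expect_equal(sp$lengths, c(3, 4))
  expect_equal(sp$mean, 3.5)
  expect_equal(sp$n_incomplete, 0)

  ens1 <- fake_ensemble(ens[1], attr(ens, "origins"), attr(ens, "grid"))
  expect_warning(sp1 <- s_phase_lengths(ens1), "SD undefined")
  expect_true(is.na(sp1$sd))
})

test_that("IODs are successive distances between fired origins", {
  grid <- genome_grid("c1", 100)
  ori <- data.frame(origin_id = paste0("o", 1:3), chrom = "c1",
                    bin = c(25, 60, 10), stringsAsFactors = FALSE)
  o <- ori; o$fate <- "fired"; o$fate_time <- 1:3
  s <- fake_sim(grid, o, time = list(c1 = rep(1, 100)),
                direction = list(c1 = rep(1L, 100)),
                parent = list(c1 = rep(1L, 100)))
  ens <- fake_ensemble(list(s), ori, grid)
  iod <- iod_distribution(ens)
  expect_equal(sort(iod$iods), c(15, 35))
  expect_equal(iod$mean, 25)

  # a single fired origin per chromosome contributes nothing
  o1 <- ori; o1$fate <- c("fired", "passivated", "passivated")
  o1$fate_time <- 1
  s1 <- fake_sim(grid, o1, time = list(c1 = rep(1, 100)),
                 direction = list(c1 = rep(1L, 100)),
                 parent = list(c1 = rep(1L, 100)))
  expect_length(iod_distribution(fake_ensemble(list(s1), ori, grid))$iods, 0)
})

test_that("efficiency is the percentage of completed sims with a firing", {
  ens <- fake_pair()
  eff <- origin_efficiency(ens)
  expect_equal(eff$efficiency_pct, c(100, 50))
  expect_equal(eff$passivated_pct, c(0, 50))
  expect_equal(eff$efficiency_pct + eff$passivated_pct, c(100, 100))
  expect_equal(eff$mean_firing_time, c(1.5, 4))
})

test_that("RFD counts fork passages only and stays within [-1, 1]", {
  ens <- fake_pair()
  rfd <- rfd_profile(ens)$c1
  expect_equal(rfd[1], -1)       # leftward in both replicates
  expect_equal(rfd[3], 1)        # rightward in both
  expect_true(is.na(rfd[2]))     # origin bin in every replicate: excluded
  expect_equal(rfd[4], 1)        # one rightward passage, one origin firing

  fx <- load_worked_fixture()
  ens2 <- run_ensemble(fx$config, fx$origins, fx$grid, n_sims = 30,
                       base_seed = 12)
  vals <- unlist(rfd_profile(ens2))
  expect_true(all(is.na(vals) | (vals >= -1 & vals <= 1)))
})

test_that("RFD is antisymmetric for a mirrored equal-rate origin pair", {
  grid <- genome_grid("c1", 60)
  ori <- data.frame(origin_id = c("a", "b"), chrom = "c1", bin = c(15, 46),
                    rate = 0.05)
  ens <- run_ensemble(sim_config(n_factors = 4), ori, grid, n_sims = 2500,
                      base_seed = 31)
  rfd <- rfd_profile(ens)$c1
  flip <- -rev(rfd)
  ok <- !is.na(rfd) & !is.na(flip)
  expect_gt(mean(ok), 0.9)
  expect_lt(mean(abs(rfd[ok] - flip[ok])), 0.08)
})

test_that("replicons tile the genome and track origin strength", {
  fx <- load_worked_fixture()
  ens <- run_ensemble(fx$config, fx$origins, fx$grid, n_sims = 40,
                      base_seed = 8)
  for (s in completed_ok <- Filter(function(x) x$completed, ens)) {
    part <- replicon_partition(s)
    expect_equal(sum(part), sum(fx$grid$length_bins))
    expect_true(all(part >= 1))
  }
  rl <- replicon_lengths(ens)
  expect_equal(rl$origin_id, fx$origins$origin_id)
  expect_true(all(rl$mean_replicon_kb > 0))

  # a 10x stronger origin claims the larger mean replicon
  grid <- genome_grid("c1", 30)
  two <- data.frame(origin_id = c("strong", "weak"), chrom = "c1",
                    bin = c(5, 25), rate = c(0.2, 0.02))
  ens2 <- run_ensemble(sim_config(n_factors = 2), two, grid, n_sims = 800,
                       base_seed = 19)
  rl2 <- replicon_lengths(ens2)
  expect_gt(rl2$mean_replicon_kb[1], rl2$mean_replicon_kb[2])
  # and per-replicate partitions still tile the 30-kb chromosome
  sums <- vapply(Filter(function(x) x$completed, ens2),
                 function(s) sum(replicon_partition(s)), numeric(1))
  expect_true(all(sums == 30))
})

test_that("firing-time samples cover fired replicates only", {
  ens <- fake_pair()
  ft <- firing_time_distributions(ens)
  expect_equal(ft$o1, c(1, 2))
  expect_equal(ft$o2, 4)  # passivated replicate excluded
})

test_that("time-resolved curves respect boundary values and conservation", {
  fx <- load_worked_fixture()
  ens <- run_ensemble(fx$config, fx$origins, fx$grid, n_sims = 15,
                      base_seed = 23, keep_events = TRUE)
  tc <- time_curves(ens, grid_step = 1)
  expect_equal(tc$fraction_unreplicated[1], 1)
  expect_equal(tc$fraction_unreplicated[nrow(tc)], 0)
  expect_equal(tc$free_factors[1], fx$config$n_factors)
  expect_true(all(tc$free_factors <= fx$config$n_factors + 1e-9))
  expect_true(all(tc$active_forks >= 0))
  n_ori <- nrow(fx$origins)
  expect_equal(tc$available_origins[1], n_ori)
  expect_true(all(tc$available_origins + tc$fired_origins <= n_ori + 1e-9))
  expect_true(all(diff(tc$fired_origins) >= -1e-9))

  ens_noev <- run_ensemble(fx$config, fx$origins, fx$grid, n_sims = 3,
                           base_seed = 23)
  expect_error(time_curves(ens_noev), "keep_events")
})

test_that("factor sweeps report MAE per F and skip underdetermined fits", {
  fx <- load_worked_fixture()
  expect_warning(
    sw <- firing_factor_sweep(fx$origins, fx$grid, fx$timing,
                              f_values = c(2, 4, 8), n_sims = 60,
                              config = fx$config, base_seed = 41),
    "polynomial")
  expect_equal(sw$table$F, c(2, 4, 8))
  expect_true(all(is.finite(sw$table$mae)))
  expect_null(sw$poly)
  # MAE at the generative F should not beat distant F values badly:
  # the fixture rates are the truth at F = 4
  expect_lt(sw$table$mae[sw$table$F == 4], sw$table$mae[sw$table$F == 2])
})
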