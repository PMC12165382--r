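#' Specification of a synthetic toy genome
#'
#' @param chrom_bins integer vector: length of each toy chromosome in 1-kb
#'   bins.
#' @param origins_per_chrom origins placed on each chromosome (recycled to
#'   the number of chromosomes).
#' @param rate_range log-uniform bounds for origin firing rates (per minute
#'   per free factor).
#' @param seed integer seed controlling placements and rates.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(chrom_bins = c(300, 300), origins_per_chrom = 6,
                     rate_range = c(0.01, 0.1), seed = 1) {
  stopifnot(all(chrom_bins >= 1), all(origins_per_chrom >= 1),
            length(rate_range) == 2, all(rate_range > 0),
            rate_range[1] < rate_range[2])
  origins_per_chrom <- rep_len(origins_per_chrom, length(chrom_bins))
  if (any(origins_per_chrom > chrom_bins))
    stop("more origins than bins on a chromosome")
  structure(list(chrom_bins = as.integer(chrom_bins),
                 origins_per_chrom = as.integer(origins_per_chrom),
                 rate_range = rate_range, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate a toy genome with known firing rates
#'
#' Places the requested number of origins uniformly at random on distinct
#' bins of each chromosome and draws their firing rates log-uniformly, so
#' the toy spans the early-to-late origin behaviour seen in real timing
#' data. Output uses the same structures and file formats the readers
#' accept, and is fully reproducible from the spec's seed.
#'
#' @param spec a [toy_spec()].
#' @return List with `grid` ([genome_grid()]), `catalog` (origin catalog
#'   data frame with bp coordinates and status `Confirmed`), and `origins`
#'   (rate table: `origin_id`, `chrom`, `bin`, `rate`).
#' @export
make_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  chrom <- sprintf("toy_chr%d", seq_along(spec$chrom_bins))
  grid <- genome_grid(chrom, spec$chrom_bins)
  rows <- list()
  for (c_i in seq_along(chrom)) {
    bins <- sort(sample.int(spec$chrom_bins[c_i], spec$origins_per_chrom[c_i]))
    rows[[c_i]] <- data.frame(chrom = chrom[c_i], bin = bins,
                              stringsAsFactors = FALSE)
  }
  ori <- do.call(rbind, rows)
  ori$origin_id <- sprintf("ori_%02d", seq_len(nrow(ori)))
  lo <- log(spec$rate_range[1]); hi <- log(spec$rate_range[2])
  ori$rate <- exp(stats::runif(nrow(ori), lo, hi))
  catalog <- data.frame(chrom = ori$chrom,
                        start = (ori$bin - 1L) * 1000L + 1L,
                        end = ori$bin * 1000L,
                        status = "Confirmed", name = ori$origin_id,
                        stringsAsFactors = FALSE)
  class(catalog) <- c("origin_catalog", "data.frame")
  list(grid = grid, catalog = catalog,
       origins = ori[c("origin_id", "chrom", "bin", "rate")])
}

#' Simulate a pseudo-experimental reference timing profile
#'
#' Runs an ensemble with known firing rates and returns the per-bin mean
#' replication time as a [timing_profile()]. Because the generative rates
#' are known, profiles made this way are ground truth for closed-loop
#' parameter-recovery tests of the fitting algorithm.
#'
#' @param grid a [genome_grid()].
#' @param origins rate table (`origin_id`, `chrom`, `bin`, `rate`).
#' @param config a [sim_config()].
#' @param n_sims ensemble size.
#' @param base_seed ensemble seed.
#' @param noise_sd optional additive Gaussian noise (minutes) applied to the
#'   mean profile, truncated at zero; 0 disables it.
#' @return A [timing_profile()].
#' @export
generate_reference_timing <- function(grid, origins, config = sim_config(),
                                      n_sims = 500, base_seed = 1,
                                      noise_sd = 0) {
  ens <- run_ensemble(config, origins, grid, n_sims = n_sims,
                      base_seed = base_seed)
  prof <- timing_profiles(ens)$mean
  if (noise_sd > 0) {
    set.seed(base_seed + 1L)
    prof$time <- lapply(prof$time, function(v)
      pmax(v + stats::rnorm(length(v), 0, noise_sd), 0))
  }
  prof
}

#' The worked synthetic fixture
#'
#' A fixed small problem used throughout the tests and documentation: two
#' 300-bin (300 kb) chromosomes carrying 12 origins whose true rates span a
#' factor of ten, with a reference timing profile simulated from those rates
#' (500 replicates). The firing-factor pool is scaled down with the genome
#' (F = 4, about a third of the origin count, mirroring the 200:626 ratio of
#' the full yeast model) so the fixture stays in the competitive regime
#' where factors are rate-limiting; recycling and fork speed keep their
#' defaults. Everything is regenerated deterministically from a fixed seed;
#' a text copy ships in `inst/extdata/worked_fixture/`.
#'
#' @param dir if non-NULL, write `grid.tsv`, `origins.tsv`, `rates.tsv` and
#'   `timing.bedgraph` there (created if missing).
#' @param n_sims ensemble size behind the reference profile.
#' @return List with `grid`, `catalog`, `origins` (true rates), `timing`
#'   (reference profile) and `config` (the [sim_config()] used).
#' @export
make_worked_fixture <- function(dir = NULL, n_sims = 500) {
  spec <- toy_spec(chrom_bins = c(300, 300), origins_per_chrom = 6,
                   rate_range = c(0.01, 0.1), seed = 20250901)
  toy <- make_toy_genome(spec)
  cfg <- sim_config(n_factors = 4)
  timing <- generate_reference_timing(toy$grid, toy$origins, cfg,
                                      n_sims = n_sims, base_seed = 104729)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(chromosome = toy$grid$chrom,
                 length_bp = toy$grid$length_bins * 1000L),
      file.path(dir, "grid.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(chromosome = toy$catalog$chrom, start = toy$catalog$start,
                 end = toy$catalog$end, status = toy$catalog$status,
                 name = toy$catalog$name),
      file.path(dir, "origins.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_rate_table(toy$origins, file.path(dir, "rates.tsv"))
    write_timing_bedgraph(timing, file.path(dir, "timing.bedgraph"))
  }
  c(toy, list(timing = timing, config = cfg))
}

#' Load the shipped copy of the worked fixture through the file readers
#'
#' @return Same shape as [make_worked_fixture()], read from
#'   `inst/extdata/worked_fixture/`.
#' @export
load_worked_fixture <- function() {
  dir <- system.file("extdata", "worked_fixture", package = "repliforge",
                     mustWork = TRUE)
  grid <- read_grid(file.path(dir, "grid.tsv"))
  catalog <- suppressMessages(
    read_origin_catalog(file.path(dir, "origins.tsv")))
  origins <- read_rate_table(file.path(dir, "rates.tsv"))
  timing <- read_timing_profile(file.path(dir, "timing.bedgraph"), grid)
  list(grid = grid, catalog = catalog, origins = origins, timing = timing,
       config = sim_config(n_factors = 4))
}
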