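# shared builders for toy problems; everything is generated in code

single_origin_setup <- function(n_bins = 15, bin = 1, rate = 1e-3,
                                n_factors = 200) {
  list(grid = genome_grid("c1", n_bins),
       origins = data.frame(origin_id = "o1", chrom = "c1", bin = bin,
                            rate = rate, stringsAsFactors = FALSE),
       config = sim_config(n_factors = n_factors))
}

# hand-built sim_result with prescribed per-bin times/directions/parents,
# for exact-arithmetic checks of the ensemble statistics
fake_sim <- function(grid, origins, time, direction, parent,
                     completed = TRUE) {
  origins$fate_time <- ifelse(origins$fate == "fired", origins$fate_time, NA)
  structure(list(grid = grid, origins = origins, time = time,
                 direction = direction, parent = parent,
                 forks = NULL, events = NULL, completed = completed,
                 completion_time = max(unlist(time)), stalled = FALSE,
                 t_end = max(unlist(time)), config = sim_config()),
            class = "sim_result")
}

fake_ensemble <- function(sims, origins, grid) {
  structure(sims, class = "sim_ensemble", config = sims[[1]]$config,
            origins = origins, grid = grid,
            base_seed = NA,
            n_completed = sum(vapply(sims, `[[`, logical(1), "completed")))
}

write_origin_tsv <- function(path, rows) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
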