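# Reduced-scale ensembles shared across acceptance checks: 20 x 20 arena,
# 500 search iterations (10 for the reduced-search experiment, preserving
# the catalogue's 100/5000 ratio), 25 timesteps, 10 realisations. Built
# lazily and memoised so several test blocks can reuse the same runs.
# Ensemble base seeds are fixed as 1000 + 10 * experiment + variant index.

.acc_cache <- new.env(parent = emptyenv())

acc_config <- function(code) {
  id <- as.integer(sub("[abcd]$", "", code))
  build_config(code, width = 20, height = 20, timesteps = 25, n_reps = 10,
               search_iterations = if (id == 7L) 10L else 500L)
}

acc_seed <- function(code) {
  id <- as.integer(sub("[abcd]$", "", code))
  vi <- match(sub("^[0-9]+", "", code), c("a", "b", "c", "d"))
  1000L + 10L * id + vi
}

acc_ensemble <- function(code) {
  if (!exists(code, envir = .acc_cache)) {
    ens <- run_ensemble(as_engine_config(acc_config(code)), n_reps = 10,
                        base_seed = acc_seed(code), record_events = FALSE)
    assign(code, ens, envir = .acc_cache)
  }
  get(code, envir = .acc_cache)
}

# Ensemble mean of the final-timestep global supply of one service.
acc_final_supply <- function(ens, service) {
  m <- ensemble_supply(ens, service)
  mean(m[nrow(m), ])
}

# Ensemble mean of final global food + recreation supply.
acc_final_total <- function(ens) {
  acc_final_supply(ens, "food") + acc_final_supply(ens, "recreation")
}

# Ensemble mean of the final share held by the given AFT indices.
acc_final_share <- function(ens, aft_idx) {
  mean(vapply(ens, function(r) {
    mean(final_snapshot(r) %in% aft_idx)
  }, numeric(1L)))
}

# Final global demand for a service (identical across realisations).
acc_final_demand <- function(ens, service) {
  dem <- ens[[1L]][[paste0("demand_", service)]]
  sum(dem[nrow(dem), ])
}
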