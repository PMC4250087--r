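# Small in-code fixtures shared across test files.

# A world with explicitly chosen capital matrices (row 1 = y 0).
toy_world <- function(crop, natural) {
  capital_grid(list(crop = crop, natural = natural))
}

# 2x2 world with hand-set, tie-free capitals.
toy_world_2x2 <- function() {
  toy_world(crop = matrix(c(0.9, 0.2, 0.6, 0.3), 2),
            natural = matrix(c(0.1, 0.8, 0.4, 0.7), 2))
}

# Random tie-free world of the given size.
random_world <- function(width, height) {
  toy_world(crop = matrix(runif(width * height), height),
            natural = matrix(runif(width * height), height))
}

baseline_afts <- function() aft_presets(c("hif", "cons"))

# Exhaustive search over all K^n assignments maximising total production;
# independent of the package's allocation code paths.
brute_force_best_assignment <- function(world, afts, value = function(sup) sum(sup)) {
  n <- world$width * world$height
  K <- length(afts)
  caps <- lapply(world$capitals, as.vector)
  prod_cell <- function(i, k) {
    cv <- vapply(caps, `[[`, numeric(1L), i)
    production_vector(afts[[k]], cv)
  }
  best <- NULL
  grid <- rep(list(seq_len(K)), n)
  for (flat in seq_len(K^n) - 1L) {
    assign_vec <- integer(n)
    rem <- flat
    for (i in seq_len(n)) {
      assign_vec[i] <- rem %% K + 1L
      rem <- rem %/% K
    }
    sup <- Reduce(`+`, lapply(seq_len(n), function(i) prod_cell(i, assign_vec[i])))
    v <- value(sup)
    if (is.null(best) || v > best$value) {
      best <- list(assignment = assign_vec, supply = sup, value = v)
    }
  }
  best
}

# Minimal engine configuration around a world, mostly defaults overridable.
toy_engine_config <- function(world, afts, demand = 10, dynamic = FALSE,
                              per_side = 1L, timesteps = 5L,
                              benefits = list(food = benefit_linear(3),
                                              recreation = benefit_linear(3)),
                              search_iterations = 50L,
                              cells_per_search = min(4L, world$width * world$height),
                              change_timestep = 2L) {
  regions <- make_region_map(world$width, world$height, per_side)
  schedule <- demand_schedule(demand, dynamic = dynamic,
                              n_regions = regions$n_regions,
                              timesteps = timesteps,
                              change_timestep = change_timestep)
  engine_config(world, regions, afts, schedule, benefits = benefits,
                search_iterations = search_iterations,
                cells_per_search = cells_per_search,
                timesteps = timesteps)
}
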