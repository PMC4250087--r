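#' Assemble an engine configuration
#'
#' Binds a world, region partition, AFT roster, demand schedule and benefit
#' functions into a runnable configuration. Defaults follow the standard
#' setup: 5000 search iterations of 10 cells per AFT per timestep, 25
#' timesteps.
#'
#' @param world A [capital_grid()].
#' @param regions A [make_region_map()] matching the world's dimensions
#'   (1 region = globalised demand, 4 = regionalised).
#' @param afts Non-empty list of [aft_spec()] objects; list order is the
#'   declaration order used for tie-breaking.
#' @param schedule A [demand_schedule()].
#' @param benefits Named list of [benefit_function][benefit_linear] objects
#'   for `food` and `recreation`.
#' @param search_iterations Search iterations per AFT per timestep.
#' @param cells_per_search Cells sampled (without replacement) per search
#'   iteration.
#' @param timesteps Run horizon (>= 0).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(world, regions, afts, schedule,
                          benefits = list(food = benefit_linear(3),
                                          recreation = benefit_linear(3)),
                          search_iterations = 5000L,
                          cells_per_search = 10L,
                          timesteps = 25L) {
  stopifnot(inherits(world, "capital_grid"), inherits(regions, "region_map"),
            inherits(schedule, "demand_schedule"))
  .check_afts(afts)
  if (regions$width != world$width || regions$height != world$height) {
    stop("region map dimensions do not match the world", call. = FALSE)
  }
  if (schedule$n_regions != regions$n_regions) {
    stop("demand schedule and region map disagree on the number of regions", call. = FALSE)
  }
  for (s in c("food", "recreation")) {
    if (!inherits(benefits[[s]], "benefit_function")) {
      stop("`benefits` must contain a benefit_function for '", s, "'", call. = FALSE)
    }
  }
  search_iterations <- as.integer(search_iterations)
  cells_per_search <- as.integer(cells_per_search)
  timesteps <- as.integer(timesteps)
  n <- world$width * world$height
  if (is.na(search_iterations) || search_iterations < 0L) {
    stop("`search_iterations` must be >= 0", call. = FALSE)
  }
  if (is.na(cells_per_search) || cells_per_search < 1L || cells_per_search > n) {
    stop("`cells_per_search` must be in 1..#cells", call. = FALSE)
  }
  if (is.na(timesteps) || timesteps < 0L) stop("`timesteps` must be >= 0", call. = FALSE)
  structure(
    list(world = world, regions = regions, afts = afts, schedule = schedule,
         benefits = benefits, search_iterations = search_iterations,
         cells_per_search = cells_per_search, timesteps = timesteps),
    class = "engine_config"
  )
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("<engine_config> %dx%d world, %d region(s), %d AFT(s), %d timesteps, %d searches x %d cells\n",
              x$world$width, x$world$height, x$regions$n_regions,
              length(x$afts), x$timesteps, x$search_iterations, x$cells_per_search))
  invisible(x)
}

# Internal: benefit parameters in flat form for the hot loop.
.benefit_flat <- function(fn) {
  list(linear = fn$form == "linear", a = if (fn$form == "linear") fn$gradient else NA_real_)
}

# Internal: supply per region from an occupancy vector, computed from scratch.
.supply_from_occ <- function(occ, pf_m, pr_m, reg, R) {
  Sf <- numeric(R); Sr <- numeric(R)
  occi <- which(occ != 0L)
  if (length(occi) > 0L) {
    idx <- cbind(occi, occ[occi])
    tf <- rowsum(pf_m[idx], reg[occi])
    tr <- rowsum(pr_m[idx], reg[occi])
    rs <- as.integer(rownames(tf))
    Sf[rs] <- tf; Sr[rs] <- tr
  }
  list(food = Sf, recreation = Sr)
}

#' Initialise a simulation state
#'
#' Seeds the RNG, occupies every cell with an agent of a uniformly random
#' AFT from the roster (thresholds sampled per agent at creation), and
#' computes the initial market. The returned state is an environment:
#' engine operations mutate it in place and also return it, so both
#' `sim_step(state)` and `state <- sim_step(state)` work.
#'
#' @param config An [engine_config()].
#' @param seed Integer seed; the single RNG stream for the whole
#'   realisation is seeded here.
#' @return An environment of class `sim_state`. Key fields: `t` (current
#'   timestep, 0 after initialisation), `occ` (per-cell 1-based AFT index,
#'   0 = unmanaged), `abv`/`ctv` (per-cell sampled thresholds),
#'   `Sf`/`Sr` (per-region supplies), `xf`/`xr` (unmet fractions),
#'   `bff`/`bfr` (per-region benefit factors).
#' @export
initialise_state <- function(config, seed) {
  stopifnot(inherits(config, "engine_config"))
  set.seed(as.integer(seed))
  world <- config$world
  K <- length(config$afts)
  n <- world$width * world$height
  R <- config$regions$n_regions
  T <- config$timesteps

  ps <- .production_surfaces(world, config$afts)
  pf_m <- ps$food %||% matrix(0, n, K)
  pr_m <- ps$recreation %||% matrix(0, n, K)

  thr_num <- function(t) if (t$kind == "constant") 1L else 2L
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$seed <- as.integer(seed)
  st$n <- n; st$K <- K; st$R <- R; st$T <- T
  st$W <- world$width; st$H <- world$height
  st$pf_m <- pf_m; st$pr_m <- pr_m
  st$pfl <- lapply(seq_len(K), function(k) pf_m[, k])
  st$prl <- lapply(seq_len(K), function(k) pr_m[, k])
  st$reg <- as.integer(config$regions$assignment)
  st$crop <- as.vector(world$capitals$crop)
  st$natural <- as.vector(world$capitals$natural)
  st$ab_kind <- vapply(config$afts, function(a) thr_num(a$abandonment), integer(1L))
  st$ab_mean <- vapply(config$afts, function(a) a$abandonment$mean, numeric(1L))
  st$ab_sd   <- vapply(config$afts, function(a) a$abandonment$sd, numeric(1L))
  st$ct_kind <- vapply(config$afts, function(a) thr_num(a$competition), integer(1L))
  st$ct_mean <- vapply(config$afts, function(a) a$competition$mean, numeric(1L))
  st$ct_sd   <- vapply(config$afts, function(a) a$competition$sd, numeric(1L))
  bf <- .benefit_flat(config$benefits$food)
  br <- .benefit_flat(config$benefits$recreation)
  st$lin_f <- bf$linear; st$a_f <- bf$a
  st$lin_r <- br$linear; st$a_r <- br$a
  st$its <- config$search_iterations
  st$cps <- config$cells_per_search

  # random initial distribution of agents
  occ <- sample.int(K, n, replace = TRUE)
  abv <- numeric(n); ctv <- numeric(n)
  for (k in seq_len(K)) {
    idx <- which(occ == k)
    if (length(idx) > 0L) {
      abv[idx] <- sample_threshold(config$afts[[k]]$abandonment, length(idx))
      ctv[idx] <- sample_threshold(config$afts[[k]]$competition, length(idx))
    }
  }
  st$occ <- occ; st$abv <- abv; st$ctv <- ctv
  st$t <- 0L

  lv <- demand_levels(config$schedule, 0L)
  st$Dft <- lv$food; st$Drt <- lv$recreation
  sup <- .supply_from_occ(occ, pf_m, pr_m, st$reg, R)
  st$Sf <- sup$food; st$Sr <- sup$recreation
  .update_benefits(st, seq_len(R))

  # per-timestep records, row 1 = initial state (t = 0)
  st$rec_sf <- matrix(NA_real_, T + 1L, R); st$rec_sf[1L, ] <- st$Sf
  st$rec_sr <- matrix(NA_real_, T + 1L, R); st$rec_sr[1L, ] <- st$Sr
  st$rec_df <- matrix(NA_real_, T + 1L, R); st$rec_df[1L, ] <- st$Dft
  st$rec_dr <- matrix(NA_real_, T + 1L, R); st$rec_dr[1L, ] <- st$Drt
  st$snaps <- matrix(NA_integer_, n, T + 1L); st$snaps[, 1L] <- occ
  st$events <- list()
  class(st) <- c("sim_state", "environment")
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: recompute unmet fractions and benefit factors for regions `rs`
# from the state's current supply and demand.
.update_benefits <- function(st, rs) {
  for (r in rs) {
    st$xf[r] <- if (st$Dft[r] > 0) (st$Dft[r] - st$Sf[r]) / st$Dft[r] else 0
    st$xr[r] <- if (st$Drt[r] > 0) (st$Drt[r] - st$Sr[r]) / st$Drt[r] else 0
    st$bff[r] <- if (st$lin_f) max(st$a_f * st$xf[r], 0) else exp(st$xf[r])
    st$bfr[r] <- if (st$lin_r) max(st$a_r * st$xr[r], 0) else exp(st$xr[r])
  }
  invisible(st)
}

#' Refresh the market from the allocation and current demand
#'
#' Recomputes per-region supplies from scratch from the allocation, loads
#' the demand levels of the state's current timestep, and updates unmet
#' fractions and benefit factors. Called at the start of every [sim_step()];
#' exposed for testing and custom schedules.
#'
#' @param state A `sim_state` environment.
#' @return The state, invisibly.
#' @export
refresh_market <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  lv <- demand_levels(state$config$schedule, state$t)
  state$Dft <- lv$food; state$Drt <- lv$recreation
  sup <- .supply_from_occ(state$occ, state$pf_m, state$pr_m, state$reg, state$R)
  state$Sf <- sup$food; state$Sr <- sup$recreation
  state$xf <- numeric(state$R); state$xr <- numeric(state$R)
  state$bff <- numeric(state$R); state$bfr <- numeric(state$R)
  .update_benefits(state, seq_len(state$R))
  invisible(state)
}

#' Abandonment pass
#'
#' Visits occupied cells in randomised order; each occupant whose
#' competitiveness at its own cell under the current market is less than or
#' equal to its abandonment threshold vacates the cell. The market is
#' updated incrementally after each vacancy, so reduced supply raises unmet
#' demand (and hence competitiveness) for occupants checked later — the
#' mechanism that makes abandonment self-limiting.
#'
#' @param state A `sim_state` environment (market must be consistent with
#'   the allocation, e.g. after [refresh_market()]).
#' @param record Record abandonment events in the event log?
#' @return The state, invisibly (mutated in place).
#' @export
abandonment_pass <- function(state, record = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  occ <- state$occ; abv <- state$abv
  Sf <- state$Sf; Sr <- state$Sr
  xf <- state$xf; xr <- state$xr
  bff <- state$bff; bfr <- state$bfr
  Dft <- state$Dft; Drt <- state$Drt
  pfl <- state$pfl; prl <- state$prl
  reg <- state$reg
  lin_f <- state$lin_f; a_f <- state$a_f
  lin_r <- state$lin_r; a_r <- state$a_r
  tnow <- state$t

  ev_cap <- 256L; ev_n <- 0L
  ev_cell <- integer(ev_cap); ev_prev <- integer(ev_cap)
  ev_comp <- numeric(ev_cap); ev_thr <- numeric(ev_cap)

  cells <- which(occ != 0L)
  if (length(cells) > 1L) cells <- sample(cells)
  for (i in cells) {
    k <- occ[i]
    r <- reg[i]
    comp <- bff[r] * pfl[[k]][i] + bfr[r] * prl[[k]][i]
    if (comp <= abv[i]) {
      occ[i] <- 0L
      Sf[r] <- Sf[r] - pfl[[k]][i]
      Sr[r] <- Sr[r] - prl[[k]][i]
      xf[r] <- if (Dft[r] > 0) (Dft[r] - Sf[r]) / Dft[r] else 0
      xr[r] <- if (Drt[r] > 0) (Drt[r] - Sr[r]) / Drt[r] else 0
      bff[r] <- if (lin_f) max(a_f * xf[r], 0) else exp(xf[r])
      bfr[r] <- if (lin_r) max(a_r * xr[r], 0) else exp(xr[r])
      if (record) {
        ev_n <- ev_n + 1L
        if (ev_n > ev_cap) {
          ev_cap <- ev_cap * 2L
          length(ev_cell) <- ev_cap; length(ev_prev) <- ev_cap
          length(ev_comp) <- ev_cap; length(ev_thr) <- ev_cap
        }
        ev_cell[ev_n] <- i; ev_prev[ev_n] <- k
        ev_comp[ev_n] <- comp; ev_thr[ev_n] <- abv[i]
      }
    }
  }

  state$occ <- occ
  state$Sf <- Sf; state$Sr <- Sr
  state$xf <- xf; state$xr <- xr
  state$bff <- bff; state$bfr <- bfr
  if (record && ev_n > 0L) {
    sq <- seq_len(ev_n)
    state$events[[length(state$events) + 1L]] <- data.frame(
      timestep = tnow, type = "abandonment", cell = ev_cell[sq],
      aft = NA_integer_, prev_aft = ev_prev[sq],
      comp_new = NA_real_, comp_prev = ev_comp[sq], threshold = ev_thr[sq]
    )
  }
  invisible(state)
}

#' Stochastic search and ranked takeover attempts
#'
#' Runs the configured number of search iterations for every AFT,
#' interleaved round-robin in an AFT order randomised per call. Each
#' iteration samples `cells_per_search` distinct cells uniformly, ranks
#' them by the searching type's competitiveness (ties broken at random),
#' then a single candidate agent (abandonment threshold freshly sampled)
#' attempts takeovers in rank order until one succeeds or the list is
#' exhausted. A takeover succeeds iff the cell is unmanaged, or the
#' challenger's competitiveness exceeds the occupant's by more than the
#' occupant's competition threshold; in either case the challenger's
#' competitiveness must also exceed its own abandonment threshold. On
#' success a fresh agent (newly sampled thresholds) occupies the cell and
#' the market is updated immediately.
#'
#' @inheritParams abandonment_pass
#' @return The state, invisibly (mutated in place).
#' @export
search_and_compete <- function(state, record = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  n <- state$n; K <- state$K
  its <- state$its; cps <- state$cps
  occ <- state$occ; abv <- state$abv; ctv <- state$ctv
  Sf <- state$Sf; Sr <- state$Sr
  xf <- state$xf; xr <- state$xr
  bff <- state$bff; bfr <- state$bfr
  Dft <- state$Dft; Drt <- state$Drt
  pfl <- state$pfl; prl <- state$prl
  reg <- state$reg
  lin_f <- state$lin_f; a_f <- state$a_f
  lin_r <- state$lin_r; a_r <- state$a_r
  ab_kind <- state$ab_kind; ab_mean <- state$ab_mean; ab_sd <- state$ab_sd
  ct_kind <- state$ct_kind; ct_mean <- state$ct_mean; ct_sd <- state$ct_sd
  tnow <- state$t

  ev_cap <- 256L; ev_n <- 0L
  ev_cell <- integer(ev_cap); ev_new <- integer(ev_cap); ev_prev <- integer(ev_cap)
  ev_cn <- numeric(ev_cap); ev_cp <- numeric(ev_cap); ev_thr <- numeric(ev_cap)

  korder <- if (K > 1L) sample.int(K) else 1L
  for (it in seq_len(its)) {
    for (k in korder) {
      pfk <- pfl[[k]]; prk <- prl[[k]]
      cells <- sample.int(n, cps)
      rg <- reg[cells]
      comp <- bff[rg] * pfk[cells] + bfr[rg] * prk[cells]
      athr <- if (ab_kind[k] == 1L) ab_mean[k] else max(stats::rnorm(1L, ab_mean[k], ab_sd[k]), 0)
      if (max(comp) <= athr) next
      o <- order(-comp, stats::runif(cps))
      for (j in o) {
        cc <- comp[j]
        if (cc <= athr) break  # sorted: no later cell can qualify
        i <- cells[j]
        prev <- occ[i]
        if (prev == k) next    # zero margin can never exceed ct >= 0
        if (prev != 0L) {
          r <- rg[j]
          oc <- bff[r] * pfl[[prev]][i] + bfr[r] * prl[[prev]][i]
          if (!(cc - oc > ctv[i])) next
        } else {
          oc <- NA_real_
        }
        # takeover succeeds
        r <- rg[j]
        ct_occ <- if (prev != 0L) ctv[i] else NA_real_
        if (prev != 0L) {
          Sf[r] <- Sf[r] - pfl[[prev]][i]
          Sr[r] <- Sr[r] - prl[[prev]][i]
        }
        occ[i] <- k
        abv[i] <- athr
        ctv[i] <- if (ct_kind[k] == 1L) ct_mean[k] else max(stats::rnorm(1L, ct_mean[k], ct_sd[k]), 0)
        Sf[r] <- Sf[r] + pfk[i]
        Sr[r] <- Sr[r] + prk[i]
        xf[r] <- if (Dft[r] > 0) (Dft[r] - Sf[r]) / Dft[r] else 0
        xr[r] <- if (Drt[r] > 0) (Drt[r] - Sr[r]) / Drt[r] else 0
        bff[r] <- if (lin_f) max(a_f * xf[r], 0) else exp(xf[r])
        bfr[r] <- if (lin_r) max(a_r * xr[r], 0) else exp(xr[r])
        if (record) {
          ev_n <- ev_n + 1L
          if (ev_n > ev_cap) {
            ev_cap <- ev_cap * 2L
            length(ev_cell) <- ev_cap; length(ev_new) <- ev_cap; length(ev_prev) <- ev_cap
            length(ev_cn) <- ev_cap; length(ev_cp) <- ev_cap; length(ev_thr) <- ev_cap
          }
          ev_cell[ev_n] <- i; ev_new[ev_n] <- k; ev_prev[ev_n] <- prev
          ev_cn[ev_n] <- cc; ev_cp[ev_n] <- oc; ev_thr[ev_n] <- ct_occ
        }
        break
      }
    }
  }

  state$occ <- occ; state$abv <- abv; state$ctv <- ctv
  state$Sf <- Sf; state$Sr <- Sr
  state$xf <- xf; state$xr <- xr
  state$bff <- bff; state$bfr <- bfr
  if (record && ev_n > 0L) {
    sq <- seq_len(ev_n)
    state$events[[length(state$events) + 1L]] <- data.frame(
      timestep = tnow, type = "takeover", cell = ev_cell[sq],
      aft = ev_new[sq], prev_aft = ev_prev[sq],
      comp_new = ev_cn[sq], comp_prev = ev_cp[sq], threshold = ev_thr[sq]
    )
  }
  invisible(state)
}

# Note: on a takeover row `comp_prev` is the displaced occupant's
# competitiveness and `threshold` its competition threshold (both NA for
# takeovers of unmanaged cells); on an abandonment row `comp_prev` is the
# leaver's competitiveness and `threshold` its abandonment threshold.

#' Advance the simulation by one timestep
#'
#' Order within a timestep: (1) refresh the market from the allocation and
#' the timestep's demand levels; (2) abandonment pass; (3) search and
#' takeover competition; (4) record supplies, demand, allocation snapshot.
#'
#' @inheritParams abandonment_pass
#' @return The state, invisibly (mutated in place, `t` incremented).
#' @export
sim_step <- function(state, record = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  if (state$t >= state$T) {
    stop("simulation horizon already reached (t = ", state$t, ")", call. = FALSE)
  }
  state$t <- state$t + 1L
  refresh_market(state)
  abandonment_pass(state, record = record)
  search_and_compete(state, record = record)
  rw <- state$t + 1L
  state$rec_sf[rw, ] <- state$Sf; state$rec_sr[rw, ] <- state$Sr
  state$rec_df[rw, ] <- state$Dft; state$rec_dr[rw, ] <- state$Drt
  state$snaps[, rw] <- state$occ
  invisible(state)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %d/%d, %d/%d cells occupied, %d region(s)\n",
              x$t, x$T, sum(x$occ != 0L), x$n, x$R))
  invisible(x)
}

#' Run a single realisation
#'
#' Initialises from the seed and advances the full horizon.
#'
#' @param config An [engine_config()].
#' @param seed Integer seed for this realisation.
#' @param record_events Keep the per-event log? (Supplies and snapshots are
#'   always recorded.)
#' @return An object of class `run_result`: a list with `seed`, `config`,
#'   `timesteps`, per-region supply/demand matrices `supply_food`,
#'   `supply_recreation`, `demand_food`, `demand_recreation` (rows are
#'   timesteps 0..T), `snapshots` (cells x (T+1) integer matrix of AFT
#'   indices, 0 = unmanaged) and `events` (data frame).
#' @export
run_realisation <- function(config, seed, record_events = TRUE) {
  st <- initialise_state(config, seed)
  while (st$t < st$T) sim_step(st, record = record_events)
  events <- if (length(st$events) > 0L) {
    do.call(rbind, st$events)
  } else {
    data.frame(timestep = integer(0L), type = character(0L), cell = integer(0L),
               aft = integer(0L), prev_aft = integer(0L),
               comp_new = numeric(0L), comp_prev = numeric(0L), threshold = numeric(0L))
  }
  tlab <- 0:st$T
  dimnames(st$rec_sf) <- dimnames(st$rec_sr) <- dimnames(st$rec_df) <-
    dimnames(st$rec_dr) <- list(tlab, NULL)
  structure(
    list(seed = st$seed, config = config, timesteps = st$T,
         supply_food = st$rec_sf, supply_recreation = st$rec_sr,
         demand_food = st$rec_df, demand_recreation = st$rec_dr,
         snapshots = st$snaps, events = events),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> seed %d, %d timesteps, %d events\n",
              x$seed, x$timesteps, nrow(x$events)))
  invisible(x)
}

#' Run a seeded ensemble of realisations
#'
#' Realisation `i` uses seed `base_seed + i - 1`, so an ensemble of size 1
#' equals `run_realisation(config, base_seed)` and repeated calls with the
#' same base seed reproduce the ensemble exactly.
#'
#' @inheritParams run_realisation
#' @param n_reps Number of realisations (default 30).
#' @param base_seed Integer base seed.
#' @return An object of class `run_ensemble`: a list of `run_result`s.
#' @export
run_ensemble <- function(config, n_reps = 30L, base_seed = 1L, record_events = TRUE) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  out <- lapply(seq_len(n_reps), function(i) {
    run_realisation(config, seed = as.integer(base_seed) + i - 1L,
                    record_events = record_events)
  })
  structure(out, class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("<run_ensemble> %d realisation(s), seeds %s..%s\n",
              length(x), x[[1L]]$seed, x[[length(x)]]$seed))
  invisible(x)
}

#' Long-format supply/demand series of a run
#'
#' @param result A `run_result`.
#' @return Data frame with columns `timestep` (0..T), `scope` (`"global"`
#'   plus `"region_<r>"` when regionalised), `service`, `demand`, `supply`.
#' @export
supply_series <- function(result) {
  stopifnot(inherits(result, "run_result"))
  R <- ncol(result$supply_food)
  tl <- 0:result$timesteps
  mk <- function(sup, dem, service) {
    rows <- data.frame(timestep = tl, scope = "global", service = service,
                       demand = rowSums(dem), supply = rowSums(sup))
    if (R > 1L) {
      for (r in seq_len(R)) {
        rows <- rbind(rows, data.frame(timestep = tl, scope = paste0("region_", r),
                                       service = service, demand = dem[, r],
                                       supply = sup[, r]))
      }
    }
    rows
  }
  out <- rbind(mk(result$supply_food, result$demand_food, "food"),
               mk(result$supply_recreation, result$demand_recreation, "recreation"))
  rownames(out) <- NULL
  out
}

#' Final allocation snapshot of a run
#'
#' @param result A `run_result`.
#' @param t Timestep (0..T); defaults to the final timestep.
#' @return Integer `height` x `width` matrix of AFT indices (0 = unmanaged).
#' @export
final_snapshot <- function(result, t = NULL) {
  stopifnot(inherits(result, "run_result"))
  if (is.null(t)) t <- result$timesteps
  t <- as.integer(t)
  if (t < 0L || t > result$timesteps) stop("`t` outside 0..timesteps", call. = FALSE)
  matrix(result$snapshots[, t + 1L], nrow = result$config$world$height)
}

#' Takeover margins from an event log
#'
#' For every takeover of an occupied cell, the challenger-minus-occupant
#' competitiveness margin. Used to verify that no takeover occurs at a
#' margin at or below the displaced occupant's competition threshold.
#'
#' @param events Event data frame from a `run_result`.
#' @return Numeric vector of margins (one per displacement takeover).
#' @export
takeover_margins <- function(events) {
  tk <- events[events$type == "takeover" & events$prev_aft != 0L, , drop = FALSE]
  tk$comp_new - tk$comp_prev
}
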