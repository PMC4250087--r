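#' Extract an ensemble supply matrix
#'
#' @param ensemble A [run_ensemble()] result.
#' @param service `"food"` or `"recreation"`.
#' @param scope `"global"` or a 1-based region index.
#' @return Numeric matrix, timesteps 0..T in rows (labelled), realisations
#'   in columns.
#' @export
ensemble_supply <- function(ensemble, service = "food", scope = "global") {
  stopifnot(inherits(ensemble, "run_ensemble"))
  field <- switch(service, food = "supply_food", recreation = "supply_recreation",
                  stop("unknown service: ", service, call. = FALSE))
  cols <- lapply(ensemble, function(r) {
    m <- r[[field]]
    if (identical(scope, "global")) rowSums(m) else m[, scope]
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(ensemble[[1L]][[field]])
  out
}

#' Detect the ensemble steady state
#'
#' A set of realisations is in a steady state once the between-realisation
#' variation in supply exceeds the timestep-to-timestep change in the
#' ensemble-mean supply: for every service, `sd_t(across realisations) >
#' |mean_t - mean_(t-1)|`, required to hold for `persist` consecutive
#' timesteps (a persistence guard against single-step flukes). Degenerate
#' ensembles with zero dispersion never satisfy the strict inequality and
#' return `NA`.
#'
#' @param x A [run_ensemble()] (global supplies of both services are used)
#'   or a named list of numeric matrices (time in rows, realisations in
#'   columns; one matrix per service).
#' @param window Optional numeric vector of time labels to search within
#'   (defaults to every timestep after the first).
#' @param persist Number of consecutive qualifying timesteps required
#'   (default 3).
#' @return The earliest qualifying time label (numeric), or `NA` if the
#'   criterion is never met.
#' @export
detect_steady_state <- function(x, window = NULL, persist = 3L) {
  if (inherits(x, "run_ensemble")) {
    x <- list(food = ensemble_supply(x, "food"),
              recreation = ensemble_supply(x, "recreation"))
  }
  stopifnot(is.list(x), length(x) > 0L)
  mats <- lapply(x, as.matrix)
  nr <- nrow(mats[[1L]])
  if (ncol(mats[[1L]]) < 2L) {
    stop("steady-state detection needs at least 2 realisations", call. = FALSE)
  }
  tl <- rownames(mats[[1L]])
  times <- if (is.null(tl)) seq_len(nr) else as.numeric(tl)
  ok <- rep(TRUE, nr)
  ok[1L] <- FALSE  # no drift defined at the first time point
  for (m in mats) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    drift <- c(NA_real_, abs(diff(mu)))
    ok <- ok & !is.na(drift) & (sdv > drift)
  }
  persist <- as.integer(persist)
  cand <- which(ok)
  if (!is.null(window)) cand <- cand[times[cand] %in% window]
  for (i in cand) {
    hi <- i + persist - 1L
    if (hi <= nr && all(ok[i:hi])) return(times[i])
  }
  NA_real_
}

#' Land-use composition of a snapshot
#'
#' @param snapshot Integer matrix or vector of per-cell AFT indices
#'   (0 = unmanaged).
#' @param afts Optional AFT list used to label the shares; defaults to
#'   `aft_1`, `aft_2`, ...
#' @return Named share vector over all AFTs plus `unmanaged`; sums to 1.
#' @export
landuse_composition <- function(snapshot, afts = NULL) {
  v <- as.integer(snapshot)
  v[is.na(v)] <- 0L
  K <- if (is.null(afts)) max(v, 1L) else length(afts)
  counts <- tabulate(v + 1L, nbins = K + 1L)  # slot 1 = unmanaged
  shares <- counts / length(v)
  labels <- if (is.null(afts)) paste0("aft_", seq_len(K)) else
    vapply(afts, function(a) a$name, character(1L))
  stats::setNames(c(shares[-1L], shares[1L]), c(labels, "unmanaged"))
}

#' Capital-space occupancy histogram
#'
#' Two-dimensional counts of the cells occupied by one AFT, binned by the
#' cells' (crop, natural) capital values over `[0, 1]`.
#'
#' @param snapshot Per-cell AFT indices (0 = unmanaged).
#' @param world A [capital_grid()] with capitals `crop` and `natural`.
#' @param aft 1-based AFT index whose occupancy is binned.
#' @param bins Number of equal-width bins per axis (>= 1).
#' @return `bins` x `bins` integer matrix (crop bins in rows, natural bins
#'   in columns); total equals the AFT's cell count.
#' @export
capital_space_histogram <- function(snapshot, world, aft, bins = 10L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("`bins` must be >= 1", call. = FALSE)
  v <- as.integer(snapshot)
  idx <- which(!is.na(v) & v == as.integer(aft))
  crop <- as.vector(world$capitals$crop)[idx]
  nat <- as.vector(world$capitals$natural)[idx]
  bx <- pmin(floor(crop * bins) + 1L, bins)
  by <- pmin(floor(nat * bins) + 1L, bins)
  h <- matrix(0L, bins, bins,
              dimnames = list(crop = NULL, natural = NULL))
  if (length(idx) > 0L) {
    tab <- table(factor(bx, levels = seq_len(bins)), factor(by, levels = seq_len(bins)))
    h[] <- as.integer(tab)
  }
  h
}

#' Mean capital level over one AFT's occupied cells
#'
#' The occupancy-weighted mean of a capital for the cells an AFT holds in a
#' snapshot (`NaN` when the AFT holds no cells).
#'
#' @inheritParams capital_space_histogram
#' @param capital Capital name (default `"natural"`).
#' @return A single mean in \[0, 1\], or `NaN`.
#' @export
occupied_capital_mean <- function(snapshot, world, aft, capital = "natural") {
  v <- as.integer(snapshot)
  idx <- which(!is.na(v) & v == as.integer(aft))
  mean(as.vector(world$capitals[[capital]])[idx])
}

#' Per-timestep profile of abandoned cells
#'
#' Counts abandonment events per timestep and averages the capitals of the
#' vacated cells, supporting analyses of whether abandoned land is marginal
#' or productive.
#'
#' @param events Event data frame from a `run_result`.
#' @param world The [capital_grid()] the run used.
#' @return Data frame with columns `timestep`, `n` and `mean_<capital>` for
#'   every capital; zero rows when nothing was abandoned.
#' @export
abandonment_profile <- function(events, world) {
  ab <- events[events$type == "abandonment", , drop = FALSE]
  capnames <- names(world$capitals)
  if (nrow(ab) == 0L) {
    out <- data.frame(timestep = integer(0L), n = integer(0L))
    for (nm in capnames) out[[paste0("mean_", nm)]] <- numeric(0L)
    return(out)
  }
  ts <- sort(unique(ab$timestep))
  out <- data.frame(timestep = ts,
                    n = as.integer(table(factor(ab$timestep, levels = ts))))
  for (nm in capnames) {
    capv <- as.vector(world$capitals[[nm]])[ab$cell]
    out[[paste0("mean_", nm)]] <- as.numeric(tapply(capv, factor(ab$timestep, levels = ts), mean))
  }
  rownames(out) <- NULL
  out
}

#' Same-type adjacency concentration
#'
#' For every occupied cell with at least one occupied 4-neighbour (von
#' Neumann neighbourhood; boundary cells use existing neighbours only), the
#' fraction of its occupied neighbours holding the same AFT; the metric is
#' the mean of those fractions. 1 for a single-type full grid, 0 for a
#' two-type checkerboard; about 0.5 for a uniformly random two-type
#' allocation. Unmanaged cells are excluded from both numerator and
#' denominator.
#'
#' @param snapshot Integer `height` x `width` matrix of AFT indices
#'   (0 = unmanaged).
#' @return Concentration in \[0, 1\] (`NaN` if no occupied cell has an
#'   occupied neighbour).
#' @export
adjacency_concentration <- function(snapshot) {
  m <- as.matrix(snapshot)
  mode(m) <- "integer"
  m[is.na(m)] <- 0L
  H <- nrow(m); W <- ncol(m)
  nb_occ <- matrix(0L, H, W)
  nb_same <- matrix(0L, H, W)
  add_pair <- function(ci, cj, ni, nj) {
    a <- m[ci, cj, drop = FALSE]; b <- m[ni, nj, drop = FALSE]
    occ <- b > 0L
    nb_occ[ci, cj] <<- nb_occ[ci, cj, drop = FALSE] + occ
    nb_same[ci, cj] <<- nb_same[ci, cj, drop = FALSE] + (occ & a == b)
  }
  if (H > 1L) {
    add_pair(1:(H - 1L), 1:W, 2:H, 1:W)       # neighbour above (next row)
    add_pair(2:H, 1:W, 1:(H - 1L), 1:W)       # neighbour below
  }
  if (W > 1L) {
    add_pair(1:H, 1:(W - 1L), 1:H, 2:W)       # neighbour right
    add_pair(1:H, 2:W, 1:H, 1:(W - 1L))       # neighbour left
  }
  valid <- m > 0L & nb_occ > 0L
  mean(nb_same[valid] / nb_occ[valid])
}

#' Supply per occupied cell
#'
#' Productive efficiency over time: supply divided by the number of
#' occupied cells in the producing scope (0 when the scope is empty).
#'
#' @param result A `run_result`.
#' @return Data frame with columns `timestep`, `scope`, `service`,
#'   `supply`, `occupied`, `efficiency`.
#' @export
productive_efficiency <- function(result) {
  stopifnot(inherits(result, "run_result"))
  R <- ncol(result$supply_food)
  reg <- as.integer(result$config$regions$assignment)
  tl <- 0:result$timesteps
  occ_counts <- sapply(tl, function(t) {
    occv <- result$snapshots[, t + 1L]
    cnt <- tabulate(reg[occv != 0L], nbins = R)
    c(sum(cnt), cnt)
  })  # (R+1) x (T+1); row 1 = global
  scopes <- c("global", if (R > 1L) paste0("region_", seq_len(R)))
  rows <- list()
  for (service in c("food", "recreation")) {
    sup <- result[[paste0("supply_", service)]]
    supm <- cbind(rowSums(sup), sup)  # col 1 = global
    for (si in seq_along(scopes)) {
      s <- supm[, si]
      occ <- occ_counts[si, ]
      rows[[length(rows) + 1L]] <- data.frame(
        timestep = tl, scope = scopes[si], service = service,
        supply = s, occupied = occ,
        efficiency = ifelse(occ > 0L, s / occ, 0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Settling time of a run's allocation
#'
#' The last timestep at which more than `tol` of cells changed occupant
#' type relative to the previous timestep (0 if the allocation never
#' changes beyond `tol`). Larger values mean the land-use configuration
#' keeps reorganising for longer.
#'
#' @param result A `run_result`.
#' @param tol Change-fraction tolerance in \[0, 1\] (default 0: any change
#'   counts).
#' @return Integer timestep in 0..T.
#' @export
settling_time <- function(result, tol = 0) {
  stopifnot(inherits(result, "run_result"))
  sn <- result$snapshots
  T <- result$timesteps
  if (T < 1L) return(0L)
  frac <- vapply(seq_len(T), function(t) {
    mean(sn[, t + 1L] != sn[, t])
  }, numeric(1L))
  changed <- which(frac > tol)
  if (length(changed) == 0L) 0L else changed[length(changed)]
}

#' Time for the land-use map to reach its final organisation
#'
#' Tracks the ensemble-mean [adjacency_concentration()] of the allocation
#' over time and returns the earliest timestep from which the trajectory
#' stays within `tol` of its final value. Individual cells keep churning
#' under zero thresholds, so cell-level change never stops; the spatial
#' organisation of the map is what stabilises, quickly under ample search
#' effort and slowly when search is limited.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param tol Absolute tolerance on the concentration trajectory
#'   (default 0.02).
#' @return Integer timestep in 0..T.
#' @export
stabilisation_time <- function(ensemble, tol = 0.02) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  T <- ensemble[[1L]]$timesteps
  H <- ensemble[[1L]]$config$world$height
  traj <- rowMeans(vapply(ensemble, function(r) {
    vapply(0:T, function(t) {
      adjacency_concentration(matrix(r$snapshots[, t + 1L], nrow = H))
    }, numeric(1L))
  }, numeric(T + 1L)))
  dev <- abs(traj - traj[T + 1L])
  bad <- which(dev > tol)
  if (length(bad) == 0L) 0L else min(bad[length(bad)], T)
}

#' Summarise an ensemble
#'
#' Per-timestep ensemble mean and between-realisation dispersion of global
#' supply per service, mean final land-use shares, and the steady-state
#' timestep of each phase (initial, and after the demand change when the
#' schedule is dynamic).
#'
#' @param ensemble A [run_ensemble()] result.
#' @param persist Persistence requirement for [detect_steady_state()].
#' @return An object of class `ensemble_summary`: list with `supply` (data
#'   frame: timestep, service, demand, mean, sd), `final_shares` (named
#'   mean shares), `steady_initial`, `steady_post` (NA when not detected or
#'   not applicable).
#' @export
ensemble_summary <- function(ensemble, persist = 3L) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  first <- ensemble[[1L]]
  sched <- first$config$schedule
  tl <- 0:first$timesteps
  sup_rows <- list()
  for (service in c("food", "recreation")) {
    m <- ensemble_supply(ensemble, service)
    dem <- rowSums(first[[paste0("demand_", service)]])
    sup_rows[[service]] <- data.frame(
      timestep = tl, service = service, demand = dem,
      mean = rowMeans(m),
      sd = apply(m, 1L, stats::sd))
  }
  shares <- rowMeans(vapply(
    ensemble,
    function(r) landuse_composition(final_snapshot(r), r$config$afts),
    numeric(length(first$config$afts) + 1L)))
  change <- if (sched$dynamic) sched$change_timestep else NA_integer_
  init_window <- if (is.na(change)) seq_len(first$timesteps) else seq_len(change)
  steady_initial <- if (length(ensemble) >= 2L && first$timesteps >= 1L) {
    detect_steady_state(ensemble, window = init_window, persist = persist)
  } else NA_real_
  steady_post <- if (!is.na(change) && length(ensemble) >= 2L) {
    detect_steady_state(ensemble, window = (change + 1L):first$timesteps, persist = persist)
  } else NA_real_
  out <- list(supply = do.call(rbind, c(sup_rows, list(make.row.names = FALSE))),
              final_shares = shares,
              steady_initial = steady_initial, steady_post = steady_post,
              n_reps = length(ensemble))
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d realisations; steady (initial) t=%s, (post-change) t=%s\n",
              x$n_reps, format(x$steady_initial), format(x$steady_post)))
  fin <- x$supply[x$supply$timestep == max(x$supply$timestep), ]
  for (i in seq_len(nrow(fin))) {
    cat(sprintf("  final %-10s supply %.2f (sd %.2f) vs demand %.2f\n",
                fin$service[i], fin$mean[i], fin$sd[i], fin$demand[i]))
  }
  invisible(x)
}
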