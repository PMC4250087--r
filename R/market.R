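# Internal: per-cell Cobb-Douglas utilisation and production surfaces for a
# set of AFTs on a world. Cells are in column-major order of the H x W
# capital matrices. Returns an n x K matrix per service.
.production_surfaces <- function(world, afts) {
  stopifnot(inherits(world, "capital_grid"))
  n <- world$width * world$height
  K <- length(afts)
  services <- .service_names(afts)
  capvecs <- lapply(world$capitals, as.vector)
  out <- lapply(services, function(s) matrix(0, n, K))
  names(out) <- services
  for (k in seq_len(K)) {
    aft <- afts[[k]]
    miss <- setdiff(names(aft$sensitivities), names(capvecs))
    if (length(miss) > 0L) {
      stop("world lacks capital(s) required by AFT '", aft$name, "': ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    u <- rep(1, n)
    for (cp in names(aft$sensitivities)) {
      u <- u * capvecs[[cp]]^aft$sensitivities[[cp]]
    }
    for (s in services) {
      p <- aft$production[s]
      out[[s]][, k] <- if (is.na(p)) 0 else p * u
    }
  }
  out
}

.service_names <- function(afts) {
  unique(unlist(lapply(afts, function(a) names(a$production))))
}

.check_afts <- function(afts) {
  if (!is.list(afts) || length(afts) == 0L ||
      any(!vapply(afts, inherits, logical(1L), "aft_spec"))) {
    stop("`afts` must be a non-empty list of aft_spec objects", call. = FALSE)
  }
  invisible(afts)
}

#' Optimal (production-maximising) cell allocation
#'
#' Assigns every cell to the AFT with the largest total production (sum over
#' services) on that cell, ties broken by declaration order. This is the
#' "optimum agent configuration" oracle used to calibrate demand, and a
#' reference point for tests; it ignores demand, thresholds and search.
#'
#' @param world A [capital_grid()].
#' @param afts Non-empty list of [aft_spec()] objects.
#' @return A list with `assignment` (a `height` x `width` integer matrix of
#'   1-based AFT indices), `supply` (named per-service totals of the
#'   assignment) and `afts`.
#' @export
optimal_allocation <- function(world, afts) {
  .check_afts(afts)
  ps <- .production_surfaces(world, afts)
  total <- Reduce(`+`, ps)
  # ties -> first (declaration-order) maximum
  assign_vec <- max.col(total, ties.method = "first")
  idx <- cbind(seq_len(nrow(total)), assign_vec)
  supply <- vapply(ps, function(m) sum(m[idx]), numeric(1L))
  list(
    assignment = matrix(as.integer(assign_vec), nrow = world$height),
    supply = supply,
    afts = afts
  )
}

#' Balanced optimal configuration for equal service demands
#'
#' The optimum agent configuration for satisfying equal demands for both
#' services: each cell is assigned to the AFT maximising the weighted
#' production `w * food + (1 - w) * recreation` (ties by declaration
#' order), with the weight chosen so that the smaller of the two resulting
#' supplies is as large as possible (the max-min point of the
#' specialisation frontier). With `weight = 1` this reduces to the food
#' specialisation extreme; the default sweep balances the services.
#'
#' @inheritParams optimal_allocation
#' @param weights Weight grid swept over (defaults to a fine grid on
#'   \[0, 1\]).
#' @return A list with `assignment` (a `height` x `width` integer matrix),
#'   `supply` (named per-service totals), `weight` (the selected weight)
#'   and `afts`.
#' @export
balanced_allocation <- function(world, afts, weights = seq(0, 1, by = 0.0025)) {
  .check_afts(afts)
  ps <- .production_surfaces(world, afts)
  n <- world$width * world$height
  pf <- ps$food %||% matrix(0, n, length(afts))
  pr <- ps$recreation %||% matrix(0, n, length(afts))
  best <- NULL
  for (w in weights) {
    av <- max.col(w * pf + (1 - w) * pr, ties.method = "first")
    idx <- cbind(seq_len(n), av)
    sup <- c(food = sum(pf[idx]), recreation = sum(pr[idx]))
    if (is.null(best) || min(sup) > min(best$supply)) {
      best <- list(assignment = av, supply = sup, weight = w)
    }
  }
  # The sweep is granular wherever many cells tie at the same weight (on
  # gradient worlds whole rows switch sides at once). Refine by single-cell
  # reassignments towards the service in deficit while the smaller supply
  # still improves.
  av <- best$assignment
  F <- best$supply[["food"]]; R <- best$supply[["recreation"]]
  bf_aft <- max.col(pf, ties.method = "first")  # best food producer per cell
  br_aft <- max.col(pr, ties.method = "first")
  for (iter in seq_len(n)) {
    if (F < R) {
      tgt <- bf_aft
      gain <- pf[cbind(seq_len(n), tgt)] - pf[cbind(seq_len(n), av)]
      loss <- pr[cbind(seq_len(n), av)] - pr[cbind(seq_len(n), tgt)]
      newmin <- pmin(F + gain, R - loss)
    } else {
      tgt <- br_aft
      gain <- pr[cbind(seq_len(n), tgt)] - pr[cbind(seq_len(n), av)]
      loss <- pf[cbind(seq_len(n), av)] - pf[cbind(seq_len(n), tgt)]
      newmin <- pmin(R + gain, F - loss)
    }
    i <- which.max(newmin)
    if (newmin[i] <= min(F, R) + 1e-12) break
    av[i] <- tgt[i]
    F <- sum(pf[cbind(seq_len(n), av)])
    R <- sum(pr[cbind(seq_len(n), av)])
  }
  list(assignment = matrix(as.integer(av), nrow = world$height),
       supply = c(food = F, recreation = R), weight = best$weight, afts = afts)
}

#' Calibrate base demand so the optimum configuration almost satisfies it
#'
#' Demand for the two services is equal and static, set just above the
#' per-service supplies of the [balanced_allocation()] (the optimum agent
#' configuration for meeting both demands):
#' `D = (1 + headroom) * mean(balanced per-service supplies)`. The optimum
#' configuration is therefore almost -- but not quite -- capable of
#' satisfying demand for each service, so every cell is required for
#' production and remains subject to competition.
#'
#' @inheritParams optimal_allocation
#' @param headroom Fraction by which demand exceeds the mean balanced
#'   supply (> 0; default 0.02).
#' @return A single base demand level (production units per timestep).
#' @export
calibrate_demand <- function(world, afts, headroom = 0.02) {
  .check_afts(afts)
  if (!is.numeric(headroom) || length(headroom) != 1L || is.na(headroom) || headroom <= 0) {
    stop("`headroom` must be a single positive number", call. = FALSE)
  }
  if (world$width * world$height < 1L) stop("empty world", call. = FALSE)
  opt <- balanced_allocation(world, afts)
  (1 + headroom) * mean(opt$supply)
}

#' Build a demand schedule
#'
#' Static schedules hold demand for both services constant at `base`.
#' Dynamic schedules drop recreation demand by `drop_fraction` after
#' `change_timestep` (i.e. from timestep `change_timestep + 1` onwards);
#' food demand is unchanged. Under regionalisation each region's demand is
#' the global demand divided by the number of regions.
#'
#' @param base Global base demand per service (production units).
#' @param dynamic Logical; apply the recreation-demand step change?
#' @param n_regions Number of equal regions demand is divided between
#'   (1 = globalised).
#' @param timesteps Horizon (number of timesteps).
#' @param change_timestep Last timestep at the original recreation demand
#'   (default 11).
#' @param drop_fraction Fraction by which recreation demand drops
#'   (default 0.75).
#' @return An object of class `demand_schedule`.
#' @examples
#' sch <- demand_schedule(100, dynamic = TRUE, timesteps = 25)
#' demand_levels(sch, 12)
#' @export
demand_schedule <- function(base, dynamic = FALSE, n_regions = 1L,
                            timesteps = 25L, change_timestep = 11L,
                            drop_fraction = 0.75) {
  if (!is.numeric(base) || length(base) != 1L || is.na(base) || base < 0) {
    stop("`base` must be a single non-negative number", call. = FALSE)
  }
  timesteps <- as.integer(timesteps)
  change_timestep <- as.integer(change_timestep)
  if (is.na(timesteps) || timesteps < 0L) stop("`timesteps` must be >= 0", call. = FALSE)
  if (drop_fraction < 0 || drop_fraction > 1) {
    stop("`drop_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (dynamic && timesteps > 0L && change_timestep >= timesteps) {
    stop("`change_timestep` must be < `timesteps` for a dynamic schedule", call. = FALSE)
  }
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1L) stop("`n_regions` must be >= 1", call. = FALSE)
  structure(
    list(base = base, dynamic = isTRUE(dynamic), n_regions = n_regions,
         timesteps = timesteps, change_timestep = change_timestep,
         drop_fraction = drop_fraction, services = c("food", "recreation")),
    class = "demand_schedule"
  )
}

#' Demand levels at a timestep
#'
#' @param schedule A [demand_schedule()].
#' @param t Timestep index in `1:timesteps` (0 is accepted and returns the
#'   initial levels).
#' @return Named list with per-region demand vectors `food` and
#'   `recreation` (length `n_regions`).
#' @export
demand_levels <- function(schedule, t) {
  stopifnot(inherits(schedule, "demand_schedule"))
  t <- as.integer(t)
  rec <- schedule$base
  if (schedule$dynamic && t > schedule$change_timestep) {
    rec <- rec * (1 - schedule$drop_fraction)
  }
  R <- schedule$n_regions
  list(food = rep(schedule$base / R, R), recreation = rep(rec / R, R))
}

#' @export
print.demand_schedule <- function(x, ...) {
  cat(sprintf("<demand_schedule> base %.4g per service, %s, %d region(s), %d timesteps\n",
              x$base, if (x$dynamic) {
                sprintf("recreation -%.0f%% after t=%d", 100 * x$drop_fraction, x$change_timestep)
              } else "static", x$n_regions, x$timesteps))
  invisible(x)
}

#' @describeIn demand_levels Long-format data frame of the full schedule
#'   (timestep, scope, service, demand).
#' @param row.names,optional,... Passed through (standard
#'   `as.data.frame` arguments; unused).
#' @export
as.data.frame.demand_schedule <- function(x, row.names = NULL, optional = FALSE, ...) {
  R <- x$n_regions
  scopes <- if (R == 1L) "global" else paste0("region_", seq_len(R))
  rows <- do.call(rbind, lapply(seq_len(max(x$timesteps, 1L)), function(t) {
    lv <- demand_levels(x, t)
    data.frame(timestep = t,
               scope = rep(scopes, times = 2L),
               service = rep(c("food", "recreation"), each = R),
               demand = c(lv$food, lv$recreation))
  }))
  rows
}

#' Supply of an allocation
#'
#' Sums each occupant's per-service production over the occupied cells of
#' every scope. Global supply is the sum of regional supplies.
#'
#' @param allocation Integer matrix (or vector) of 1-based AFT indices per
#'   cell, 0 or `NA` meaning unmanaged.
#' @param world A [capital_grid()].
#' @param afts List of [aft_spec()] objects indexed by the allocation.
#' @param regions Optional [make_region_map()]; defaults to a single global
#'   region.
#' @return A list with `global` (named per-service totals) and `regional`
#'   (`n_regions` x services matrix).
#' @export
compute_supply <- function(allocation, world, afts, regions = NULL) {
  .check_afts(afts)
  if (is.null(regions)) regions <- make_region_map(world$width, world$height, 1L)
  alloc <- as.integer(allocation)
  n <- world$width * world$height
  if (length(alloc) != n) stop("allocation length does not match world size", call. = FALSE)
  alloc[is.na(alloc)] <- 0L
  if (any(alloc < 0L) || any(alloc > length(afts))) {
    stop("allocation contains AFT indices outside 0..length(afts)", call. = FALSE)
  }
  ps <- .production_surfaces(world, afts)
  services <- names(ps)
  reg <- as.integer(regions$assignment)
  R <- regions$n_regions
  regional <- matrix(0, R, length(services), dimnames = list(NULL, services))
  occ <- which(alloc > 0L)
  if (length(occ) > 0L) {
    for (s in services) {
      v <- ps[[s]][cbind(occ, alloc[occ])]
      agg <- rowsum(v, reg[occ])
      regional[as.integer(rownames(agg)), s] <- agg
    }
  }
  list(global = colSums(regional), regional = regional)
}

#' Unmet-demand fraction
#'
#' `(demand - supply) / demand` when demand is positive, else 0 (zero demand
#' gives no inducement to produce rather than an undefined fraction).
#' Negative values indicate oversupply.
#'
#' @param demand,supply Numeric vectors (recycled) of demand and supply in
#'   production units; demand must be >= 0.
#' @return Dimensionless unmet fraction(s).
#' @export
unmet_fraction <- function(demand, supply) {
  if (any(demand < 0, na.rm = TRUE)) stop("`demand` must be >= 0", call. = FALSE)
  ifelse(demand > 0, (demand - supply) / demand, 0)
}

#' Competitiveness of an AFT on a cell
#'
#' The utility an agent of the type would obtain on the cell under the
#' current market: the sum over services of the per-unit benefit of the
#' service (at the cell's scope's unmet fraction) times the type's
#' production on the cell.
#'
#' @param aft An [aft_spec()].
#' @param capitals Named per-cell capital values in \[0, 1\].
#' @param unmet Named numeric vector of unmet-demand fractions per service
#'   at the cell's scope.
#' @param benefits Named list of [benefit_function][benefit_linear] objects
#'   per service.
#' @return Competitiveness in utility units.
#' @examples
#' hif <- aft_presets("hif")[[1]]
#' competitiveness(hif, c(crop = 1, natural = 0.3),
#'                 unmet = c(food = 1, recreation = 0.2),
#'                 benefits = list(food = benefit_linear(3),
#'                                 recreation = benefit_linear(3)))
#' @export
competitiveness <- function(aft, capitals, unmet, benefits) {
  prodv <- production_vector(aft, capitals)
  services <- names(prodv)
  miss <- setdiff(services, names(unmet))
  if (length(miss) > 0L) stop("missing unmet fraction(s): ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(services, names(benefits))
  if (length(miss) > 0L) stop("missing benefit function(s): ", paste(miss, collapse = ", "), call. = FALSE)
  total <- 0
  for (s in services) {
    total <- total + benefit_value(benefits[[s]], unmet[[s]]) * prodv[[s]]
  }
  unname(total)
}
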