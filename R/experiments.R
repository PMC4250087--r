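# Experiment parameter table. Each of the 19 experiments deviates from the
# baseline (experiment 1) only in the entries listed here: abandonment (at)
# and competition (ct) thresholds per AFT slot, the number of search
# iterations, and the benefit-function form. "N" marks the Gaussian
# threshold N(0.2, 0.03) sampled per agent. Slots `mif`/`lif` bind to the
# roster's mid/low-intensity farmer, which is the non-multifunctional "(1)"
# variant for experiments 9-13 and the multifunctional "(2)" variant for
# experiments 14-19; experiments 1-8 run the two-type roster (high-intensity
# farmer + conservationist).
.experiment_rows <- list(
  `1`  = list(),
  `2`  = list(at = list(hif = 0.2)),
  `3`  = list(at = list(cons = 0.2)),
  `4`  = list(at = list(hif = 0.2, cons = 0.2)),
  `5`  = list(at = list(cons = "N")),
  `6`  = list(ct = list(cons = "N")),
  `7`  = list(search = 100L),
  `8`  = list(benefit = "exponential"),
  `9`  = list(),
  `10` = list(at = list(hif = 0.2, cons = 0.2)),
  `11` = list(ct = list(mif = 0.1, lif = 0.2)),
  `12` = list(benefit = "exponential"),
  `13` = list(ct = list(mif = 0.1, lif = 0.2), benefit = "exponential"),
  `14` = list(),
  `15` = list(at = list(hif = 0.2, cons = 0.2)),
  `16` = list(at = list(hif = "N", cons = "N")),
  `17` = list(at = list(mif = "N", lif = "N")),
  `18` = list(ct = list(mif = 0.1, lif = 0.2)),
  `19` = list(benefit = "exponential")
)

.experiment_roster <- function(id) {
  if (id <= 8L) c("hif", "cons")
  else if (id <= 13L) c("hif", "mif1", "lif1", "cons")
  else c("hif", "mif2", "lif2", "cons")
}

.slot_of_key <- c(hif = "hif", mif1 = "mif", mif2 = "mif",
                  lif1 = "lif", lif2 = "lif", cons = "cons")

.thr_from_entry <- function(v) {
  if (identical(v, "N")) threshold_gaussian(0.2, 0.03) else threshold_constant(v)
}

.parse_code <- function(code) {
  m <- regmatches(code, regexec("^([0-9]+)([abcd])$", code))[[1L]]
  if (length(m) != 3L) {
    stop("experiment code must look like '1a'..'19d', got '", code, "'", call. = FALSE)
  }
  id <- as.integer(m[2L])
  if (id < 1L || id > length(.experiment_rows)) {
    stop("unknown experiment number: ", id, call. = FALSE)
  }
  list(id = id, variant = m[3L])
}

#' Build one experiment configuration
#'
#' Assembles the configuration for an experiment code such as `"3b"`: the
#' experiment number (1-19) selects the AFT roster, thresholds, search
#' effort and benefit form from the parameter table; the variant letter
#' selects the demand scenario (`a` = static globalised, `b` = dynamic
#' globalised, `c` = static regionalised, `d` = dynamic regionalised).
#' Defaults are the full-scale setup (60 x 60 grid, 25 timesteps, 30
#' realisations, 5000 searches of 10 cells); overrides support scaled-down
#' runs.
#'
#' @param code Experiment code, `"1a"` .. `"19d"`.
#' @param width,height Grid dimensions (regionalised variants require both
#'   to be even).
#' @param timesteps Run horizon.
#' @param n_reps Default ensemble size.
#' @param base_seed Default base seed for ensembles.
#' @param headroom Demand-calibration headroom (see [calibrate_demand()]).
#' @param search_iterations,cells_per_search Search effort per AFT per
#'   timestep; `NULL` keeps the experiment's tabulated value.
#' @param floor,ceiling Capital gradient endpoints.
#' @param change_timestep,drop_fraction Recreation-demand step change
#'   (dynamic variants).
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- build_config("7a", width = 20, height = 20, n_reps = 10)
#' cfg$search_iterations
#' @export
build_config <- function(code, width = 60L, height = 60L, timesteps = 25L,
                         n_reps = 30L, base_seed = 1L, headroom = 0.02,
                         search_iterations = NULL, cells_per_search = NULL,
                         floor = 0.05, ceiling = 1,
                         change_timestep = 11L, drop_fraction = 0.75) {
  pc <- .parse_code(code)
  id <- pc$id; variant <- pc$variant
  row <- .experiment_rows[[as.character(id)]]
  roster <- .experiment_roster(id)
  afts <- aft_presets(roster)
  for (key in roster) {
    slot <- .slot_of_key[[key]]
    at <- row$at[[slot]]; ct <- row$ct[[slot]]
    if (!is.null(at)) afts[[key]]$abandonment <- .thr_from_entry(at)
    if (!is.null(ct)) afts[[key]]$competition <- .thr_from_entry(ct)
  }
  dynamic <- variant %in% c("b", "d")
  regional <- variant %in% c("c", "d")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop("`width` and `height` must be positive integers", call. = FALSE)
  }
  if (regional && (width %% 2L != 0L || height %% 2L != 0L)) {
    stop("regionalised variants need even grid dimensions (4 equal quadrants)", call. = FALSE)
  }
  timesteps <- as.integer(timesteps)
  change_timestep <- as.integer(change_timestep)
  if (dynamic && change_timestep >= timesteps) {
    stop("`change_timestep` must be < `timesteps` for dynamic variants", call. = FALSE)
  }
  si <- if (is.null(search_iterations)) row$search %||% 5000L else as.integer(search_iterations)
  cp <- if (is.null(cells_per_search)) 10L else as.integer(cells_per_search)
  if (cp > width * height) stop("`cells_per_search` exceeds the number of cells", call. = FALSE)
  structure(
    list(code = code, experiment = id, variant = variant,
         dynamic = dynamic, regional = regional,
         multifunctional = id >= 14L,
         roster = roster, afts = afts,
         benefit_form = row$benefit %||% "linear", benefit_gradient = 3,
         search_iterations = si, cells_per_search = cp,
         width = width, height = height, timesteps = timesteps,
         n_reps = as.integer(n_reps), base_seed = as.integer(base_seed),
         headroom = headroom, floor = floor, ceiling = ceiling,
         change_timestep = change_timestep, drop_fraction = drop_fraction),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s: %s, %s demand; %d AFTs (%s); %s benefit; %d x %d, %d steps\n",
              x$code,
              if (x$regional) "regionalised" else "globalised",
              if (x$dynamic) "dynamic" else "static",
              length(x$afts), paste(x$roster, collapse = ","),
              x$benefit_form, x$width, x$height, x$timesteps))
  invisible(x)
}

#' The full experiment catalogue
#'
#' All 19 experiments x 4 demand variants = 76 configurations at full
#' scale.
#'
#' @return Named list of [build_config()] results keyed by code
#'   (`"1a"` .. `"19d"`).
#' @export
experiment_catalogue <- function() {
  codes <- as.vector(t(outer(seq_along(.experiment_rows), c("a", "b", "c", "d"), paste0)))
  out <- lapply(codes, build_config)
  names(out) <- codes
  out
}

#' Experiment codes
#'
#' @return Character vector of the 76 valid experiment codes.
#' @export
experiment_codes <- function() {
  as.vector(t(outer(seq_along(.experiment_rows), c("a", "b", "c", "d"), paste0)))
}

#' Turn an experiment configuration into a runnable engine configuration
#'
#' Generates the capital surfaces and region partition, calibrates base
#' demand from the optimal-allocation oracle, builds the demand schedule
#' and benefit functions, and assembles the [engine_config()].
#'
#' @param cfg An [build_config()] result.
#' @return An [engine_config()].
#' @export
as_engine_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  world <- generate_capital_grids(cfg$width, cfg$height, cfg$floor, cfg$ceiling)
  regions <- make_region_map(cfg$width, cfg$height,
                             per_side = if (cfg$regional) 2L else 1L)
  # Demand is calibrated once, from the baseline roster (high-intensity
  # farmer + conservationist), and the same demands confront every
  # experiment: cross-experiment supply comparisons presuppose identical
  # demand levels, and richer rosters must face the baseline's market.
  base <- calibrate_demand(world, aft_presets(c("hif", "cons")), cfg$headroom)
  schedule <- demand_schedule(base, dynamic = cfg$dynamic,
                              n_regions = regions$n_regions,
                              timesteps = cfg$timesteps,
                              change_timestep = cfg$change_timestep,
                              drop_fraction = cfg$drop_fraction)
  mk_benefit <- function() {
    if (cfg$benefit_form == "linear") benefit_linear(cfg$benefit_gradient)
    else benefit_exponential()
  }
  engine_config(world, regions, cfg$afts, schedule,
                benefits = list(food = mk_benefit(), recreation = mk_benefit()),
                search_iterations = cfg$search_iterations,
                cells_per_search = cfg$cells_per_search,
                timesteps = cfg$timesteps)
}

#' Run an experiment ensemble
#'
#' Convenience wrapper: build (or accept) an experiment configuration and
#' run its ensemble.
#'
#' @param x An experiment code (string) or [build_config()] result.
#' @param n_reps,base_seed Override the configuration's ensemble size and
#'   base seed.
#' @param record_events Keep per-event logs.
#' @param ... Passed to [build_config()] when `x` is a code.
#' @return A [run_ensemble()] result.
#' @export
run_experiment <- function(x, n_reps = NULL, base_seed = NULL,
                           record_events = TRUE, ...) {
  cfg <- if (is.character(x)) build_config(x, ...) else x
  stopifnot(inherits(cfg, "experiment_config"))
  run_ensemble(as_engine_config(cfg),
               n_reps = n_reps %||% cfg$n_reps,
               base_seed = base_seed %||% cfg$base_seed,
               record_events = record_events)
}
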