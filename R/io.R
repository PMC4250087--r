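.config_keys <- c("experiment", "width", "height", "timesteps", "realisations",
                  "seed", "headroom", "search_iterations", "cells_per_search",
                  "floor", "ceiling", "change_timestep", "drop_fraction")

#' Load an experiment configuration from a YAML file
#'
#' The file must name an `experiment` code; every other key is optional and
#' overrides the catalogue default (see [build_config()]). Unknown keys are
#' rejected with a field-level message.
#'
#' @param path Path to a YAML configuration file.
#' @return An [build_config()] result.
#' @examples
#' path <- tempfile(fileext = ".yml")
#' writeLines("experiment: 1a", path)
#' load_config(path)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.config_keys, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(raw$experiment)) stop("config must name an `experiment` code", call. = FALSE)
  args <- list(code = as.character(raw$experiment))
  map <- c(width = "width", height = "height", timesteps = "timesteps",
           realisations = "n_reps", seed = "base_seed", headroom = "headroom",
           search_iterations = "search_iterations",
           cells_per_search = "cells_per_search", floor = "floor",
           ceiling = "ceiling", change_timestep = "change_timestep",
           drop_fraction = "drop_fraction")
  for (key in names(map)) {
    if (!is.null(raw[[key]])) args[[map[[key]]]] <- raw[[key]]
  }
  do.call(build_config, args)
}

#' Save an experiment configuration to YAML
#'
#' Writes every field [load_config()] reads, so a save/load round trip
#' reproduces the configuration exactly.
#'
#' @param cfg An [build_config()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  yaml::write_yaml(list(
    experiment = cfg$code,
    width = cfg$width, height = cfg$height,
    timesteps = cfg$timesteps, realisations = cfg$n_reps,
    seed = cfg$base_seed, headroom = cfg$headroom,
    search_iterations = cfg$search_iterations,
    cells_per_search = cfg$cells_per_search,
    floor = cfg$floor, ceiling = cfg$ceiling,
    change_timestep = cfg$change_timestep,
    drop_fraction = cfg$drop_fraction
  ), path)
  invisible(path)
}

# Internal: long-format data frames for one realisation.
.result_tables <- function(result, realisation) {
  H <- result$config$world$height
  sup <- supply_series(result)
  sup <- cbind(realisation = realisation, sup)

  n <- nrow(result$snapshots)
  tt <- 0:result$timesteps
  cells <- seq_len(n)
  alloc <- data.frame(
    realisation = realisation,
    timestep = rep(tt, each = n),
    x = rep(cell_x(cells, H), times = length(tt)),
    y = rep(cell_y(cells, H), times = length(tt)),
    aft = as.integer(result$snapshots)
  )

  ev <- result$events
  events <- data.frame(
    realisation = rep(realisation, nrow(ev)),
    timestep = ev$timestep, type = ev$type,
    x = cell_x(ev$cell, H), y = cell_y(ev$cell, H),
    aft = ev$aft, prev_aft = ev$prev_aft,
    comp_new = ev$comp_new, comp_prev = ev$comp_prev,
    threshold = ev$threshold,
    crop = as.vector(result$config$world$capitals$crop)[ev$cell],
    natural = as.vector(result$config$world$capitals$natural)[ev$cell]
  )
  list(supplies = sup, allocations = alloc, events = events)
}

#' Export a run (or ensemble) as delimited text plus a manifest
#'
#' Writes `supplies.csv` (realisation, timestep, scope, service, demand,
#' supply), `allocations.csv` (realisation, timestep, x, y, aft; x/y are
#' 0-based with x increasing rightwards and y upwards), `events.csv`
#' (abandonments and takeovers with the capitals of affected cells),
#' `summary.csv` (ensemble mean/sd supply; ensembles of >= 2 only) and
#' `manifest.json` (seeds, configuration echo, file inventory, tool
#' version, wall-clock timestamp). Data files are deterministic given the
#' run; only the manifest carries wall-clock metadata.
#'
#' @param x A `run_result` or `run_ensemble`.
#' @param out_dir Output directory (created if missing).
#' @param experiment_code Optional code recorded in the manifest.
#' @return Character vector of the files written (the inventory),
#'   invisibly.
#' @export
export_run <- function(x, out_dir, experiment_code = NULL) {
  if (inherits(x, "run_result")) x <- structure(list(x), class = "run_ensemble")
  stopifnot(inherits(x, "run_ensemble"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  tabs <- lapply(seq_along(x), function(i) .result_tables(x[[i]], i))
  files <- character(0L)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(do.call(rbind, lapply(tabs, `[[`, "supplies")), "supplies.csv")
  wr(do.call(rbind, lapply(tabs, `[[`, "allocations")), "allocations.csv")
  wr(do.call(rbind, lapply(tabs, `[[`, "events")), "events.csv")
  if (length(x) >= 2L) {
    smry <- ensemble_summary(x)
    wr(smry$supply, "summary.csv")
  }

  cfg <- x[[1L]]$config
  manifest <- list(
    tool = "aftsim",
    version = as.character(utils::packageVersion("aftsim")),
    experiment = experiment_code,
    seeds = vapply(x, `[[`, integer(1L), "seed"),
    n_realisations = length(x),
    config = list(
      width = cfg$world$width, height = cfg$world$height,
      n_regions = cfg$regions$n_regions,
      afts = vapply(cfg$afts, `[[`, character(1L), "name"),
      timesteps = cfg$timesteps,
      search_iterations = cfg$search_iterations,
      cells_per_search = cfg$cells_per_search,
      benefit_food = cfg$benefits$food$form,
      benefit_recreation = cfg$benefits$recreation$form,
      demand_base = cfg$schedule$base,
      demand_dynamic = cfg$schedule$dynamic
    ),
    files = basename(files),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, manifest_path))
}
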