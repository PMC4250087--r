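#' Construct a capital grid from explicit matrices
#'
#' A capital grid holds one matrix per named capital, all of identical
#' dimension, with every value in \[0, 1\]. Matrices are indexed
#' `[y + 1, x + 1]` where `x` is the 0-based column (increasing rightwards)
#' and `y` the 0-based row (increasing upwards); all text exports use the
#' same convention.
#'
#' @param capitals Named list of numeric matrices with values in \[0, 1\],
#'   all sharing the same dimensions.
#' @return An object of class `capital_grid` with fields `width`, `height`
#'   and `capitals`.
#' @seealso [generate_capital_grids()] for the default gradient surfaces.
#' @export
capital_grid <- function(capitals) {
  if (!is.list(capitals) || length(capitals) == 0L || is.null(names(capitals)) ||
      any(!nzchar(names(capitals)))) {
    stop("`capitals` must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- lapply(capitals, dim)
  if (any(vapply(dims, is.null, logical(1L)))) {
    stop("every capital must be a matrix", call. = FALSE)
  }
  d1 <- dims[[1L]]
  for (d in dims) {
    if (!identical(d, d1)) stop("all capital grids must share identical dimensions", call. = FALSE)
  }
  for (nm in names(capitals)) {
    v <- capitals[[nm]]
    if (anyNA(v) || any(v < 0) || any(v > 1)) {
      stop(sprintf("capital '%s' has values outside [0, 1]", nm), call. = FALSE)
    }
  }
  structure(
    list(width = d1[2L], height = d1[1L], capitals = capitals),
    class = "capital_grid"
  )
}

#' Generate the default gradient capital surfaces
#'
#' Builds the simulated arena's two capitals. Crop productivity is a
#' horizontal linear gradient from `floor` at the leftmost column to
#' `ceiling` at the rightmost. Natural capital is the same horizontal
#' gradient modulated by a vertical linear factor rising from 0.5 at the
#' bottom row to 1 at the top row, so both capitals are maximised on the
#' right-hand side of the arena while natural capital also varies
#' top-to-bottom (separating agent types without removing competition for
#' the most productive cells).
#'
#' Degenerate dimensions are handled by convention: a single column takes
#' the `ceiling` value, a single row takes vertical factor 1.
#'
#' @param width,height Grid dimensions in cells (>= 1).
#' @param floor,ceiling Gradient endpoints, `0 <= floor <= ceiling <= 1`.
#' @return A [capital_grid()] with capitals `crop` and `natural`.
#' @examples
#' w <- generate_capital_grids(60, 60)
#' sapply(w$capitals, max)
#' @export
generate_capital_grids <- function(width, height, floor = 0.05, ceiling = 1) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop("`width` and `height` must be positive integers", call. = FALSE)
  }
  if (floor < 0 || ceiling > 1 || floor > ceiling) {
    stop("need 0 <= floor <= ceiling <= 1", call. = FALSE)
  }
  gx <- if (width > 1L) floor + (ceiling - floor) * (seq_len(width) - 1) / (width - 1) else ceiling
  vy <- if (height > 1L) 0.5 + 0.5 * (seq_len(height) - 1) / (height - 1) else 1
  crop <- matrix(rep(gx, each = height), nrow = height)
  natural <- outer(vy, gx)
  capital_grid(list(crop = crop, natural = natural))
}

#' @export
print.capital_grid <- function(x, ...) {
  cat(sprintf("<capital_grid> %d x %d cells; capitals: %s\n",
              x$width, x$height, paste(names(x$capitals), collapse = ", ")))
  invisible(x)
}

#' Partition the arena into equal square-block regions
#'
#' Splits a `width` x `height` grid into `per_side^2` equal rectangular
#' regions. `per_side = 1` is the globalised arena (a single region);
#' `per_side = 2` is the regionalised arena of four equal quadrants.
#'
#' @param width,height Grid dimensions in cells.
#' @param per_side Number of regions along each axis; must divide both
#'   `width` and `height`.
#' @return An object of class `region_map` with fields `width`, `height`,
#'   `per_side`, `n_regions` and `assignment` (a `height` x `width` integer
#'   matrix of region indices in `1:n_regions`).
#' @examples
#' rm4 <- make_region_map(60, 60, 2)
#' table(rm4$assignment)
#' @export
make_region_map <- function(width, height, per_side = 1) {
  width <- as.integer(width); height <- as.integer(height)
  per_side <- as.integer(per_side)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop("`width` and `height` must be positive integers", call. = FALSE)
  }
  if (is.na(per_side) || per_side < 1L) stop("`per_side` must be >= 1", call. = FALSE)
  if (width %% per_side != 0L || height %% per_side != 0L) {
    stop(sprintf("`per_side` (%d) must divide both width (%d) and height (%d)",
                 per_side, width, height), call. = FALSE)
  }
  bw <- width %/% per_side
  bh <- height %/% per_side
  bx <- rep((seq_len(width) - 1L) %/% bw, each = height)   # 0-based block column
  by <- rep((seq_len(height) - 1L) %/% bh, times = width)  # 0-based block row
  assignment <- matrix(bx * per_side + by + 1L, nrow = height)
  structure(
    list(width = width, height = height, per_side = per_side,
         n_regions = per_side^2L, assignment = assignment),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d x %d cells in %d region(s)\n",
              x$width, x$height, x$n_regions))
  invisible(x)
}

# Column-major cell index helpers: cell i (1-based) of an H x W matrix has
# x = (i-1) %/% H, y = (i-1) %% H (both 0-based).
cell_x <- function(i, height) (i - 1L) %/% height
cell_y <- function(i, height) (i - 1L) %% height

#' Write capital grids as delimited text
#'
#' One tab-separated file per capital, named `capital-<name>.tsv`, with a
#' header comment recording width, height and capital name. Rows are written
#' bottom-up so that the first data line is row y = 0.
#'
#' @param world A [capital_grid()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_capital_grids <- function(world, dir) {
  stopifnot(inherits(world, "capital_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0L)
  for (nm in names(world$capitals)) {
    path <- file.path(dir, paste0("capital-", nm, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# width=%d height=%d capital=%s  (rows are y=0..height-1; columns x=0..width-1)",
                       world$width, world$height, nm), con)
    utils::write.table(world$capitals[[nm]], con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read capital grids written by [write_capital_grids()]
#'
#' @param dir Directory containing `capital-*.tsv` files.
#' @return A [capital_grid()].
#' @export
read_capital_grids <- function(dir) {
  files <- list.files(dir, pattern = "^capital-.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop("no capital-*.tsv files found in ", dir, call. = FALSE)
  capitals <- list()
  for (path in files) {
    header <- readLines(path, n = 1L)
    nm <- sub(".*capital=(\\S+).*", "\\1", header)
    m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
    dimnames(m) <- NULL
    capitals[[nm]] <- m
  }
  capital_grid(capitals)
}
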