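#' Threshold specifications
#'
#' Abandonment and competition thresholds are specified either as a constant
#' or as a Gaussian distribution sampled once per agent at creation; draws
#' are clamped at zero (negative willingness thresholds are meaningless).
#'
#' @param value,mean Threshold mean in utility units (>= 0 for constants).
#' @param sd Standard deviation in utility units (>= 0).
#' @return An object of class `threshold_spec`.
#' @examples
#' sample_threshold(threshold_gaussian(0.2, 0.03), 5)
#' @export
threshold_constant <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("`value` must be a single number", call. = FALSE)
  }
  structure(list(kind = "constant", mean = as.numeric(value), sd = 0),
            class = "threshold_spec")
}

#' @rdname threshold_constant
#' @export
threshold_gaussian <- function(mean, sd) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("`sd` must be a single non-negative number", call. = FALSE)
  }
  structure(list(kind = "gaussian", mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "threshold_spec")
}

#' Sample threshold values from a specification
#'
#' Constant specs return the mean exactly (no random draw); Gaussian specs
#' draw from `N(mean, sd)` and clamp at zero.
#'
#' @param spec A [threshold_constant()] or [threshold_gaussian()].
#' @param n Number of values to sample.
#' @return Numeric vector of length `n`, all values >= 0 for Gaussian specs.
#' @export
sample_threshold <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$kind == "constant") {
    rep(spec$mean, n)
  } else {
    pmax(stats::rnorm(n, spec$mean, spec$sd), 0)
  }
}

#' Define an agent functional type
#'
#' An agent functional type (AFT) is a class of land managers sharing a
#' production function and behavioural parameters. Production on a cell is
#' Cobb-Douglas: a single utilisation factor
#' `prod_c capital_c ^ sensitivity_c` (with `0^0 = 1`) multiplies each
#' service's optimal production, so at capitals all equal to 1 the type
#' produces exactly its optimal levels.
#'
#' @param name Type label.
#' @param sensitivities Named non-negative numeric vector of capital
#'   exponents, e.g. `c(crop = 1, natural = 0)`.
#' @param production Named non-negative numeric vector of optimal production
#'   per service, e.g. `c(food = 1, recreation = 0)` (units per cell per
#'   timestep).
#' @param abandonment,competition [threshold_spec][threshold_constant]
#'   objects (defaults: constant 0).
#' @return An object of class `aft_spec`.
#' @seealso [aft_presets()] for the six standard types.
#' @export
aft_spec <- function(name, sensitivities, production,
                     abandonment = threshold_constant(0),
                     competition = threshold_constant(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  for (v in list(sensitivities, production)) {
    if (!is.numeric(v) || is.null(names(v)) || any(!nzchar(names(v))) ||
        anyNA(v) || any(v < 0)) {
      stop("`sensitivities` and `production` must be named non-negative numeric vectors",
           call. = FALSE)
    }
  }
  stopifnot(inherits(abandonment, "threshold_spec"),
            inherits(competition, "threshold_spec"))
  structure(
    list(name = name, sensitivities = sensitivities, production = production,
         abandonment = abandonment, competition = competition),
    class = "aft_spec"
  )
}

#' @export
print.aft_spec <- function(x, ...) {
  fmt_thr <- function(t) {
    if (t$kind == "constant") sprintf("%.3g", t$mean) else sprintf("N(%.3g, %.3g)", t$mean, t$sd)
  }
  cat(sprintf("<aft_spec> %s | sens: %s | prod: %s | AT %s; CT %s\n", x$name,
              paste(sprintf("%s=%.3g", names(x$sensitivities), x$sensitivities), collapse = " "),
              paste(sprintf("%s=%.3g", names(x$production), x$production), collapse = " "),
              fmt_thr(x$abandonment), fmt_thr(x$competition)))
  invisible(x)
}

# Capital sensitivities and optimal production levels for the six standard
# agent functional types (exponents over crop productivity and natural
# capital; units per cell per timestep for food and recreation). The "(2)"
# mid/low-intensity farmers are multifunctional (produce both services).
.aft_preset_table <- list(
  hif  = list(name = "High Intensity Farmer",
              sens = c(crop = 1.0,  natural = 0.0),
              prod = c(food = 1.0,  recreation = 0.0)),
  mif1 = list(name = "Mid Intensity Farmer (1)",
              sens = c(crop = 0.5,  natural = 0.0),
              prod = c(food = 0.5,  recreation = 0.0)),
  lif1 = list(name = "Low Intensity Farmer (1)",
              sens = c(crop = 0.25, natural = 0.0),
              prod = c(food = 0.25, recreation = 0.0)),
  mif2 = list(name = "Mid Intensity Farmer (2)",
              sens = c(crop = 0.75, natural = 0.20),
              prod = c(food = 0.75, recreation = 0.15)),
  lif2 = list(name = "Low Intensity Farmer (2)",
              sens = c(crop = 0.35, natural = 0.4),
              prod = c(food = 0.35, recreation = 0.4)),
  cons = list(name = "Conservationist",
              sens = c(crop = 0.0,  natural = 1.0),
              prod = c(food = 0.0,  recreation = 1.0))
)

#' Standard agent functional type presets
#'
#' The six standard types: high/mid/low-intensity farmers (with the
#' multifunctional "(2)" variants of the mid and low intensity types, which
#' also produce recreation) and the conservationist. Thresholds default to
#' constant zero; experiment configurations override them.
#'
#' @param keys Preset keys to return, a subset of
#'   `c("hif", "mif1", "lif1", "mif2", "lif2", "cons")`; `NULL` returns all
#'   six.
#' @return Named list of [aft_spec()] objects, in the order requested
#'   (declaration order matters for tie-breaking in allocation).
#' @examples
#' production_vector(aft_presets("hif")[[1]], c(crop = 1, natural = 1))
#' @export
aft_presets <- function(keys = NULL) {
  if (is.null(keys)) keys <- names(.aft_preset_table)
  unknown <- setdiff(keys, names(.aft_preset_table))
  if (length(unknown) > 0L) {
    stop("unknown AFT preset key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(keys, function(k) {
    p <- .aft_preset_table[[k]]
    aft_spec(p$name, p$sens, p$prod)
  })
  names(out) <- keys
  out
}

#' Cobb-Douglas capital utilisation factor
#'
#' The dimensionless factor `prod_c capital_c ^ sensitivity_c` in \[0, 1\]
#' by which an AFT's optimal production is scaled on a cell, with `0^0`
#' defined as 1 (a capital the type is insensitive to never limits it).
#'
#' @param aft An [aft_spec()].
#' @param capitals Named numeric vector of per-cell capital values in
#'   \[0, 1\]; must cover every capital the type is sensitive to.
#' @return A single factor in \[0, 1\].
#' @export
capital_utilisation <- function(aft, capitals) {
  stopifnot(inherits(aft, "aft_spec"))
  if (!is.numeric(capitals) || is.null(names(capitals)) ||
      anyNA(capitals) || any(capitals < 0) || any(capitals > 1)) {
    stop("`capitals` must be a named numeric vector with values in [0, 1]", call. = FALSE)
  }
  sens <- aft$sensitivities
  missing_caps <- setdiff(names(sens), names(capitals))
  if (length(missing_caps) > 0L) {
    stop("missing capital value(s): ", paste(missing_caps, collapse = ", "), call. = FALSE)
  }
  prod(capitals[names(sens)]^sens)  # 0^0 == 1 in R, as required
}

#' Per-service production of an AFT on a cell
#'
#' Each service's optimal production multiplied by the type's
#' [capital_utilisation()] on the cell.
#'
#' @inheritParams capital_utilisation
#' @return Named numeric vector of production per service (units per cell
#'   per timestep).
#' @export
production_vector <- function(aft, capitals) {
  aft$production * capital_utilisation(aft, capitals)
}

#' Benefit (utility) functions of unmet demand
#'
#' Map the unmet-demand fraction `x` of a service to the benefit of
#' producing one unit of it. The linear form is `max(a * x, 0)`: negative
#' values are floored at zero so overproduction is neither rewarded nor
#' punished. The exponential form is `e^x`, strictly positive even under
#' oversupply, modelling insensitivity to demand levels (or limited trade of
#' surpluses).
#'
#' @param gradient Linear gradient `a` in benefit per unit unmet-demand
#'   fraction (default 3).
#' @return An object of class `benefit_function`.
#' @examples
#' benefit_value(benefit_linear(3), c(1, 0, -0.4))
#' benefit_value(benefit_exponential(), 0)
#' @export
benefit_linear <- function(gradient = 3) {
  if (!is.numeric(gradient) || length(gradient) != 1L || is.na(gradient)) {
    stop("`gradient` must be a single number", call. = FALSE)
  }
  structure(list(form = "linear", gradient = as.numeric(gradient)),
            class = "benefit_function")
}

#' @rdname benefit_linear
#' @export
benefit_exponential <- function() {
  structure(list(form = "exponential", gradient = NA_real_),
            class = "benefit_function")
}

#' Evaluate a benefit function
#'
#' @param fn A [benefit_linear()] or [benefit_exponential()].
#' @param x Unmet-demand fraction(s); may be negative under oversupply.
#' @return Benefit per unit of service, vectorised over `x`.
#' @export
benefit_value <- function(fn, x) {
  stopifnot(inherits(fn, "benefit_function"), is.numeric(x))
  if (fn$form == "linear") pmax(fn$gradient * x, 0) else exp(x)
}
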