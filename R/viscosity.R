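#' Temperature-dependent blood viscosity curve
#'
#' A viscosity curve maps temperature (degrees C) to dynamic viscosity (Pa s)
#' by piecewise-linear interpolation between knots, clamped to the end values
#' outside the knot range. Whole blood thins as it warms, reaching a minimum
#' viscosity at the coagulation onset near 55 degC, and stiffens sharply above
#' it as plasma proteins denature.
#'
#' @param temperature_C numeric vector of knot temperatures (degC), strictly
#'   increasing.
#' @param viscosity_Pa_s numeric vector of dynamic viscosities (Pa s) at the
#'   knots, all positive.
#' @return An object of class `viscosity_curve`.
#' @seealso [viscosity_at()], [default_viscosity_curve()],
#'   [read_viscosity_curve()]
#' @export
viscosity_curve <- function(temperature_C, viscosity_Pa_s) {
  if (length(temperature_C) != length(viscosity_Pa_s))
    stop("temperature and viscosity vectors must have equal length")
  if (length(temperature_C) < 2)
    stop("a viscosity curve needs at least two knots")
  if (any(!is.finite(temperature_C)) || any(diff(temperature_C) <= 0))
    stop("viscosity curve temperatures must be finite and strictly increasing")
  if (any(!is.finite(viscosity_Pa_s)) || any(viscosity_Pa_s <= 0))
    stop("viscosities must be finite and positive")
  structure(
    list(temperature_C = as.numeric(temperature_C),
         viscosity_Pa_s = as.numeric(viscosity_Pa_s),
         interpolation = "linear", extrapolation = "clamp"),
    class = "viscosity_curve")
}

#' Default whole-blood viscosity curve
#'
#' A synthetic curve (no tabulated rheology data ship with the package)
#' constrained to the experimentally established shape: dynamic viscosity
#' decreases from its baseline value near 37 degC down to a minimum at 55 degC,
#' then increases steeply as coagulation stiffens the blood. Baseline whole
#' blood viscosity is taken as 3.5 mPa s. Replace it with measured data via
#' [read_viscosity_curve()] when available.
#'
#' @return A `viscosity_curve`.
#' @export
default_viscosity_curve <- function() {
  viscosity_curve(
    temperature_C  = c(20,     30,     37,     45,     50,     55,
                       60,     65,     70,     80,     90,     100),
    viscosity_Pa_s = c(5.0e-3, 4.0e-3, 3.5e-3, 3.0e-3, 2.8e-3, 2.6e-3,
                       3.2e-3, 5.0e-3, 9.0e-3, 2.5e-2, 6.0e-2, 1.2e-1))
}

#' Evaluate a viscosity curve
#'
#' Piecewise-linear interpolation between knots; temperatures beyond the end
#' knots are clamped to the end values.
#'
#' @param curve a `viscosity_curve`.
#' @param temperature_C numeric vector of temperatures (degC).
#' @return Dynamic viscosity (Pa s), same shape as `temperature_C`.
#' @export
viscosity_at <- function(curve, temperature_C) {
  stopifnot(inherits(curve, "viscosity_curve"))
  out <- stats::approx(curve$temperature_C, curve$viscosity_Pa_s,
                       xout = as.numeric(temperature_C), rule = 2)$y
  if (is.matrix(temperature_C)) dim(out) <- dim(temperature_C)
  out
}

#' Read a viscosity curve from a two-column CSV
#'
#' The file must have a header line with columns `temperature_C` and
#' `viscosity_Pa_s`.
#'
#' @param path path to the CSV file.
#' @return A `viscosity_curve`.
#' @export
read_viscosity_curve <- function(path) {
  d <- utils::read.csv(path)
  need <- c("temperature_C", "viscosity_Pa_s")
  if (!all(need %in% names(d)))
    stop("viscosity CSV must have columns 'temperature_C' and 'viscosity_Pa_s'")
  viscosity_curve(d$temperature_C, d$viscosity_Pa_s)
}

#' @export
print.viscosity_curve <- function(x, ...) {
  i_min <- which.min(x$viscosity_Pa_s)
  cat(sprintf(
    "Viscosity curve: %d knots, %g-%g degC, minimum %.3g Pa s at %g degC\n",
    length(x$temperature_C), min(x$temperature_C), max(x$temperature_C),
    x$viscosity_Pa_s[i_min], x$temperature_C[i_min]))
  invisible(x)
}
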