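#' Wavelength grid of a spectrometer
#'
#' A wavelength grid is the ordered vector of channel wavelengths (in nm)
#' shared by every spectrum in a dataset. The default grid mimics the
#' VIS/NIR spectrometer used for enamel measurements: 2305 channels
#' covering 420--1000 nm, i.e. a spacing of roughly 0.25 nm.
#'
#' @param wavelengths_nm strictly increasing numeric vector of channel
#'   wavelengths in nanometres; length at least 2.
#' @return a numeric vector of class `"wavelength_grid"`.
#' @examples
#' g <- wavelength_grid(c(420, 710, 1000))
#' nearest_channel(g, 700)
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L) {
    stop("a wavelength grid needs at least 2 channels", call. = FALSE)
  }
  if (anyNA(w) || any(!is.finite(w))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(w, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @details `default_wavelength_grid()` returns the 2305-channel grid
#'   spanning 420--1000 nm inclusive. Wavelengths are kept to 4 decimal
#'   places in nm, which exceeds instrument precision and keeps text
#'   round-trips exact.
#' @export
default_wavelength_grid <- function() {
  wavelength_grid(round(seq(420, 1000, length.out = 2305L), 4L))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d channels, %.4f-%.4f nm (spacing ~%.4f nm)\n",
    length(x), x[1L], x[length(x)], stats::median(diff(unclass(x)))
  ))
  invisible(x)
}

#' Map target wavelengths to grid channels
#'
#' Rules are written as "the intensity at a wavelength of about X nm";
#' on a discrete grid this is realized as the channel whose wavelength is
#' closest to the target. Ties break toward the lower channel index, and
#' targets outside the grid clamp to the nearest endpoint with a warning.
#'
#' @param grid a [wavelength_grid()].
#' @param target_nm numeric vector of target wavelengths (nm).
#' @return integer vector of channel indices, one per target.
#' @export
nearest_channel <- function(grid, target_nm) {
  grid <- as_grid(grid)
  w <- unclass(grid)
  vapply(as.numeric(target_nm), function(t) {
    if (t < w[1L] || t > w[length(w)]) {
      warning(sprintf("target %.4f nm outside grid [%.4f, %.4f]; clamping",
                      t, w[1L], w[length(w)]), call. = FALSE)
    }
    which.min(abs(w - t))
  }, integer(1L))
}

# coerce plain numeric vectors for convenience; validates either way
as_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) x else wavelength_grid(x)
}
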