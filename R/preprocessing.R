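#' Reference-based normalization of raw spectra
#'
#' Scales raw detector counts S(lambda) between the dark-current
#' spectrum D(lambda) (signal with no light, the thermal-noise floor)
#' and the white-reference spectrum W(lambda) (a maximal-reflectance
#' standard), channel by channel:
#' \deqn{I(\lambda) = \frac{S(\lambda) - D(\lambda)}{W(\lambda) - D(\lambda)}}
#' The result, the normalized intensity, is nominally in `[0, 1]` but is
#' deliberately not clipped: noisy channels may stray slightly outside,
#' and clipping would bias threshold searches near 0 and 1.
#'
#' @param raw numeric vector or channels-x-samples matrix of raw counts.
#' @param dark,white per-channel reference spectra; `white` must exceed
#'   `dark` at every channel (equality is a degenerate calibration and a
#'   hard error).
#' @param saturation optional detector ceiling; raw values at or above it
#'   trigger a per-sample warning naming the affected samples (they are
#'   flagged, not excluded).
#' @return normalized intensities with the shape of `raw`.
#' @export
normalize_spectra <- function(raw, dark, white, saturation = NULL) {
  m <- as_intensity_matrix(raw)
  dark <- as.numeric(dark)
  white <- as.numeric(white)
  if (length(dark) != nrow(m) || length(white) != nrow(m)) {
    stop("reference spectra must have one value per channel", call. = FALSE)
  }
  if (any(white == dark)) {
    stop("degenerate calibration: white == dark at some channel",
         call. = FALSE)
  }
  if (any(white < dark)) {
    stop("invalid reference pair: white < dark at some channel",
         call. = FALSE)
  }
  if (!is.null(saturation)) {
    sat <- colSums(m >= saturation) > 0L
    if (any(sat)) {
      warning(sprintf("saturated channels in sample(s): %s",
                      paste(which(sat), collapse = ", ")), call. = FALSE)
    }
  }
  out <- (m - dark) / (white - dark)
  if (is.matrix(raw)) out else drop(out)
}

#' Average replicate measurements
#'
#' Each enamel point is measured many times in a row (one hundred in the
#' reference protocol) and the spectra are averaged, shrinking the
#' zero-mean thermal noise standard deviation by `1/sqrt(n)`.
#'
#' @param replicates a channels-x-replicates matrix, or a list of
#'   per-replicate spectra on a shared grid.
#' @return the channel-wise mean spectrum (numeric vector).
#' @export
average_replicates <- function(replicates) {
  if (is.list(replicates)) {
    if (!length(replicates)) stop("no replicates to average", call. = FALSE)
    len <- lengths(replicates)
    if (any(len != len[1L])) {
      stop("replicates must share one wavelength grid", call. = FALSE)
    }
    replicates <- matrix(unlist(replicates, use.names = FALSE), nrow = len[1L])
  }
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 1L) stop("no replicates to average", call. = FALSE)
  rowMeans(replicates)
}

#' Savitzky-Golay smoothing configuration
#'
#' Defaults to the reference protocol: a 61-channel window (30 channels
#' either side of the centre) and sixth-degree polynomials.
#'
#' @param window_length odd positive integer, in channels.
#' @param poly_degree non-negative integer, strictly smaller than
#'   `window_length`.
#' @return an object of class `"smoothing_config"`.
#' @export
smoothing_config <- function(window_length = 61L, poly_degree = 6L) {
  window_length <- as.integer(window_length)
  poly_degree <- as.integer(poly_degree)
  if (window_length < 1L || window_length %% 2L == 0L) {
    stop("window_length must be an odd positive integer", call. = FALSE)
  }
  if (poly_degree < 0L || poly_degree >= window_length) {
    stop("poly_degree must be in [0, window_length)", call. = FALSE)
  }
  structure(list(window_length = window_length, poly_degree = poly_degree),
            class = "smoothing_config")
}

# Projection (hat) matrix of a least-squares polynomial fit over one
# window. Built from a QR of the basis on abscissae scaled to [-1, 1];
# the scaling keeps the degree-6 fit conditioned well enough that
# polynomials are reproduced to ~1e-13 even at the window ends.
sg_projection <- function(cfg) {
  h <- (cfg$window_length - 1L) %/% 2L
  t <- if (h > 0L) seq(-h, h) / h else 0
  B <- outer(t, 0:cfg$poly_degree, `^`)
  Q <- qr.Q(qr(B))
  tcrossprod(Q)
}

#' Savitzky-Golay smoothing of normalized spectra
#'
#' For every channel, fits a least-squares polynomial of the configured
#' degree to the window of channels centred there and replaces the value
#' by the polynomial's value at the centre. This removes fast, small,
#' noise-driven wiggles while reproducing any polynomial of degree up to
#' `poly_degree` essentially exactly. Near the spectrum ends, where a
#' centred window does not fit, the first (last) full window's fitted
#' polynomial is evaluated at the edge channels, so the output keeps the
#' length of the input.
#'
#' @param x numeric vector, channels-x-samples matrix, or
#'   [drs_dataset()] (smoothed in place, same class out).
#' @param cfg a [smoothing_config()].
#' @return smoothed data with the shape/class of `x`.
#' @export
smooth_spectra <- function(x, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  if (inherits(x, "drs_dataset")) {
    x$intensities <- smooth_spectra(x$intensities, cfg)
    return(x)
  }
  m <- as_intensity_matrix(x)
  n <- nrow(m)
  if (n < cfg$window_length) {
    stop(sprintf("spectrum has %d channels, shorter than the %d-channel window",
                 n, cfg$window_length), call. = FALSE)
  }
  H <- sg_projection(cfg)
  h <- (cfg$window_length - 1L) %/% 2L
  w <- H[h + 1L, ]
  out <- apply(m, 2L, function(y) {
    s <- as.numeric(stats::filter(y, w, sides = 2L))
    if (h > 0L) {
      s[1:h] <- H[1:h, , drop = FALSE] %*% y[1:(2L * h + 1L)]
      s[(n - h + 1L):n] <-
        H[(h + 2L):(2L * h + 1L), , drop = FALSE] %*% y[(n - 2L * h):n]
    }
    s
  })
  if (is.matrix(x)) {
    dimnames(out) <- dimnames(x)
    out
  } else {
    drop(out)
  }
}
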