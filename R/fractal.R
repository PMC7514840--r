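# Directional Hurst-exponent fractal analysis. The image is treated as a
# realisation of fractional Brownian motion along each sampling direction;
# its first-difference profiles (fractional Gaussian noise) have a log-log
# power spectral density of slope 1 - 2H, estimated by least squares.

# Bilinear sample of matrix m at fractional (row, col) positions given as
# equally shaped matrices. Positions must lie inside [1, nrow] x [1, ncol].
.bilinear_sample <- function(m, rows, cols) {
  r0 <- floor(rows); c0 <- floor(cols)
  r0 <- pmin(pmax(r0, 1), nrow(m) - 1L)
  c0 <- pmin(pmax(c0, 1), ncol(m) - 1L)
  wr <- rows - r0; wc <- cols - c0
  idx <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
  v <- (1 - wr) * (1 - wc) * idx(r0, c0) +
    (1 - wr) * wc * idx(r0, c0 + 1L) +
    wr * (1 - wc) * idx(r0 + 1L, c0) +
    wr * wc * idx(r0 + 1L, c0 + 1L)
  matrix(v, nrow(rows), ncol(rows))
}

# largest axis-aligned rectangle inscribed in a w x h rectangle rotated by
# theta (radians, 0 < theta < pi/2); returns c(width, height)
.inscribed_rect <- function(w, h, theta) {
  s <- sin(theta); cth <- cos(theta)
  short <- min(w, h)
  if (short <= 2 * s * cth * max(w, h)) {
    x <- 0.5 * short
    if (w <= h) c(x / s, x / cth) else c(x / cth, x / s)
  } else {
    cos2 <- cth^2 - s^2
    c((w * cth - h * s) / cos2, (h * cth - w * s) / cos2)
  }
}

#' Directional intensity profiles
#'
#' Resamples a grayscale crop so that its rows run along direction `theta`
#' (degrees anticlockwise from the image x-axis). For oblique angles the
#' crop is rotated by bilinear interpolation and trimmed to the largest
#' inscribed axis-aligned rectangle, preserving unit sampling spacing;
#' `theta = 0` returns the rows, `theta = 90` the columns.
#'
#' @param m numeric matrix.
#' @param theta angle in degrees, in \[0, 90\].
#' @return matrix whose rows are the directional profiles.
#' @export
directional_profiles <- function(m, theta) {
  stopifnot(theta >= 0, theta <= 90)
  if (theta == 0) return(m)
  if (theta == 90) return(t(m))
  th <- theta * pi / 180
  H <- nrow(m); W <- ncol(m)
  wh <- .inscribed_rect(W, H, th)
  Wr <- max(2L, floor(wh[1])); Hr <- max(2L, floor(wh[2]))
  c0r <- (H + 1) / 2; c0c <- (W + 1) / 2
  along <- seq_len(Wr) - (Wr + 1) / 2
  perp <- seq_len(Hr) - (Hr + 1) / 2
  # row axis points down, so a profile "up at angle theta" decreases row
  rows <- c0r + outer(perp, along, function(p, q) -q * sin(th) + p * cos(th))
  cols <- c0c + outer(perp, along, function(p, q) q * cos(th) + p * sin(th))
  .bilinear_sample(m, rows, cols)
}

#' Hurst exponent along one direction
#'
#' Profiles are sampled along `theta`, first-differenced (the increment
#' process of the fractional Brownian motion), and the squared-magnitude
#' DFT of each increment profile is averaged into one power spectral
#' density. A least-squares line through `log10(PSD)` versus
#' `log10(frequency)` over the positive frequencies up to Nyquist gives the
#' slope `1 - 2H`, hence `H = (1 - slope)/2`, returned unclamped with an
#' attribute `valid` set FALSE when the estimate is degenerate (constant
#' input) or falls outside \[0, 1\].
#'
#' @param channel numeric matrix (grayscale crop).
#' @param theta sampling direction in degrees (0, 30, 45, 60 or 90).
#' @param min_len minimum usable profile length.
#' @return scalar estimate of H with attribute `valid`.
#' @export
hurst_exponent <- function(channel, theta = 0, min_len = 16) {
  prof <- directional_profiles(channel, theta)
  if (ncol(prof) < min_len) {
    stop("profiles must span at least ", min_len, " pixels; got ", ncol(prof))
  }
  d <- prof[, -1, drop = FALSE] - prof[, -ncol(prof), drop = FALSE]
  L <- ncol(d)
  # DFT of each increment profile (columns of t(d)), averaged power
  D <- mvfft(t(d))
  pw <- rowMeans(Mod(D)^2)
  half <- L %/% 2L
  psd <- pw[2:(half + 1L)]
  freq <- (1:half) / L
  if (all(psd <= .Machine$double.eps)) {
    return(structure(0, valid = FALSE))
  }
  keep <- psd > 0
  fit <- lm.fit(cbind(1, log10(freq[keep])), log10(psd[keep]))
  slope <- fit$coefficients[2]
  h <- unname((1 - slope) / 2)
  structure(h, valid = (h >= 0 && h <= 1))
}

#' Directional Hurst features of a candidate
#'
#' The Hurst exponent along 0, 30, 45, 60 and 90 degrees for the cyan,
#' hematoxylin and eosin channels of the candidate's bounding box: 15
#' features.
#'
#' @param channels named list with `cyan`, `hematoxylin`, `eosin` matrices
#'   (see [candidate_channels()]).
#' @return named numeric vector of 15 features (`fractal.<channel>.h<angle>`).
#' @export
fractal_features <- function(channels) {
  angles <- c(0, 30, 45, 60, 90)
  out <- numeric(0)
  for (ch in c("cyan", "hematoxylin", "eosin")) {
    for (th in angles) {
      h <- hurst_exponent(channels[[ch]], th)
      out[paste0("fractal.", ch, ".h", th)] <- as.numeric(h)
    }
  }
  out
}
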