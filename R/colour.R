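#' Colour-space conversions
#'
#' Convert 8-bit sRGB pixel values to CIE L*a*b* (D65 reference white) or to
#' the hue angle of the HSI colour model.  These are the two colour
#' representations the wafer pipeline relies on: segmentation measures
#' colour distances in Lab, where Euclidean distance approximates perceptual
#' difference, while the mixing statistic is computed on HSI hue, where the
#' red and green dyes of the test gum sit at 0 and 120 degrees.
#'
#' `rgb_to_lab()` applies the standard transform: the piecewise sRGB
#' electro-optical function, the sRGB/D65 RGB-to-XYZ matrix, and the CIE
#' cube-root lightness function.  Neutral greys map to `a = b = 0`.
#'
#' @param x for `rgb_to_lab()`: an `h x w x 3` array or an `n x 3` matrix of
#'   8-bit sRGB values in `[0, 255]`.
#' @return `rgb_to_lab()` returns an object of the same shape with L in
#'   `[0, 100]` and unbounded a/b.
#' @examples
#' rgb_to_lab(matrix(c(255, 0, 0), 1))
#' @export
rgb_to_lab <- function(x) {
  dm <- dim(x)
  is_arr <- length(dm) == 3L
  if (is_arr) {
    if (dm[3] != 3L) stop("expected a 3-channel RGB input")
    m <- cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 3L) stop("expected a 3-channel RGB input")
  }
  s <- m / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1, 1.08883)
  xyz <- sweep(xyz, 2, white, "/")
  d3 <- (6 / 29)^3
  f <- ifelse(xyz > d3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  if (is_arr) {
    out <- array(0, dm)
    out[, , 1] <- lab[, 1]; out[, , 2] <- lab[, 2]; out[, , 3] <- lab[, 3]
    out
  } else lab
}

#' @rdname rgb_to_lab
#'
#' @details
#' `rgb_to_hue()` uses the angular hue of the RGB-to-HSI transform,
#' `H = acos(((R-G)+(R-B)) / (2 sqrt((R-G)^2 + (R-B)(G-B))))`, reflected to
#' `360 - H` when `B > G`.  Hue is undefined near the grey axis, so pixels
#' whose channel spread `max(R,G,B) - min(R,G,B)` falls below
#' `chroma_threshold` are excluded and counted rather than binned.
#'
#' @param pixels an `n x 3` matrix of 8-bit sRGB values.
#' @param chroma_threshold minimum channel spread (8-bit scale) for a pixel
#'   to count as chromatic; default 8.
#' @return `rgb_to_hue()` returns a list with `hue` (degrees in `[0, 360)`
#'   for the chromatic pixels) and `n_excluded` (achromatic pixel count).
#' @export
rgb_to_hue <- function(pixels, chroma_threshold = 8) {
  m <- as.matrix(pixels)
  if (ncol(m) != 3L || nrow(m) == 0L) stop("expected a non-empty n x 3 RGB matrix")
  spread <- apply(m, 1, max) - apply(m, 1, min)
  keep <- spread >= chroma_threshold
  if (!any(keep)) stop("no chromatic bolus pixels")
  m <- m[keep, , drop = FALSE]
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  arg <- pmin(1, pmax(-1, num / pmax(den, .Machine$double.eps)))
  h <- acos(arg) * 180 / pi
  h <- ifelse(b > g, 360 - h, h)
  h[h >= 360] <- 0
  list(hue = h, n_excluded = sum(!keep))
}

#' @rdname rgb_to_lab
#'
#' @details
#' `hsi_to_rgb()` is the inverse sector transform used by the wafer
#' renderer; saturation and intensity are held fixed per image so that hue
#' alone encodes dye identity.  `intensity * (1 + 2 * saturation)` must not
#' exceed 1 or the dominant channel would clip.
#'
#' @param hue hue angle(s) in degrees, `[0, 360)`.
#' @param saturation HSI saturation in `[0, 1]`.
#' @param intensity HSI intensity in `[0, 1]`.
#' @return `hsi_to_rgb()` returns an `n x 3` matrix of 8-bit sRGB values.
#' @export
hsi_to_rgb <- function(hue, saturation = 0.7, intensity = 0.4) {
  h <- hue %% 360
  n <- length(h)
  out <- matrix(0, n, 3)
  sector <- ifelse(h < 120, 1L, ifelse(h < 240, 2L, 3L))
  hh <- h - (sector - 1L) * 120
  x <- rep(intensity * (1 - saturation), n)
  y <- intensity * (1 + saturation * cos(hh * pi / 180) / cos((60 - hh) * pi / 180))
  z <- 3 * intensity - x - y
  for (k in 1:3) {
    idx <- sector == k
    # sector 1: (R,G,B) = (y,z,x); sector 2: (x,y,z); sector 3: (z,x,y)
    perm <- switch(k, c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    out[idx, perm[1]] <- y[idx]
    out[idx, perm[2]] <- z[idx]
    out[idx, perm[3]] <- x[idx]
  }
  round(pmin(pmax(out * 255, 0), 255))
}
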