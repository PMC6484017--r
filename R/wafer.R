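#' Specification of a synthetic gum-wafer image
#'
#' Describes one rendered image of a flattened two-coloured chewing-gum
#' wafer: a roughly circular bolus of red/green dyed gum on a light uniform
#' scanner background.  The latent parameter `m` is the mixing degree the
#' VhH statistic is meant to measure: at `m = 0` the bolus is a patchwork of
#' pure red and pure green regions (an unchewed specimen), and as `m` grows
#' the patch hues converge along the shorter circular arc towards the
#' red/green midpoint (yellow), emulating progressive dye blending under
#' mastication.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param blob_radius_px bolus radius in pixels; the bolus must lie fully
#'   inside the canvas.
#' @param blob_center `(row, col)` centre of the bolus; defaults to the
#'   canvas centre.
#' @param m mixing degree in `[0, 1]`.
#' @param hue_a,hue_b hues (degrees) of the two unmixed dyes; defaults 0
#'   (red) and 120 (green).
#' @param patch_scale_px spatial granularity (pixels) of the unmixed colour
#'   patches; real boluses show coherent colour regions, not pixel noise.
#' @param hue_jitter_sd per-patch hue jitter SD (degrees) at `m = 0`; the
#'   applied SD is `hue_jitter_sd * (1 - m)`, so tone heterogeneity
#'   shrinks as mixing completes and vanishes in the fully mixed limit.
#' @param saturation,intensity fixed HSI saturation/intensity of the gum.
#' @param background_rgb 8-bit background triple (light grey default).
#' @param noise_sd per-channel additive Gaussian noise SD on the 8-bit scale.
#' @param seed integer seed; identical specs with identical seeds render
#'   byte-identical images.
#' @return an object of class `wafer_spec`.
#' @seealso [generate_wafer()]
#' @export
wafer_spec <- function(width_px = 160, height_px = 160, blob_radius_px = 52,
                       blob_center = NULL, m = 0, hue_a = 0, hue_b = 120,
                       patch_scale_px = 12, hue_jitter_sd = 12,
                       saturation = 0.7, intensity = 0.4,
                       background_rgb = c(200, 200, 200), noise_sd = 4,
                       seed = NULL) {
  if (is.null(blob_center)) blob_center <- c((height_px + 1) / 2, (width_px + 1) / 2)
  spec <- list(width_px = width_px, height_px = height_px,
               blob_radius_px = blob_radius_px, blob_center = blob_center,
               m = m, hue_a = hue_a %% 360, hue_b = hue_b %% 360,
               patch_scale_px = patch_scale_px, hue_jitter_sd = hue_jitter_sd,
               saturation = saturation, intensity = intensity,
               background_rgb = background_rgb, noise_sd = noise_sd,
               seed = seed)
  class(spec) <- "wafer_spec"
  validate_wafer_spec(spec)
  spec
}

validate_wafer_spec <- function(spec) {
  with(spec, {
    if (m < 0 || m > 1) stop("mixing degree m must lie in [0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (patch_scale_px < 1) stop("patch_scale_px must be >= 1")
    if (hue_jitter_sd < 0) stop("hue_jitter_sd must be >= 0")
    if (blob_center[1] - blob_radius_px < 1 || blob_center[1] + blob_radius_px > height_px ||
        blob_center[2] - blob_radius_px < 1 || blob_center[2] + blob_radius_px > width_px)
      stop("blob extends outside the canvas")
    if (length(background_rgb) != 3 || any(background_rgb < 0 | background_rgb > 255))
      stop("background_rgb must be an 8-bit triple")
    if (intensity * (1 + 2 * saturation) > 1)
      stop("intensity * (1 + 2 * saturation) must be <= 1 to avoid channel clipping")
  })
  invisible(spec)
}

# Interpolate both dye hues a fraction m along the shorter circular arc
# towards their midpoint (red -> green passes through yellow).
mixed_hues <- function(hue_a, hue_b, m) {
  delta <- ((hue_b - hue_a + 180) %% 360) - 180  # signed shorter arc a -> b
  mid <- (hue_a + delta / 2) %% 360
  c(a = (hue_a + m * delta / 2) %% 360,
    b = (mid + (1 - m) * delta / 2) %% 360)
}

#' Render a synthetic wafer image with ground-truth mask
#'
#' Draws the bolus described by a [wafer_spec()] on a uniform background and
#' returns both the 8-bit RGB image and the exact bolus footprint, which
#' downstream tests use as segmentation ground truth.  Inside the bolus the
#' canvas is tiled into `patch_scale_px` grid cells (with a random global
#' offset so patch boundaries are not axis-locked across images); each cell
#' is assigned one of the two (partially mixed) dye hues with probability
#' one half.  Hue plus the fixed saturation/intensity is converted to RGB,
#' and i.i.d. Gaussian noise is added to every channel of every pixel.
#'
#' @param spec a [wafer_spec()].
#' @return a list of class `wafer` with elements `image` (an
#'   `height x width x 3` array of integers in 0..255), `mask` (logical
#'   matrix, `TRUE` on bolus pixels) and `spec`.
#' @examples
#' w <- generate_wafer(wafer_spec(m = 0.5, seed = 1))
#' dim(w$image)
#' @export
generate_wafer <- function(spec) {
  stopifnot(inherits(spec, "wafer_spec"))
  validate_wafer_spec(spec)
  with_seed(spec$seed, {
    h <- spec$height_px; w <- spec$width_px
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- (rows - spec$blob_center[1])^2 + (cols - spec$blob_center[2])^2 <=
      spec$blob_radius_px^2

    hues2 <- mixed_hues(spec$hue_a, spec$hue_b, spec$m)
    ps <- spec$patch_scale_px
    off <- floor(runif(2, 0, ps))
    prow <- (rows - 1 + off[1]) %/% ps
    pcol <- (cols - 1 + off[2]) %/% ps
    npr <- max(prow) + 1
    patch_id <- prow + pcol * npr + 1
    n_patch <- max(patch_id)
    pick <- rbinom(n_patch, 1, 0.5)        # one Bernoulli draw per patch
    jitter <- rnorm(n_patch, 0, spec$hue_jitter_sd * (1 - spec$m))
    hue_patch <- (ifelse(pick == 1, hues2["a"], hues2["b"]) + jitter) %% 360
    hue_map <- hue_patch[patch_id]
    dim(hue_map) <- dim(rows)

    img <- array(0, c(h, w, 3))
    for (k in 1:3) img[, , k] <- spec$background_rgb[k]
    gum_rgb <- hsi_to_rgb(hue_map[mask], spec$saturation, spec$intensity)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[mask] <- gum_rgb[, k]
      img[, , k] <- ch
    }
    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
    }
    img <- round(pmin(pmax(img, 0), 255))
    structure(list(image = img, mask = mask, spec = spec), class = "wafer")
  })
}
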