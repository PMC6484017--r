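#' Segmentation configuration
#'
#' Tunable parameters of the colour-based bolus segmentation.  The defaults
#' (spatial bandwidth 8 px, range bandwidth 8 Lab units) give superpixels a
#' little larger than the colour patches of an unmixed bolus while keeping
#' the uniform background in a single cluster on typical scans.
#'
#' @param spatial_bw mean-shift spatial bandwidth, pixels.
#' @param range_bw mean-shift range bandwidth, CIE Lab units.
#' @param eps additive stabilizer inside the distance-map logarithm; the
#'   log of a zero colour distance is undefined, and `log(d + eps)` keeps
#'   the map finite without disturbing the ordering.
#' @param max_iter,tol mean-shift convergence controls.
#' @param min_separation minimum gap (log-distance units) between the two
#'   k-means centres for an image to count as having foreground/background
#'   contrast; below it the image is rejected as degenerate (e.g. a blank
#'   background-only scan).
#' @return a list of class `segment_config`.
#' @export
segment_config <- function(spatial_bw = 8, range_bw = 8, eps = 1e-6,
                           max_iter = 20, tol = 0.1, min_separation = 1) {
  stopifnot(spatial_bw > 0, range_bw > 0, eps > 0)
  structure(list(spatial_bw = spatial_bw, range_bw = range_bw, eps = eps,
                 max_iter = max_iter, tol = tol,
                 min_separation = min_separation),
            class = "segment_config")
}

#' Mean-shift superpixels in CIE Lab
#'
#' Runs joint spatial-range mean-shift filtering (flat kernel, bandwidths
#' `spatial_bw` pixels and `range_bw` Lab units) and merges pixels whose
#' converged modes lie within `range_bw / 2` of each other into 4-connected
#' superpixels.  Cluster mean colours are the arithmetic means of the
#' member pixels' original Lab values.
#'
#' @param lab an `h x w x 3` CIE Lab array (see [rgb_to_lab()]).
#' @param spatial_bw,range_bw bandwidths; must be positive.
#' @param max_iter,tol convergence controls of the filtering stage.
#' @return a list of class `superpixel_map` with `labels` (integer matrix,
#'   1-based), `means` (`K x 3` matrix of cluster mean Lab colours) and
#'   `sizes`.
#' @export
mean_shift_superpixels <- function(lab, spatial_bw = 8, range_bw = 8,
                                   max_iter = 20, tol = 0.1) {
  stopifnot(spatial_bw > 0, range_bw > 0)
  modes <- ms_filter(lab[, , 1], lab[, , 2], lab[, , 3],
                     spatial_bw, range_bw, as.integer(max_iter), tol)
  labels <- ms_label(modes$L, modes$a, modes$b, range_bw / 2)
  k <- max(labels)
  if (k > 1e4)
    warning(sprintf("mean shift produced %d clusters; bandwidths may be too small", k))
  idx <- as.vector(labels)
  means <- cbind(
    rowsum(as.vector(lab[, , 1]), idx),
    rowsum(as.vector(lab[, , 2]), idx),
    rowsum(as.vector(lab[, , 3]), idx))
  sizes <- tabulate(idx, k)
  means <- means / sizes
  colnames(means) <- c("L", "a", "b")
  structure(list(labels = labels, means = means, sizes = sizes),
            class = "superpixel_map")
}

#' Estimate the background colour from corner superpixels
#'
#' The scanner background surrounds the bolus, so the superpixels containing
#' the four image corners are taken as background; the background colour
#' `bg` is the unweighted mean of the mean Lab colours of the distinct
#' corner clusters (up to 4).
#'
#' @param sp a `superpixel_map`.
#' @return a numeric Lab triple of class `background_colour`.
#' @export
estimate_background <- function(sp) {
  l <- sp$labels
  nr <- nrow(l); nc <- ncol(l)
  corner_labels <- unique(c(l[1, 1], l[1, nc], l[nr, 1], l[nr, nc]))
  bg <- colMeans(sp$means[corner_labels, , drop = FALSE])
  structure(bg, class = "background_colour")
}

#' Log-distance map to the background colour
#'
#' For every pixel computes `log(||x_i - bg||_2 + eps)` (natural log), the
#' logarithm of the Euclidean Lab distance to the estimated background.
#' The log compresses the colour heterogeneity inside the bolus (red,
#' green and blended regions all sit far from the grey background) while
#' preserving the near-zero homogeneity of the background itself; `eps`
#' keeps the map finite where a pixel equals `bg` exactly.
#'
#' @param lab an `h x w x 3` Lab array.
#' @param bg a Lab triple from [estimate_background()].
#' @param eps positive stabilizer, default `1e-6`.
#' @return a numeric matrix of class `distance_map`.
#' @export
distance_map <- function(lab, bg, eps = 1e-6) {
  stopifnot(eps > 0)
  d <- sqrt((lab[, , 1] - bg[1])^2 + (lab[, , 2] - bg[2])^2 +
              (lab[, , 3] - bg[3])^2)
  structure(log(d + eps), class = c("distance_map", "matrix"))
}

#' Two-class k-means bolus extraction from a distance map
#'
#' Clusters the scalar distance-map values into two groups with k-means
#' (`k = 2`).  To make the nominally stochastic step a pure function of the
#' image, the two centroids are initialized at the 10th and 90th
#' percentiles of the map.  The bolus is the cluster whose member pixels
#' lie, on average, closer to the geometric image centre (ties broken
#' toward the smaller cluster, since the bolus occupies less area than the
#' background on a scanner bed); the mask is then post-processed by keeping
#' its largest 4-connected component and filling interior holes.
#'
#' @param dm a `distance_map`.
#' @param min_separation reject the image as degenerate when the two
#'   cluster centres end up closer than this (log-distance units).
#' @return a logical matrix of class `bolus_mask`.
#' @export
kmeans_bolus <- function(dm, min_separation = 1) {
  v <- as.vector(dm)
  if (length(unique(v)) < 2 || diff(range(v)) < .Machine$double.eps)
    stop("degenerate image: no foreground/background contrast")
  centers <- matrix(quantile(v, c(0.1, 0.9), names = FALSE), ncol = 1)
  if (abs(diff(centers[, 1])) < .Machine$double.eps)
    stop("degenerate image: no foreground/background contrast")
  km <- suppressWarnings(kmeans(v, centers = centers, iter.max = 100))
  if (abs(diff(km$centers[, 1])) < min_separation)
    stop("degenerate image: no foreground/background contrast")

  assign <- matrix(km$cluster, nrow(dm), ncol(dm))
  nr <- nrow(dm); nc <- ncol(dm)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dctr <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  mean_d <- c(mean(dctr[assign == 1]), mean(dctr[assign == 2]))
  sizes <- c(sum(assign == 1), sum(assign == 2))
  bolus_cl <- if (abs(diff(mean_d)) < 1e-9) which.min(sizes) else which.min(mean_d)

  mask <- assign == bolus_cl
  mask <- keep_largest_component(mask)
  mask <- fill_holes(mask)
  structure(mask, class = c("bolus_mask", "matrix"))
}

keep_largest_component <- function(mask) {
  lab <- cc_label(mask)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

fill_holes <- function(mask) {
  inv <- cc_label(!mask)
  if (max(inv) == 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(inv[1, ], inv[nr, ], inv[, 1], inv[, nc]))
  border <- border[border > 0]
  mask | !(inv %in% c(0, border))
}

#' Segment the bolus in a wafer image
#'
#' Runs the full five-step colour-based segmentation on one RGB image:
#' conversion to CIE Lab, mean-shift superpixels, background colour from
#' the corner superpixels, log-distance map to the background, and
#' two-class k-means with centre-based bolus selection.  The whole chain is
#' a pure function of `(image, config)` — repeated runs on the same image
#' give identical masks and pixel lists.
#'
#' @param image an `h x w x 3` 8-bit RGB array.
#' @param config a [segment_config()].
#' @return a list of class `bolus_segmentation` with `mask` (logical
#'   matrix), `pixels` (`n x 3` matrix of the bolus RGB values from the
#'   original image), `n_pixels`, and `bg` (estimated Lab background).
#' @examples
#' w <- generate_wafer(wafer_spec(seed = 7))
#' s <- segment(w$image)
#' mean(s$mask == w$mask)
#' @export
segment <- function(image, config = segment_config()) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected a 3-channel RGB image array")
  lab <- rgb_to_lab(image)
  sp <- mean_shift_superpixels(lab, config$spatial_bw, config$range_bw,
                               config$max_iter, config$tol)
  bg <- estimate_background(sp)
  dm <- distance_map(lab, bg, config$eps)
  mask <- kmeans_bolus(dm, config$min_separation)
  pix <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  colnames(pix) <- c("r", "g", "b")
  structure(list(mask = mask, pixels = pix, n_pixels = sum(mask), bg = bg),
            class = "bolus_segmentation")
}

#' Dice overlap between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; used to score segmentations against the
#' generator's ground-truth bolus footprint.
#'
#' @param a,b logical matrices of equal dimension.
#' @return a number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
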