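#' Hue histogram of bolus pixels
#'
#' Bins hue angles into `bins` equal-width intervals
#' `[k * 360/B, (k+1) * 360/B)` over `[0, 360)`.  No circular pooling is
#' applied: 0.1 and 359.9 degrees fall in the first and last bin
#' respectively, matching the conventional linear histogram of the hue
#' channel.
#'
#' @param hues numeric vector of hue angles in `[0, 360)`.
#' @param bins number of bins `B >= 2`; default 256 (8-bit hue convention).
#' @return a list of class `hue_histogram` with `counts` (length `B`),
#'   `bins` and `n_pixels`.
#' @export
hue_histogram <- function(hues, bins = 256) {
  stopifnot(bins >= 2)
  if (any(hues < 0 | hues >= 360)) stop("hues must lie in [0, 360)")
  idx <- pmin(floor(hues * bins / 360), bins - 1)
  counts <- tabulate(idx + 1L, bins)
  structure(list(counts = counts, bins = bins, n_pixels = length(hues)),
            class = "hue_histogram")
}

#' Variance of the hue histogram (VhH)
#'
#' The masticatory-performance statistic: the population variance of the
#' hue-bin count vector,
#' \deqn{VhH = \frac{1}{B}\sum_k (c_k - n/B)^2 = \frac{\sum_k c_k^2}{B} -
#'   \left(\frac{n}{B}\right)^2.}
#' A well-mixed bolus concentrates its pixels in a single hue band, which
#' maximizes the spread of the count vector, so higher VhH indicates
#' greater colour mixing.  The statistic scales with the square of the
#' pixel count (multiplying every count by `s` multiplies VhH by `s^2`) and
#' is bounded by `n^2 (B-1) / B^2`.
#'
#' @param hist a [hue_histogram()], or a bare vector of bin counts.
#' @return a non-negative number.
#' @examples
#' vhh(c(1000, rep(0, 255)))
#' @export
vhh <- function(hist) {
  counts <- if (inherits(hist, "hue_histogram")) hist$counts else hist
  b <- length(counts)
  n <- sum(counts)
  sum(counts^2) / b - (n / b)^2
}

#' One masticatory-performance measurement from a two-sided sample
#'
#' A flattened wafer is scanned on both sides; the sample's VhH is computed
#' on the pooled hue histogram of the bolus pixels of the two sides, so
#' both images contribute symmetrically to a single measurement.  Per-side
#' VhH values are also reported for diagnostics.
#'
#' @param side1,side2 `n x 3` matrices of segmented bolus RGB pixels (see
#'   [segment()]).
#' @param sample_id identifier carried into the result.
#' @param bins hue histogram bin count.
#' @param chroma_threshold achromatic-exclusion threshold of
#'   [rgb_to_hue()].
#' @return a list of class `mp_measurement` with `sample_id`, `vhh`,
#'   `n_pixels` (chromatic, pooled), `n_excluded`, `side_vhh` (length-2
#'   vector) and `bins`.
#' @export
measure_sample <- function(side1, side2, sample_id = NA_character_,
                           bins = 256, chroma_threshold = 8) {
  sides <- list(side1, side2)
  hues <- vector("list", 2)
  for (i in 1:2) {
    if (is.null(sides[[i]]) || nrow(sides[[i]]) == 0)
      stop(sprintf("side %d has no bolus pixels", i))
    hues[[i]] <- tryCatch(rgb_to_hue(sides[[i]], chroma_threshold),
                          error = function(e)
                            stop(sprintf("side %d: %s", i, conditionMessage(e)),
                                 call. = FALSE))
  }
  pooled <- c(hues[[1]]$hue, hues[[2]]$hue)
  h <- hue_histogram(pooled, bins)
  side_vhh <- vapply(hues, function(x) vhh(hue_histogram(x$hue, bins)),
                     numeric(1))
  structure(list(sample_id = sample_id, vhh = vhh(h),
                 n_pixels = h$n_pixels,
                 n_excluded = hues[[1]]$n_excluded + hues[[2]]$n_excluded,
                 side_vhh = side_vhh, bins = bins),
            class = "mp_measurement")
}
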