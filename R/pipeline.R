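#' Render wafer image pairs for every cohort measurement
#'
#' Maps each row's latent VhH monotonically to a mixing degree `m` by
#' min-max scaling over the whole cohort and renders two wafer images (the
#' two scanned sides of the flattened sample) per measurement.  If every
#' VhH value is identical the scaling is degenerate and all `m` are set to
#' 0.5 with a warning.  Side seeds are derived deterministically from
#' `spec$seed` and the row index, so the same cohort and spec reproduce an
#' identical image set.
#'
#' @param cohort a cohort table.
#' @param spec a [wafer_spec()] providing canvas geometry, colours and
#'   noise; its `m` field is ignored and its `seed` anchors the whole set.
#' @param dir optional output directory; when given, sides are written as
#'   uncompressed TIFF, masks as PNG, and the manifest gains file-path
#'   columns.
#' @return a list with `manifest` (data frame: `sample_id`, `subject_id`,
#'   `session`, `vhh`, `m`, seeds, and paths when written) and `samples`
#'   (list of per-row lists with `side1`, `side2` wafer objects), plus the
#'   spec echo.
#' @export
render_cohort_images <- function(cohort, spec = wafer_spec(seed = 1),
                                 dir = NULL) {
  # one rendered pair per measurement row; a subset of a cohort (single
  # sessions, single subjects) is fine here, so only row-level checks apply
  req <- c("subject_id", "session", "vhh")
  if (!all(req %in% names(cohort)))
    stop("cohort table is missing columns: ",
         paste(setdiff(req, names(cohort)), collapse = ", "))
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!is.numeric(cohort$vhh) || any(!is.finite(cohort$vhh)))
    stop("vhh must be finite and numeric")
  rng <- range(cohort$vhh)
  if (diff(rng) == 0) {
    warning("degenerate cohort: all vhh equal; using m = 0.5 throughout")
    m <- rep(0.5, nrow(cohort))
  } else {
    m <- (cohort$vhh - rng[1]) / diff(rng)
  }
  base_seed <- spec$seed %||% 0
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- data.frame(
    sample_id = paste0(cohort$subject_id, "_s", cohort$session),
    subject_id = cohort$subject_id, session = cohort$session,
    vhh = cohort$vhh, m = m,
    seed1 = (base_seed + 2L * (seq_len(nrow(cohort)) - 1L)) %% .Machine$integer.max,
    seed2 = (base_seed + 2L * (seq_len(nrow(cohort)) - 1L) + 1L) %% .Machine$integer.max,
    stringsAsFactors = FALSE)

  samples <- lapply(seq_len(nrow(cohort)), function(i) {
    s1 <- spec; s1$m <- m[i]; s1$seed <- manifest$seed1[i]
    s2 <- spec; s2$m <- m[i]; s2$seed <- manifest$seed2[i]
    list(side1 = generate_wafer(s1), side2 = generate_wafer(s2))
  })

  if (!is.null(dir)) {
    manifest$side1_path <- file.path(dir, paste0(manifest$sample_id, "_a.tiff"))
    manifest$side2_path <- file.path(dir, paste0(manifest$sample_id, "_b.tiff"))
    for (i in seq_along(samples)) {
      write_wafer_image(samples[[i]]$side1$image, manifest$side1_path[i])
      write_wafer_image(samples[[i]]$side2$image, manifest$side2_path[i])
      write_mask_png(samples[[i]]$side1$mask,
                     file.path(dir, paste0(manifest$sample_id[i], "_a_mask.png")))
      write_mask_png(samples[[i]]$side2$mask,
                     file.path(dir, paste0(manifest$sample_id[i], "_b_mask.png")))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(manifest = manifest, samples = samples, spec = spec)
}

#' Pipeline run configuration
#'
#' Bundles the segmentation, mixture and statistics options of a pipeline
#' run so that every output manifest can echo the exact configuration that
#' produced it.
#'
#' @param segmentation a [segment_config()].
#' @param bins hue histogram bin count.
#' @param chroma_threshold achromatic-exclusion threshold.
#' @param gee_corr GEE working correlation.
#' @param seed run seed echoed into manifests.
#' @return a list of class `run_config`.
#' @export
run_config <- function(segmentation = segment_config(), bins = 256,
                       chroma_threshold = 8, gee_corr = "independence",
                       seed = NULL) {
  structure(list(segmentation = segmentation, bins = bins,
                 chroma_threshold = chroma_threshold, gee_corr = gee_corr,
                 seed = seed),
            class = "run_config")
}

#' Process a batch of wafer image pairs into VhH measurements
#'
#' For every manifest row, reads the two side images, segments each,
#' pools the bolus pixels and computes the sample's VhH.  Samples whose
#' images are missing or unreadable are skipped, recorded in the
#' `failures` attribute and reported with a warning — the run continues.
#'
#' @param manifest a data frame with columns `sample_id`, `side1_path`,
#'   `side2_path`, or the path of a CSV holding one.
#' @param config a [run_config()].
#' @param out optional path to write the measurement CSV.
#' @return a data frame with one row per successful sample: `sample_id`,
#'   `n_pixels`, `n_excluded`, `vhh`, `side1_vhh`, `side2_vhh`.  The
#'   attribute `failures` lists skipped samples and reasons.
#' @export
run_images <- function(manifest, config = run_config(), out = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- read.table(manifest, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  }
  req <- c("sample_id", "side1_path", "side2_path")
  if (!all(req %in% names(manifest)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  if (nrow(manifest) == 0) stop("empty manifest: no samples to process")

  rows <- vector("list", nrow(manifest))
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      img1 <- read_wafer_image(manifest$side1_path[i])
      img2 <- read_wafer_image(manifest$side2_path[i])
      seg1 <- segment(img1, config$segmentation)
      seg2 <- segment(img2, config$segmentation)
      mp <- measure_sample(seg1$pixels, seg2$pixels,
                           sample_id = manifest$sample_id[i],
                           bins = config$bins,
                           chroma_threshold = config$chroma_threshold)
      data.frame(sample_id = mp$sample_id, n_pixels = mp$n_pixels,
                 n_excluded = mp$n_excluded, vhh = mp$vhh,
                 side1_vhh = mp$side_vhh[1], side2_vhh = mp$side_vhh[2],
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(
        sample_id = manifest$sample_id[i], message = conditionMessage(res))
    } else rows[[i]] <- res
  }
  out_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out_df))
    out_df <- data.frame(sample_id = character(), n_pixels = integer(),
                         n_excluded = integer(), vhh = numeric(),
                         side1_vhh = numeric(), side2_vhh = numeric())
  if (length(failures))
    warning(sprintf("%d sample(s) skipped: %s", length(failures),
                    paste(vapply(failures, `[[`, "", "sample_id"),
                          collapse = ", ")))
  attr(out_df, "failures") <- failures
  if (!is.null(out)) write.csv(out_df, out, row.names = FALSE, quote = FALSE)
  out_df
}

#' End-to-end pipeline run
#'
#' Composes the image and statistics stages into one reproducible run.
#' Two entry modes are supported: a cohort table (or cohort CSV path) for a
#' statistics-only run, or an image manifest plus a covariate table that is
#' joined to the recomputed VhH measurements by `sample_id` before the
#' statistical battery.  The output directory receives
#' `measurements.csv` (image mode), `table3.csv` ... `table7.csv`,
#' `report.json` and `manifest.json` (config echo).
#'
#' @param cohort a cohort table or path to a cohort CSV (statistics-only
#'   mode).
#' @param images an image manifest (see [run_images()]); requires
#'   `covariates`.
#' @param covariates a data frame with `sample_id`, `subject_id`, `age`,
#'   `sex`, `dental_status`, `cgc`, `session` used to promote image
#'   measurements to a cohort table.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the `chewmix_report`, invisibly, with the measurement table (if
#'   any) attached as attribute `measurements`.
#' @export
run_full <- function(cohort = NULL, images = NULL, covariates = NULL,
                     out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  measurements <- NULL
  if (!is.null(images)) {
    if (is.null(covariates))
      stop("image mode needs a covariate table to build the cohort")
    measurements <- run_images(images, config,
                               out = file.path(out_dir, "measurements.csv"))
    merged <- merge(covariates, measurements[, c("sample_id", "vhh")],
                    by = "sample_id")
    cohort <- merged[, c("subject_id", "age", "sex", "dental_status",
                         "cgc", "session", "vhh")]
  } else if (is.character(cohort)) {
    cohort <- read_supplementary(cohort, quiet = TRUE)
  }
  if (is.null(cohort)) stop("provide either a cohort or an image manifest")
  report <- build_report(cohort, gee_corr = config$gee_corr)
  write_report(report, out_dir)
  jsonlite::write_json(
    list(seed = config$seed, bins = config$bins,
         chroma_threshold = config$chroma_threshold,
         gee_corr = config$gee_corr,
         segmentation = unclass(config$segmentation),
         n_rows = nrow(cohort)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  attr(report, "measurements") <- measurements
  invisible(report)
}
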