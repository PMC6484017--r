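test_that("mean shift collapses homogeneous structures to the right clusters", {
  # constant image: a single cluster whose mean is the image colour
  img <- array(0, c(24, 24, 3)); img[, , 1] <- 120; img[, , 2] <- 140; img[, , 3] <- 90
  sp <- mean_shift_superpixels(rgb_to_lab(img))
  expect_equal(max(sp$labels), 1)
  expect_equal(unname(sp$means[1, ]), unname(rgb_to_lab(matrix(c(120, 140, 90), 1))[1, ]))

  # two homogeneous halves far apart in Lab: exactly 2 clusters, means exact
  img2 <- array(0, c(30, 40, 3))
  img2[, 1:20, ] <- 40
  img2[, 21:40, 1] <- 220; img2[, 21:40, 2] <- 220; img2[, 21:40, 3] <- 220
  lab2 <- rgb_to_lab(img2)
  sp2 <- mean_shift_superpixels(lab2)
  expect_equal(max(sp2$labels), 2)
  halves <- rgb_to_lab(rbind(c(40, 40, 40), c(220, 220, 220)))
  got <- sp2$means[c(sp2$labels[1, 1], sp2$labels[1, 40]), ]
  expect_equal(unname(got), unname(halves), tolerance = 1e-8)

  # idempotence: repainting with cluster means reproduces the partition
  w <- generate_wafer(small_wafer(seed = 21, noise_sd = 2))
  lab <- rgb_to_lab(w$image)
  spw <- mean_shift_superpixels(lab)
  repainted <- array(0, dim(lab))
  for (k in 1:3) repainted[, , k] <- matrix(spw$means[spw$labels, k],
                                            nrow(spw$labels))
  sp_re <- mean_shift_superpixels(repainted)
  expect_equal(max(sp_re$labels), max(spw$labels))
  expect_true(all(tapply(sp_re$labels, spw$labels,
                         function(v) length(unique(v))) == 1))
})

test_that("background colour is the unweighted mean over corner clusters", {
  # four quadrants of distinct luminance -> 4 corner clusters, mean L exact
  img <- array(0, c(40, 40, 3))
  vals <- c(30, 80, 150, 230)
  img[1:20, 1:20, ] <- vals[1];  img[1:20, 21:40, ] <- vals[2]
  img[21:40, 1:20, ] <- vals[3]; img[21:40, 21:40, ] <- vals[4]
  sp <- mean_shift_superpixels(rgb_to_lab(img))
  bg <- estimate_background(sp)
  labs <- rgb_to_lab(cbind(vals, vals, vals))
  expect_equal(unname(bg[1]), mean(labs[, 1]), tolerance = 1e-6)
  expect_lt(abs(bg[2]), 0.5)

  # synthetic wafer: estimated bg within 2 Lab units of the rendered background
  w <- generate_wafer(small_wafer(seed = 8))
  spw <- mean_shift_superpixels(rgb_to_lab(w$image))
  bgw <- estimate_background(spw)
  truth <- rgb_to_lab(matrix(w$spec$background_rgb, 1))[1, ]
  expect_lt(sqrt(sum((bgw - truth)^2)), 2)
})

test_that("distance map is the stabilized log of the Lab distance", {
  lab <- array(0, c(2, 2, 3))
  lab[1, 1, ] <- c(50, 0, 0)
  lab[1, 2, ] <- c(50 + exp(1) - 1e-6, 0, 0)
  lab[2, 1, ] <- c(53, 0, 0)
  lab[2, 2, ] <- c(60, 0, 0)
  dm <- distance_map(lab, c(50, 0, 0), eps = 1e-6)
  expect_equal(dm[1, 1], log(1e-6))          # pixel equal to bg
  expect_equal(dm[1, 2], 1)                  # ||x - bg|| = e - eps
  expect_lt(dm[2, 1], dm[2, 2])              # monotone in the distance
  # invariance to a global lightness shift
  lab_shift <- lab; lab_shift[, , 1] <- lab_shift[, , 1] + 7
  expect_equal(distance_map(lab_shift, c(57, 0, 0), eps = 1e-6)[1:2, 1:2],
               dm[1:2, 1:2])
})

test_that("k-means bolus selection is spatial and robust to contrast inversion", {
  mk_disk <- function(fg, bg) {
    img <- array(bg, c(60, 60, 3))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[outer(1:60, 1:60, function(r, c) (r - 30.5)^2 + (c - 30.5)^2 <= 18^2)] <- fg
      img[, , k] <- ch
    }
    img
  }
  seg_dark <- segment(mk_disk(40, 200))     # disk darker than background
  seg_bright <- segment(mk_disk(250, 90))   # disk brighter than background
  expect_identical(seg_dark$mask, seg_bright$mask)
  truth <- outer(1:60, 1:60, function(r, c) (r - 30.5)^2 + (c - 30.5)^2 <= 18^2)
  expect_gte(dice(seg_dark$mask, truth), 0.98)

  expect_error(kmeans_bolus(structure(matrix(1, 5, 5), class = "distance_map")),
               "degenerate")
  # blank background-only image
  blank <- array(200, c(40, 40, 3))
  expect_error(segment(blank), "degenerate")
})

test_that("segmentation recovers the bolus footprint across mixing degrees", {
  for (m in c(0, 0.5, 1)) {
    w <- generate_wafer(small_wafer(m = m, seed = 30 + round(10 * m)))
    s <- segment(w$image)
    expect_gte(dice(s$mask, w$mask), 0.95)
  }
  wn <- generate_wafer(small_wafer(m = 0.5, noise_sd = 0, seed = 33))
  expect_gte(dice(segment(wn$image)$mask, wn$mask), 0.98)
})

test_that("segment is a pure function of image and config", {
  w <- generate_wafer(small_wafer(m = 0.25, seed = 44))
  s1 <- segment(w$image)
  s2 <- segment(w$image)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$pixels, s2$pixels)
})
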