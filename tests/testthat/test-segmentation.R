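# Candidate detection, ROI handling, view sorting and pixel masks.

# paste a 45 x 45 rendering into a larger blank field at a given center
paste_synapse <- function(field, render, center) {
  h <- 22
  for (i in seq_along(field$channels)) {
    field$channels[[i]][(center[1] - h):(center[1] + h),
                        (center[2] - h):(center[2] + h)] <-
      render$image$channels[[i]]
  }
  field
}

blank_field <- function(n = 128) {
  raster_image(list(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n)))
}

test_that("candidate detection recovers planted synapses without duplicates", {
  r <- render_clean_sideview(60)
  f1 <- paste_synapse(blank_field(), r, c(50, 70))
  cand <- detect_candidates(get_channel(f1, "Bassoon"),
                            get_channel(f1, "Dyn1xA"))
  expect_equal(nrow(cand), 1)
  # detection keys on the Bassoon bar, which sits half the bar separation
  # (150 / 2 nm = 3.75 px) off the synapse midline
  expect_lte(abs(cand$row - 50), 1.5)
  expect_lte(abs(cand$col - (70 - 3.75)), 1.5)
  # blank image: empty list
  f0 <- blank_field()
  expect_equal(nrow(detect_candidates(get_channel(f0, "Bassoon"),
                                      get_channel(f0, "Dyn1xA"))), 0)
  # two synapses 100 px apart: two centers, ROIs recover both
  f2 <- paste_synapse(paste_synapse(blank_field(200), r, c(50, 50)),
                      r, c(50, 150))
  cand2 <- detect_candidates(get_channel(f2, "Bassoon"),
                             get_channel(f2, "Dyn1xA"))
  expect_equal(nrow(cand2), 2)
  rois <- lapply(seq_len(nrow(cand2)), function(i) {
    extract_roi(f2, c(cand2$row[i], cand2$col[i]))
  })
  expect_true(all(!vapply(rois, is.null, logical(1))))
})

test_that("ROI extraction crops exactly and rejects border centers", {
  img <- raster_image(list(matrix(seq_len(101 * 101), 101),
                           matrix(0, 101, 101), matrix(0, 101, 101)))
  roi <- extract_roi(img, c(51, 51))
  expect_equal(dim(roi$crops[[1]]), c(45, 45))
  expect_equal(roi$crops[[1]], img$channels[[1]][29:73, 29:73])
  expect_warning(r2 <- extract_roi(img, c(10, 51)), "border")
  expect_null(r2)
  cimg <- raster_image(list(matrix(2, 60, 60)), channel_roles = "Bassoon")
  rc <- extract_roi(cimg, c(30, 30))
  expect_true(all(rc$crops[[1]] == 2))
})

test_that("view sorting separates bars from discs by elongation", {
  side <- extract_roi(render_clean_sideview(60)$image, c(23, 23))
  expect_equal(classify_view(side)$view, "side", ignore_attr = TRUE)
  top <- extract_roi(render_topview(topview_truth(photon_scale = Inf))$image,
                     c(23, 23))
  expect_equal(classify_view(top)$view, "top", ignore_attr = TRUE)
  blank <- extract_roi(blank_field(60), c(30, 30))
  expect_equal(classify_view(blank)$view, "rejected", ignore_attr = TRUE)
})

test_that("view sorting matches ground truth on seeded noiseless fixtures", {
  views <- character(0); truth <- character(0)
  for (i in 1:10) {
    ang <- (i * 17) %% 180
    s <- render_sideview(sideview_truth(bar_angle_deg = ang,
                                        photon_scale = Inf))
    t <- render_topview(topview_truth(photon_scale = Inf))
    views <- c(views,
               classify_view(extract_roi(s$image, c(23, 23)))$view,
               classify_view(extract_roi(t$image, c(23, 23)))$view)
    truth <- c(truth, "side", "top")
  }
  expect_equal(unname(views), truth, ignore_attr = TRUE)
})

test_that("pixel classification recovers objects and enforces polarity", {
  # two-level image: mask equals the object exactly
  m <- matrix(0, 45, 45); m[15:30, 18:28] <- 1
  expect_equal(pixel_classify(m), m)
  # affine intensity rescaling leaves the mask unchanged
  expect_equal(pixel_classify(0.2 + 3.7 * m), pixel_classify(m))
  # noiseless rendered bar: mask covers >= 95% of the bar's half-max support
  r <- render_clean_sideview(0)
  ch1 <- get_channel(r$image, "Bassoon")
  mask <- pixel_classify(ch1)
  support <- ch1 >= 0.5 * max(ch1)
  expect_gte(sum(mask[support]) / sum(support), 0.95)
})

test_that("polarity enforcement maps the bright class to foreground", {
  # a logistic stand-in trained with inverted labels produces an inverted
  # mask; enforcement must flip it back
  m <- matrix(0, 45, 45); m[10:35, 20:26] <- 1
  # perfectly separable training data: glm convergence warnings expected
  inverted <- suppressWarnings(train_pixel_classifier(list(m), list(1 - m)))
  mask <- pixel_classify(m, classifier = inverted)
  expect_gt(mean(mask[m == 1]), 0.9)
  expect_lt(mean(mask[m == 0]), 0.1)
})
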