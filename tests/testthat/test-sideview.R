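# Center-line geometry, rotation/orientation standardization, band line
# scan and peak calling for side-view synapses.

test_that("mask ellipse fitting recovers shape, size and angle", {
  # axis-aligned filled rectangle: long axis horizontal, angle 0
  rect <- matrix(0, 45, 45); rect[20:26, 12:32] <- 1  # 7 rows x 21 cols
  fr <- fit_mask_ellipse(rect)
  expect_lt(axial_difference_deg(fr$angle_deg, 0), 1)
  expect_gt(fr$major_len, fr$minor_len)
  # filled disc: degenerate axes within 5%, angle normalized to [0, 180)
  disc <- make_ellipse_mask(45, 23, 23, 10, 10, 0)
  fd <- fit_mask_ellipse(disc)
  expect_lt(abs(fd$major_len - fd$minor_len) / fd$major_len, 0.05)
  expect_gte(fd$angle_deg, 0); expect_lt(fd$angle_deg, 180)
  # render-and-recover: known axes and angle
  ell <- make_ellipse_mask(45, 21, 24, 15, 5, 37)
  fe <- fit_mask_ellipse(ell)
  expect_lt(abs(fe$center_row - 21), 0.5)
  expect_lt(abs(fe$center_col - 24), 0.5)
  expect_lt(axial_difference_deg(fe$angle_deg, 37), 2)
  # too few points: unanalyzable
  tiny <- matrix(0, 45, 45); tiny[23, 23] <- 1
  expect_error(fit_mask_ellipse(tiny), "unanalyzable")
})

test_that("axial angle averaging handles wrap-around", {
  expect_equal(average_axis_angles(10, 30), 20, tolerance = 1e-12)
  expect_equal(average_axis_angles(179, 1), 0, tolerance = 1e-9)
  for (a in c(0, 17.5, 90, 135.2)) {
    expect_equal(average_axis_angles(a, a), a, tolerance = 1e-12)
  }
})

test_that("the center-line averages axes and anchors at the midpoint", {
  e1 <- structure(list(center_row = 10, center_col = 20, major_len = 22,
                       minor_len = 8, angle_deg = 90), class = "ellipse_fit")
  e2 <- structure(list(center_row = 10, center_col = 40, major_len = 22,
                       minor_len = 8, angle_deg = 90), class = "ellipse_fit")
  cl <- compute_center_line(e1, e2)
  expect_equal(cl$angle_deg, 90)
  expect_equal(c(cl$anchor_row, cl$anchor_col), c(10, 30))
  expect_equal(cl$length_px, 22)
  # > 30 degree difference: must equal the brute-force unit-vector sum
  e3 <- e1; e3$angle_deg <- 0
  e4 <- e2; e4$angle_deg <- 40
  cl2 <- compute_center_line(e3, e4)
  u1 <- c(cos(0), sin(0))
  u2 <- c(cos(40 * pi / 180), sin(40 * pi / 180))
  if (sum(u1 * u2) < 0) u2 <- -u2
  s <- u1 + u2
  oracle <- (atan2(s[2], s[1]) * 180 / pi) %% 180
  expect_equal(cl2$angle_deg, oracle, tolerance = 1e-10)
  # length is always the mean of the major axes
  e5 <- e2; e5$major_len <- 30
  expect_equal(compute_center_line(e1, e5)$length_px, 26)
})

test_that("rotation to vertical behaves as an isometry of the geometry", {
  r <- render_clean_sideview(0)
  roi <- extract_roi(r$image, c(23, 23))
  vert <- structure(list(anchor_row = 23, anchor_col = 23, angle_deg = 90,
                         length_px = 20), class = "center_line")
  out <- rotate_to_vertical(roi, vert)
  expect_equal(out$crops, roi$crops, tolerance = 1e-12)  # angle 0 rotation
  # a horizontal bar rotated from a 0 degree center-line becomes vertical
  horiz <- render_clean_sideview(0, angle_deg = 0)
  roih <- extract_roi(horiz$image, c(23, 23))
  clh <- structure(list(anchor_row = 23, anchor_col = 23, angle_deg = 0,
                        length_px = 20), class = "center_line")
  roth <- rotate_to_vertical(roih, clh)
  ch1 <- roth$crops[[1]]
  cols_spread <- which(colSums(ch1 > 0.5 * max(ch1)) > 0)
  rows_spread <- which(rowSums(ch1 > 0.5 * max(ch1)) > 0)
  expect_gt(length(rows_spread), 2 * length(cols_spread))
  # constant channels are fixed points (fill equals the mean)
  cimg <- structure(list(crops = list(matrix(4, 45, 45)),
                         channel_roles = "Bassoon", pixel_size_nm = 20),
                    class = "synapse_roi")
  cr <- rotate_to_vertical(cimg, clh)
  expect_equal(cr$crops[[1]], matrix(4, 45, 45), tolerance = 1e-9)
})

test_that("orientation standardization puts Bassoon right of PSD95", {
  r <- render_clean_sideview(60)
  roi <- extract_roi(r$image, c(23, 23))
  mb <- pixel_classify(roi_channel_pkg(roi, "Bassoon"))
  mp <- pixel_classify(roi_channel_pkg(roi, "PSD95"))
  cl <- compute_center_line(fit_mask_ellipse(mb), fit_mask_ellipse(mp))
  rot <- rotate_to_vertical(roi, cl)
  std <- standardize_orientation(rot, mb, mp, cl)
  centroid_col <- function(m) mean(which(m > 0.5 * max(m), arr.ind = TRUE)[, 2])
  expect_gt(centroid_col(std$crops[[1]]), centroid_col(std$crops[[2]]))
  # applying the operation again to the standardized ROI (with masks
  # recomputed in its frame) is a no-op
  mb2 <- pixel_classify(std$crops[[1]])
  mp2 <- pixel_classify(std$crops[[2]])
  std_again <- std
  std_again$rotation_deg <- 0
  std2 <- standardize_orientation(std_again, mb2, mp2, cl)
  expect_false(std2$flipped)
  expect_equal(std2$crops, std$crops)
})

test_that("standardized geometry is orientation-idempotent across fixtures", {
  for (i in 1:8) {
    ang <- (i * 23.5) %% 180
    r <- render_clean_sideview(80, angle_deg = ang)
    res <- sideview_profile(r$image)
    std <- res$roi
    mb <- pixel_classify(roi_channel_pkg(std, "Bassoon"))
    mp <- pixel_classify(roi_channel_pkg(std, "PSD95"))
    cl2 <- compute_center_line(fit_mask_ellipse(mb), fit_mask_ellipse(mp))
    expect_lt(abs(90 - cl2$angle_deg), 2)
    std2 <- standardize_orientation(std, mb, mp, cl2)
    expect_false(std2$flipped)
    # Bassoon always ends up right of the center-line
    expect_gt(mean(which(mb > 0, arr.ind = TRUE)[, 2]), 23)
  }
})

test_that("the band line scan averages rows 2..43 and recenters x", {
  roi <- structure(list(crops = list(matrix(5, 45, 45), matrix(5, 45, 45),
                                     matrix(5, 45, 45)),
                        channel_roles = c("Bassoon", "PSD95", "Dyn1xA"),
                        pixel_size_nm = 20),
                   class = "synapse_roi")
  prof <- band_line_scan(roi)
  expect_true(all(prof$CH1_norm == 0))  # constant: degenerate normalization
  expect_equal(range(prof$x_nm), c(-440, 440))
  # a vertical line 5 px right of center peaks at +100 nm
  m <- matrix(0, 45, 45); m[, 28] <- 1
  roi$crops[[3]] <- m
  prof2 <- band_line_scan(roi)
  expect_equal(prof2$x_nm[which.max(prof2$CH3_norm)], 100)
  expect_error(band_line_scan(roi, band_width_px = 50), "band width")
})

test_that("peak calling applies the strict > 0.5 amplitude gate", {
  prof <- tibble::tibble(x_px_from_centerline = -22:22,
                         x_nm = 20 * (-22:22),
                         CH1_norm = 0, CH2_norm = 0,
                         CH3_norm = pmax(0, 1 - abs(-22:22 + 2) / 10))
  attr(prof, "channel_roles") <- c("Bassoon", "PSD95", "Dyn1xA")
  attr(prof, "pixel_size_nm") <- 20
  class(prof) <- c("linescan_profile", class(prof))
  pk <- call_peaks(prof)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$x_nm, -40)
  # a peak of exactly 0.5 is rejected
  prof$CH3_norm <- pmax(0, 0.5 - abs(-22:22 + 2) / 10 * 0.5)
  expect_equal(nrow(call_peaks(prof)), 0)
})

test_that("noiseless puncta are recovered at their planted offsets", {
  r <- render_clean_sideview(c(-100, 100))
  res <- sideview_profile(r$image)
  expect_equal(nrow(res$peaks), 2)
  expect_true(all(abs(sort(res$peaks$x_nm) - c(-100, 100)) <= 20))
  expect_true(all(res$peaks$amplitude > 0.5))
})

test_that("exported CSVs round-trip the profile and peak tables", {
  r <- render_clean_sideview(60)
  res <- sideview_profile(r$image)
  out <- withr::local_tempdir()
  pk <- dplyr::mutate(res$peaks, roi_id = "roi001", .before = 1)
  export_sideview(list(roi001 = res$profile), pk, out)
  files <- list.files(out)
  expect_setequal(files, c("roi001_profile.csv", "peaks.csv"))
  back <- readr::read_csv(file.path(out, "roi001_profile.csv"),
                          show_col_types = FALSE)
  expect_equal(signif(back$CH3_norm, 6),
               signif(res$profile$CH3_norm, 6))
  expect_equal(back$x_nm, res$profile$x_nm)
})
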