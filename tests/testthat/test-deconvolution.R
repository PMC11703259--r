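test_that("min-max normalization maps channels onto [0, 1]", {
  m <- matrix(c(10, 20, 30, 10), 2)
  expect_equal(sort(unique(as.vector(normalize_minmax(m)))), c(0, 0.5, 1))
  expect_equal(normalize_minmax(matrix(7, 3, 3)), matrix(0, 3, 3))
  img <- raster_image(list(matrix(runif(25), 5), matrix(5, 5, 5)))
  out <- normalize_minmax(img)
  expect_equal(range(out$channels[[1]]), c(0, 1))
  expect_true(all(out$channels[[2]] == 0))
})

test_that("the Gaussian pre-filter preserves flux and spreads variance", {
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  out <- gaussian_prefilter(imp, 1.2)
  expect_equal(sum(out), 1, tolerance = 1e-10)
  cst <- gaussian_prefilter(matrix(3.5, 20, 20), 1.2)
  expect_equal(cst, matrix(3.5, 20, 20), tolerance = 1e-10)
  # variance of a blurred point source grows by radius^2 per axis
  spot <- make_spot(45, 23, 23, 2)
  blur <- gaussian_prefilter(spot, 1.5)
  moment_var <- function(m) {
    w <- m / sum(m)
    r <- row(m); mu <- sum(r * w)
    sum((r - mu)^2 * w)
  }
  expect_equal(moment_var(blur) - moment_var(spot), 1.5^2, tolerance = 0.01)
})

test_that("PSF estimation averages background-free unit-sum patches", {
  spot <- make_spot(45, 23, 23, 2, amp = 100)
  est <- estimate_psf(spot, cbind(23, 23), patch_radius_px = 8)
  expect_equal(sum(est$kernel), 1, tolerance = 1e-12)
  expect_true(all(est$kernel >= 0))
  expect_equal(est$provenance, "measured")
  # kernel proportional to the single background-subtracted spot
  patch <- spot[15:31, 15:31]
  ring <- c(patch[1, ], patch[17, ], patch[, 1], patch[, 17])
  patch <- pmax(patch - median(ring), 0)
  expect_equal(est$kernel, patch / sum(patch), tolerance = 1e-12)
  # several identical spots give the same kernel as one
  img <- make_spot(91, 25, 25, 2, 100) + make_spot(91, 65, 60, 2, 100)
  est2 <- estimate_psf(img, rbind(c(25, 25), c(65, 60)), 8)
  expect_equal(est2$kernel, est$kernel, tolerance = 1e-6)
  # unequal amplitudes, equal shape: same normalized kernel
  img3 <- make_spot(91, 25, 25, 2, 50) + make_spot(91, 65, 60, 2, 200)
  est3 <- estimate_psf(img3, rbind(c(25, 25), c(65, 60)), 8)
  expect_equal(est3$kernel, est$kernel, tolerance = 1e-4)
  # border spots are skipped with a warning; none left is an error
  expect_warning(estimate_psf(spot, rbind(c(23, 23), c(3, 3)), 8), "skipped")
  expect_error(suppressWarnings(estimate_psf(spot, cbind(2, 2), 8)),
               "no valid spots")
})

test_that("blind deconvolution has the delta fixed point and conserves flux", {
  spot <- make_spot(45, 23, 21, 2, 80)
  blur <- gaussian_prefilter(spot, 2)
  delta <- matrix(0, 11, 11); delta[6, 6] <- 1
  res <- blind_deconvolve(blur, delta, iterations = 6)
  expect_equal(res$image, blur, tolerance = 1e-10)
  expect_equal(res$psf$kernel, delta, tolerance = 1e-12)
  expect_equal(res$psf$provenance, "refined")
  # flux conservation on an interior fixture
  init <- synquant:::gaussian_kernel(2.4, 5)
  res2 <- blind_deconvolve(blur, init, iterations = 10)
  expect_lt(abs(sum(res2$image) - sum(blur)) / sum(blur), 1e-6)
  expect_true(all(res2$image >= 0))
  expect_equal(sum(res2$psf$kernel), 1, tolerance = 1e-12)
  expect_true(all(res2$psf$kernel >= 0))
  expect_error(blind_deconvolve(blur, matrix(0, 5, 5)), "zero sum")
})

test_that("restored peak intensity is non-decreasing over iterations", {
  spot <- make_spot(45, 23, 23, 1.5, 100)
  blur <- gaussian_prefilter(spot, 2)
  init <- synquant:::gaussian_kernel(2, 5)
  peaks <- vapply(1:6, function(it) {
    max(blind_deconvolve(blur, init, iterations = it)$image)
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-9))
})

test_that("two-step deconvolution restores and never shifts point sources", {
  spot <- make_spot(45, 20, 26, 1.2, 100)
  blur <- gaussian_prefilter(spot, 2.5)
  delta <- matrix(0, 9, 9); delta[5, 5] <- 1
  expect_equal(two_step_deconvolve(blur, delta), blur, tolerance = 1e-9)
  out <- two_step_deconvolve(blur, synquant:::gaussian_kernel(2.2, 5))
  pk <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(20, 26))), 1)
  expect_gt(max(out), max(blur))  # restoration sharpens the source
  # deterministic: identical inputs, identical outputs
  expect_identical(out, two_step_deconvolve(blur, synquant:::gaussian_kernel(2.2, 5)))
})

test_that("two-step deconvolution keeps synthetic punctum maxima in place", {
  r <- render_clean_sideview(c(-100, 100))
  img <- gaussian_prefilter(normalize_minmax(r$image), 1.2)
  psf0 <- synquant:::gaussian_kernel(60 / 20, 5)
  dec <- two_step_deconvolve(img, psf0)
  mx <- find_local_maxima(get_channel(dec, "Dyn1xA"), min_prominence = 0.3)
  expect_equal(nrow(mx), 2)
  expect_true(all(abs(sort(mx$col) - c(18, 28)) <= 1))
  expect_true(all(abs(mx$row - 23) <= 1))
})
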