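# The synthetic generators are first-class, ground-truthed simulators;
# every downstream module is tested against their planted truth.

test_that("side-view rendering places puncta at the planted offsets", {
  # zero offset: CH3 maximum lies exactly on the midline between the bars
  r0 <- render_clean_sideview(0)
  ch3 <- get_channel(r0$image, "Dyn1xA")
  pk <- which(ch3 == max(ch3), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(23, 23))
  # +-100 nm: maxima 5 px either side of the midline (20 nm per pixel)
  r <- render_clean_sideview(c(-100, 100))
  mx <- find_local_maxima(get_channel(r$image, "Dyn1xA"),
                          min_prominence = 0.3)
  expect_setequal(mx$col, c(18, 28))
  expect_true(all(mx$row == 23))
})

test_that("side-view rendering validates canvas size", {
  tr <- sideview_truth(bar_length_nm = 2000, photon_scale = Inf)
  expect_error(render_sideview(tr), "too small")
})

test_that("top-view half-max geometry matches the closed form", {
  # analytic half-max boundary of exp(-r^2 / 2 sigma^2) is sigma sqrt(2 ln 2)
  tr <- topview_truth(az_radius_nm = 150, punctum_distances_nm = 0,
                      photon_scale = Inf)
  r <- render_topview(tr)
  ch1 <- get_channel(r$image, "Bassoon")
  b <- half_max_boundary(ch1, c(23, 23))
  rad <- sqrt((b$vertices[, 1] - 23)^2 + (b$vertices[, 2] - 23)^2)
  expect_lt(mean(abs(rad - 150 / 20)), 0.25)
  # a punctum at distance 0 sits on that circle
  pos <- r$truth$punctum_positions_px
  expect_equal(unname(sqrt((pos[1, 1] - 23)^2 + (pos[1, 2] - 23)^2)),
               150 / 20, tolerance = 1e-10)
})

test_that("top-view rejects puncta planted beyond the blob center", {
  expect_error(render_topview(topview_truth(az_radius_nm = 100,
                                            punctum_distances_nm = -150)),
               "farther inside")
})

test_that("renderings are bit-identical for a fixed seed", {
  a <- render_sideview(sideview_truth(seed = 7))
  b <- render_sideview(sideview_truth(seed = 7))
  expect_identical(a$image$channels, b$image$channels)
  c1 <- render_topview(topview_truth(seed = 7))
  c2 <- render_topview(topview_truth(seed = 7))
  expect_identical(c1$image$channels, c2$image$channels)
  t1 <- make_calcium_trace(calcium_truth(seed = 7))
  t2 <- make_calcium_trace(calcium_truth(seed = 7))
  expect_identical(t1$F, t2$F)
  e1 <- make_em_fixture(em_fixture_truth(n_profiles = 3, seed = 7))
  e2 <- make_em_fixture(em_fixture_truth(n_profiles = 3, seed = 7))
  expect_identical(e1$text, e2$text)
  # different seeds give different noise
  d <- render_sideview(sideview_truth(seed = 8))
  expect_false(identical(a$image$channels, d$image$channels))
})

test_that("doubling photon_scale doubles expected total intensity", {
  t1 <- sideview_truth(photon_scale = 150, seed = 11)
  t2 <- sideview_truth(photon_scale = 300, seed = 12)
  s1 <- sum(get_channel(render_sideview(t1)$image, "Dyn1xA"))
  s2 <- sum(get_channel(render_sideview(t2)$image, "Dyn1xA"))
  # Poisson: var = expected total; allow 3 sd on the comparison
  sd_tot <- sqrt(2 * s1 + s2)
  expect_lt(abs(s2 - 2 * s1), 3 * sd_tot)
})

test_that("EM fixture text round-trips through the parser losslessly", {
  fx <- make_em_fixture(em_fixture_truth(n_profiles = 5, seed = 2))
  rec <- parse_annotations(fx$text)
  expect_true(all(rec$profile_id %in% fx$truth$counts$profile_id))
  met <- em_profile_metrics(rec)
  m <- dplyr::inner_join(met$counts, fx$truth$counts, by = "profile_id",
                         suffix = c("", ".t"))
  expect_equal(m$n_pits, m$n_pits.t)
  expect_equal(m$n_lev, m$n_lev.t)
  expect_equal(m$n_endosomes, m$n_endosomes.t)
  expect_equal(m$n_ccp, m$n_ccp.t)
  expect_equal(m$n_sv, m$n_sv.t)
})

test_that("a pit touching the active zone has distance 0", {
  rec <- parse_annotations(make_simple_pit_file(gap_nm = 0))
  met <- em_profile_metrics(rec)
  expect_equal(met$pits$distance_to_az_nm, 0, tolerance = 1e-9)
})

test_that("circular endosome polygon area matches the shoelace oracle", {
  # plain inscribed 64-gon of a 50 nm circle: within 2% of pi 50^2
  t <- 2 * pi * (0:63) / 64
  poly <- cbind(50 * cos(t), 50 * sin(t))
  # independent shoelace oracle, written out directly
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:64, 1)
  oracle <- abs(sum(x * y[j] - x[j] * y)) / 2
  expect_equal(endosome_area(poly, 1), oracle, tolerance = 1e-12)
  expect_equal(oracle, pi * 50^2, tolerance = 0.02)
})

test_that("calcium traces follow the stated generative model", {
  # zero transients, zero noise: pure exponential baseline
  tr <- calcium_truth(stim_times_ms = 70, transient_amplitudes = 0,
                      noise_sd = 0)
  tc <- make_calcium_trace(tr)
  expect_equal(tc$F, 95 + 5 * exp(-tc$t_ms / 2000), tolerance = 1e-12)
  # one transient at 70 ms: trace minimum occurs at or after 70 ms
  tc2 <- make_calcium_trace(calcium_truth(noise_sd = 0))
  expect_gte(tc2$t_ms[which.min(tc2$F)], 70)
})
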