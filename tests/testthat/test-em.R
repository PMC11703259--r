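# EM annotation parsing and morphometry.

test_that("the annotation parser validates the dialect", {
  txt <- make_simple_pit_file(gap_nm = 10)
  rec <- parse_annotations(txt)
  expect_equal(nrow(rec), 3)
  expect_setequal(rec$feature_class,
                  c("plasma_membrane", "active_zone", "uncoated_pit"))
  expect_equal(rec$scale_nm_per_px[1], 1)
  # malformed inputs name the offending line
  bad_class <- c(txt[1:2], "p1\tmystery_organelle\tpolyline\t0,0;1,1")
  expect_error(parse_annotations(bad_class), "unknown feature class")
  bad_num <- c(txt[1:2], "p1\tactive_zone\tpolyline\t0,zero;1,1")
  expect_error(parse_annotations(bad_num), "non-numeric")
  bad_poly <- c(txt[1:2], "p1\tendosome\tpolygon\t0,0;1,1")
  expect_error(parse_annotations(bad_poly), "at least 3 vertices")
  expect_error(parse_annotations(txt[-2]), "scale_nm_per_px")
})

test_that("vesicle classification applies the size and shape rules", {
  expect_equal(classify_vesicle(circle_polygon(0, 0, 20), 1),
               "synaptic_vesicle")
  # strict "over 60 nm" for large vesicles
  expect_equal(classify_vesicle(circle_polygon(0, 0, 61 / 2), 1),
               "large_vesicle")
  expect_equal(classify_vesicle(circle_polygon(0, 0, 30), 1),
               "synaptic_vesicle")  # 60 nm exactly: not "over 60"
  # inclusive "100 nm or more" for endosomes
  expect_equal(classify_vesicle(circle_polygon(0, 0, 50), 1), "endosome")
  expect_equal(classify_vesicle(circle_polygon(0, 0, 49.9), 1),
               "large_vesicle")
  # oblong rule: low circularity and over 60 nm equivalent diameter
  expect_equal(classify_vesicle(ellipse_polygon(0, 0, 60, 20), 1),
               "endosome")
  # scale consistency: rescaling coordinates and scale together
  p <- circle_polygon(0, 0, 35)
  expect_equal(classify_vesicle(p, 1), classify_vesicle(p / 4, 4))
})

test_that("per-profile counts match planted truth exactly", {
  fx <- make_em_fixture(em_fixture_truth(n_profiles = 15, seed = 5))
  met <- em_profile_metrics(parse_annotations(fx$text))
  m <- dplyr::inner_join(met$counts, fx$truth$counts, by = "profile_id",
                         suffix = c("", ".t"))
  expect_equal(nrow(m), 15)
  for (col in c("n_pits", "n_lev", "n_endosomes", "n_ccp", "n_sv")) {
    expect_equal(m[[col]], m[[paste0(col, ".t")]])
  }
  # empty profile: all zeros
  empty <- parse_annotations(c("# em-annotation v1", "# scale_nm_per_px 2",
                               "p9\tplasma_membrane\tpolyline\t0,0;100,0"))
  cz <- count_profile(empty)
  expect_true(all(cz[, -1] == 0))
})

test_that("pit distance is the arc-length interval gap along the membrane", {
  mem <- cbind(seq(0, 1000, 50), 0)
  az <- cbind(seq(0, 290, 29), 0)
  pit <- pit_arc(300, 0, 40, 20)$xy
  expect_equal(pit_distance_to_az(pit, az, mem), 10, tolerance = 1e-9)
  # contact: distance 0
  pit0 <- pit_arc(290, 0, 40, 20)$xy
  expect_equal(pit_distance_to_az(pit0, az, mem), 0, tolerance = 1e-9)
  # overlap also gives 0
  pit_in <- pit_arc(270, 0, 40, 20)$xy
  expect_equal(pit_distance_to_az(pit_in, az, mem), 0)
  # symmetric in which AZ endpoint is nearer: pit left of the AZ
  az2 <- cbind(seq(500, 790, 29), 0)
  pit_l <- pit_arc(450, 0, 40, 20)$xy  # base 450..490, gap 10 to AZ start
  expect_equal(pit_distance_to_az(pit_l, az2, mem), 10, tolerance = 1e-9)
  # euclidean mode for comparison: straight-line base-to-endpoint distance
  expect_equal(pit_distance_to_az(pit, az, mem, mode = "euclidean"), 10,
               tolerance = 1e-9)
  # projection tolerance: pit floating off the membrane errors
  pit_off <- pit
  pit_off[, 2] <- pit_off[, 2] + 50
  expect_error(pit_distance_to_az(pit_off, az, mem), "off the membrane")
})

test_that("pit geometry measures neck and chord-parallel diameter", {
  # semicircular pit of radius 20: neck 40, diameter 40
  semi <- pit_arc(0, 0, 40, 20, n = 101)
  g <- pit_geometry(semi$xy)
  expect_equal(unname(g["neck_width"]), 40, tolerance = 1e-9)
  expect_equal(unname(g["diameter"]), 40, tolerance = 1e-3)
  # shallow arc: diameter equals the chord-parallel maximum width,
  # cross-checked against brute force over all vertex pairs
  shallow <- pit_arc(0, 0, 60, 15, n = 51)$xy
  g2 <- pit_geometry(shallow)
  u <- (shallow[nrow(shallow), ] - shallow[1, ])
  u <- u / sqrt(sum(u^2))
  proj <- shallow %*% u
  expect_equal(unname(g2["diameter"]), max(proj) - min(proj),
               tolerance = 1e-12)
  # bulbous pit: diameter (full width) exceeds the neck
  bulb <- pit_arc(0, 0, 30, 40, n = 101)
  g3 <- pit_geometry(bulb$xy)
  expect_gt(g3[["diameter"]], g3[["neck_width"]])
  expect_equal(g3[["diameter"]], bulb$diameter, tolerance = 0.05)
  # rigid rotation leaves the neck width unchanged
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g4 <- pit_geometry(semi$xy %*% t(Rm))
  expect_equal(g4[["neck_width"]], g[["neck_width"]], tolerance = 1e-9)
})

test_that("endosome areas follow the shoelace formula", {
  rect <- cbind(c(0, 100, 100, 0), c(0, 0, 60, 60))
  expect_equal(endosome_area(rect, 1), 6000)
  expect_equal(endosome_area(rect[4:1, ], 1), 6000)  # orientation-free
  expect_equal(endosome_area(rect, 2), 24000)        # scale^2
  bow <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(endosome_area(bow, 1), "self-intersecting")
})

test_that("median confidence intervals use binomial order statistics", {
  s <- median_ci(c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(s$median, 4.5)
  expect_true(s$ci_low %in% 1:8 && s$ci_high %in% 1:8)
  # oracle: endpoints are the order statistics at the exact binomial ranks
  set.seed(9)
  for (n in c(6, 15, 40)) {
    x <- sort(rnorm(n))
    k <- qbinom(0.025, n, 0.5)
    while (k >= 1 && pbinom(k - 1, n, 0.5) > 0.025) k <- k - 1
    res <- median_ci(x)
    expect_equal(res$ci_low, x[k])
    expect_equal(res$ci_high, x[n + 1 - k])
    # permutation invariance and boundedness
    res2 <- median_ci(sample(x))
    expect_equal(res2$median, res$median)
    expect_gte(res$median, min(x)); expect_lte(res$median, max(x))
  }
  # all-equal values: zero-width interval
  eq <- median_ci(rep(2.5, 10))
  expect_equal(eq$ci_low, eq$ci_high)
  # small samples report the range with a flag
  small <- median_ci(c(1, 2, 3))
  expect_equal(small$method, "range")
  expect_equal(c(small$ci_low, small$ci_high), c(1, 3))
})
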