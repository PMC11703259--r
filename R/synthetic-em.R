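# Synthetic electron-micrograph annotation fixtures. The generator plants
# per-profile ground truth (structure counts, pit base-interval gaps to the
# active zone measured along the membrane, pit chord/width geometry, and
# endosome areas) and emits annotation text in the package's documented
# dialect, so the parser and every morphometric operation can be tested
# against exact values.
#
# Annotation dialect (version 1, UTF-8, tab-separated):
#   # em-annotation v1
#   # scale_nm_per_px <s>
#   <profile_id> TAB <feature_class> TAB <polyline|polygon> TAB x1,y1;x2,y2;...
# Coordinates are in pixels; polygons list each vertex once (no repeated
# closing vertex). Feature classes: synaptic_vesicle, large_vesicle,
# endosome, uncoated_pit, clathrin_coated_pit, active_zone,
# plasma_membrane, psd.

em_feature_classes <- c("synaptic_vesicle", "large_vesicle", "endosome",
                        "uncoated_pit", "clathrin_coated_pit",
                        "active_zone", "plasma_membrane", "psd")

# Regular n-gon on a circle of radius r, scaled so its shoelace area equals
# pi r^2 exactly ("area-true" polygon); same factor applies to ellipses.
area_true_factor <- function(n) 1 / sqrt((n / (2 * pi)) * sin(2 * pi / n))

#' Area-true circle polygon
#'
#' Regular `n`-gon whose shoelace area equals `pi r^2` exactly (the vertex
#' radius is scaled up to cancel the inscribed-polygon area deficit), so
#' size-threshold tests on equivalent-circle diameter are exact.
#'
#' @param cx,cy Center.
#' @param r Radius.
#' @param n Number of vertices (default 64).
#' @return Two-column x,y matrix (open ring).
#' @export
circle_polygon <- function(cx, cy, r, n = 64) {
  t <- 2 * pi * (0:(n - 1)) / n
  f <- area_true_factor(n)
  cbind(x = cx + r * f * cos(t), y = cy + r * f * sin(t))
}

#' Area-true ellipse polygon
#'
#' @param cx,cy Center.
#' @param a,b Semi-axes.
#' @param n Number of vertices (default 64).
#' @return Two-column x,y matrix (open ring) with shoelace area `pi a b`.
#' @export
ellipse_polygon <- function(cx, cy, a, b, n = 64) {
  t <- 2 * pi * (0:(n - 1)) / n
  f <- area_true_factor(n)
  cbind(x = cx + a * f * cos(t), y = cy + b * f * sin(t))
}

#' Circular-arc pit polyline
#'
#' Pit with base chord `w` and sagitta (depth) `h`, base on a horizontal
#' membrane at height `y0` starting at `x0`, invaginating toward +y.
#' Depths beyond the arc radius produce bulbous (omega-like) pits whose
#' chord-parallel maximum width exceeds the neck.
#'
#' @param x0,y0 Left base point.
#' @param w Base chord (neck) width.
#' @param h Pit depth (sagitta).
#' @param n Number of vertices (default 33).
#' @return List: `xy` polyline matrix, `neck`, `diameter` (true
#'   chord-parallel maximum width).
#' @export
pit_arc <- function(x0, y0, w, h, n = 33) {
  stopifnot(w > 0, h > 0)
  R <- (h^2 + (w / 2)^2) / (2 * h)
  cx <- x0 + w / 2
  cy <- y0 + h - R
  t1 <- asin(pmin(pmax((R - h) / R, -1), 1))
  t <- seq(t1, pi - t1, length.out = n)
  xy <- cbind(x = cx + R * cos(t), y = cy + R * sin(t))
  # exact base points at the membrane
  xy[1, ] <- c(x0 + w, y0)
  xy[n, ] <- c(x0, y0)
  diameter <- if (h > R) 2 * R else w
  list(xy = xy, neck = w, diameter = diameter)
}

#' Ground truth for a synthetic electron-micrograph annotation cohort
#'
#' Draws per-profile feature counts and geometry parameters from seeded
#' distributions chosen to resemble cortical synaptic profiles: uncoated
#' pits near the active zone with nearest-edge gaps of a few tens of nm,
#' synaptic vesicles of ~40 nm diameter, large vesicles of 60-100 nm,
#' endosomes of >= 100 nm equivalent diameter or oblong shape, and
#' occasional clathrin-coated pits. All planted values are recorded so
#' that parsing and morphometry can be checked exactly.
#'
#' @param n_profiles Number of synaptic profiles.
#' @param mean_pits,mean_lev,mean_endosomes,mean_ccp Poisson means of the
#'   per-profile counts of uncoated pits, large vesicles, endosomes and
#'   clathrin-coated pits.
#' @param mean_sv Poisson mean of the synaptic-vesicle count.
#' @param mean_pit_gap_nm Mean of the exponential distribution of pit
#'   nearest-edge gaps to the active zone (default 15 nm).
#' @param az_length_nm Active-zone length along the membrane (default 300).
#' @param scale_nm_per_px Annotation scale (default 2 nm per pixel).
#' @param seed Integer master seed.
#' @return An object of class `em_fixture_truth`: a list with tibbles
#'   `counts`, `pits`, `endosomes`, plus `scale_nm_per_px`, `az_length_nm`
#'   and `seed`.
#' @export
em_fixture_truth <- function(n_profiles = 10, mean_pits = 0.8,
                             mean_lev = 0.6, mean_endosomes = 0.5,
                             mean_ccp = 0.15, mean_sv = 8,
                             mean_pit_gap_nm = 15, az_length_nm = 300,
                             scale_nm_per_px = 2, seed = 1) {
  stopifnot(n_profiles >= 1, scale_nm_per_px > 0)
  with_rng_seed(split_seed(seed, "em_fixture"), {
    counts <- tibble::tibble(
      profile_id = sprintf("p%03d", seq_len(n_profiles)),
      n_pits = stats::rpois(n_profiles, mean_pits),
      n_lev = stats::rpois(n_profiles, mean_lev),
      n_endosomes = stats::rpois(n_profiles, mean_endosomes),
      n_ccp = stats::rpois(n_profiles, mean_ccp),
      n_sv = stats::rpois(n_profiles, mean_sv)
    )
    pits <- lapply(seq_len(n_profiles), function(i) {
      k <- counts$n_pits[i] + counts$n_ccp[i]
      if (k == 0) return(NULL)
      coated <- c(rep(FALSE, counts$n_pits[i]), rep(TRUE, counts$n_ccp[i]))
      w <- stats::runif(k, 40, 80)               # neck width, nm
      h <- w * stats::runif(k, 0.35, 0.9)        # depth: shallow to bulbous
      g <- stats::rexp(k, 1 / mean_pit_gap_nm)   # drawn nearest-edge gap, nm
      side <- rep_len(c(1L, -1L), k)
      tibble::tibble(profile_id = counts$profile_id[i],
                     pit_index = seq_len(k), coated = coated,
                     gap_nm = g, neck_nm = w, depth_nm = h, side = side)
    })
    pits <- dplyr::bind_rows(pits)
    endos <- lapply(seq_len(n_profiles), function(i) {
      k <- counts$n_endosomes[i]
      if (k == 0) return(NULL)
      oblong <- stats::runif(k) < 0.3
      # oblong endosomes must clear the > 60 nm equivalent-diameter gate:
      # D_eq = 2 sqrt(a b) = 2 a / sqrt(3) > 60 requires a > 52 nm
      a <- ifelse(oblong, stats::runif(k, 56, 75), stats::runif(k, 52, 70))
      b <- ifelse(oblong, a / 3, a)
      tibble::tibble(profile_id = counts$profile_id[i],
                     endosome_index = seq_len(k), oblong = oblong,
                     semi_a_nm = a, semi_b_nm = b,
                     area_nm2 = pi * a * b)
    })
    endos <- dplyr::bind_rows(endos)
    lev <- lapply(seq_len(n_profiles), function(i) {
      k <- counts$n_lev[i]
      if (k == 0) return(NULL)
      tibble::tibble(profile_id = counts$profile_id[i],
                     lev_index = seq_len(k),
                     diameter_nm = stats::runif(k, 65, 95))
    })
    lev <- dplyr::bind_rows(lev)
    sv <- lapply(seq_len(n_profiles), function(i) {
      k <- counts$n_sv[i]
      if (k == 0) return(NULL)
      tibble::tibble(profile_id = counts$profile_id[i],
                     sv_index = seq_len(k),
                     diameter_nm = stats::runif(k, 35, 48))
    })
    sv <- dplyr::bind_rows(sv)
    structure(list(counts = counts, pits = pits, endosomes = endos,
                   lev = lev, sv = sv,
                   az_length_nm = az_length_nm,
                   membrane_length_nm = 3000,
                   scale_nm_per_px = scale_nm_per_px, seed = seed),
              class = "em_fixture_truth")
  })
}

#' Emit annotation text for a synthetic EM cohort
#'
#' Lays the planted features out on a straight plasma membrane per profile
#' (so membrane arc length equals Euclidean length and planted gaps are
#' exact), draws pits as circular arcs with the planted chord and depth,
#' vesicles and endosomes as area-true polygons, and writes the dialect
#' described in [parse_annotations()]. Pits on the same flank are spaced
#' sequentially; the realized nearest-edge gap of every pit is returned in
#' the updated truth (`pits$distance_nm`), together with its true diameter
#' (`pits$diameter_nm`).
#'
#' @param truth An [em_fixture_truth()].
#' @return A list with `text` (character vector of lines) and `truth`
#'   (updated with realized pit distances and diameters).
#' @export
make_em_fixture <- function(truth) {
  stopifnot(inherits(truth, "em_fixture_truth"))
  s <- truth$scale_nm_per_px
  mem_len <- truth$membrane_length_nm
  y0 <- 500  # membrane height, nm (converted to px on output)
  az_lo <- (mem_len - truth$az_length_nm) / 2
  az_hi <- (mem_len + truth$az_length_nm) / 2
  lines <- c("# em-annotation v1",
             paste("# scale_nm_per_px", format(s, digits = 15)))
  fmt_xy <- function(xy) {
    paste(sprintf("%.6f,%.6f", xy[, 1] / s, xy[, 2] / s), collapse = ";")
  }
  emit <- function(profile, class, type, xy) {
    lines[[length(lines) + 1]] <<-
      paste(profile, class, type, fmt_xy(xy), sep = "\t")
  }
  pits_out <- NULL
  for (i in seq_len(nrow(truth$counts))) {
    pid <- truth$counts$profile_id[i]
    mem <- cbind(x = seq(0, mem_len, length.out = 31), y = y0)
    emit(pid, "plasma_membrane", "polyline", mem)
    emit(pid, "active_zone", "polyline",
         cbind(x = seq(az_lo, az_hi, length.out = 7), y = y0))
    emit(pid, "psd", "polyline",
         cbind(x = seq(az_lo, az_hi, length.out = 5), y = y0 + 30))
    p <- truth$pits
    p <- if (is.null(p) || nrow(p) == 0) NULL else p[p$profile_id == pid, ]
    if (!is.null(p) && nrow(p) > 0) {
      cursor <- c(`1` = az_hi, `-1` = az_lo)  # running edge per flank
      for (j in seq_len(nrow(p))) {
        w <- p$neck_nm[j]; h <- p$depth_nm[j]; g <- p$gap_nm[j]
        side <- p$side[j]
        if (side > 0) {
          x0 <- cursor["1"] + g
          if (x0 + w > mem_len - 20) { x0 <- cursor["1"] + 5; g <- 5 }
          cursor["1"] <- x0 + w
          dist <- x0 - az_hi
        } else {
          x1 <- cursor["-1"] - g
          if (x1 - w < 20) { x1 <- cursor["-1"] - 5; g <- 5 }
          x0 <- x1 - w
          cursor["-1"] <- x0
          dist <- az_lo - x1
        }
        arc <- pit_arc(x0, y0, w, h)
        cls <- if (p$coated[j]) "clathrin_coated_pit" else "uncoated_pit"
        emit(pid, cls, "polyline", arc$xy)
        pits_out <- dplyr::bind_rows(pits_out, tibble::tibble(
          profile_id = pid, pit_index = p$pit_index[j],
          coated = p$coated[j], distance_nm = dist,
          neck_nm = arc$neck, diameter_nm = arc$diameter))
      }
    }
    place_row <- function(tbl, r_fun, class) {
      if (is.null(tbl) || nrow(tbl) == 0) return(invisible())
      tbl <- tbl[tbl$profile_id == pid, ]
      if (nrow(tbl) == 0) return(invisible())
      for (j in seq_len(nrow(tbl))) {
        xy <- r_fun(tbl[j, ], 150 + 160 * j, y0 - 200 -
                      150 * match(class, c("synaptic_vesicle",
                                           "large_vesicle", "endosome")))
        emit(pid, class, "polygon", xy)
      }
    }
    place_row(truth$sv, function(r, cx, cy)
      circle_polygon(cx, cy, r$diameter_nm / 2), "synaptic_vesicle")
    place_row(truth$lev, function(r, cx, cy)
      circle_polygon(cx, cy, r$diameter_nm / 2), "large_vesicle")
    place_row(truth$endosomes, function(r, cx, cy)
      ellipse_polygon(cx, cy, r$semi_a_nm, r$semi_b_nm), "endosome")
  }
  truth$pits <- pits_out
  list(text = unlist(lines), truth = truth)
}

#' Write an EM fixture to disk
#'
#' @param fixture Result of [make_em_fixture()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_em_fixture <- function(fixture, path) {
  writeLines(fixture$text, path, useBytes = TRUE)
  invisible(path)
}
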