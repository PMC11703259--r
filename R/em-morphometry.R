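# Electron-micrograph morphometry. Annotations are consumed as plain text
# (one feature per line: profile id, class token, geometry type, vertex
# list; a scale header per file) and analyzed per synaptic profile:
# structure counts, pit nearest-edge distances to the active zone measured
# along the plasma membrane, pit neck/diameter geometry, endosome areas,
# and pooled medians with distribution-free 95% confidence intervals.
#
# Classification rules for vesicular polygons (equivalent-circle diameter
# D = 2 sqrt(area / pi), circularity c = 4 pi area / perimeter^2):
#   D >= 100 nm                      -> endosome (inclusive bound)
#   D > 60 nm and c < c_round (0.8)  -> endosome (oblong rule)
#   60 nm < D < 100 nm               -> large vesicle (strict "over 60")
#   otherwise                        -> synaptic vesicle
# Pit coat state (uncoated vs clathrin-coated) is always taken from the
# annotation label, never inferred from geometry.

#' Parse an EM annotation file
#'
#' Dialect (version 1): comment/header lines start with `#`; the header
#' `# scale_nm_per_px <s>` sets the scale. Every other line is
#' `profile_id TAB class TAB polyline|polygon TAB x1,y1;x2,y2;...`
#' with coordinates in pixels. Polygons list each vertex once and need
#' at least 3 vertices; polylines at least 2. Malformed lines raise an
#' error naming the line number.
#'
#' @param text Path to a file, or a character vector of lines.
#' @return A tibble with columns `profile_id`, `feature_class`,
#'   `geom_type`, `vertices` (list of two-column x,y matrices, px) and
#'   `scale_nm_per_px`.
#' @export
parse_annotations <- function(text) {
  lines <- if (length(text) == 1 && !grepl("[\t\n]", text) &&
               file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  scale <- NA_real_
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("scale_nm_per_px\\s+([0-9.eE+-]+)", ln))[[1]]
      if (length(m) == 2) scale <- as.numeric(m[2])
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4) {
      stop("line ", i, ": expected 4 tab-separated fields, got ",
           length(parts))
    }
    cls <- parts[2]
    if (!cls %in% em_feature_classes) {
      stop("line ", i, ": unknown feature class '", cls, "'")
    }
    gt <- parts[3]
    if (!gt %in% c("polyline", "polygon")) {
      stop("line ", i, ": geometry type must be polyline or polygon")
    }
    pairs <- strsplit(strsplit(parts[4], ";", fixed = TRUE)[[1]], ",",
                      fixed = TRUE)
    bad <- vapply(pairs, length, integer(1)) != 2
    if (any(bad)) stop("line ", i, ": malformed coordinate pair")
    xy <- matrix(suppressWarnings(as.numeric(unlist(pairs))),
                 ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("x", "y")))
    if (anyNA(xy)) stop("line ", i, ": non-numeric coordinate")
    if (gt == "polygon" && nrow(xy) < 3) {
      stop("line ", i, ": polygon needs at least 3 vertices")
    }
    if (gt == "polyline" && nrow(xy) < 2) {
      stop("line ", i, ": polyline needs at least 2 vertices")
    }
    recs[[length(recs) + 1]] <- tibble::tibble(
      profile_id = parts[1], feature_class = cls, geom_type = gt,
      vertices = list(xy))
  }
  if (is.na(scale)) stop("missing '# scale_nm_per_px' header")
  out <- dplyr::bind_rows(recs)
  out$scale_nm_per_px <- scale
  out
}

polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4],
                             seg[j, 1:2], seg[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Classify a vesicular polygon
#'
#' @param polygon Two-column x,y matrix of vertices (px), open ring.
#' @param scale Scale in nm per pixel.
#' @param c_round Circularity threshold separating round from oblong
#'   organelles (default 0.8).
#' @param size_tol_nm Numerical tolerance applied at the 60 nm (exclusive)
#'   and 100 nm (inclusive) bounds, so floating-point noise in a polygon
#'   whose exact diameter sits on a bound cannot flip the class
#'   (default 1e-9).
#' @return One of `"synaptic_vesicle"`, `"large_vesicle"`, `"endosome"`.
#' @export
classify_vesicle <- function(polygon, scale, c_round = 0.8,
                             size_tol_nm = 1e-9) {
  xy <- as.matrix(polygon)
  if (nrow(xy) < 3) stop("degenerate polygon")
  area <- abs(shoelace_area(xy[, 1], xy[, 2])) * scale^2
  if (area <= 0) stop("degenerate polygon (zero area)")
  per <- polygon_perimeter(xy[, 1], xy[, 2]) * scale
  D <- 2 * sqrt(area / pi)
  circ <- 4 * pi * area / per^2
  if (D >= 100 - size_tol_nm) return("endosome")
  if (D > 60 + size_tol_nm && circ < c_round) return("endosome")
  if (D > 60 + size_tol_nm) return("large_vesicle")
  "synaptic_vesicle"
}

#' Count endocytic structures in one synaptic profile
#'
#' Vesicular polygons are (re)classified from their geometry via
#' [classify_vesicle()]; pit coat state comes from the annotation label.
#'
#' @param records Tibble of parsed records (one profile, or several; counts
#'   are grouped by `profile_id`).
#' @return Tibble with `profile_id`, `n_pits`, `n_lev`, `n_endosomes`,
#'   `n_ccp`, `n_sv`.
#' @export
count_profile <- function(records) {
  vesicular <- c("synaptic_vesicle", "large_vesicle", "endosome")
  ids <- unique(records$profile_id)
  out <- lapply(ids, function(pid) {
    r <- records[records$profile_id == pid, ]
    cls <- character(nrow(r))
    for (i in seq_len(nrow(r))) {
      cls[i] <- if (r$feature_class[i] %in% vesicular) {
        classify_vesicle(r$vertices[[i]], r$scale_nm_per_px[i])
      } else {
        r$feature_class[i]
      }
    }
    tibble::tibble(profile_id = pid,
                   n_pits = sum(cls == "uncoated_pit"),
                   n_lev = sum(cls == "large_vesicle"),
                   n_endosomes = sum(cls == "endosome"),
                   n_ccp = sum(cls == "clathrin_coated_pit"),
                   n_sv = sum(cls == "synaptic_vesicle"))
  })
  dplyr::bind_rows(out)
}

# Arc-length parameter of the projection of point p onto a polyline.
# Returns list(s = arc length at the closest point, d = distance to it).
project_onto_polyline <- function(p, poly) {
  n <- nrow(poly)
  seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                             poly[-n, , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))
  best_d <- Inf; best_s <- 0
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) sum((p - a) * ab) / len2 else 0
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best_d) {
      best_d <- d
      best_s <- cum0[i] + t * seg_len[i]
    }
  }
  list(s = best_s, d = best_d)
}

#' Nearest-edge distance from a pit to the active zone along the membrane
#'
#' Projects the pit's two base points (its polyline endpoints) and the
#' active-zone endpoints onto the arc-length parameterization of the
#' plasma-membrane polyline; the distance is the minimum arc-length gap
#' between the pit base interval and the active-zone interval (0 if they
#' touch or overlap). With `mode = "euclidean"` the straight-line distance
#' between the nearest pit base point and active-zone endpoint is returned
#' instead, for comparison.
#'
#' @param pit_polyline,az_polyline Two-column x,y matrices (px).
#' @param membrane_polyline Two-column x,y matrix (px).
#' @param scale Scale in nm per pixel (default 1: px units).
#' @param mode `"arc"` (default) or `"euclidean"`.
#' @param tol_px Maximum allowed projection distance of pit/AZ endpoints
#'   from the membrane (default 2 px).
#' @return Distance in nm (or px when `scale = 1`).
#' @export
pit_distance_to_az <- function(pit_polyline, az_polyline, membrane_polyline,
                               scale = 1, mode = c("arc", "euclidean"),
                               tol_px = 2) {
  mode <- match.arg(mode)
  pit <- as.matrix(pit_polyline); az <- as.matrix(az_polyline)
  mem <- as.matrix(membrane_polyline)
  base <- pit[c(1, nrow(pit)), , drop = FALSE]
  az_ends <- az[c(1, nrow(az)), , drop = FALSE]
  if (mode == "euclidean") {
    d <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j) {
      sqrt(sum((base[i, ] - az_ends[j, ])^2))
    }))
    return(min(d) * scale)
  }
  proj <- function(pts, what) {
    res <- apply(pts, 1, function(p) {
      pr <- project_onto_polyline(p, mem)
      if (pr$d > tol_px) {
        stop(what, " endpoint lies ", format(pr$d, digits = 3),
             " px off the membrane (tolerance ", tol_px, ")")
      }
      pr$s
    })
    sort(res)
  }
  pi_s <- proj(base, "pit base")
  az_s <- proj(az_ends, "active zone")
  gap <- max(pi_s[1] - az_s[2], az_s[1] - pi_s[2], 0)
  gap * scale
}

#' Pit neck width and diameter
#'
#' The neck width is the straight-line distance between the pit's two base
#' points (its polyline endpoints); the diameter is the maximum extent of
#' the pit polyline measured parallel to the base chord.
#'
#' @param pit_polyline Two-column x,y matrix with at least 5 vertices.
#' @param scale Scale in nm per pixel (default 1).
#' @return Named numeric vector `c(diameter, neck_width)` in nm.
#' @export
pit_geometry <- function(pit_polyline, scale = 1) {
  pit <- as.matrix(pit_polyline)
  if (nrow(pit) < 5) stop("pit polyline needs at least 5 vertices")
  b1 <- pit[1, ]; b2 <- pit[nrow(pit), ]
  chord <- b2 - b1
  neck <- sqrt(sum(chord^2))
  if (neck <= 0) stop("unidentifiable base: coincident base points")
  u <- chord / neck
  proj <- pit[, 1] * u[1] + pit[, 2] * u[2]
  diameter <- max(proj) - min(proj)
  c(diameter = diameter * scale, neck_width = neck * scale)
}

#' Endosome area from its polygon
#'
#' Shoelace area times the squared scale. Self-intersecting polygons are
#' rejected.
#'
#' @param polygon Two-column x,y matrix (open ring).
#' @param scale Scale in nm per pixel.
#' @return Area in nm^2.
#' @export
endosome_area <- function(polygon, scale) {
  xy <- as.matrix(polygon)
  if (nrow(xy) < 3) stop("degenerate polygon")
  if (polygon_self_intersects(xy)) stop("self-intersecting polygon")
  abs(shoelace_area(xy[, 1], xy[, 2])) * scale^2
}

#' Median with a distribution-free 95% confidence interval
#'
#' The interval endpoints are order statistics chosen by the exact
#' binomial method: the largest `k` with `pbinom(k - 1, n, 1/2) <= 0.025`
#' gives the interval `(x_(k), x_(n + 1 - k))`, which covers the median
#' with probability at least 95%. For `n < 6` no such interval exists and
#' the data range is reported with `method = "range"`.
#'
#' @param values Numeric vector (n >= 1).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `n`, `median`, `ci_low`, `ci_high`, `method`.
#' @export
median_ci <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("no values to summarize")
  s <- sort(values)
  med <- stats::median(s)
  alpha <- (1 - conf) / 2
  k <- stats::qbinom(alpha, n, 0.5)
  while (k >= 1 && stats::pbinom(k - 1, n, 0.5) > alpha) k <- k - 1
  if (k < 1) {
    return(tibble::tibble(n = n, median = med, ci_low = s[1], ci_high = s[n],
                          method = "range"))
  }
  tibble::tibble(n = n, median = med, ci_low = s[k], ci_high = s[n + 1 - k],
                 method = "binomial")
}

#' Per-profile metrics for a parsed EM annotation set
#'
#' Convenience wrapper computing structure counts, pit metrics (distance
#' to the active zone, diameter, neck width) and endosome areas for every
#' profile in one pass.
#'
#' @param records Parsed records from [parse_annotations()].
#' @param mode Distance mode for [pit_distance_to_az()].
#' @return List of tibbles: `counts`, `pits`, `endosomes`.
#' @export
em_profile_metrics <- function(records, mode = "arc") {
  counts <- count_profile(records)
  s <- records$scale_nm_per_px[1]
  pits <- list(); endos <- list()
  for (pid in unique(records$profile_id)) {
    r <- records[records$profile_id == pid, ]
    mem <- r$vertices[r$feature_class == "plasma_membrane"]
    az <- r$vertices[r$feature_class == "active_zone"]
    pit_rows <- which(r$feature_class %in% c("uncoated_pit",
                                             "clathrin_coated_pit"))
    for (i in pit_rows) {
      g <- pit_geometry(r$vertices[[i]], scale = s)
      d <- if (length(mem) && length(az)) {
        pit_distance_to_az(r$vertices[[i]], az[[1]], mem[[1]],
                           scale = s, mode = mode)
      } else {
        NA_real_
      }
      pits[[length(pits) + 1]] <- tibble::tibble(
        profile_id = pid, feature_class = r$feature_class[i],
        distance_to_az_nm = d, diameter_nm = g[["diameter"]],
        neck_width_nm = g[["neck_width"]])
    }
    for (i in which(r$feature_class %in% c("synaptic_vesicle",
                                           "large_vesicle", "endosome"))) {
      cls <- classify_vesicle(r$vertices[[i]], s)
      if (cls == "endosome") {
        endos[[length(endos) + 1]] <- tibble::tibble(
          profile_id = pid,
          area_nm2 = endosome_area(r$vertices[[i]], s))
      }
    }
  }
  list(counts = counts,
       pits = dplyr::bind_rows(pits),
       endosomes = dplyr::bind_rows(endos))
}
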