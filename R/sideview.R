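# Side-view analysis: the Bassoon and PSD95 masks are each fit with an
# ellipse; the center-line runs parallel to the averaged major axes through
# the midpoint of the two ellipse centers; the ROI is rotated so the
# center-line is vertical and flipped so Bassoon lies right of it; a
# 42-pixel band line scan across the trans-synaptic axis yields per-channel
# profiles, on which Dyn1xA peaks above amplitude 0.5 are called.
#
# Angles are degrees from the +column axis, axial range [0, 180).

#' Least-squares ellipse fit of a mask's largest external contour
#'
#' Traces the sub-pixel external contours of the binary mask, selects the
#' contour enclosing the largest area (ties break to the first in raster
#' order), and fits an ellipse to its points by direct least squares
#' (constrained conic fit). The angle is normalized to the major axis in
#' [0, 180).
#'
#' @param mask Binary 0/1 matrix with at least 5 boundary points.
#' @return An `ellipse_fit`: list with `center_row`, `center_col`,
#'   `major_len`, `minor_len` (full axis lengths, px), `angle_deg`.
#' @export
fit_mask_ellipse <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask > 0) == 0) stop("empty mask: ROI unanalyzable")
  cl <- grDevices::contourLines(x = 1:nr, y = 1:nc, z = mask, levels = 0.5)
  if (length(cl) == 0) stop("no contour found: ROI unanalyzable")
  best <- NULL; best_area <- -1
  for (ct in cl) {
    n <- length(ct$x)
    if (n < 4) next
    closed <- ct$x[1] == ct$x[n] && ct$y[1] == ct$y[n]
    xs <- if (closed) ct$x[-n] else ct$x
    ys <- if (closed) ct$y[-n] else ct$y
    if (length(xs) < 3) next
    area <- abs(shoelace_area(xs, ys))
    if (area > best_area) {
      best_area <- area
      best <- list(row = xs, col = ys)
    }
  }
  if (is.null(best) || length(best$row) < 5) {
    stop("too few contour points (< 5) for an ellipse fit: ROI unanalyzable")
  }
  fit_ellipse_points(x = best$col, y = best$row)
}

# Direct least-squares conic ellipse fit (Fitzgibbon-style, with the
# quadratic/linear block split), on centered coordinates for conditioning.
# x = col, y = row.
fit_ellipse_points <- function(x, y) {
  stopifnot(length(x) >= 5)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, rep(1, length(xs)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  ok <- which(abs(Im(e$values)) < 1e-8)
  a1 <- NULL
  for (i in ok) {
    v <- Re(e$vectors[, i])
    if (4 * v[1] * v[3] - v[2]^2 > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stop("ellipse fit failed (no elliptic solution)")
  co <- c(a1, as.vector(Tm %*% a1))  # a, b, c, d, e, f in centered frame
  a <- co[1]; b <- co[2]; cc <- co[3]; d <- co[4]; ee <- co[5]; f <- co[6]
  den <- 4 * a * cc - b^2
  x0 <- (b * ee - 2 * cc * d) / den
  y0 <- (b * d - 2 * a * ee) / den
  f0 <- a * x0^2 + b * x0 * y0 + cc * y0^2 + d * x0 + ee * y0 + f
  Mq <- matrix(c(a, b / 2, b / 2, cc), 2)
  eg <- eigen(Mq, symmetric = TRUE)
  semi <- sqrt(pmax(-f0 / eg$values, 0))
  imaj <- which.max(semi)
  major <- 2 * semi[imaj]; minor <- 2 * min(semi)
  vmaj <- eg$vectors[, imaj]
  ang <- wrap_axial(atan2(vmaj[2], vmaj[1]) * 180 / pi)
  structure(list(center_row = y0 + my, center_col = x0 + mx,
                 major_len = major, minor_len = minor,
                 angle_deg = ang),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.2f, %.2f), axes %.2f x %.2f px, %.1f deg\n",
              x$center_row, x$center_col, x$major_len, x$minor_len,
              x$angle_deg))
  invisible(x)
}

#' Axial (period-180) circular mean of two axis angles
#'
#' Averages on doubled angles, halves, and maps back to [0, 180), so that
#' e.g. 179 and 1 average to 0 rather than 90.
#'
#' @param a_deg,b_deg Angles in [0, 180).
#' @return Averaged angle in [0, 180).
#' @export
average_axis_angles <- function(a_deg, b_deg) {
  a2 <- 2 * a_deg * pi / 180
  b2 <- 2 * b_deg * pi / 180
  m <- atan2(sin(a2) + sin(b2), cos(a2) + cos(b2)) / 2
  wrap_axial(m * 180 / pi)
}

#' Compute the center-line between two scaffold ellipses
#'
#' The center-line is parallel to both major axes and passes through the
#' midpoint between the two ellipse centers; its length is the mean of the
#' two major-axis lengths. Nearly parallel axes (axial difference <= 30
#' degrees) are averaged axially; otherwise the two axes are converted to
#' unit vectors (the second flipped into the half-plane of the first) and
#' vector-averaged via atan2. A degenerate zero-norm vector sum falls back
#' to the axial average with a warning.
#'
#' @param ell_bassoon,ell_psd `ellipse_fit` objects.
#' @return A `center_line`: list with `anchor_row`, `anchor_col`,
#'   `angle_deg`, `length_px`.
#' @export
compute_center_line <- function(ell_bassoon, ell_psd) {
  stopifnot(inherits(ell_bassoon, "ellipse_fit"),
            inherits(ell_psd, "ellipse_fit"))
  a <- ell_bassoon$angle_deg; b <- ell_psd$angle_deg
  if (axial_difference(a, b) <= 30) {
    ang <- average_axis_angles(a, b)
  } else {
    u1 <- c(cos(a * pi / 180), sin(a * pi / 180))
    u2 <- c(cos(b * pi / 180), sin(b * pi / 180))
    if (sum(u1 * u2) < 0) u2 <- -u2
    s <- u1 + u2
    if (sqrt(sum(s^2)) < 1e-9) {
      warning("antipodal axis vectors: falling back to axial average")
      ang <- average_axis_angles(a, b)
    } else {
      ang <- wrap_axial(atan2(s[2], s[1]) * 180 / pi)
    }
  }
  structure(list(anchor_row = (ell_bassoon$center_row + ell_psd$center_row) / 2,
                 anchor_col = (ell_bassoon$center_col + ell_psd$center_col) / 2,
                 angle_deg = ang,
                 length_px = (ell_bassoon$major_len + ell_psd$major_len) / 2),
            class = "center_line")
}

#' @export
print.center_line <- function(x, ...) {
  cat(sprintf("<center_line> anchor (%.2f, %.2f), %.1f deg, length %.1f px\n",
              x$anchor_row, x$anchor_col, x$angle_deg, x$length_px))
  invisible(x)
}

#' Rotate an ROI so the center-line becomes vertical
#'
#' Every channel is rotated about the ROI center by `90 - angle` degrees
#' (bicubic interpolation); pixels undefined after rotation are filled
#' with the channel's mean intensity. The applied rotation is stored in
#' the ROI (`rotation_deg`).
#'
#' @param roi A `synapse_roi`.
#' @param cl A `center_line`.
#' @return The rotated ROI.
#' @export
rotate_to_vertical <- function(roi, cl) {
  stopifnot(inherits(roi, "synapse_roi"), inherits(cl, "center_line"))
  rot <- 90 - cl$angle_deg
  roi$crops <- lapply(roi$crops, function(m) {
    rotate_image(m, rot, fill = mean(m))
  })
  names(roi$crops) <- roi$channel_roles
  roi$rotation_deg <- rot
  roi
}

mask_centroid_col <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  mean(idx[, 2])
}

#' Standardize ROI orientation (Bassoon right of the center-line)
#'
#' Rotates the Bassoon and PSD95 masks by the ROI's stored rotation and
#' compares their horizontal centroids; if the Bassoon centroid lies left
#' of the PSD95 centroid, all channels are flipped 180 degrees. Applying
#' the operation twice equals applying it once.
#'
#' @param roi_rotated ROI returned by [rotate_to_vertical()].
#' @param mask_bassoon,mask_psd Binary masks in the unrotated ROI frame.
#' @param cl The `center_line` used for rotation.
#' @return The standardized ROI, with `flipped` set.
#' @export
standardize_orientation <- function(roi_rotated, mask_bassoon, mask_psd, cl) {
  stopifnot(inherits(roi_rotated, "synapse_roi"))
  rot <- if (!is.null(roi_rotated$rotation_deg)) {
    roi_rotated$rotation_deg
  } else {
    90 - cl$angle_deg
  }
  mb <- rotate_image(mask_bassoon, rot, fill = 0) > 0.5
  mp <- rotate_image(mask_psd, rot, fill = 0) > 0.5
  bc <- mask_centroid_col(mb)
  pc <- mask_centroid_col(mp)
  if (is.na(bc) || is.na(pc)) {
    stop("cannot standardize orientation: empty mask after rotation")
  }
  flip <- FALSE
  if (bc < pc) {
    flip <- TRUE
  } else if (bc == pc) {
    warning("equal Bassoon/PSD95 centroid columns: no flip applied")
  }
  if (flip) {
    roi_rotated$crops <- lapply(roi_rotated$crops, function(m) {
      m[nrow(m):1, ncol(m):1]
    })
    names(roi_rotated$crops) <- roi_rotated$channel_roles
  }
  roi_rotated$flipped <- flip
  roi_rotated
}

#' Band line scan across a standardized side-view ROI
#'
#' For each column, averages the `band_width_px` rows centered on the
#' image's horizontal midline (rows `center - floor(w/2)` through
#' `center + w/2 - 1`; for the default 45 x 45 ROI and 42-row band, rows
#' 2..43), then min-max normalizes each channel's profile to [0, 1]
#' (constant profiles map to zeros). The x axis is recentered so 0 is the
#' center-line column (the central column of the rotated ROI), left
#' negative, right positive, in nm.
#'
#' @param roi_std Standardized `synapse_roi`.
#' @param band_width_px Band height in rows (default 42).
#' @return A tibble of class `linescan_profile` with columns
#'   `x_px_from_centerline`, `x_nm`, and one `CHk_norm` column per channel.
#' @export
band_line_scan <- function(roi_std, band_width_px = 42) {
  stopifnot(inherits(roi_std, "synapse_roi"))
  nr <- nrow(roi_std$crops[[1]]); nc <- ncol(roi_std$crops[[1]])
  if (band_width_px > nr) stop("band width exceeds ROI height")
  ctr_row <- (nr + 1) %/% 2
  start <- ctr_row - band_width_px %/% 2
  rows <- start:(start + band_width_px - 1)
  ctr_col <- (nc + 1) %/% 2
  x_px <- seq_len(nc) - ctr_col
  prof <- lapply(roi_std$crops, function(m) {
    p <- colMeans(m[rows, , drop = FALSE])
    if (max(p) > min(p)) (p - min(p)) / (max(p) - min(p)) else rep(0, nc)
  })
  out <- tibble::tibble(x_px_from_centerline = x_px,
                        x_nm = x_px * roi_std$pixel_size_nm)
  for (i in seq_along(prof)) {
    out[[paste0("CH", i, "_norm")]] <- prof[[i]]
  }
  attr(out, "channel_roles") <- roi_std$channel_roles
  attr(out, "pixel_size_nm") <- roi_std$pixel_size_nm
  class(out) <- c("linescan_profile", class(out))
  out
}

# Local maxima of a 1-D profile; plateaus resolve to their middle index
profile_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1 && r$values[i - 1] < r$values[i]
    right_ok <- i < k && r$values[i + 1] < r$values[i]
    if (left_ok && right_ok) {
      out <- c(out, floor((starts[i] + ends[i]) / 2))
    }
  }
  out
}

#' Call peaks on a normalized line-scan profile
#'
#' Local maxima of the selected channels' normalized profiles; peaks with
#' amplitude strictly greater than `threshold` are retained (a peak of
#' exactly the threshold is rejected).
#'
#' @param profile A `linescan_profile`.
#' @param threshold Amplitude gate (default 0.5).
#' @param channels Channel roles to call peaks on (default `"Dyn1xA"`;
#'   pass e.g. `c("Bassoon", "PSD95", "Dyn1xA")` for all).
#' @return Tibble with columns `channel`, `x_nm`, `amplitude`.
#' @export
call_peaks <- function(profile, threshold = 0.5, channels = "Dyn1xA") {
  stopifnot(inherits(profile, "linescan_profile"))
  roles <- attr(profile, "channel_roles")
  out <- list()
  for (ch in channels) {
    i <- match(ch, roles)
    if (is.na(i)) stop("no channel with role '", ch, "'")
    v <- profile[[paste0("CH", i, "_norm")]]
    idx <- profile_local_maxima(v)
    idx <- idx[v[idx] > threshold]
    if (length(idx)) {
      out[[length(out) + 1]] <- tibble::tibble(
        channel = ch, x_nm = profile$x_nm[idx], amplitude = v[idx])
    }
  }
  if (length(out)) {
    dplyr::bind_rows(out)
  } else {
    tibble::tibble(channel = character(0), x_nm = numeric(0),
                   amplitude = numeric(0))
  }
}

#' Full side-view analysis of one ROI
#'
#' Builds Bassoon and PSD95 masks ([pixel_classify()]), fits ellipses,
#' computes the center-line, rotates the ROI to vertical, standardizes
#' orientation, runs the band line scan and calls Dyn1xA peaks.
#'
#' @param roi A `synapse_roi` (or the `image` element of a
#'   [render_sideview()] result, which is converted to a full-canvas ROI).
#' @param band_width_px Band height (default 42).
#' @param peak_threshold Peak amplitude gate (default 0.5).
#' @param peak_channels Channels to call peaks on (default `"Dyn1xA"`).
#' @return List with `profile` (a `linescan_profile`), `peaks` (tibble),
#'   `center_line`, `ellipses`, and the standardized `roi`.
#' @export
sideview_profile <- function(roi, band_width_px = 42, peak_threshold = 0.5,
                             peak_channels = "Dyn1xA") {
  if (inherits(roi, "raster_image")) {
    d <- dim(roi$channels[[1]])
    roi <- extract_roi(roi, c((d[1] + 1) / 2, (d[2] + 1) / 2),
                       size_px = d[1])
  }
  stopifnot(inherits(roi, "synapse_roi"))
  mask_b <- pixel_classify(roi_channel(roi, "Bassoon"))
  mask_p <- pixel_classify(roi_channel(roi, "PSD95"))
  eb <- fit_mask_ellipse(mask_b)
  ep <- fit_mask_ellipse(mask_p)
  cl <- compute_center_line(eb, ep)
  rot <- rotate_to_vertical(roi, cl)
  std <- standardize_orientation(rot, mask_b, mask_p, cl)
  profile <- band_line_scan(std, band_width_px)
  peaks <- call_peaks(profile, threshold = peak_threshold,
                      channels = peak_channels)
  list(profile = profile, peaks = peaks, center_line = cl,
       ellipses = list(bassoon = eb, psd = ep), roi = std)
}

#' Export side-view profiles and peaks as CSV files
#'
#' Writes one profile CSV per ROI (columns `x_px_from_centerline`, `x_nm`,
#' `CH1_norm`, `CH2_norm`, `CH3_norm`) plus a pooled peak table
#' (`roi_id`, `channel`, `x_nm`, `amplitude`). Optional QC panels (one PNG
#' per ROI) show the profile curves; QC rendering uses 1st-99th percentile
#' display scaling, while the exported analysis values stay min-max
#' normalized.
#'
#' @param profiles Named list of `linescan_profile` tibbles (names are
#'   ROI ids).
#' @param peaks Tibble with a `roi_id` column plus [call_peaks()] columns.
#' @param out_dir Output directory (created if needed).
#' @param qc Write QC PNG panels (default FALSE).
#' @return Tibble manifest of written files, invisibly.
#' @export
export_sideview <- function(profiles, peaks, out_dir, qc = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  ids <- names(profiles)
  if (is.null(ids)) ids <- sprintf("roi%03d", seq_along(profiles))
  files <- character(0)
  for (i in seq_along(profiles)) {
    p <- file.path(out_dir, paste0(ids[i], "_profile.csv"))
    readr::write_csv(tibble::as_tibble(profiles[[i]]), p)
    files <- c(files, p)
    if (qc) {
      qp <- file.path(out_dir, paste0(ids[i], "_qc.png"))
      g <- plot_linescan(profiles[[i]])
      ggplot2::ggsave(qp, g, width = 5, height = 3.5, dpi = 120)
      files <- c(files, qp)
    }
  }
  pk <- file.path(out_dir, "peaks.csv")
  readr::write_csv(peaks, pk)
  files <- c(files, pk)
  invisible(tibble::tibble(path = files))
}
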