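# Top-view analysis: the active-zone boundary is the sub-pixel iso-contour
# at half the intensity of each Bassoon local maximum; Dyn1xA puncta are
# local-maxima pixels; each punctum gets the signed minimum distance to the
# boundary (negative inside the active zone). Spots truncated by the ROI
# edge are flagged and excluded.

#' Find strict local maxima of a channel
#'
#' A pixel is a maximum if it is at least as large as its 8-neighborhood
#' and strictly larger than the pixels surrounding its equal-valued
#' plateau; plateau ties resolve to the plateau centroid pixel. With
#' `min_prominence > 0`, a maximum is retained only if no strictly higher
#' pixel is reachable without descending more than `min_prominence` below
#' it.
#'
#' @param channel Numeric matrix.
#' @param min_prominence Minimum prominence in intensity units (default 0).
#' @return Tibble with columns `row`, `col`, `value` (possibly empty).
#' @export
find_local_maxima <- function(channel, min_prominence = 0) {
  nr <- nrow(channel); nc <- ncol(channel)
  empty <- tibble::tibble(row = integer(0), col = integer(0),
                          value = numeric(0))
  if (max(channel) <= min(channel)) return(empty)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- channel
  nbmax <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbmax <- pmax(nbmax, pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  cand <- channel >= nbmax
  if (!any(cand)) return(empty)
  # adjacent candidate pixels always share one value, so every candidate
  # component is a constant-valued plateau; it is a maximum iff every
  # pixel just outside the plateau is strictly lower
  lab <- label_components(cand, connectivity = 8)
  lab_pad <- matrix(0L, nr + 2, nc + 2)
  lab_pad[2:(nr + 1), 2:(nc + 1)] <- lab
  out <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    v <- channel[px[1, 1], px[1, 2]]
    dominated <- TRUE
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      nb_v <- pad[r:(r + 2), c:(c + 2)]
      nb_l <- lab_pad[r:(r + 2), c:(c + 2)]
      outside <- nb_l != k & is.finite(nb_v)
      if (any(nb_v[outside] >= v)) { dominated <- FALSE; break }
    }
    if (!dominated) next
    out[[length(out) + 1]] <- c(round(mean(px[, 1])), round(mean(px[, 2])), v)
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  res <- tibble::tibble(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                        value = m[, 3])
  if (min_prominence > 0) {
    keep <- vapply(seq_len(nrow(res)), function(i) {
      v <- res$value[i]
      region <- label_components(channel > v - min_prominence,
                                 connectivity = 8)
      id <- region[res$row[i], res$col[i]]
      max(channel[region == id]) <= v
    }, logical(1))
    res <- res[keep, , drop = FALSE]
  }
  res
}

new_az_boundary <- function(vertices, level, source, crossing = FALSE) {
  structure(list(vertices = vertices, level = level,
                 source = source, crossing = crossing),
            class = "az_boundary")
}

#' @export
print.az_boundary <- function(x, ...) {
  cat(sprintf("<az_boundary> %d vertices, level %.4g, source (%d, %d)%s\n",
              nrow(x$vertices), x$level, x$source[1], x$source[2],
              if (x$crossing) ", CROSSING" else ""))
  invisible(x)
}

#' Half-maximum boundary of a Bassoon local maximum
#'
#' Extracts the sub-pixel iso-contour at half the intensity of the given
#' local maximum (marching-squares linear interpolation via
#' [grDevices::contourLines()]) and selects the closed contour enclosing
#' the maximum. If the enclosing contour is truncated by the image edge,
#' the boundary is flagged `crossing` (which feeds the exclusion rule).
#'
#' @param bassoon_channel Numeric matrix.
#' @param maximum Length-2 vector (row, col) of a detected local maximum.
#' @return An `az_boundary`: closed polyline (first vertex repeated last)
#'   in (row, col) pixel coordinates, the contour level, the source
#'   maximum, and a `crossing` flag.
#' @export
half_max_boundary <- function(bassoon_channel, maximum) {
  maximum <- as.numeric(unlist(maximum)[1:2])
  nr <- nrow(bassoon_channel); nc <- ncol(bassoon_channel)
  level <- 0.5 * bassoon_channel[maximum[1], maximum[2]]
  if (level <= 0) stop("maximum intensity must be positive")
  cl <- grDevices::contourLines(x = 1:nr, y = 1:nc, z = bassoon_channel,
                                levels = level)
  best_open <- NULL
  for (ct in cl) {
    n <- length(ct$x)
    closed <- n >= 4 && ct$x[1] == ct$x[n] && ct$y[1] == ct$y[n]
    if (closed) {
      if (point_in_polygon(maximum[1], maximum[2],
                           ct$x[-n], ct$y[-n])) {
        return(new_az_boundary(cbind(row = ct$x, col = ct$y), level,
                               c(row = maximum[1], col = maximum[2])))
      }
    } else {
      d <- min(sqrt((ct$x - maximum[1])^2 + (ct$y - maximum[2])^2))
      if (is.null(best_open) || d < best_open$d) {
        best_open <- list(d = d, xy = cbind(row = ct$x, col = ct$y))
      }
    }
  }
  verts <- if (is.null(best_open)) {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  } else {
    best_open$xy
  }
  new_az_boundary(verts, level, c(row = maximum[1], col = maximum[2]),
                  crossing = TRUE)
}

#' Signed minimum distance from a punctum to an active-zone boundary
#'
#' The unsigned distance is the minimum point-to-segment distance over all
#' contour segments; the sign is negative iff the punctum lies inside the
#' closed contour (even-odd rule). Distances convert to nm via
#' `pixel_size_nm`.
#'
#' @param punctum Length-2 vector (row, col), pixel coordinates.
#' @param boundary An `az_boundary` (closed).
#' @param pixel_size_nm Physical pixel size (default 20).
#' @return One-row tibble: `row`, `col`, `signed_distance_nm`,
#'   `distance_px`, `inside`.
#' @export
punctum_boundary_distance <- function(punctum, boundary, pixel_size_nm = 20) {
  stopifnot(inherits(boundary, "az_boundary"))
  if (boundary$crossing || nrow(boundary$vertices) < 4) {
    stop("boundary is not closed (flagged crossing)")
  }
  punctum <- as.numeric(unlist(punctum)[1:2])
  v <- boundary$vertices
  n <- nrow(v)
  d <- point_segment_distance(punctum[1], punctum[2],
                              v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2])
  inside <- point_in_polygon(punctum[1], punctum[2], v[-n, 1], v[-n, 2])
  dmin <- min(d)
  tibble::tibble(row = punctum[1], col = punctum[2],
                 distance_px = dmin,
                 inside = inside,
                 signed_distance_nm = (if (inside) -dmin else dmin) * pixel_size_nm)
}

# The half-max support region of a spot: connected component of pixels at
# or above half the spot's peak containing the peak.
spot_halfmax_region <- function(channel, row, col) {
  v <- channel[row, col]
  lab <- label_components(channel >= 0.5 * v, connectivity = 8)
  lab == lab[row, col]
}

#' Apply exclusion rules to puncta and boundaries
#'
#' Drops puncta whose half-max support region touches the ROI border ring,
#' drops boundaries flagged `crossing`, and (if a neuron mask is supplied)
#' drops Bassoon boundaries whose source maximum falls outside the mask.
#' All drops are logged with reasons.
#'
#' @param puncta Tibble with `row`, `col`, `value` (from
#'   [find_local_maxima()] on the Dyn1xA channel).
#' @param boundaries List of `az_boundary` objects.
#' @param roi A [raster_image()] or `synapse_roi` providing the Dyn1xA
#'   channel for support regions.
#' @param neuron_mask Optional binary matrix; Bassoon maxima outside it
#'   are excluded.
#' @return List with `puncta` (kept tibble), `boundaries` (kept list) and
#'   `log` (tibble of drops: kind, row, col, reason).
#' @export
apply_exclusions <- function(puncta, boundaries, roi, neuron_mask = NULL) {
  dyn <- if (inherits(roi, "synapse_roi")) {
    roi_channel(roi, "Dyn1xA")
  } else if (inherits(roi, "raster_image")) {
    get_channel(roi, "Dyn1xA")
  } else {
    roi
  }
  nr <- nrow(dyn); nc <- ncol(dyn)
  log <- tibble::tibble(kind = character(0), row = numeric(0),
                        col = numeric(0), reason = character(0))
  keep_b <- vapply(boundaries, function(b) !b$crossing, logical(1))
  for (b in boundaries[!keep_b]) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      kind = "boundary", row = b$source[1], col = b$source[2],
      reason = "crossing_roi"))
  }
  if (!is.null(neuron_mask)) {
    in_mask <- vapply(boundaries, function(b) {
      neuron_mask[b$source[1], b$source[2]] > 0
    }, logical(1))
    for (b in boundaries[keep_b & !in_mask]) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        kind = "boundary", row = b$source[1], col = b$source[2],
        reason = "outside_neuron_mask"))
    }
    keep_b <- keep_b & in_mask
  }
  keep_p <- rep(TRUE, nrow(puncta))
  for (i in seq_len(nrow(puncta))) {
    reg <- spot_halfmax_region(dyn, puncta$row[i], puncta$col[i])
    border <- any(reg[1, ]) || any(reg[nr, ]) || any(reg[, 1]) || any(reg[, nc])
    if (border) {
      keep_p[i] <- FALSE
      log <- dplyr::bind_rows(log, tibble::tibble(
        kind = "punctum", row = puncta$row[i], col = puncta$col[i],
        reason = "crossing_roi"))
    }
  }
  list(puncta = puncta[keep_p, , drop = FALSE],
       boundaries = boundaries[keep_b],
       log = log)
}

#' Summarize signed punctum-boundary distances
#'
#' @param distances Numeric vector of signed distances in nm (>= 1 value).
#' @param band Inclusive band around the active-zone edge, nm (default
#'   -50 to +50, the periactive zone).
#' @param binwidth_nm Histogram bin width (default 20, one pixel).
#' @return List with `fraction_in_band`, `histogram` (tibble: `bin_mid_nm`,
#'   `count`), and `cumulative` (tibble: `distance_nm`, `cumulative_fraction`).
#' @export
distance_summary <- function(distances, band = c(-50, 50), binwidth_nm = 20) {
  if (length(distances) == 0) stop("no distances to summarize")
  stopifnot(length(band) == 2, band[1] <= band[2])
  frac <- mean(distances >= band[1] & distances <= band[2])
  lo <- floor(min(distances) / binwidth_nm) * binwidth_nm
  hi <- ceiling(max(distances) / binwidth_nm) * binwidth_nm
  if (hi <= lo) hi <- lo + binwidth_nm
  breaks <- seq(lo, hi, by = binwidth_nm)
  h <- hist(distances, breaks = breaks, plot = FALSE, right = FALSE)
  s <- sort(distances)
  list(fraction_in_band = frac,
       histogram = tibble::tibble(bin_mid_nm = h$mids, count = h$counts),
       cumulative = tibble::tibble(distance_nm = s,
                                   cumulative_fraction = seq_along(s) / length(s)))
}

#' Full top-view distance analysis of one image
#'
#' Detects Bassoon local maxima (CH1) and their half-max boundaries,
#' Dyn1xA local-maxima puncta (CH3), assigns each punctum to the boundary
#' giving the minimum absolute distance, and applies the exclusion rules.
#'
#' @param image A [raster_image()] or `synapse_roi`.
#' @param bassoon_prominence,dyn_prominence Prominence gates as fractions
#'   of the channel maximum (defaults 0.3).
#' @param presmooth_sigma_px Optional Gaussian pre-smoothing applied to
#'   both channels before maxima detection (default 0: none; use ~1.2 px
#'   for noisy, non-deconvolved inputs).
#' @param neuron_mask Optional binary matrix for the neuron exclusion rule.
#' @param pixel_size_nm Pixel size; taken from the image when available.
#' @return Tibble: one row per retained punctum with `row`, `col`,
#'   `boundary_id`, `signed_distance_nm`, `inside`; the exclusion log and
#'   boundaries are attached as attributes `exclusions` and `boundaries`.
#' @export
topview_distances <- function(image, bassoon_prominence = 0.3,
                              dyn_prominence = 0.3,
                              presmooth_sigma_px = 0,
                              neuron_mask = NULL,
                              pixel_size_nm = NULL) {
  if (inherits(image, "synapse_roi")) {
    ch1 <- roi_channel(image, "Bassoon")
    ch3 <- roi_channel(image, "Dyn1xA")
    if (is.null(pixel_size_nm)) pixel_size_nm <- image$pixel_size_nm
  } else {
    ch1 <- get_channel(image, "Bassoon")
    ch3 <- get_channel(image, "Dyn1xA")
    if (is.null(pixel_size_nm)) pixel_size_nm <- image$pixel_size_nm
  }
  if (presmooth_sigma_px > 0) {
    ch1 <- conv2_reflect(ch1, gaussian_kernel(presmooth_sigma_px))
    ch3 <- conv2_reflect(ch3, gaussian_kernel(presmooth_sigma_px))
  }
  mx1 <- find_local_maxima(ch1, min_prominence = bassoon_prominence * max(ch1))
  mx3 <- find_local_maxima(ch3, min_prominence = dyn_prominence * max(ch3))
  empty <- tibble::tibble(row = integer(0), col = integer(0),
                          boundary_id = integer(0),
                          signed_distance_nm = numeric(0),
                          inside = logical(0))
  if (nrow(mx1) == 0 || nrow(mx3) == 0) return(empty)
  boundaries <- lapply(seq_len(nrow(mx1)), function(i) {
    half_max_boundary(ch1, c(mx1$row[i], mx1$col[i]))
  })
  filt <- apply_exclusions(mx3, boundaries, ch3, neuron_mask = neuron_mask)
  if (length(filt$boundaries) == 0 || nrow(filt$puncta) == 0) {
    attr(empty, "exclusions") <- filt$log
    return(empty)
  }
  rows <- lapply(seq_len(nrow(filt$puncta)), function(i) {
    ds <- lapply(seq_along(filt$boundaries), function(j) {
      punctum_boundary_distance(c(filt$puncta$row[i], filt$puncta$col[i]),
                                filt$boundaries[[j]], pixel_size_nm)
    })
    ad <- vapply(ds, function(d) abs(d$signed_distance_nm), numeric(1))
    j <- which.min(ad)
    dplyr::mutate(ds[[j]], boundary_id = j)
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(row = out$row, col = out$col,
                        boundary_id = out$boundary_id,
                        signed_distance_nm = out$signed_distance_nm,
                        inside = out$inside)
  attr(out, "exclusions") <- filt$log
  attr(out, "boundaries") <- filt$boundaries
  out
}
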