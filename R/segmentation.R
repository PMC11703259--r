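# Candidate-synapse segmentation: presynaptic boutons are selected
# indiscriminately as local maxima of the smoothed Bassoon channel that
# carry Dyn1xA signal, cropped into fixed 45 x 45 px regions of interest,
# and sorted into side-view / top-view classes by the elongation of the
# Bassoon blob (a deterministic stand-in for supervised sorting). A
# feature-stack pixel classifier produces the binary masks consumed by the
# side-view geometry.

#' Detect candidate synapse centers
#'
#' Centers are local maxima of the Gaussian-smoothed Bassoon channel above
#' `bassoon_rel_threshold` (relative to the smoothed maximum) that have
#' Dyn1xA signal above `dyn_rel_threshold` (relative to the Dyn1xA
#' maximum) somewhere within the prospective ROI. Maxima closer than
#' `min_separation_px` are merged, keeping the brighter.
#'
#' @param bassoon_channel,dyn_channel Numeric matrices of equal shape.
#' @param min_separation_px Minimum center separation (default 20).
#' @param smooth_sigma_px Gaussian sigma for pre-smoothing (default 2).
#' @param bassoon_rel_threshold,dyn_rel_threshold Relative thresholds in
#'   (0, 1).
#' @param roi_size_px ROI edge length used for the Dyn1xA gate (default 45).
#' @return Tibble with columns `row`, `col`, `intensity` (possibly empty).
#' @export
detect_candidates <- function(bassoon_channel, dyn_channel,
                              min_separation_px = 20,
                              smooth_sigma_px = 2,
                              bassoon_rel_threshold = 0.25,
                              dyn_rel_threshold = 0.1,
                              roi_size_px = 45) {
  stopifnot(all(dim(bassoon_channel) == dim(dyn_channel)))
  empty <- tibble::tibble(row = integer(0), col = integer(0),
                          intensity = numeric(0))
  if (max(bassoon_channel) <= min(bassoon_channel)) return(empty)
  sm <- conv2_reflect(bassoon_channel, gaussian_kernel(smooth_sigma_px))
  thr <- min(sm) + bassoon_rel_threshold * (max(sm) - min(sm))
  mx <- find_local_maxima(sm)
  if (nrow(mx) == 0) return(empty)
  mx <- mx[mx$value >= thr, , drop = FALSE]
  if (nrow(mx) == 0) return(empty)
  # Dyn1xA gate within the prospective ROI
  h <- (roi_size_px - 1) %/% 2
  dyn_max <- max(dyn_channel)
  keep <- vapply(seq_len(nrow(mx)), function(i) {
    r0 <- max(1, mx$row[i] - h); r1 <- min(nrow(dyn_channel), mx$row[i] + h)
    c0 <- max(1, mx$col[i] - h); c1 <- min(ncol(dyn_channel), mx$col[i] + h)
    dyn_max > 0 && max(dyn_channel[r0:r1, c0:c1]) >= dyn_rel_threshold * dyn_max
  }, logical(1))
  mx <- mx[keep, , drop = FALSE]
  if (nrow(mx) == 0) return(empty)
  # merge close maxima, keeping the brighter
  ord <- order(-mx$value)
  mx <- mx[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(mx))
  out <- list()
  for (i in seq_len(nrow(mx))) {
    if (taken[i]) next
    d <- sqrt((mx$row - mx$row[i])^2 + (mx$col - mx$col[i])^2)
    taken[d < min_separation_px] <- TRUE
    out[[length(out) + 1]] <- mx[i, ]
  }
  res <- dplyr::bind_rows(out)
  tibble::tibble(row = res$row, col = res$col, intensity = res$value)
}

#' Extract a fixed-size ROI around a candidate center
#'
#' @param image A [raster_image()].
#' @param center Length-2 vector (row, col) or one-row data frame.
#' @param size_px ROI edge length (default 45; the center pixel sits at
#'   index `(size_px + 1) / 2`).
#' @return A `synapse_roi` (list of per-channel crops plus metadata), or
#'   `NULL` with a warning if the ROI would overlap the image border.
#' @export
extract_roi <- function(image, center, size_px = 45) {
  stopifnot(inherits(image, "raster_image"), size_px %% 2 == 1)
  center <- as.numeric(unlist(center)[1:2])
  h <- (size_px - 1) / 2
  nr <- nrow(image$channels[[1]]); nc <- ncol(image$channels[[1]])
  r <- round(center[1]); c <- round(center[2])
  if (r - h < 1 || r + h > nr || c - h < 1 || c + h > nc) {
    warning(sprintf("ROI at (%d, %d) overlaps the image border: skipped", r, c))
    return(NULL)
  }
  crops <- lapply(image$channels, function(m) m[(r - h):(r + h), (c - h):(c + h)])
  structure(list(crops = crops,
                 parent_center = c(row = r, col = c),
                 view = NA_character_,
                 pixel_size_nm = image$pixel_size_nm,
                 channel_roles = image$channel_roles),
            class = "synapse_roi")
}

#' @export
print.synapse_roi <- function(x, ...) {
  cat(sprintf("<synapse_roi> %d x %d px at (%d, %d), view: %s\n",
              nrow(x$crops[[1]]), ncol(x$crops[[1]]),
              x$parent_center[1], x$parent_center[2], x$view))
  invisible(x)
}

roi_channel <- function(roi, role) {
  i <- match(role, roi$channel_roles)
  if (is.na(i)) stop("no channel with role '", role, "'")
  roi$crops[[i]]
}

# 256-bin Otsu threshold on values min-max normalized to [0, 1]; returns
# the threshold on the normalized scale. Invariant to affine rescaling of
# the input by construction.
otsu_threshold <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(0.5)
  v <- (m - lo) / (hi - lo)
  br <- seq(0, 1, length.out = 257)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), 256), 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / pmax(omega * (1 - omega), 1e-12)
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1]
}

# Label connected components of a binary matrix (small images only);
# component ids follow raster order of first encounter, so ties in
# "largest component" break to the lowest raster-order label.
label_components <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask > 0)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1) %% nr) + 1
      c <- ((p - 1) %/% nr) + 1
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1) * nr + rr
          if (mask[q] > 0 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Elongation (major/minor axis ratio of the moment ellipse) of a set of
# pixel coordinates
mask_elongation <- function(rows, cols) {
  if (length(rows) < 2) return(1)
  cv <- stats::cov(cbind(cols, rows)) + diag(1 / 12, 2)  # pixel variance
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 0) / max(ev[2], .Machine$double.eps))
}

#' Sort an ROI into side view, top view or rejected
#'
#' Thresholds the Bassoon crop (Otsu), takes the largest connected
#' component (ties broken by lowest raster-order label), and computes the
#' elongation of its moment ellipse (major / minor axis). Elongation at or
#' above `e_side` classifies as `"side"`, at or below `e_top` as `"top"`,
#' anything between as `"rejected"`. Empty foreground is `"rejected"`.
#'
#' @param roi A `synapse_roi`.
#' @param e_side,e_top Elongation thresholds (defaults 1.8 and 1.4).
#' @return The ROI with its `view` field set.
#' @export
classify_view <- function(roi, e_side = 1.8, e_top = 1.4) {
  stopifnot(inherits(roi, "synapse_roi"), e_side > e_top)
  m <- roi_channel(roi, "Bassoon")
  if (max(m) <= min(m)) {
    roi$view <- "rejected"
    return(roi)
  }
  v <- (m - min(m)) / (max(m) - min(m))
  fg <- v > otsu_threshold(m)
  if (!any(fg)) {
    roi$view <- "rejected"
    return(roi)
  }
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  big <- which(lab == which.max(sizes), arr.ind = TRUE)
  e <- mask_elongation(big[, 1], big[, 2])
  roi$view <- if (e >= e_side) "side" else if (e <= e_top) "top" else "rejected"
  attr(roi$view, "elongation") <- e
  roi
}

#' Feature stack for pixel classification
#'
#' Gaussian-smoothed intensity and gradient-magnitude images of a channel
#' at the standard scales sigma = 0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0 px.
#'
#' @param channel Numeric matrix.
#' @param scales Gaussian scales in pixels.
#' @return A 3-D array (rows x cols x 2 * length(scales)).
#' @export
pixel_features <- function(channel,
                           scales = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)) {
  nr <- nrow(channel); nc <- ncol(channel)
  out <- array(0, c(nr, nc, 2 * length(scales)))
  for (i in seq_along(scales)) {
    sm <- conv2_reflect(channel, gaussian_kernel(scales[i]))
    gr <- sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]
    gc <- sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]
    out[, , 2 * i - 1] <- sm
    out[, , 2 * i] <- sqrt(gr^2 + gc^2) / 2
  }
  dimnames(out) <- list(NULL, NULL,
                        paste0(rep(c("I", "G"), length(scales)),
                               rep(scales, each = 2)))
  out
}

#' Train a logistic pixel classifier on labeled fixtures
#'
#' @param channels List of channel matrices.
#' @param labels List of matching label matrices (1 = object, 0 =
#'   background, NA = unlabeled).
#' @param scales Feature scales, as in [pixel_features()].
#' @return A fitted `glm` object usable as `classifier` in
#'   [pixel_classify()].
#' @export
train_pixel_classifier <- function(channels, labels,
                                   scales = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)) {
  stopifnot(length(channels) == length(labels))
  xs <- list(); ys <- list()
  for (i in seq_along(channels)) {
    f <- pixel_features(normalize_minmax(channels[[i]]), scales)
    x <- matrix(f, ncol = dim(f)[3])
    colnames(x) <- dimnames(f)[[3]]
    y <- as.vector(labels[[i]])
    ok <- !is.na(y)
    xs[[i]] <- x[ok, , drop = FALSE]
    ys[[i]] <- y[ok]
  }
  df <- as.data.frame(do.call(rbind, xs))
  df$.y <- unlist(ys)
  stats::glm(.y ~ ., data = df, family = stats::binomial())
}

#' Binarize a channel into a foreground mask
#'
#' Default method: Otsu threshold on the sigma = 1.0 Gaussian-smoothed,
#' min-max normalized intensity. With a trained `classifier` (from
#' [train_pixel_classifier()]), the full feature stack is scored instead.
#' Foreground polarity is enforced afterwards: the class with the higher
#' mean smoothed intensity (the bright object class) is mapped to 1.
#'
#' @param roi_channel Numeric matrix.
#' @param classifier Optional fitted classifier.
#' @param scales Feature scales.
#' @return Binary 0/1 matrix with attribute `channel_role` if the input
#'   carried one.
#' @export
pixel_classify <- function(roi_channel, classifier = NULL,
                           scales = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)) {
  v <- normalize_minmax(roi_channel)
  sm <- conv2_reflect(v, gaussian_kernel(1.0))
  if (is.null(classifier)) {
    mask <- (normalize_minmax(sm) > otsu_threshold(sm)) * 1
  } else {
    f <- pixel_features(v, scales)
    x <- as.data.frame(matrix(f, ncol = dim(f)[3]))
    colnames(x) <- dimnames(f)[[3]]
    p <- stats::predict(classifier, newdata = x, type = "response")
    mask <- matrix((p > 0.5) * 1, nrow(v), ncol(v))
  }
  # polarity: the brighter class is foreground
  if (any(mask == 1) && any(mask == 0)) {
    if (mean(sm[mask == 1]) < mean(sm[mask == 0])) mask <- 1 - mask
  }
  mask
}
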