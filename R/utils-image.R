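# Low-level image numerics shared by the deconvolution, segmentation and
# geometry modules: reflective-padding convolution, Gaussian kernels,
# bicubic interpolation and rotation. All image matrices are indexed
# [row, col], 1-based, with pixel centers at integer coordinates. Angles
# are measured in degrees counter-clockwise from the +column ("horizontal")
# axis toward the +row axis, and axial (undirected) angles live in [0, 180).

#' Reflectively pad a matrix
#'
#' @param m Numeric matrix.
#' @param pr,pc Padding (rows, cols) on each side; must be < dim(m).
#' @return Padded matrix of size (nr + 2 pr) x (nc + 2 pc).
#' @keywords internal
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(pr < nr, pc < nc)
  ri <- c(if (pr > 0) (pr + 1):2 else integer(0), 1:nr,
          if (pr > 0) (nr - 1):(nr - pr) else integer(0))
  ci <- c(if (pc > 0) (pc + 1):2 else integer(0), 1:nc,
          if (pc > 0) (nc - 1):(nc - pc) else integer(0))
  m[ri, ci, drop = FALSE]
}

# Circular 2-D convolution via FFT with the kernel centered at its middle
# element. Kernel must have odd dimensions and be no larger than the image.
conv2_circular <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1, kr <= nr, kc <= nc)
  big <- matrix(0, nr, nc)
  big[1:kr, 1:kc] <- k
  # shift so the kernel center sits at element (1, 1) with wrap-around
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  big <- big[((0:(nr - 1) + hr) %% nr) + 1, ((0:(nc - 1) + hc) %% nc) + 1]
  Re(stats::fft(stats::fft(m) * stats::fft(big), inverse = TRUE)) / (nr * nc)
}

#' 2-D convolution with reflective boundary handling
#'
#' Convolves `m` with an odd-sized kernel `k`, padding the image by
#' reflection so that flux is not lost at the boundary of small regions of
#' interest.
#'
#' @param m Numeric matrix (image channel).
#' @param k Odd-dimensioned numeric kernel.
#' @return Matrix of the same size as `m`.
#' @keywords internal
conv2_reflect <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- min((kr - 1) / 2, nrow(m) - 1)
  pc <- min((kc - 1) / 2, ncol(m) - 1)
  p <- pad_reflect(m, pr, pc)
  out <- conv2_circular(p, k)
  out[(pr + 1):(pr + nrow(m)), (pc + 1):(pc + ncol(m)), drop = FALSE]
}

# Cross-correlation of a with b at lags |dr| <= hr, |dc| <= hc
# (zero-padded): C[u, v] = sum_s a[s] * b[s - (u, v)].
# Returns a (2 hr + 1) x (2 hc + 1) matrix with lag (0, 0) at the center.
xcorr_lags <- function(a, b, hr, hc) {
  nr <- nrow(a); nc <- ncol(a)
  stopifnot(all(dim(a) == dim(b)))
  out <- matrix(0, 2 * hr + 1, 2 * hc + 1)
  for (dr in -hr:hr) {
    ra <- max(1, 1 + dr):min(nr, nr + dr)
    rb <- ra - dr
    for (dc in -hc:hc) {
      ca <- max(1, 1 + dc):min(nc, nc + dc)
      cb <- ca - dc
      out[dr + hr + 1, dc + hc + 1] <-
        sum(a[ra, ca, drop = FALSE] * b[rb, cb, drop = FALSE])
    }
  }
  out
}

#' Normalized 2-D Gaussian kernel
#'
#' @param sigma Standard deviation in pixels.
#' @param half_size Half-width of the (odd) support; defaults to
#'   `ceiling(4 * sigma)`.
#' @return Kernel matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(sigma, half_size = NULL) {
  stopifnot(sigma > 0)
  if (is.null(half_size)) half_size <- max(1L, ceiling(4 * sigma))
  x <- -half_size:half_size
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

# Catmull-Rom (Keys, a = -1/2) cubic interpolation weight
cubic_weight <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

#' Bicubic sampling of an image at fractional coordinates
#'
#' Samples `m` at the (row, col) positions given by `rs`, `cs` using
#' Catmull-Rom bicubic interpolation. Positions outside the image domain
#' return `NA`; positions inside use index clamping for the outermost
#' support rows/cols.
#'
#' @param m Numeric matrix.
#' @param rs,cs Numeric vectors of row/col query coordinates (1-based).
#' @return Numeric vector of sampled values.
#' @keywords internal
interp_bicubic <- function(m, rs, cs) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(rs))
  ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  if (!any(ok)) return(out)
  r <- rs[ok]; c <- cs[ok]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  acc <- numeric(length(r))
  wsum <- numeric(length(r))
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 1), nr)
    wr <- cubic_weight(fr - i)
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 1), nc)
      wc <- cubic_weight(fc - j)
      w <- wr * wc
      acc <- acc + w * m[cbind(ri, cj)]
      wsum <- wsum + w
    }
  }
  out[ok] <- acc / wsum
  out
}

#' Rotate an image channel about a center point
#'
#' Rotates image content by `angle_deg` so that a feature lying along
#' direction theta (degrees from the +column axis toward the +row axis)
#' ends up along direction theta + angle_deg. Interpolation is bicubic;
#' pixels whose pre-image falls outside the input domain are filled with
#' `fill` (by default the channel mean, so constant images are fixed
#' points of any rotation).
#'
#' @param m Numeric matrix.
#' @param angle_deg Rotation angle in degrees.
#' @param center `(row, col)` center of rotation; defaults to the image
#'   center `((nr + 1) / 2, (nc + 1) / 2)`.
#' @param fill Fill value for undefined pixels; default `mean(m)`.
#' @return Rotated matrix, same size as `m`.
#' @export
rotate_image <- function(m, angle_deg,
                         center = c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2),
                         fill = mean(m)) {
  if (angle_deg %% 360 == 0) return(m)
  a <- angle_deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  grid <- expand.grid(row = 1:nr, col = 1:nc)
  dx <- grid$col - center[2]
  dy <- grid$row - center[1]
  # inverse rotation of the output grid into the input frame
  sx <- cos(a) * dx + sin(a) * dy
  sy <- -sin(a) * dx + cos(a) * dy
  vals <- interp_bicubic(m, center[1] + sy, center[2] + sx)
  vals[is.na(vals)] <- fill
  matrix(vals, nr, nc)
}

# Map an angle in degrees to the axial range [0, 180)
wrap_axial <- function(a) {
  a <- a %% 180
  ifelse(a < 0, a + 180, a)
}

# Axial (period-180) absolute difference between two angles, in [0, 90]
axial_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Shoelace signed area of a polygon given as x, y vectors (open: last
# vertex not repeated)
shoelace_area <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# Even-odd point-in-polygon test (vertices open-ring)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- c(n, 1:(n - 1))
  inside <- FALSE
  for (i in 1:n) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j[i]]; yj <- vy[j[i]]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
  }
  inside
}

# Minimum distance from point (px, py) to the segment (x1,y1)-(x2,y2),
# vectorized over segments.
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}
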