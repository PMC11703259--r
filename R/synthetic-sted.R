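# Synthetic STED renderings with known ground truth. Two geometries are
# emulated: side-view synapses (the trans-synaptic axis lies in the imaging
# plane, so Bassoon and PSD95 appear as two parallel elongated bars with
# Dyn1xA puncta at known signed offsets from the inter-bar center-line) and
# top-view synapses (the active zone is seen face-on as a compact blob with
# Dyn1xA puncta at known signed distances from its half-maximum boundary).
# Bars are line segments convolved with an anisotropic Gaussian; puncta are
# isotropic Gaussians of the PSF width. Poisson shot noise is applied to
# expected photon counts after blurring; an infinite photon_scale disables
# noise for oracle tests (the noiseless rendering then has unit peak
# amplitude).

#' Ground truth for a synthetic side-view synapse
#'
#' @param bar_separation_nm Distance between the Bassoon and PSD95 bar
#'   centers along the trans-synaptic axis (default 150 nm, the typical
#'   Bassoon-to-PSD95 epitope separation of an excitatory synapse).
#' @param bar_length_nm Length of each scaffold bar (default 400 nm).
#' @param bar_angle_deg Orientation of the bar long axis in the rendered
#'   frame, degrees from the +column axis (default 90: vertical bars,
#'   horizontal trans-synaptic axis).
#' @param punctum_offsets_nm Signed distances of Dyn1xA puncta from the
#'   true center-line; positive on the Bassoon side.
#' @param psf_sigma_nm Gaussian PSF standard deviation (default 60 nm,
#'   a typical effective STED resolution).
#' @param photon_scale Expected peak photon count (default 200). `Inf`
#'   disables Poisson noise.
#' @param seed Integer master seed for the noise streams.
#' @return An object of class `sideview_truth`.
#' @export
sideview_truth <- function(bar_separation_nm = 150, bar_length_nm = 400,
                           bar_angle_deg = 90, punctum_offsets_nm = 60,
                           psf_sigma_nm = 60, photon_scale = 200, seed = 1) {
  stopifnot(bar_separation_nm > 0, bar_length_nm > 0,
            psf_sigma_nm >= 0, photon_scale > 0)
  structure(list(bar_separation_nm = bar_separation_nm,
                 bar_length_nm = bar_length_nm,
                 bar_angle_deg = bar_angle_deg,
                 punctum_offsets_nm = punctum_offsets_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 photon_scale = photon_scale,
                 seed = seed),
            class = "sideview_truth")
}

#' Ground truth for a synthetic top-view synapse
#'
#' @param az_radius_nm Radius of the active-zone blob, defined as the
#'   radius of the half-maximum boundary of the noiseless rendering
#'   (default 150 nm).
#' @param punctum_distances_nm Signed distances of Dyn1xA puncta from the
#'   half-max boundary; negative inside the active zone.
#' @param psf_sigma_nm Gaussian PSF standard deviation for the puncta
#'   (default 60 nm).
#' @param photon_scale Expected peak photon count; `Inf` disables noise.
#' @param seed Integer master seed.
#' @return An object of class `topview_truth`.
#' @export
topview_truth <- function(az_radius_nm = 150, punctum_distances_nm = 0,
                          psf_sigma_nm = 60, photon_scale = 200, seed = 1) {
  stopifnot(az_radius_nm > 0, psf_sigma_nm >= 0, photon_scale > 0,
            all(is.finite(punctum_distances_nm)))
  structure(list(az_radius_nm = az_radius_nm,
                 punctum_distances_nm = punctum_distances_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 photon_scale = photon_scale,
                 seed = seed),
            class = "topview_truth")
}

# Expected-intensity field of a bar: a segment of length len_px centered at
# (cr, cc) along unit vector (ux, uy) (x = col, y = row), convolved with an
# isotropic Gaussian of sd sigma_px. Evaluated analytically via erf.
bar_field <- function(n, cr, cc, ux, uy, len_px, sigma_px, amp) {
  grid <- expand.grid(row = 1:n, col = 1:n)
  dx <- grid$col - cc
  dy <- grid$row - cr
  dpar <- dx * ux + dy * uy
  dperp <- -dx * uy + dy * ux
  h <- len_px / 2
  if (sigma_px > 0) {
    s2 <- sigma_px * sqrt(2)
    lon <- 0.5 * (pracma::erf((dpar + h) / s2) - pracma::erf((dpar - h) / s2))
    lon_peak <- pracma::erf(h / s2)  # longitudinal factor at the bar center
    v <- amp * exp(-dperp^2 / (2 * sigma_px^2)) * lon / max(lon_peak, .Machine$double.eps)
  } else {
    v <- amp * as.numeric(abs(dperp) < 0.5 & abs(dpar) <= h + 0.5)
  }
  matrix(v, n, n)
}

# Isotropic Gaussian punctum (or single-pixel deposit when sigma_px = 0)
punctum_field <- function(n, cr, cc, sigma_px, amp) {
  m <- matrix(0, n, n)
  if (sigma_px > 0) {
    grid <- expand.grid(row = 1:n, col = 1:n)
    v <- amp * exp(-((grid$col - cc)^2 + (grid$row - cr)^2) / (2 * sigma_px^2))
    m <- matrix(v, n, n)
  } else {
    r <- round(cr); c <- round(cc)
    if (r >= 1 && r <= n && c >= 1 && c <= n) m[r, c] <- amp
  }
  m
}

apply_shot_noise <- function(channel, seed, stream) {
  with_rng_seed(split_seed(seed, stream), {
    matrix(stats::rpois(length(channel), pmax(channel, 0)),
           nrow(channel), ncol(channel))
  })
}

#' Render a synthetic side-view synapse
#'
#' Renders CH1 (Bassoon) and CH2 (PSD95) as parallel elongated bars
#' separated by `bar_separation_nm`, and CH3 (Dyn1xA) puncta at the stated
#' signed offsets from the midline between the bars (positive toward the
#' Bassoon bar). The midline passes through the canvas center. PSF blur is
#' analytic; Poisson noise is applied per channel from seeds split off the
#' truth seed.
#'
#' @param truth A [sideview_truth()].
#' @param canvas_px Square canvas size in pixels (default 45, the analysis
#'   ROI size; larger canvases are allowed for whole-field tests).
#' @param pixel_size_nm Pixel size (default 20 nm).
#' @return A list with elements `image` (a [raster_image()]) and `truth`.
#' @export
render_sideview <- function(truth, canvas_px = 45, pixel_size_nm = 20) {
  stopifnot(inherits(truth, "sideview_truth"))
  n <- canvas_px
  px <- pixel_size_nm
  ctr <- (n + 1) / 2
  sig <- truth$psf_sigma_nm / px
  sep <- truth$bar_separation_nm / px
  len <- truth$bar_length_nm / px
  th <- truth$bar_angle_deg * pi / 180
  u <- c(cos(th), sin(th))        # bar long axis (x = col, y = row)
  v <- c(-sin(th), cos(th))       # trans-synaptic normal; +v = Bassoon side
  # sizing: bars and puncta plus a 3 sigma margin must fit on the canvas
  off_px <- truth$punctum_offsets_nm / px
  bar_x <- len / 2 * abs(u[1]) + sep / 2 * abs(v[1])
  bar_y <- len / 2 * abs(u[2]) + sep / 2 * abs(v[2])
  off_max <- if (length(off_px)) max(abs(off_px)) else 0
  reach_x <- max(bar_x, off_max * abs(v[1])) + 3 * sig
  reach_y <- max(bar_y, off_max * abs(v[2])) + 3 * sig
  if (ctr - max(reach_x, reach_y) < 0.5) {
    stop("canvas of ", n, " px is too small to contain the side-view geometry")
  }
  amp <- if (is.finite(truth$photon_scale)) truth$photon_scale else 1
  b_ctr <- c(ctr + sep / 2 * v[2], ctr + sep / 2 * v[1])  # (row, col)
  p_ctr <- c(ctr - sep / 2 * v[2], ctr - sep / 2 * v[1])
  ch1 <- bar_field(n, b_ctr[1], b_ctr[2], u[1], u[2], len, sig, amp)
  ch2 <- bar_field(n, p_ctr[1], p_ctr[2], u[1], u[2], len, sig, amp)
  ch3 <- matrix(0, n, n)
  for (d in off_px) {
    ch3 <- ch3 + punctum_field(n, ctr + d * v[2], ctr + d * v[1], sig, amp)
  }
  if (is.finite(truth$photon_scale)) {
    ch1 <- apply_shot_noise(ch1, truth$seed, "sideview/CH1")
    ch2 <- apply_shot_noise(ch2, truth$seed, "sideview/CH2")
    ch3 <- apply_shot_noise(ch3, truth$seed, "sideview/CH3")
  }
  list(image = raster_image(list(ch1, ch2, ch3), pixel_size_nm = px),
       truth = truth)
}

#' Render a synthetic top-view synapse
#'
#' CH1 is an isotropic Gaussian active-zone blob whose analytic half-max
#' boundary is a circle of radius `az_radius_nm` (the blob sd is therefore
#' `az_radius_nm / sqrt(2 ln 2)`, absorbing the optics). CH3 puncta are
#' placed at radius `az_radius_nm + d` for each signed distance `d`, at
#' deterministic evenly spaced azimuths with a seeded rotation offset, so
#' that each punctum's true signed distance to the half-max boundary equals
#' `punctum_distances_nm` exactly. CH2 is empty.
#'
#' @inheritParams render_sideview
#' @param truth A [topview_truth()].
#' @return A list with `image` and `truth` (truth gains a
#'   `punctum_positions_px` matrix of planted (row, col) centers).
#' @export
render_topview <- function(truth, canvas_px = 45, pixel_size_nm = 20) {
  stopifnot(inherits(truth, "topview_truth"))
  n <- canvas_px
  px <- pixel_size_nm
  ctr <- (n + 1) / 2
  sig_p <- truth$psf_sigma_nm / px
  r_half <- truth$az_radius_nm / px
  sigma_blob <- r_half / sqrt(2 * log(2))
  d_px <- truth$punctum_distances_nm / px
  radii <- r_half + d_px
  if (any(radii < 0)) {
    stop("punctum placed farther inside than the blob center permits ",
         "(radius ", truth$az_radius_nm, " nm)")
  }
  if (any(radii + 3 * sig_p > ctr - 0.5) || r_half + 3 > ctr - 0.5) {
    stop("canvas of ", n, " px is too small to contain the top-view geometry")
  }
  amp <- if (is.finite(truth$photon_scale)) truth$photon_scale else 1
  grid <- expand.grid(row = 1:n, col = 1:n)
  r2 <- (grid$row - ctr)^2 + (grid$col - ctr)^2
  ch1 <- matrix(amp * exp(-r2 / (2 * sigma_blob^2)), n, n)
  ch2 <- matrix(0, n, n)
  ch3 <- matrix(0, n, n)
  k <- length(radii)
  ang0 <- with_rng_seed(split_seed(truth$seed, "topview/azimuth"),
                        stats::runif(1, 0, 2 * pi))
  angles <- ang0 + 2 * pi * (seq_len(k) - 1) / max(k, 1)
  pos <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(k)) {
    pr <- ctr + radii[i] * sin(angles[i])
    pc <- ctr + radii[i] * cos(angles[i])
    pos[i, ] <- c(pr, pc)
    ch3 <- ch3 + punctum_field(n, pr, pc, sig_p, amp)
  }
  if (is.finite(truth$photon_scale)) {
    ch1 <- apply_shot_noise(ch1, truth$seed, "topview/CH1")
    ch3 <- apply_shot_noise(ch3, truth$seed, "topview/CH3")
  }
  truth$punctum_positions_px <- pos
  list(image = raster_image(list(ch1, ch2, ch3), pixel_size_nm = px),
       truth = truth)
}
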