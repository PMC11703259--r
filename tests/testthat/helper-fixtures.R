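# Shared fixture builders: everything is generated in code at test time.

axial_difference_deg <- function(a, b) synquant:::axial_difference(a, b)
roi_channel_pkg <- function(roi, role) synquant:::roi_channel(roi, role)

# Isotropic Gaussian spot on an n x n canvas
make_spot <- function(n, r, c, sigma, amp = 1) {
  g <- expand.grid(row = 1:n, col = 1:n)
  matrix(amp * exp(-((g$row - r)^2 + (g$col - c)^2) / (2 * sigma^2)), n, n)
}

# Filled rotated-ellipse mask (semi-axes a >= b, angle from +col axis)
make_ellipse_mask <- function(n, r0, c0, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  g <- expand.grid(row = 1:n, col = 1:n)
  dx <- g$col - c0; dy <- g$row - r0
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  matrix(as.numeric((u / a)^2 + (v / b)^2 <= 1), n, n)
}

# Noiseless side-view rendering
render_clean_sideview <- function(offsets_nm, angle_deg = 90, ...) {
  render_sideview(sideview_truth(punctum_offsets_nm = offsets_nm,
                                 bar_angle_deg = angle_deg,
                                 photon_scale = Inf, ...))
}

# A minimal EM annotation file with a straight membrane, an AZ and one
# semicircular pit at a given nearest-edge gap (units nm, scale 1)
make_simple_pit_file <- function(gap_nm, pit_radius_nm = 20,
                                 az = c(1000, 1300), mem_len = 3000) {
  arc <- pit_arc(az[2] + gap_nm, 100, 2 * pit_radius_nm, pit_radius_nm)
  fmt <- function(xy) paste(sprintf("%.6f,%.6f", xy[, 1], xy[, 2]),
                            collapse = ";")
  c("# em-annotation v1",
    "# scale_nm_per_px 1",
    paste("p1", "plasma_membrane", "polyline",
          fmt(cbind(seq(0, mem_len, length.out = 11), 100)), sep = "\t"),
    paste("p1", "active_zone", "polyline",
          fmt(cbind(seq(az[1], az[2], length.out = 5), 100)), sep = "\t"),
    paste("p1", "uncoated_pit", "polyline", fmt(arc$xy), sep = "\t"))
}
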