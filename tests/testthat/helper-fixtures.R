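## shared fixtures; all generated in code at test time

circle_contour <- function(n = 200, r = 500, role = "lumen", phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  contour(cbind(r * cos(th), r * sin(th)), role = role)
}

## small phantom for fast unit tests (scaled-down vessel)
small_geometry <- function(deformation_amplitude_um = 20, ...) {
  phantom_geometry(lumen_diameter_um = 500, wall_thickness_um = 100,
                   deformation_amplitude_um = deformation_amplitude_um,
                   chain_spacing_um = 4, ...)
}

## independent even-odd point-in-polygon oracle (ray casting)
pip_oracle <- function(pts, poly) {
  n <- nrow(poly)
  out <- logical(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    x <- pts[q, 1]; y <- pts[q, 2]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
        xint <- poly[i, 1] + (y - poly[i, 2]) *
          (poly[j, 1] - poly[i, 1]) / (poly[j, 2] - poly[i, 2])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    out[q] <- inside
  }
  out
}

grid_points <- function(lo, hi, by) {
  xs <- seq(lo[1], hi[1], by = by)
  ys <- seq(lo[2], hi[2], by = by)
  cbind(rep(xs, length(ys)), rep(ys, each = length(xs)))
}

## distance from points to a closed polyline (point-to-segment, exact)
polyline_distance <- function(pts, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  out <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(a))) {
    dx <- b[s, 1] - a[s, 1]; dy <- b[s, 2] - a[s, 2]
    L2 <- dx^2 + dy^2
    t <- ((pts[, 1] - a[s, 1]) * dx + (pts[, 2] - a[s, 2]) * dy) / max(L2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((pts[, 1] - a[s, 1] - t * dx)^2 + (pts[, 2] - a[s, 2] - t * dy)^2)
    out <- pmin(out, d)
  }
  out
}
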