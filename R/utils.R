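#' @importFrom stats rnorm runif approx sd var median quantile shapiro.test t.test wilcox.test lm coef
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertices, not repeated at the end.
#' @return Signed area; positive for counterclockwise orientation.
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test for many points
#'
#' Thin wrapper around \code{mgcv::in.out}; boundary points are resolved by
#' that routine's crossing count, which downstream code treats as a tie
#' broken by region label order.
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

#' Evaluate a scoped RNG computation
#'
#' All generators funnel their randomness through this helper so that a
#' single integer seed fully determines the output and the caller's RNG
#' state is left untouched.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## distance from each point in `pts` to the nearest point of `ref`,
## computed in column chunks to bound memory for dense reference sets.
nearest_point_distance <- function(pts, ref, chunk = 4000L) {
  m <- nrow(pts)
  out <- rep(Inf, m)
  rx <- ref[, 1]; ry <- ref[, 2]
  for (s in seq(1L, nrow(ref), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ref))
    d2 <- outer(pts[, 1], rx[s:e], "-")^2 + outer(pts[, 2], ry[s:e], "-")^2
    out <- pmin(out, apply(d2, 1, min))
  }
  sqrt(out)
}

## resample an open polyline at (approximately) spacing h by arc length,
## always keeping both endpoints; closed=TRUE treats the input as a closed
## ring (first point not repeated) and returns n points without the
## duplicate closing vertex.
resample_polyline <- function(xy, spacing = NULL, n = NULL, closed = FALSE) {
  if (closed) xy <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(xy)^2))
  len <- c(0, cumsum(seg))
  total <- len[length(len)]
  if (is.null(n)) {
    n <- max(if (closed) 3L else 2L, round(total / spacing) + if (closed) 0L else 1L)
  }
  s <- if (closed) seq(0, total, length.out = n + 1L)[seq_len(n)] else
    seq(0, total, length.out = n)
  cbind(approx(len, xy[, 1], xout = s, ties = "ordered")$y,
        approx(len, xy[, 2], xout = s, ties = "ordered")$y)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
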