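#' Closed planar contours
#'
#' A contour is an ordered set of 2D points in micrometres with a role label.
#' Contours are stored counterclockwise; clockwise input is reversed on
#' construction. Consecutive duplicate points are collapsed.
#'
#' @param xy two-column numeric matrix of points (x, y in um).
#' @param role one of `"lumen"`, `"outer"`, `"region_boundary"`, `"auxiliary"`.
#' @param closed logical; open contours are supported only as auxiliaries.
#' @return An object of class `contour`.
#' @export
contour <- function(xy, role = c("auxiliary", "lumen", "outer", "region_boundary"),
                    closed = TRUE) {
  role <- match.arg(role)
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2) stop("contour points must be a two-column matrix")
  dup <- c(FALSE, rowSums(abs(diff(xy))) == 0)
  xy <- xy[!dup, , drop = FALSE]
  if (closed && nrow(xy) > 1 &&
      all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12)) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  if (nrow(xy) < 3) stop("a contour needs at least 3 distinct points")
  if (closed && polygon_area(xy) < 0) xy <- xy[nrow(xy):1, , drop = FALSE]
  structure(list(xy = xy, role = role, closed = closed), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> role=%s, %d points, %s\n", x$role, nrow(x$xy),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

contour_points <- function(c) if (inherits(c, "contour")) c$xy else as.matrix(c)

## chord-length parameterisation in [0, 1) for a closed contour
contour_parameter <- function(xy) {
  seg <- sqrt(rowSums((rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy)^2))
  len <- c(0, cumsum(seg))
  len[seq_len(nrow(xy))] / len[length(len)]
}

## One-dimensional biharmonic spline: radial basis |t - t_j|^3 with a linear
## polynomial tail. This is the 1D Green-function analogue of the biharmonic
## (thin-plate) interpolant and coincides with the natural cubic spline.
bi_spline_fit <- function(t, v) {
  m <- length(t)
  G <- abs(outer(t, t, "-"))^3
  A <- rbind(cbind(G, 1, t),
             c(rep(1, m), 0, 0),
             c(t, 0, 0))
  rhs <- c(v, 0, 0)
  coef <- solve(A, rhs)
  coef <- coef + solve(A, rhs - A %*% coef)   # one refinement step
  list(t = t, w = coef[seq_len(m)], c0 = coef[m + 1], c1 = coef[m + 2])
}

bi_spline_eval <- function(fit, tout, chunk = 2000L) {
  out <- numeric(length(tout))
  for (s in seq(1L, length(tout), by = chunk)) {
    e <- min(s + chunk - 1L, length(tout))
    G <- abs(outer(tout[s:e], fit$t, "-"))^3
    out[s:e] <- drop(G %*% fit$w) + fit$c0 + fit$c1 * tout[s:e]
  }
  out
}

#' Resample a closed contour with biharmonic spline interpolation
#'
#' Fits a periodic biharmonic (cubic radial basis) spline through the input
#' points, parameterised by normalised chord length, and evaluates it at `n`
#' equally spaced parameter values. The interpolant passes exactly through
#' every input point and preserves orientation. Periodicity is obtained by
#' replicating the data over three parameter periods before fitting.
#'
#' @param c a [contour()].
#' @param n number of output points; must be at least the input point count.
#' @param check_simple if `TRUE`, verify the result is non-self-intersecting
#'   (quadratic cost; intended for modest `n`).
#' @return A resampled [contour()] with `n` points.
#' @export
resample_contour_biharmonic <- function(c, n, check_simple = FALSE) {
  xy <- contour_points(c)
  m <- nrow(xy)
  if (n < m) stop("n must be >= the number of input points")
  t0 <- contour_parameter(xy)
  text <- c(t0 - 1, t0, t0 + 1)
  tout <- seq(0, 1, length.out = n + 1L)[seq_len(n)]
  ctr <- colMeans(xy)
  scl <- max(abs(sweep(xy, 2, ctr)), 1)
  out <- vapply(1:2, function(k) {
    v <- (xy[, k] - ctr[k]) / scl
    fit <- bi_spline_fit(text, rep(v, 3L))
    bi_spline_eval(fit, tout) * scl + ctr[k]
  }, numeric(n))
  res <- contour(out, role = if (inherits(c, "contour")) c$role else "auxiliary")
  if (check_simple && !contour_is_simple(res)) {
    stop("resampled contour is self-intersecting (input pathology)")
  }
  res
}

## brute-force segment intersection check; O(n^2), for diagnostics only
contour_is_simple <- function(c) {
  xy <- contour_points(c)
  n <- nrow(xy)
  p <- xy
  q <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    j <- j[!(i == 1L & j == n)]
    if (!length(j)) next
    d1 <- cross(q[i, 1] - p[i, 1], q[i, 2] - p[i, 2], p[j, 1] - p[i, 1], p[j, 2] - p[i, 2])
    d2 <- cross(q[i, 1] - p[i, 1], q[i, 2] - p[i, 2], q[j, 1] - p[i, 1], q[j, 2] - p[i, 2])
    d3 <- cross(q[j, 1] - p[j, 1], q[j, 2] - p[j, 2], p[i, 1] - p[j, 1], p[i, 2] - p[j, 2])
    d4 <- cross(q[j, 1] - p[j, 1], q[j, 2] - p[j, 2], q[i, 1] - p[j, 1], q[i, 2] - p[j, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Nearest-point RMSE between a moved contour and a dense target
#'
#' Root mean square, over the points of `moved`, of the Euclidean distance
#' to the nearest point of `target`. The target should be densely resampled
#' (at least ten times the moved point count) so that the nearest-point
#' distance approximates the distance to the target curve.
#'
#' @param moved,target contours or two-column point matrices (um).
#' @return RMSE in micrometres.
#' @export
contour_rmse <- function(moved, target) {
  d <- nearest_point_distance(contour_points(moved), contour_points(target))
  sqrt(mean(d^2))
}

#' Check that contour point ordering is preserved
#'
#' `TRUE` iff the angular sequence of `after`'s points about its centroid is
#' strictly monotone with the same winding sense as `before`. Registration
#' of strongly curved contours can fold the point order; this is the
#' corresponding acceptance check.
#'
#' @param before,after contours with equal point counts and common indexing.
#' @return logical flag.
#' @export
ordering_preserved <- function(before, after) {
  a <- contour_points(before); b <- contour_points(after)
  if (nrow(a) != nrow(b)) stop("contours must have equal point counts")
  sense <- function(xy) {
    ctr <- colMeans(xy)
    ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
    d <- diff(c(ang, ang[1]))
    d <- ((d + pi) %% (2 * pi)) - pi
    if (all(d > 0)) 1L else if (all(d < 0)) -1L else 0L
  }
  sb <- sense(a); sa <- sense(b)
  sb != 0L && sa == sb
}
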