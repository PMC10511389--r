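#' Warp parameter vector
#'
#' The 12-parameter affine warp used for direct deformation estimation.
#' Parameters 1-9 are the dimensionless entries of the deformation
#' gradient (laid out column-wise: column one is `1+p1, p2, p3`), and
#' parameters 10-12 are translations in voxels.
#'
#' @param p numeric vector of length 12.
#' @return Validated numeric parameter vector of class `warp_parameters`.
#' @export
warp_parameters <- function(p = rep(0, 12)) {
  p <- as.numeric(p)
  if (length(p) != 12 || any(!is.finite(p))) {
    stop("warp parameters must be 12 finite numbers")
  }
  structure(p, class = "warp_parameters")
}

#' Deformation gradient of an affine warp
#'
#' Reads the 3x3 deformation gradient off the first nine warp parameters:
#' row 1 is `(1+p1, p4, p7)`, row 2 `(p2, 1+p5, p8)`, row 3 `(p3, p6, 1+p9)`.
#' A non-positive determinant is flagged as non-physical via the
#' `physical` attribute (with a warning) since it does not correspond to an
#' orientation-preserving deformation.
#'
#' @param p a [warp_parameters()] vector.
#' @return 3x3 deformation gradient matrix with attribute `physical`.
#' @export
warp_to_deformation_gradient <- function(p) {
  p <- warp_parameters(p)
  Fm <- diag(3) + matrix(p[1:9], 3, 3)
  physical <- det(Fm) > 0
  if (!physical) warning("deformation gradient has non-positive determinant")
  structure(Fm, physical = physical)
}

## apply the affine warp about origin `center`, plus translation
warp_apply <- function(p, X, center = c(0, 0, 0)) {
  Fm <- diag(3) + matrix(as.numeric(p)[1:9], 3, 3)
  sweep(sweep(X, 2, center) %*% t(Fm), 2, center + as.numeric(p)[10:12], "+")
}

#' First principal Green-Lagrange strain of a deformation gradient
#'
#' Computes `E = (F'F - I)/2` and its symmetric eigendecomposition. Works
#' for 2x2 (in-plane) and 3x3 deformation gradients.
#'
#' @param F deformation gradient matrix with positive determinant.
#' @return List with `E1` (largest eigenvalue), `direction` (unit
#'   eigenvector of `E1`), `values`, `vectors` and the strain tensor `E`.
#' @export
green_lagrange_principal <- function(F) {
  F <- unclass(F)
  attributes(F)$physical <- NULL
  if (det(F) <= 0) stop("deformation gradient must have positive determinant")
  E <- (crossprod(F) - diag(nrow(F))) / 2
  eg <- eigen(E, symmetric = TRUE)
  list(E1 = eg$values[1], direction = eg$vectors[, 1],
       values = eg$values, vectors = eg$vectors, E = E)
}

## ---- cubic B-spline volume interpolation ------------------------------
##
## True interpolating cubic splines: the sample array is prefiltered into
## B-spline coefficients (tridiagonal solve per grid line), after which
## separable evaluation of the cubic B-spline basis reproduces the samples
## exactly and is fourth-order accurate for smooth intensities.

bspline_prefilter <- function(vol) {
  dm <- dim(vol)
  sys <- lapply(dm, function(n) {
    A <- diag(2 / 3, n)
    A[cbind(1:(n - 1), 2:n)] <- 1 / 6
    A[cbind(2:n, 1:(n - 1))] <- 1 / 6
    A[1, 1] <- A[n, n] <- 2 / 3 + 1 / 6   # mirror boundary
    solve(A)
  })
  v <- matrix(vol, dm[1], dm[2] * dm[3])
  v <- sys[[1]] %*% v
  v <- array(v, dm)
  v <- aperm(v, c(2, 1, 3))
  v <- array(sys[[2]] %*% matrix(v, dm[2], dm[1] * dm[3]), c(dm[2], dm[1], dm[3]))
  v <- aperm(v, c(2, 1, 3))
  v <- aperm(v, c(3, 2, 1))
  v <- array(sys[[3]] %*% matrix(v, dm[3], dm[2] * dm[1]), c(dm[3], dm[2], dm[1]))
  aperm(v, c(3, 2, 1))
}

cr_weights <- function(s, deriv = FALSE) {
  ## cubic B-spline basis for samples at offsets -1, 0, 1, 2 of floor(x)
  if (!deriv) {
    cbind((1 - s)^3 / 6,
          (3 * s^3 - 6 * s^2 + 4) / 6,
          (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
          s^3 / 6)
  } else {
    cbind(-(1 - s)^2 / 2,
          (9 * s^2 - 12 * s) / 6,
          (-9 * s^2 + 6 * s + 3) / 6,
          s^2 / 2)
  }
}

## sample a volume (and optionally its gradient) at fractional voxel
## coordinates; `coef` is the prefiltered coefficient array (computed here
## if not supplied). Points must lie within [2, n-1] on each axis, with a
## quarter-voxel extrapolation band (clamped stencil) so that windows
## whose warp grazes the border remain fittable.
interp_volume <- function(vol, pts, gradient = FALSE, coef = NULL) {
  dm <- dim(vol)
  if (is.null(coef)) coef <- bspline_prefilter(vol)
  vol <- coef
  if (any(pts < 1.75 - 1e-9) ||
      any(sweep(pts, 2, dm - 0.75) > 1e-9)) {
    stop("interpolation points outside the cubic-support domain")
  }
  i0 <- pmin(pmax(floor(pts), 2), matrix(dm - 2, nrow(pts), 3, byrow = TRUE))
  fr <- pts - i0
  w <- lapply(1:3, function(a) cr_weights(fr[, a]))
  dw <- if (gradient) lapply(1:3, function(a) cr_weights(fr[, a], deriv = TRUE)) else NULL
  val <- numeric(nrow(pts))
  gx <- gy <- gz <- if (gradient) numeric(nrow(pts)) else NULL
  nxy <- dm[1] * dm[2]
  for (a in 1:4) for (b in 1:4) {
    base_ab <- (i0[, 1] + a - 2L) + (i0[, 2] + b - 3L) * dm[1]
    wab <- w[[1]][, a] * w[[2]][, b]
    for (cc in 1:4) {
      idx <- base_ab + (i0[, 3] + cc - 3L) * nxy
      v <- vol[idx]
      val <- val + v * wab * w[[3]][, cc]
      if (gradient) {
        gx <- gx + v * dw[[1]][, a] * w[[2]][, b] * w[[3]][, cc]
        gy <- gy + v * w[[1]][, a] * dw[[2]][, b] * w[[3]][, cc]
        gz <- gz + v * wab * dw[[3]][, cc]
      }
    }
  }
  if (gradient) list(value = val, grad = cbind(gx, gy, gz)) else val
}

#' Estimate the affine warp between two volumes over a window
#'
#' Direct deformation estimation: finds the 12 warp parameters minimising
#' the sum of squared intensity differences between the reference window
#' and the target volume sampled through the warp, by Gauss-Newton
#' iteration with cubic intensity interpolation and step halving. The warp
#' acts about the volume centre, matching [generate_volume_pair()].
#'
#' @param pair a `volume_pair` (or list with `reference`, `target`).
#' @param window list with integer vectors `lo` and `hi` (inclusive voxel
#'   bounds); default is the central half of the volume. Window sides must
#'   be at least 8 voxels.
#' @param init starting [warp_parameters()].
#' @param max_iter,tol iteration cap and relative residual-change tolerance.
#' @param min_texture_var minimum intensity variance of the reference
#'   window; flat windows carry no deformation information and are refused.
#' @return List of class `warp_fit`: `p`, `residual` (root mean square
#'   intensity error), `converged`, `iterations`, `history`.
#' @export
estimate_warp <- function(pair, window = NULL, init = warp_parameters(),
                          max_iter = 200L, tol = 1e-8,
                          min_texture_var = 1e-8) {
  ref <- pair$reference; tgt <- pair$target
  dm <- dim(ref)
  stopifnot(all(dim(tgt) == dm))
  if (is.null(window)) {
    window <- list(lo = pmax(ceiling(dm * 0.25), 3), hi = floor(dm * 0.75))
  }
  if (any(window$hi - window$lo + 1 < 8)) stop("window side must be >= 8 voxels")
  if (any(window$lo < 2) || any(window$hi > dm - 1)) {
    stop("window must be interior to the volumes")
  }
  ctr <- (dm + 1) / 2
  grid <- as.matrix(expand.grid(x = seq.int(window$lo[1], window$hi[1]),
                                y = seq.int(window$lo[2], window$hi[2]),
                                z = seq.int(window$lo[3], window$hi[3])))
  rvals <- ref[cbind(grid[, 1], grid[, 2], grid[, 3])]
  if (var(rvals) < min_texture_var) {
    stop("reference window is texture-flat; warp is not identifiable")
  }
  xc <- sweep(grid, 2, ctr)

  p <- as.numeric(warp_parameters(init))
  history <- numeric(0)
  sample_res <- function(p) {
    wpts <- warp_apply(p, grid, center = ctr)
    if (any(wpts < 1.75) || any(sweep(wpts, 2, dm - 0.75) > 0)) return(NULL)
    wpts
  }
  tcoef <- bspline_prefilter(tgt)
  wpts <- sample_res(p)
  if (is.null(wpts)) stop("initial warp maps the window outside the volume")
  iv <- interp_volume(tgt, wpts, gradient = TRUE, coef = tcoef)
  r <- iv$value - rvals
  rss <- sum(r^2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- iv$grad
    J <- cbind(g[, 1] * xc[, 1], g[, 2] * xc[, 1], g[, 3] * xc[, 1],
               g[, 1] * xc[, 2], g[, 2] * xc[, 2], g[, 3] * xc[, 2],
               g[, 1] * xc[, 3], g[, 2] * xc[, 3], g[, 3] * xc[, 3],
               g)
    JtJ <- crossprod(J)
    delta <- tryCatch(solve(JtJ, -crossprod(J, r)),
                      error = function(e) solve(JtJ + diag(1e-8 * max(diag(JtJ)), 12),
                                                -crossprod(J, r)))
    step <- 1
    repeat {
      p_try <- p + step * drop(delta)
      wpts_try <- sample_res(p_try)
      if (!is.null(wpts_try)) {
        iv_try <- interp_volume(tgt, wpts_try, gradient = TRUE, coef = tcoef)
        r_try <- iv_try$value - rvals
        rss_try <- sum(r_try^2)
        if (rss_try <= rss) break
      }
      step <- step / 2
      if (step < 1e-6) { rss_try <- rss; p_try <- p; iv_try <- iv; r_try <- r; break }
    }
    improve <- (rss - rss_try) / max(rss, .Machine$double.eps)
    p <- p_try; iv <- iv_try; r <- r_try; rss <- rss_try
    history <- c(history, sqrt(rss / length(r)))
    if (improve < tol) { converged <- TRUE; break }
  }
  structure(list(p = warp_parameters(p), residual = sqrt(rss / length(r)),
                 converged = converged, iterations = it, history = history),
            class = "warp_fit")
}

#' Per-window first-principal strain field from a volume pair
#'
#' Tiles the foreground with overlapping cubic windows, estimates the
#' affine warp in each, and assigns the resulting first principal
#' Green-Lagrange strain to the window centre. Windows that fail (flat
#' texture, non-convergence, non-physical gradient) are masked.
#'
#' @param pair a `volume_pair`.
#' @param window_vox window side in voxels (default 16).
#' @param overlap fractional window overlap (default 0.5).
#' @param margin_frac fraction of each axis kept as a border margin, so
#'   that windows remain warpable without leaving the volume.
#' @param ... passed to [estimate_warp()].
#' @return List of class `strain_volume_field`: `E1` (3D array over window
#'   centres, `NA` where masked), `centers` (per-axis centre coordinates in
#'   voxels), `window_vox`, `n_failed`.
#' @export
strain_field_from_volumes <- function(pair, window_vox = 16L, overlap = 0.5,
                                      margin_frac = 0.06, ...) {
  dm <- dim(pair$reference)
  w <- as.integer(window_vox)
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- lapply(1:3, function(a) {
    m0 <- max(2L, as.integer(ceiling(margin_frac * dm[a])))
    s <- seq.int(m0, dm[a] - w - m0 + 2L, by = stride)
    if (length(s) == 0) max(2L, (dm[a] - w) %/% 2L) else s
  })
  centers <- lapply(starts, function(s) s + (w - 1) / 2)
  E1 <- array(NA_real_, dim = vapply(starts, length, integer(1)))
  nfail <- 0L
  for (i in seq_along(starts[[1]])) for (j in seq_along(starts[[2]]))
    for (k in seq_along(starts[[3]])) {
      lo <- c(starts[[1]][i], starts[[2]][j], starts[[3]][k])
      fit <- tryCatch(estimate_warp(pair, window = list(lo = lo, hi = lo + w - 1L), ...),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { nfail <- nfail + 1L; next }
      Fm <- diag(3) + matrix(as.numeric(fit$p)[1:9], 3, 3)
      if (det(Fm) <= 0) { nfail <- nfail + 1L; next }
      E1[i, j, k] <- green_lagrange_principal(Fm)$E1
    }
  if (all(is.na(E1))) stop("all windows failed; empty strain field")
  structure(list(E1 = E1, centers = centers, window_vox = w, n_failed = nfail),
            class = "strain_volume_field")
}
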