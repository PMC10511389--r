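#' Non-rigid coherent point drift registration of contours
#'
#' Registers an unloaded (histological) contour onto a loaded (in vivo)
#' contour with the non-rigid coherent point drift model: source-point
#' motion is a Gaussian-kernel-smoothed displacement field estimated by
#' EM, with kernel width `interaction_sigma` and regularisation weight
#' `smoothing_weight`. Source and target centroids are superimposed before
#' the EM iterations; that rigid shift is included in the reported
#' displacements. The target should be densely resampled (the analysis
#' default is 20,000 points) since registration quality is judged by
#' nearest-point RMSE against it.
#'
#' @param source source [contour()] (the histological geometry).
#' @param target target [contour()] or point matrix, densely resampled.
#' @param interaction_sigma Gaussian kernel width of the motion model (um).
#' @param smoothing_weight regularisation weight (dimensionless).
#' @param tol EM convergence tolerance on the relative change of the
#'   estimated variance.
#' @param max_iter iteration cap.
#' @param outlier_weight CPD outlier mass; 0 for closed clean contours.
#' @param sigma2_init initial Gaussian mixture variance (um^2). The
#'   default, twice the mean squared nearest-point distance after centroid
#'   alignment, suits pre-aligned contour pairs: it avoids the large
#'   tangential redistribution transient that the classical all-pairs
#'   initialisation produces on closed curves.
#' @return Object of class `registration_result` with elements `moved`
#'   (displaced contour), `displacement` (per-point, um), `rmse` (um),
#'   `steps_used`, `ordering_preserved`, `uniformity`, `converged`,
#'   `iterations`, `sigma2`.
#' @export
cpd_nonrigid <- function(source, target, interaction_sigma = 150,
                         smoothing_weight = 0.2, tol = 1e-7,
                         max_iter = 120L, outlier_weight = 0,
                         sigma2_init = NULL) {
  Y0 <- contour_points(source)
  X <- contour_points(target)
  M <- nrow(Y0); N <- nrow(X)
  if (max(dist(X[seq.int(1L, N, length.out = min(N, 50L)), ])) < 1e-9) {
    stop("degenerate target: all points coincide")
  }
  shift <- colMeans(X) - colMeans(Y0)
  Y <- sweep(Y0, 2, shift, "+")

  d2 <- outer(Y[, 1], Y[, 1], "-")^2 + outer(Y[, 2], Y[, 2], "-")^2
  G <- exp(-d2 / (2 * interaction_sigma^2))

  sigma2 <- sigma2_init %||%
    (2 * mean(nearest_point_distance(Y, X)^2) + 1e-6)
  sigma2 <- max(sigma2, 1e-12)
  W <- matrix(0, M, 2)
  Tm <- Y
  converged <- FALSE
  it <- 0L
  chunk <- 20000L
  while (it < max_iter) {
    it <- it + 1L
    ## E-step, accumulated over target chunks to bound memory
    P1 <- numeric(M); PX <- matrix(0, M, 2); Np <- 0; Exx <- 0
    cw <- if (outlier_weight > 0) {
      (outlier_weight / (1 - outlier_weight)) * M / N *
        (2 * pi * sigma2)
    } else 0
    for (s in seq(1L, N, by = chunk)) {
      e <- min(s + chunk - 1L, N)
      D <- outer(Tm[, 1], X[s:e, 1], "-")^2 + outer(Tm[, 2], X[s:e, 2], "-")^2
      num <- exp(-D / (2 * sigma2))
      den <- colSums(num) + cw + 1e-300
      Pc <- sweep(num, 2, den, "/")
      P1 <- P1 + rowSums(Pc)
      PX <- PX + Pc %*% X[s:e, , drop = FALSE]
      Np <- Np + sum(Pc)
      Exx <- Exx + sum(t(Pc) * rowSums(X[s:e, , drop = FALSE]^2))
    }
    ## M-step
    A <- G * P1 + diag(smoothing_weight * sigma2 + 1e-9, M)
    rhs <- PX - P1 * Y
    W <- solve(A, rhs)
    Tm <- Y + G %*% W
    sigma2_new <- (Exx - 2 * sum(PX * Tm) + sum(P1 * rowSums(Tm^2))) / (2 * Np)
    sigma2_new <- max(sigma2_new, 1e-14)
    if (abs(sigma2 - sigma2_new) / sigma2 < tol) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }

  moved <- contour(Tm, role = if (inherits(source, "contour")) source$role else "auxiliary")
  disp <- Tm - Y0
  res <- structure(list(
    moved = moved, displacement = disp,
    rmse = contour_rmse(Tm, X), steps_used = 1L,
    ordering_preserved = ordering_preserved(Y0, Tm),
    uniformity = uniformity_score(Tm),
    converged = converged, iterations = it, sigma2 = sigma2),
    class = "registration_result")
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rmse=%.4g um, steps=%d, ordering %s, uniformity %.2f\n",
              x$rmse, x$steps_used, if (x$ordering_preserved) "preserved" else "BROKEN",
              x$uniformity))
  invisible(x)
}

#' Arc-length uniformity of a registered contour
#'
#' One minus the coefficient of variation of consecutive point spacings
#' (clipped at zero). A perfectly evenly registered contour scores 1;
#' the validation gate requires the score to stay above a floor,
#' operationalising the requirement that source points be registered as
#' evenly as possible onto the target.
#' @param c contour or point matrix.
#' @return score in \[0, 1\].
#' @export
uniformity_score <- function(c) {
  xy <- contour_points(c)
  seg <- sqrt(rowSums((rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy)^2))
  max(0, 1 - sd(seg) / mean(seg))
}

#' Programmatic auxiliary contours between a source and a target
#'
#' Linear blends between the source contour and an equal-count resampling
#' of the target, at the given fractions, replacing manually drawn
#' intermediate contours in multi-step registration.
#'
#' @param source contour with M points.
#' @param target dense target contour.
#' @param fractions blend fractions in (0, 1), ordered source-like to
#'   target-like.
#' @return List of auxiliary [contour()]s.
#' @export
make_auxiliary_contours <- function(source, target, fractions = c(1 / 3, 2 / 3)) {
  S <- contour_points(source)
  Xd <- contour_points(target)
  M <- nrow(S)
  ## equal-count arc-length resampling of the target, phase-aligned to the
  ## source's first point and matching its orientation
  Tr <- resample_polyline(Xd, n = M, closed = TRUE)
  if (polygon_area(S) * polygon_area(Tr) < 0) Tr <- Tr[nrow(Tr):1, , drop = FALSE]
  ctrS <- colMeans(S); ctrT <- colMeans(Tr)
  Tc <- sweep(Tr, 2, ctrT)
  S1 <- S[1, ] - ctrS
  start <- which.min((Tc[, 1] - S1[1])^2 + (Tc[, 2] - S1[2])^2)
  Tr <- Tr[c(start:M, seq_len(start - 1L)), , drop = FALSE]
  Talign <- sweep(sweep(Tr, 2, ctrT), 2, ctrS, "+")
  lapply(fractions, function(f) {
    contour((1 - f) * S + f * Talign, role = "auxiliary")
  })
}

#' Multi-step coherent point drift registration
#'
#' Chains [cpd_nonrigid()] through a ladder of auxiliary contours (ordered
#' from source-like to target-like), each step starting from the previous
#' displaced contour; contours whose alternation of concave and convex
#' segments defeats single-step registration are handled this way. The
#' total displacement is the per-point sum over steps.
#'
#' @param source,target as in [cpd_nonrigid()].
#' @param auxiliaries ordered list of auxiliary contours, or `NULL` to use
#'   none (single-step registration). Auxiliary targets are densified to
#'   `aux_density` points before use.
#' @param aux_density point count for densified auxiliary targets.
#' @param ... passed to every [cpd_nonrigid()] call.
#' @return A `registration_result`; `steps_used` counts the chained calls.
#' @export
multistep_register <- function(source, target, auxiliaries = NULL,
                               aux_density = 5000L, ...) {
  targets <- c(lapply(auxiliaries %||% list(), function(a) {
    a <- if (inherits(a, "contour")) a else contour(a)
    if (nrow(contour_points(a)) < aux_density) {
      resample_contour_biharmonic(a, aux_density)
    } else a
  }), list(target))
  current <- source
  total <- matrix(0, nrow(contour_points(source)), 2)
  last <- NULL
  for (k in seq_along(targets)) {
    r <- cpd_nonrigid(current, targets[[k]], ...)
    if (!r$ordering_preserved) {
      stop("point ordering broken at registration step ", k)
    }
    total <- total + r$displacement
    current <- r$moved
    last <- r
  }
  last$displacement <- total
  last$moved <- current
  last$steps_used <- length(targets)
  last$rmse <- contour_rmse(current, target)
  last$ordering_preserved <- ordering_preserved(source, current)
  last$uniformity <- uniformity_score(current)
  last
}

#' Registration acceptance gate
#'
#' A registration is accepted when its nearest-point RMSE is below the
#' role-specific threshold (0.2 um for lumen contours, 0.75 um for outer
#' wall contours), point ordering is preserved, and the arc-length
#' uniformity score is above the configured floor.
#'
#' @param r a `registration_result`.
#' @param role `"lumen"` or `"outer"`.
#' @param thresholds named RMSE thresholds (um).
#' @param uniformity_floor minimum uniformity score.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty when passing).
#' @export
validate_registration <- function(r, role = c("lumen", "outer"),
                                  thresholds = c(lumen = 0.2, outer = 0.75),
                                  uniformity_floor = 0.5) {
  role <- match.arg(role)
  reasons <- character(0)
  if (!(r$rmse < thresholds[[role]])) {
    reasons <- c(reasons, sprintf("rmse %.3g um exceeds %s threshold %.3g um",
                                  r$rmse, role, thresholds[[role]]))
  }
  if (!isTRUE(r$ordering_preserved)) {
    reasons <- c(reasons, "contour point ordering not preserved")
  }
  if (!(r$uniformity > uniformity_floor)) {
    reasons <- c(reasons, sprintf("uniformity %.2f below floor %.2f",
                                  r$uniformity, uniformity_floor))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
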