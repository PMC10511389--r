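#' Tissue region sets
#'
#' A `tissue_region_set` describes the partition of a vessel-wall cross
#' section into labelled tissue regions (A1 intact elastin without thrombus,
#' A2 intact elastin with thrombus attachment, A3 fragmented elastin,
#' A4 thrombus with red blood cells, A5 thrombus without RBCs). The
#' geometry is stored as shared boundary polylines ("chains") plus, per
#' region, the ordered chain loop that bounds it. Shared storage guarantees
#' that neighbouring regions agree exactly on their common interface, which
#' the conforming mesher relies on.
#'
#' @param chains list of two-column matrices (open polylines, um); chains
#'   that form a complete ring on their own are marked in `closed`.
#' @param regions named list; each element is a data.frame with columns
#'   `chain` (index into `chains`) and `rev` (logical, traverse reversed),
#'   in counterclockwise loop order.
#' @param lumen_chains,outer_chains indices of the chains lying on the
#'   lumen / outer wall boundary.
#' @param closed logical vector, one per chain.
#' @return An object of class `tissue_region_set`.
#' @export
tissue_region_set <- function(chains, regions, lumen_chains, outer_chains,
                              closed = rep(FALSE, length(chains))) {
  stopifnot(length(closed) == length(chains), length(regions) >= 1)
  structure(list(chains = chains, regions = regions, closed = closed,
                 lumen_chains = lumen_chains, outer_chains = outer_chains),
            class = "tissue_region_set")
}

#' @export
print.tissue_region_set <- function(x, ...) {
  cat(sprintf("<tissue_region_set> %d regions (%s), %d chains\n",
              length(x$regions), paste(names(x$regions), collapse = ", "),
              length(x$chains)))
  invisible(x)
}

#' Closed polygon of one region of a tissue region set
#'
#' @param ts a [tissue_region_set()].
#' @param label region label.
#' @return Two-column matrix of the region's closed boundary polygon
#'   (counterclockwise, closing vertex not repeated).
#' @export
region_polygon <- function(ts, label) {
  loop <- ts$regions[[label]]
  if (is.null(loop)) stop("no region labelled ", label)
  if (nrow(loop) == 1L && isTRUE(ts$closed[loop$chain[1]])) {
    p <- ts$chains[[loop$chain[1]]]
    if (loop$rev[1]) p <- p[nrow(p):1, , drop = FALSE]
    return(p)           # already a full ring without the closing vertex
  }
  parts <- lapply(seq_len(nrow(loop)), function(i) {
    p <- ts$chains[[loop$chain[i]]]
    if (loop$rev[i]) p <- p[nrow(p):1, , drop = FALSE]
    p[-nrow(p), , drop = FALSE]  # junction point owned by the next chain
  })
  do.call(rbind, parts)
}

## full lumen / outer ring polygons (counterclockwise)
boundary_ring <- function(ts, which = c("lumen", "outer")) {
  which <- match.arg(which)
  ids <- if (which == "lumen") ts$lumen_chains else ts$outer_chains
  ring <- do.call(rbind, lapply(ids, function(i) {
    p <- ts$chains[[i]]
    p[-nrow(p), , drop = FALSE]
  }))
  if (length(ids) == 1L && ts$closed[ids[1]]) ring <- ts$chains[[ids[1]]]
  if (polygon_area(ring) < 0) ring <- ring[nrow(ring):1, , drop = FALSE]
  ring
}

region_areas <- function(ts) {
  vapply(names(ts$regions), function(l) abs(polygon_area(region_polygon(ts, l))),
         numeric(1))
}

apply_displacement <- function(ts, u) {
  ts$chains <- lapply(ts$chains, function(p) p + u(p))
  ts
}

#' Phantom geometry parameters
#'
#' Defaults emulate the cross sections of the murine dissecting-aneurysm
#' study that motivates this package: a roughly annular wall with a lumen
#' diameter of about 1,000 um, partitioned into sector-like tissue regions,
#' and a smooth diastole-to-systole boundary motion of a few percent of the
#' radius.
#'
#' @param lumen_diameter_um lumen diameter (um).
#' @param wall_thickness_um wall thickness (um).
#' @param proportions named nonnegative vector of target area fractions for
#'   the present regions; must sum to 1.
#' @param deformation_amplitude_um maximum boundary displacement (um).
#' @param smoothness dimensionless; values above 1 damp the higher angular
#'   modes of the boundary deformation.
#' @param lumen_wobble relative amplitude of the radial perturbation that
#'   keeps the lumen/outer contours from being perfect circles.
#' @param angle_jitter_sd standard deviation (radians) of the perturbation
#'   of the internal sector boundary angles.
#' @param chain_spacing_um sampling density of the stored boundary chains.
#' @return Parameter list of class `phantom_geometry`.
#' @export
phantom_geometry <- function(lumen_diameter_um = 1000,
                             wall_thickness_um = 200,
                             proportions = c(A1 = 0.25, A2 = 0.15, A3 = 0.15,
                                             A4 = 0.20, A5 = 0.25),
                             deformation_amplitude_um = 40,
                             smoothness = 1,
                             lumen_wobble = 0.03,
                             angle_jitter_sd = 0.01 * pi,
                             chain_spacing_um = 4) {
  if (lumen_diameter_um <= 0) stop("lumen_diameter_um must be > 0")
  if (wall_thickness_um <= 0) stop("wall_thickness_um must be > 0")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("proportions must be named by region label")
  structure(as.list(environment()), class = "phantom_geometry")
}

## Ground-truth interior deformation. Every component below is an exact
## equilibrium displacement field of homogeneous isotropic linear
## elasticity for arbitrary Poisson ratio:
##   - affine fields M x + c                 (homogeneous deformation),
##   - the Lame annulus fields x/r^2 and x_perp/r^2,
##   - curl fields of harmonic stream functions Re(c z^n), Re(d z^-n).
## The finite-element recovery test is therefore well posed: at moderate
## strain the nonlinear solution differs from this field only by
## finite-deformation corrections.
make_displacement_field <- function(coef) {
  force(coef)
  function(xy) {
    xy <- as.matrix(xy)
    x <- xy[, 1]; y <- xy[, 2]
    z <- complex(real = x, imaginary = y)
    r2 <- pmax(x^2 + y^2, 1e-12)
    L2 <- coef$L0^2
    u1 <- coef$M[1, 1] * x + coef$M[1, 2] * y + coef$trans[1] * coef$L0 +
      coef$b * L2 * x / r2 - coef$g * L2 * y / r2
    u2 <- coef$M[2, 1] * x + coef$M[2, 2] * y + coef$trans[2] * coef$L0 +
      coef$b * L2 * y / r2 + coef$g * L2 * x / r2
    if (nrow(coef$modes) > 0) {
      gp <- 0 + 0i
      for (i in seq_len(nrow(coef$modes))) {
        n <- coef$modes$n[i]
        cc <- complex(real = coef$modes$cre[i], imaginary = coef$modes$cim[i])
        dd <- complex(real = coef$modes$dre[i], imaginary = coef$modes$dim[i])
        gp <- gp + cc * (z / coef$Ro)^(n - 1) + dd * (coef$Ri / z)^(n + 1)
      }
      u1 <- u1 - Im(gp)
      u2 <- u2 - Re(gp)
    }
    matrix(c(u1, u2), ncol = 2) * coef$scale
  }
}

#' Generate a synthetic vessel cross-section phantom
#'
#' Builds an annular wall partitioned into perturbed angular sectors with
#' the requested area proportions, draws a smooth nonrigid unloaded-to-
#' loaded boundary deformation with known interior continuation, and
#' attaches a region-coded synthetic strain field on the deformed domain.
#' The interior displacement field is composed of closed-form equilibrium
#' solutions of annulus elasticity (see the methods vignette), so the
#' finite-element mapping stage can be validated against it.
#'
#' @param geometry a [phantom_geometry()] parameter set.
#' @param seed integer seed; the phantom is a pure function of
#'   `(geometry, seed)`.
#' @param region_levels named mean strain per region for the attached
#'   synthetic strain field (dimensionless E1).
#' @param noise_sd,resolution_um strain-field noise level and voxel size.
#' @return An object of class `phantom` with elements
#'   `undeformed_regions`, `deformed_regions`, `deformed_lumen`,
#'   `deformed_outer`, `displacement` (vectorised function of an n-by-2
#'   point matrix), `strain_field`, `coefficients`, `seed`, `geometry`.
#' @export
generate_cross_section_phantom <- function(geometry = phantom_geometry(),
                                           seed = 1L,
                                           region_levels = NULL,
                                           noise_sd = 0.02,
                                           resolution_um = 40) {
  g <- geometry
  Ri <- g$lumen_diameter_um / 2
  Ro <- Ri + g$wall_thickness_um
  labs <- names(g$proportions)
  K <- length(labs)

  st <- with_seed(seed, {
    theta0 <- runif(1, 0, 2 * pi)
    cum <- cumsum(g$proportions) / sum(g$proportions)
    bnd <- 2 * pi * c(0, cum)
    if (K > 1) {
      jit <- rnorm(K - 1, 0, g$angle_jitter_sd)
      bnd[2:K] <- bnd[2:K] + jit
      if (any(diff(bnd) <= 0.05)) stop("proportions produce a degenerate sector")
    }
    wob <- function() list(a = g$lumen_wobble * runif(4, 0.5, 1) * 2 / c(2, 3, 4, 5),
                           ph = runif(4, 0, 2 * pi))
    wl <- wob(); wo <- wob()
    M <- matrix(rnorm(4, 0, 1), 2, 2)
    Msym <- (M + t(M)) / 2 * 0.6
    rot <- (M[2, 1] - M[1, 2]) / 2 * 0.05
    coef <- list(
      M = Msym + matrix(c(0, rot, -rot, 0), 2, 2),
      trans = rnorm(2, 0, 0.5),
      b = rnorm(1), g = rnorm(1, 0, 0.5),
      modes = data.frame(n = c(2L, 3L),
                         cre = rnorm(2, 0, 1) / c(2, 3)^2 / g$smoothness,
                         cim = rnorm(2, 0, 1) / c(2, 3)^2 / g$smoothness,
                         dre = rnorm(2, 0, 1) / c(2, 3)^2 / g$smoothness,
                         dim = rnorm(2, 0, 1) / c(2, 3)^2 / g$smoothness),
      L0 = Ri, Ri = Ri, Ro = Ro, scale = 1)
    list(bnd = bnd, theta0 = theta0, wl = wl, wo = wo, coef = coef)
  })

  wsum <- function(w, th) {
    out <- 1
    for (j in 1:4) out <- out + w$a[j] * cos((j + 1) * th + w$ph[j])
    out
  }
  r_lumen <- function(th) Ri * wsum(st$wl, th)
  r_outer <- function(th) Ro * wsum(st$wo, th)
  pt <- function(r, th) cbind(r * cos(th + st$theta0), r * sin(th + st$theta0))

  ## boundary node at each sector angle, shared exactly between chains
  lum_node <- lapply(st$bnd, function(a) pt(r_lumen(a), a))
  out_node <- lapply(st$bnd, function(a) pt(r_outer(a), a))

  arc <- function(rfun, a0, a1, nodes0, nodes1) {
    n <- max(2L, ceiling((a1 - a0) * (Ri + Ro) / 2 / g$chain_spacing_um))
    th <- seq(a0, a1, length.out = n + 1L)
    p <- pt(rfun(th), th)
    p[1, ] <- nodes0; p[nrow(p), ] <- nodes1
    p
  }
  radial <- function(a, p0, p1) {
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / g$chain_spacing_um))
    s <- seq(0, 1, length.out = n + 1L)
    cbind(p0[1] + s * (p1[1] - p0[1]), p0[2] + s * (p1[2] - p0[2]))
  }

  chains <- list(); closed <- logical(0)
  lum_id <- out_id <- rad_id <- integer(K + 1L)
  for (k in seq_len(K)) {
    chains[[length(chains) + 1L]] <-
      arc(r_lumen, st$bnd[k], st$bnd[k + 1], lum_node[[k]], lum_node[[k + 1]])
    lum_id[k] <- length(chains); closed <- c(closed, FALSE)
    chains[[length(chains) + 1L]] <-
      arc(r_outer, st$bnd[k], st$bnd[k + 1], out_node[[k]], out_node[[k + 1]])
    out_id[k] <- length(chains); closed <- c(closed, FALSE)
  }
  for (k in seq_len(K + 1L)) {
    if (k == K + 1L) { rad_id[k] <- rad_id[1]; break }
    chains[[length(chains) + 1L]] <- radial(st$bnd[k], lum_node[[k]], out_node[[k]])
    rad_id[k] <- length(chains); closed <- c(closed, FALSE)
  }
  ## the ring closes: last sector boundary is the first
  ## counterclockwise loop: up the leading radial interface, along the
  ## outer arc, down the trailing interface, back along the lumen arc
  regions <- stats::setNames(lapply(seq_len(K), function(k) {
    data.frame(chain = c(rad_id[k], out_id[k], rad_id[k + 1L], lum_id[k]),
               rev = c(FALSE, FALSE, TRUE, TRUE))
  }), labs)
  und <- tissue_region_set(chains, regions, lumen_chains = lum_id[seq_len(K)],
                           outer_chains = out_id[seq_len(K)], closed = closed)

  ## scale the deformation field to the requested boundary amplitude
  coef <- st$coef
  ufield0 <- make_displacement_field(coef)
  bpts <- rbind(boundary_ring(und, "lumen"), boundary_ring(und, "outer"))
  umax <- max(sqrt(rowSums(ufield0(bpts)^2)))
  coef$scale <- if (umax > 0) g$deformation_amplitude_um / umax else 0
  ufield <- make_displacement_field(coef)

  ## feasibility: the deformed wall must keep positive thickness and the
  ## deformation gradient must stay invertible
  def_l <- boundary_ring(und, "lumen"); def_l <- def_l + ufield(def_l)
  def_o <- boundary_ring(und, "outer"); def_o <- def_o + ufield(def_o)
  gap <- min(nearest_point_distance(def_l, def_o))
  h <- 1e-3 * Ri
  probe <- pt(rep(c(Ri, (Ri + Ro) / 2, Ro), each = 72), rep(seq(0, 2 * pi, length.out = 73)[-73], 3))
  gradmax <- max(abs(cbind((ufield(cbind(probe[, 1] + h, probe[, 2])) -
                              ufield(cbind(probe[, 1] - h, probe[, 2]))) / (2 * h),
                           (ufield(cbind(probe[, 1], probe[, 2] + h)) -
                              ufield(cbind(probe[, 1], probe[, 2] - h))) / (2 * h))))
  if (gap <= 1 || gradmax >= 0.6) {
    stop("infeasible geometry: deformation_amplitude_um = ",
         g$deformation_amplitude_um,
         " collapses the wall (deformed thickness or gradient out of range)")
  }

  def <- apply_displacement(und, ufield)

  if (is.null(region_levels)) {
    base <- c(A1 = 0.12, A2 = 0.055, A3 = 0.05, A4 = 0.10, A5 = 0.035)
    region_levels <- base[labs]
    region_levels[is.na(region_levels)] <- 0.05
    names(region_levels) <- labs
  }
  sf <- generate_strain_field(def, region_levels = region_levels,
                              noise_sd = noise_sd,
                              resolution_um = resolution_um, seed = seed)

  structure(list(undeformed_regions = und, deformed_regions = def,
                 deformed_lumen = contour(def_l, role = "lumen"),
                 deformed_outer = contour(def_o, role = "outer"),
                 displacement = ufield, coefficients = coef,
                 strain_field = sf, region_levels = region_levels,
                 seed = as.integer(seed), geometry = g),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed=%d, %d regions, lumen diameter %g um, amplitude %g um\n",
              x$seed, length(x$undeformed_regions$regions),
              x$geometry$lumen_diameter_um, x$geometry$deformation_amplitude_um))
  invisible(x)
}
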