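#' Strain fields on a voxel grid
#'
#' @param values matrix of first-principal Green-Lagrange strain values
#'   (`NA` outside the measured domain); rows index x, columns index y.
#' @param origin coordinates (um) of the lower-left corner of voxel (1, 1).
#' @param resolution_um voxel edge length (um).
#' @return Object of class `strain_field`.
#' @export
strain_field <- function(values, origin = c(0, 0), resolution_um = 40) {
  stopifnot(is.matrix(values), resolution_um > 0)
  structure(list(values = values, mask = !is.na(values),
                 origin = as.numeric(origin),
                 resolution_um = resolution_um),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d x %d voxels at %g um, %d defined\n",
              nrow(x$values), ncol(x$values), x$resolution_um, sum(x$mask)))
  invisible(x)
}

## centres of all voxels, as an n-by-2 matrix in field row-major order
strain_field_centers <- function(f) {
  nx <- nrow(f$values); ny <- ncol(f$values)
  cbind(f$origin[1] + (rep(seq_len(nx), ny) - 0.5) * f$resolution_um,
        f$origin[2] + (rep(seq_len(ny), each = nx) - 0.5) * f$resolution_um)
}

#' Generate a region-coded synthetic strain field
#'
#' Every voxel whose centre falls inside a region receives that region's
#' mean strain level plus zero-mean Gaussian noise, clipped at zero from
#' below; voxels outside all regions are flagged missing. The voxel size
#' defaults to the 40 um isotropic resolution of the volumetric imaging the
#' analysis is designed around.
#'
#' @param deformed_regions a [tissue_region_set()] in the deformed frame.
#' @param region_levels named mean strain per region, within \[0, 0.5\].
#' @param noise_sd noise standard deviation (dimensionless strain).
#' @param resolution_um voxel size (um).
#' @param seed integer seed.
#' @return A [strain_field()].
#' @export
generate_strain_field <- function(deformed_regions, region_levels,
                                  noise_sd = 0.02, resolution_um = 40,
                                  seed = 1L) {
  if (!inherits(deformed_regions, "tissue_region_set") ||
      length(deformed_regions$regions) == 0) {
    stop("deformed_regions must be a non-empty tissue_region_set")
  }
  if (resolution_um <= 0) stop("resolution_um must be > 0")
  if (any(region_levels < 0 | region_levels > 0.5))
    stop("region_levels must lie within [0, 0.5]")
  labs <- names(deformed_regions$regions)
  if (!all(labs %in% names(region_levels)))
    stop("region_levels must cover every region label")

  ring <- boundary_ring(deformed_regions, "outer")
  lo <- apply(ring, 2, min) - resolution_um
  hi <- apply(ring, 2, max) + resolution_um
  nx <- ceiling((hi[1] - lo[1]) / resolution_um)
  ny <- ceiling((hi[2] - lo[2]) / resolution_um)
  ctr <- cbind(lo[1] + (rep(seq_len(nx), ny) - 0.5) * resolution_um,
               lo[2] + (rep(seq_len(ny), each = nx) - 0.5) * resolution_um)

  assign <- rep(NA_integer_, nrow(ctr))
  for (k in seq_along(labs)) {       # label order is the boundary tie-break
    free <- is.na(assign)
    if (!any(free)) break
    inside <- points_in_polygon(ctr[free, , drop = FALSE],
                                region_polygon(deformed_regions, labs[k]))
    assign[which(free)[inside]] <- k
  }

  vals <- with_seed(seed, {
    v <- rep(NA_real_, nrow(ctr))
    idx <- which(!is.na(assign))
    noise <- if (noise_sd > 0) rnorm(length(idx), 0, noise_sd) else numeric(length(idx))
    v[idx] <- pmax(region_levels[labs[assign[idx]]] + noise, 0)
    v
  })
  strain_field(matrix(vals, nx, ny), origin = lo, resolution_um = resolution_um)
}

#' Generate a reference/target volume pair related by an affine warp
#'
#' The reference volume is a smooth, feature-rich Gaussian-blob texture
#' evaluated analytically on the voxel grid; the target is the same
#' analytic texture resampled through the inverse of the affine warp
#' parameterised by `p`, so that warping the target forward by `p` exactly
#' reproduces the reference. The warp acts about the volume centre.
#'
#' @param shape integer voxel triple, at least 16 per axis.
#' @param p warp parameter 12-vector (see [warp_parameters()]).
#' @param noise_sd intensity noise as a fraction of the texture's standard
#'   deviation.
#' @param seed integer seed.
#' @param blob_sigma_vox texture feature size in voxels.
#' @param blobs_per_1000_vox texture feature density.
#' @return Object of class `volume_pair` with elements `reference`,
#'   `target`, `voxel_size_um`, `p_true`, `center`.
#' @export
generate_volume_pair <- function(shape = c(32L, 32L, 32L), p = rep(0, 12),
                                 noise_sd = 0, seed = 1L,
                                 blob_sigma_vox = 2.2,
                                 blobs_per_1000_vox = 8) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16)) stop("shape must be >= 16 per axis")
  p <- warp_parameters(p)
  Fm <- warp_to_deformation_gradient(p)
  tvec <- p[10:12]
  ctr <- (shape + 1) / 2

  ## central test window must stay inside the domain under the warp
  win <- as.matrix(expand.grid(x = c(0.25, 0.75) * shape[1],
                               y = c(0.25, 0.75) * shape[2],
                               z = c(0.25, 0.75) * shape[3]))
  wc <- sweep(sweep(win, 2, ctr) %*% t(Fm), 2, ctr + tvec, "+")
  if (any(wc < 2) || any(sweep(wc, 2, shape - 1) > 0)) {
    stop("warp maps the central test window outside the volume domain")
  }

  nb <- max(20L, round(blobs_per_1000_vox * prod(shape) / 1000))
  blobs <- with_seed(seed, {
    list(c = cbind(runif(nb, -2, shape[1] + 2),
                   runif(nb, -2, shape[2] + 2),
                   runif(nb, -2, shape[3] + 2)),
         a = runif(nb, 0.5, 1) * sample(c(-1, 1), nb, replace = TRUE),
         s = runif(nb, 0.85, 1.25) * blob_sigma_vox)
  })
  texture <- function(pts) {
    out <- numeric(nrow(pts))
    for (k in seq_len(nb)) {
      d2 <- (pts[, 1] - blobs$c[k, 1])^2 + (pts[, 2] - blobs$c[k, 2])^2 +
        (pts[, 3] - blobs$c[k, 3])^2
      out <- out + blobs$a[k] * exp(-d2 / (2 * blobs$s[k]^2))
    }
    out
  }

  grid <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                z = seq_len(shape[3])))
  ref <- array(texture(grid), dim = shape)
  Finv <- solve(Fm)
  back <- sweep(sweep(grid, 2, ctr + tvec) %*% t(Finv), 2, ctr, "+")
  tgt <- array(texture(back), dim = shape)
  if (noise_sd > 0) {
    s <- sd(ref) * noise_sd
    noise <- with_seed(seed + 1L, rnorm(length(tgt), 0, s))
    tgt <- tgt + array(noise, dim = shape)
  }
  structure(list(reference = ref, target = tgt, voxel_size_um = 40,
                 p_true = p, center = ctr),
            class = "volume_pair")
}

#' Generate paired AAA-like and non-AAA-like strain sample groups
#'
#' Per-specimen strain-value samples from two skewed families emulating the
#' study's group structure: aneurysmal-like specimens draw from a shifted
#' log-normal (right-skewed: many small strains, a long tail of few large
#' ones, low mean, high heterogeneity), non-aneurysmal-like specimens from
#' a reflected log-normal (left-skewed: majority of large strains). A small
#' common "hotspot" component with an identical law in both groups models
#' the observation that peak local strains are similar in all animals, so
#' the maximum is not expected to separate the groups.
#'
#' @param n_aaa,n_non_aaa specimen counts (>= 1).
#' @param skew_magnitude multiplies the log-scale widths of both families.
#' @param seed integer seed.
#' @param samples_per_specimen strain values per specimen.
#' @return List with elements `aaa` and `non_aaa`, each of class
#'   `group_dataset`: a list of per-specimen sample vectors plus metadata.
#' @export
generate_group_dataset <- function(n_aaa = 5L, n_non_aaa = 3L,
                                   skew_magnitude = 1, seed = 1L,
                                   samples_per_specimen = 2000L) {
  if (n_aaa < 1 || n_non_aaa < 1) stop("specimen counts must be >= 1")
  n <- as.integer(samples_per_specimen)
  k_hot <- max(1L, round(0.002 * n))
  hotspot <- function() rnorm(k_hot, 0.32, 0.01)
  draw_aaa <- function() {
    scale <- 0.02 * exp(rnorm(1, 0, 0.15))
    v <- scale * exp(rnorm(n - k_hot, 0, 0.6 * skew_magnitude))
    pmax(c(v, hotspot()), -0.49)
  }
  draw_non <- function() {
    scale <- 0.186 * exp(rnorm(1, 0, 0.05))
    v <- 0.30 - scale * exp(rnorm(n - k_hot, 0, 0.25 * skew_magnitude))
    pmax(c(v, hotspot()), -0.49)
  }
  with_seed(seed, {
    aaa <- lapply(seq_len(n_aaa), function(i) draw_aaa())
    non <- lapply(seq_len(n_non_aaa), function(i) draw_non())
    list(aaa = structure(list(samples = aaa, group = "AAA-like",
                              seed = as.integer(seed)),
                         class = "group_dataset"),
         non_aaa = structure(list(samples = non, group = "non-AAA-like",
                                  seed = as.integer(seed)),
                             class = "group_dataset"))
  })
}
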