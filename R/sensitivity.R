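#' Dice similarity index of two areas
#'
#' Percentile overlap `SI = 2 |A intersect B| / (|A| + |B|) * 100`,
#' computed by counting raster pixels at the stated resolution, so that
#' the two pixel counts play the roles of the two contour areas being
#' compared.
#'
#' @param a,b closed polygons (two-column matrices or [contour()]s) in a
#'   common frame.
#' @param resolution_um raster pixel size (um); 1 um is far below the
#'   contour feature size of the cross sections this is used for.
#' @return Similarity index in percent.
#' @export
dice_similarity <- function(a, b, resolution_um = 1) {
  pa <- contour_points(a); pb <- contour_points(b)
  lo <- pmin(apply(pa, 2, min), apply(pb, 2, min)) - resolution_um
  hi <- pmax(apply(pa, 2, max), apply(pb, 2, max)) + resolution_um
  nx <- ceiling((hi[1] - lo[1]) / resolution_um)
  ny <- ceiling((hi[2] - lo[2]) / resolution_um)
  ina <- logical(nx * ny); inb <- logical(nx * ny)
  ## row-block rasterisation bounds memory at large extents
  rows_per_block <- max(1L, floor(4e6 / nx))
  for (j0 in seq(1L, ny, by = rows_per_block)) {
    j1 <- min(j0 + rows_per_block - 1L, ny)
    ctr <- cbind(lo[1] + (rep(seq_len(nx), j1 - j0 + 1L) - 0.5) * resolution_um,
                 lo[2] + (rep(j0:j1, each = nx) - 0.5) * resolution_um)
    idx <- (j0 - 1L) * nx + seq_len(nx * (j1 - j0 + 1L))
    ina[idx] <- points_in_polygon(ctr, pa)
    inb[idx] <- points_in_polygon(ctr, pb)
  }
  pc <- sum(ina); pv <- sum(inb)
  if (pc + pv == 0) {
    warning("both areas empty at this resolution; similarity undefined")
    return(NA_real_)
  }
  2 * sum(ina & inb) / (pc + pv) * 100
}

#' Material-parameter sensitivity of the region mapping
#'
#' The central methodological check of the mapping pipeline: because the
#' boundary displacement is fully prescribed and no tractions act, the
#' mapped interior region contours should depend only weakly on the
#' constitutive parameters. The experiment meshes the phantom, solves the
#' displacement--zero-traction problem twice -- once with uniform
#' stiffness and once with the tissue-specific stiffness ladder -- and
#' quantifies the disagreement per region: Dice similarity of the mapped
#' areas, the absolute difference of the median grouped strains (in
#' percentage points of E1), and the relative error of the medians
#' (relative to the uniform-stiffness run, the pipeline default).
#'
#' @param phantom a [generate_cross_section_phantom()] output.
#' @param uniform uniform-stiffness [material_spec()].
#' @param tissue_specific per-region [material_spec()] (default: the
#'   65 kPa / 2.5x / 10x / 15x tangent-modulus ladder).
#' @param edge_lengths,default_edge mesh resolution passed to
#'   [mesh_cross_section()].
#' @param dice_resolution_um raster resolution for the similarity index.
#' @param ... passed to [solve_zero_traction()].
#' @return Object of class `sensitivity_report`: data.frame with one row
#'   per region (`SI_percent`, `strain_diff_pp`, `rel_error_percent`).
#' @export
material_sensitivity_experiment <- function(phantom,
                                            uniform = material_spec(1e6),
                                            tissue_specific = material_ladder(),
                                            edge_lengths = NULL,
                                            default_edge = 25,
                                            dice_resolution_um = 1, ...) {
  ts <- phantom$undeformed_regions
  labs <- names(ts$regions)
  if (is.null(edge_lengths)) {
    fine <- intersect(c("A1", "A2", "A3"), labs)
    edge_lengths <- stats::setNames(rep(default_edge / 2, length(fine)), fine)
  }
  mesh <- mesh_cross_section(ts, edge_lengths = edge_lengths,
                             default_edge = default_edge)
  bnodes <- sort(unique(c(mesh$boundary$lumen, mesh$boundary$outer)))
  ub <- phantom$displacement(mesh$nodes[bnodes, , drop = FALSE])
  bc <- data.frame(node = bnodes, ux = ub[, 1], uy = ub[, 2])

  run <- function(mat, tag) {
    tryCatch({
      solved <- solve_zero_traction(mesh, bc, mat, ...)
      extract_deformed_region_contours(solved)
    }, error = function(e) stop("mapping run '", tag, "' failed: ",
                                conditionMessage(e)))
  }
  reg_u <- run(uniform, "uniform")
  reg_t <- run(tissue_specific, "tissue_specific")

  gs_u <- group_strains(phantom$strain_field, reg_u)
  gs_t <- group_strains(phantom$strain_field, reg_t)

  rows <- lapply(labs, function(l) {
    si <- dice_similarity(region_polygon(reg_u, l), region_polygon(reg_t, l),
                          resolution_um = dice_resolution_um)
    mu_ <- median(gs_u$samples[[l]])
    mt_ <- median(gs_t$samples[[l]])
    data.frame(region = l, SI_percent = si,
               strain_diff_pp = abs(mu_ - mt_) * 100,
               rel_error_percent = abs(mu_ - mt_) / abs(mu_) * 100,
               median_uniform = mu_, median_tissue = mt_)
  })
  structure(list(table = do.call(rbind, rows),
                 regions_uniform = reg_u, regions_tissue = reg_t,
                 grouped_uniform = gs_u, grouped_tissue = gs_t),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  print(x$table[, c("region", "SI_percent", "strain_diff_pp", "rel_error_percent")],
        row.names = FALSE)
  invisible(x)
}

## shift internal sector interfaces of a phantom-style region set to
## change region areas by a target mean fraction (bisection on the shift)
perturb_region_set <- function(phantom, area_fraction) {
  ts <- phantom$undeformed_regions
  labs <- names(ts$regions)
  K <- length(labs)
  if (K < 2) stop("perturbation needs at least two regions")
  area0 <- region_areas(ts)
  rotate_ifaces <- function(delta) {
    ts2 <- ts
    for (k in seq_len(K)) {
      loop <- ts2$regions[[labs[k]]]
      iface <- loop$chain[2]              # radial interface ahead of region k
      ch <- ts$chains[[iface]]
      sgn <- if (k %% 2 == 0) -1 else 1
      ctr <- c(0, 0)
      ang <- delta * sgn
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      ## rotate interior of the interface, keeping endpoints on the rings
      n <- nrow(ch)
      w <- sin(seq(0, pi, length.out = n))     # taper to preserve endpoints
      rot <- ch %*% t(R)
      ts2$chains[[iface]] <- ch + (rot - ch) * w
    }
    ts2
  }
  objective <- function(delta) {
    mean(abs(region_areas(rotate_ifaces(delta)) - area0) / area0)
  }
  lo <- 0; hi <- 0.2
  target <- area_fraction
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (objective(mid) < target) lo <- mid else hi <- mid
  }
  rotate_ifaces((lo + hi) / 2)
}

#' Segmentation-perturbation error of the mapped strains
#'
#' Estimates how an area error in the histological segmentation propagates
#' into the grouped median strains: the internal region interfaces are
#' perturbed to change region areas by each requested fraction, the
#' mapping and grouping are re-run, and the median-strain differences
#' against the unperturbed run are reported.
#'
#' @param phantom a phantom.
#' @param perturbations area-change fractions in (0, 0.1].
#' @param mat material for the mapping runs.
#' @param default_edge mesh resolution (um).
#' @param ... passed to [solve_zero_traction()].
#' @return data.frame with one row per perturbation level: realised mean
#'   area change, maximum median-strain difference (percentage points of
#'   E1) and maximum relative error (%) across regions.
#' @export
segmentation_perturbation_error <- function(phantom,
                                            perturbations = c(0.005, 0.01, 0.02),
                                            mat = material_spec(1e6),
                                            default_edge = 25, ...) {
  if (any(perturbations <= 0 | perturbations > 0.1)) {
    stop("perturbations must lie in (0, 0.1]")
  }
  baseline <- run_mapping_once(phantom, phantom$undeformed_regions, mat,
                               default_edge, ...)
  area0 <- region_areas(phantom$undeformed_regions)
  out <- lapply(perturbations, function(pf) {
    ts2 <- perturb_region_set(phantom, pf)
    a2 <- region_areas(ts2)
    per <- run_mapping_once(phantom, ts2, mat, default_edge, ...)
    labs <- intersect(names(baseline$med), names(per$med))
    dmed <- abs(per$med[labs] - baseline$med[labs])
    data.frame(perturbation = pf,
               area_change = mean(abs(a2 - area0) / area0),
               strain_diff_pp = max(dmed) * 100,
               rel_error_percent = max(dmed / abs(baseline$med[labs])) * 100)
  })
  do.call(rbind, out)
}

run_mapping_once <- function(phantom, ts, mat, default_edge, ...) {
  labs <- names(ts$regions)
  fine <- intersect(c("A1", "A2", "A3"), labs)
  mesh <- mesh_cross_section(ts, edge_lengths =
                               stats::setNames(rep(default_edge / 2, length(fine)), fine),
                             default_edge = default_edge)
  bnodes <- sort(unique(c(mesh$boundary$lumen, mesh$boundary$outer)))
  ub <- phantom$displacement(mesh$nodes[bnodes, , drop = FALSE])
  bc <- data.frame(node = bnodes, ux = ub[, 1], uy = ub[, 2])
  solved <- solve_zero_traction(mesh, bc, mat, ...)
  reg <- extract_deformed_region_contours(solved)
  gs <- group_strains(phantom$strain_field, reg)
  list(regions = reg, grouped = gs,
       med = vapply(gs$samples, median, numeric(1)))
}
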