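#' Default end-to-end case configuration
#'
#' All tunable parameters of the histology-to-strain mapping pipeline in
#' one nested list, suitable for serialisation to YAML. Stage blocks
#' mirror the pipeline order: phantom generation (or input paths),
#' contour resampling, registration, its validation gate, meshing, the
#' zero-traction solve, and grouping/statistics.
#'
#' @param seed integer seed for every stochastic stage.
#' @param outdir optional output directory; `NULL` keeps results in memory.
#' @return Nested configuration list of class `case_config`.
#' @export
case_config <- function(seed = 1L, outdir = NULL) {
  structure(list(
    case_id = sprintf("case-%d", seed),
    seed = as.integer(seed),
    outdir = outdir,
    phantom = list(use = TRUE, geometry = phantom_geometry()),
    inputs = list(contours_csv = NULL, strain_field_tiff = NULL),
    resample = list(histology_points = 1000L, ultrasound_points = 20000L),
    registration = list(interaction_sigma = 150, smoothing_weight = 0.2,
                        max_iter = 120L, tol = 1e-7,
                        outer_fractions = c(1 / 3, 2 / 3)),
    validation = list(thresholds = c(lumen = 0.2, outer = 0.75),
                      uniformity_floor = 0.5),
    mesh = list(edge_lengths = c(A1 = 12, A2 = 12, A3 = 12),
                default_edge = 25),
    solve = list(C10 = 1e6, nu = 0.45, n_increments = 20L, tol = 1e-8,
                 rebase = TRUE),
    stats = list(alpha = 0.05)
  ), class = "case_config")
}

load_case_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    raw <- yaml::read_yaml(config)
    base <- case_config()
    base[names(raw)] <- raw
    config <- base
  }
  config
}

#' Run one cross-section case end to end
#'
#' Executes the full mapping workflow in order: resample contours,
#' register the lumen (single step) and outer wall (multi-step through
#' blended auxiliary contours), gate on the registration thresholds, mesh
#' the histological segmentation, solve the displacement--zero-traction
#' problem, extract the deformed region contours, group the strain field
#' by region, and compute per-region indices and pairwise tests. A failed
#' registration gate halts the pipeline before the finite-element stage.
#'
#' @param config a [case_config()] list or a YAML file path.
#' @return A `case_manifest`: config hash, seeds, per-stage status and
#'   metrics, and (in-memory or on-disk) stage outputs.
#' @export
run_case <- function(config = case_config()) {
  cfg <- load_case_config(config)
  manifest <- list(case_id = cfg$case_id, seed = cfg$seed,
                   config_hash = hash_object(cfg),
                   stages = list(), outputs = list())
  class(manifest) <- "case_manifest"
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) list(status = "ok") else
      list(status = "failed", error = res$error)
    if (!res$ok) return(NULL)
    res$value
  }

  ## ---- inputs ---------------------------------------------------------
  ph <- stage("inputs", function() {
    if (isTRUE(cfg$phantom$use)) {
      generate_cross_section_phantom(cfg$phantom$geometry, seed = cfg$seed)
    } else {
      stop("external-input mode requires run_case_external helpers; see vignette")
    }
  })
  if (is.null(ph)) return(manifest)
  und <- ph$undeformed_regions

  ## ---- resample -------------------------------------------------------
  dense <- stage("resample", function() {
    nl <- cfg$resample$ultrasound_points
    list(lumen = resample_contour_biharmonic(ph$deformed_lumen, nl),
         outer = resample_contour_biharmonic(ph$deformed_outer, nl))
  })
  if (is.null(dense)) return(manifest)

  ## ---- mesh (sources for registration are its boundary loops) ---------
  mesh <- stage("mesh", function() {
    mesh_cross_section(und, edge_lengths = cfg$mesh$edge_lengths,
                       default_edge = cfg$mesh$default_edge)
  })
  if (is.null(mesh)) return(manifest)

  ## ---- registration ---------------------------------------------------
  rp <- cfg$registration
  reg <- stage("register", function() {
    src_l <- contour(mesh$nodes[order_boundary_loop(mesh, "lumen"), ], role = "lumen")
    src_o <- contour(mesh$nodes[order_boundary_loop(mesh, "outer"), ], role = "outer")
    rl <- cpd_nonrigid(src_l, dense$lumen,
                       interaction_sigma = rp$interaction_sigma,
                       smoothing_weight = rp$smoothing_weight,
                       tol = rp$tol, max_iter = rp$max_iter)
    aux <- make_auxiliary_contours(src_o, dense$outer, rp$outer_fractions)
    ro <- multistep_register(src_o, dense$outer, auxiliaries = aux,
                             interaction_sigma = rp$interaction_sigma,
                             smoothing_weight = rp$smoothing_weight,
                             tol = rp$tol, max_iter = rp$max_iter)
    list(lumen = rl, outer = ro,
         lumen_nodes = order_boundary_loop(mesh, "lumen"),
         outer_nodes = order_boundary_loop(mesh, "outer"))
  })
  if (is.null(reg)) return(manifest)
  manifest$stages$register$metrics <-
    list(lumen_rmse_um = reg$lumen$rmse, outer_rmse_um = reg$outer$rmse,
         outer_steps = reg$outer$steps_used)

  ## ---- validation gate ------------------------------------------------
  gate <- stage("validate", function() {
    vl <- validate_registration(reg$lumen, "lumen", cfg$validation$thresholds,
                                cfg$validation$uniformity_floor)
    vo <- validate_registration(reg$outer, "outer", cfg$validation$thresholds,
                                cfg$validation$uniformity_floor)
    if (!vl$pass) stop("lumen registration rejected: ",
                       paste(vl$reasons, collapse = "; "))
    if (!vo$pass) stop("outer registration rejected: ",
                       paste(vo$reasons, collapse = "; "))
    list(lumen = vl, outer = vo)
  })
  if (is.null(gate)) return(manifest)

  ## ---- zero-traction solve -------------------------------------------
  solved <- stage("solve", function() {
    bc <- rbind(data.frame(node = reg$lumen_nodes,
                           ux = reg$lumen$displacement[, 1],
                           uy = reg$lumen$displacement[, 2]),
                data.frame(node = reg$outer_nodes,
                           ux = reg$outer$displacement[, 1],
                           uy = reg$outer$displacement[, 2]))
    bc <- bc[!duplicated(bc$node), ]
    solve_zero_traction(mesh, bc,
                        material_spec(cfg$solve$C10, cfg$solve$nu),
                        n_increments = cfg$solve$n_increments,
                        tol = cfg$solve$tol,
                        rebase = isTRUE(cfg$solve$rebase))
  })
  if (is.null(solved)) return(manifest)

  ## ---- extract & group ------------------------------------------------
  grouped <- stage("group", function() {
    reg_def <- extract_deformed_region_contours(solved)
    list(regions = reg_def,
         strains = group_strains(ph$strain_field, reg_def,
                                 case_id = cfg$case_id))
  })
  if (is.null(grouped)) return(manifest)

  ## ---- statistics -----------------------------------------------------
  stats_out <- stage("stats", function() {
    rs <- grouped$strains
    sdis <- lapply(rs$samples[vapply(rs$samples, length, integer(1)) >= 3],
                   compute_sdi)
    tests <- pairwise_region_tests(rs, alpha = cfg$stats$alpha)
    list(sdis = sdis, pairwise = tests)
  })

  manifest$outputs <- list(phantom = ph, mesh = mesh, registration = reg,
                           solved = solved, regions = grouped$regions,
                           strains = grouped$strains, stats = stats_out)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(region_strains_table(grouped$strains),
                     file.path(cfg$outdir, "region_strains.csv"), row.names = FALSE)
    write_mesh_vtk(solved, file.path(cfg$outdir, "deformed_mesh.vtk"))
    write_registration_result(reg$lumen, file.path(cfg$outdir, "registration_lumen.csv"))
    write_registration_result(reg$outer, file.path(cfg$outdir, "registration_outer.csv"))
    jsonlite::write_json(list(case_id = cfg$case_id, seed = cfg$seed,
                              config_hash = manifest$config_hash,
                              stages = manifest$stages),
                         file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

## ordered node cycle along the lumen/outer boundary of a mesh
order_boundary_loop <- function(mesh, which = c("lumen", "outer")) {
  which <- match.arg(which)
  ids <- mesh$boundary[[which]]
  xy <- mesh$nodes[ids, , drop = FALSE]
  ctr <- colMeans(xy)
  ids[order(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]))]
}

#' @export
print.case_manifest <- function(x, ...) {
  cat(sprintf("<case_manifest> %s (seed %d, config %s)\n", x$case_id, x$seed,
              substr(x$config_hash, 1, 8)))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %s%s\n", s, st$status,
                if (!is.null(st$error)) paste0(": ", st$error) else ""))
  }
  invisible(x)
}

#' Run a two-group strain-distribution study
#'
#' Generates (or accepts) per-specimen strain samples for an AAA-like and
#' a non-AAA-like group, computes the four strain distribution indices per
#' specimen, and compares each index between groups with the
#' normality-screened location test.
#'
#' @param n_aaa,n_non_aaa specimen counts (at least 2 each for testing).
#' @param seed integer seed.
#' @param samples_per_specimen strain values per specimen.
#' @param alpha significance level.
#' @param datasets optional pre-built output of [generate_group_dataset()].
#' @return List of class `group_study`: per-specimen SDI table, per-index
#'   test outcomes, and the seeds used.
#' @export
run_group_study <- function(n_aaa = 5L, n_non_aaa = 3L, seed = 1L,
                            samples_per_specimen = 2000L, alpha = 0.05,
                            datasets = NULL) {
  if (n_aaa < 2 || n_non_aaa < 2) stop("need at least 2 specimens per group")
  gd <- datasets %||% generate_group_dataset(n_aaa, n_non_aaa, seed = seed,
                                             samples_per_specimen = samples_per_specimen)
  tab <- do.call(rbind, lapply(c("aaa", "non_aaa"), function(g) {
    do.call(rbind, lapply(seq_along(gd[[g]]$samples), function(i) {
      s <- compute_sdi(gd[[g]]$samples[[i]])
      data.frame(group = gd[[g]]$group, specimen = i, mean = s$mean,
                 maximum = s$maximum, cv = s$coefficient_of_variation,
                 skewness = s$skewness)
    }))
  }))
  idx <- c("mean", "maximum", "cv", "skewness")
  tests <- stats::setNames(lapply(idx, function(v) {
    compare_groups_sdi(tab[[v]][tab$group == gd$aaa$group],
                       tab[[v]][tab$group == gd$non_aaa$group], alpha = alpha)
  }), idx)
  structure(list(sdis = tab, tests = tests, seed = as.integer(seed),
                 alpha = alpha), class = "group_study")
}

#' @export
print.group_study <- function(x, ...) {
  cat("<group_study> per-index comparisons (AAA-like vs non-AAA-like):\n")
  for (v in names(x$tests)) {
    t <- x$tests[[v]]
    cat(sprintf("  %-9s branch=%-4s p=%.4g %s\n", v, t$branch, t$p_value,
                if (t$reject) "*" else "-"))
  }
  invisible(x)
}
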