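#' Write contours to CSV
#'
#' Columns: `role`, `region_label`, `point_index`, `x_um`, `y_um`.
#'
#' @param contours named list of [contour()]s (names become region labels).
#' @param path output CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(names(contours), function(nm) {
    cc <- contours[[nm]]
    xy <- contour_points(cc)
    data.frame(role = if (inherits(cc, "contour")) cc$role else "auxiliary",
               region_label = nm, point_index = seq_len(nrow(xy)),
               x_um = xy[, 1], y_um = xy[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read contours from CSV
#' @param path CSV written by [write_contours_csv()].
#' @return Named list of [contour()]s.
#' @export
read_contours_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("role", "region_label", "point_index", "x_um", "y_um")
  if (!all(need %in% names(d))) stop("contour CSV lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  out <- lapply(split(d, d$region_label), function(g) {
    g <- g[order(g$point_index), ]
    contour(cbind(g$x_um, g$y_um), role = g$role[1])
  })
  out
}

#' Write a strain field as a TIFF image with a JSON sidecar
#'
#' The sidecar records the voxel size and origin; missing values are
#' stored as the sidecar's `missing_value` sentinel.
#'
#' @param field a [strain_field()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_strain_field_tiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF requires the 'tiff' package")
  }
  v <- field$values
  sentinel <- -1
  v[is.na(v)] <- sentinel
  ## affine-normalise into [0, 1] for the float TIFF round trip; the
  ## sidecar records the transform
  lo <- min(v, sentinel)
  hi <- max(v, lo + 1e-9)
  tiff::writeTIFF(t((v[, rev(seq_len(ncol(v))), drop = FALSE] - lo) / (hi - lo)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = field$resolution_um,
                            origin_um = field$origin,
                            missing_value = sentinel,
                            value_offset = lo, value_scale = hi - lo),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a strain field written by [write_strain_field_tiff()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @return A [strain_field()].
#' @export
read_strain_field_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the 'tiff' package")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  v <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  v <- v * meta$value_scale + meta$value_offset
  v[abs(v - meta$missing_value) < 1e-5 * max(1, abs(meta$value_scale))] <- NA
  strain_field(v, origin = meta$origin_um, resolution_um = meta$voxel_size_um)
}

#' Write a mesh in legacy VTK ASCII format
#'
#' Triangles with a `region_label` cell-data field (integer codes plus a
#' comment naming them), readable by standard mesh viewers.
#'
#' @param mesh a `vessel_mesh`.
#' @param path output `.vtk` path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  labs <- sort(unique(mesh$region))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("vessel cross-section mesh; regions:",
                     paste(seq_along(labs), labs, sep = "=", collapse = " ")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS region_label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, labs)), con)
  invisible(path)
}

#' Write per-point registration displacements and a JSON summary
#' @param r a `registration_result`.
#' @param csv_path per-point displacement CSV path.
#' @param json_path summary JSON path (default: alongside the CSV).
#' @export
write_registration_result <- function(r, csv_path,
                                      json_path = sub("\\.csv$", ".json", csv_path)) {
  xy <- contour_points(r$moved)
  utils::write.csv(data.frame(point_index = seq_len(nrow(xy)),
                              ux_um = r$displacement[, 1],
                              uy_um = r$displacement[, 2],
                              x_um = xy[, 1], y_um = xy[, 2]),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(rmse_um = r$rmse, steps_used = r$steps_used,
                            ordering_preserved = r$ordering_preserved,
                            uniformity = r$uniformity,
                            converged = r$converged),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
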