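test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  pts <- withr::with_seed(13, cbind(runif(25, 0, 100), runif(25, 0, 100)))
  tri <- delaunay_triangulate(pts)
  cc <- histostrain:::circumcircles(pts, tri)
  for (t in seq_len(nrow(tri))) {
    d2 <- (pts[, 1] - cc[t, 1])^2 + (pts[, 2] - cc[t, 2])^2
    inside <- d2 < cc[t, 3] * (1 - 1e-9)
    inside[tri[t, ]] <- FALSE
    expect_false(any(inside))
  }
  ## repeated call is bit-identical
  expect_identical(tri, delaunay_triangulate(pts))
})

test_that("region meshes hit the target edge lengths within 15%", {
  g <- phantom_geometry(lumen_diameter_um = 120, wall_thickness_um = 40,
                        proportions = c(A1 = 0.5, A4 = 0.5),
                        deformation_amplitude_um = 5, chain_spacing_um = 2)
  ph <- generate_cross_section_phantom(g, seed = 1)
  m <- mesh_cross_section(ph$undeformed_regions,
                          edge_lengths = c(A1 = 4), default_edge = 8.6)
  q <- mesh_edge_lengths(m)
  expect_gt(q[["A1"]], 3.4)
  expect_lt(q[["A1"]], 4.6)
  expect_lt(abs(q[["A4"]] - 8.6) / 8.6, 0.15)
})

test_that("meshes conserve area, avoid inversion and trace region loops", {
  ph <- generate_cross_section_phantom(small_geometry(), seed = 6)
  m <- mesh_cross_section(ph$undeformed_regions,
                          edge_lengths = c(A1 = 8, A2 = 8, A3 = 8),
                          default_edge = 16)
  a <- element_areas(m)
  expect_gt(min(a), 0)
  wall <- abs(polygon_area(boundary_ring(ph$undeformed_regions, "outer"))) -
    abs(polygon_area(boundary_ring(ph$undeformed_regions, "lumen")))
  expect_lt(abs(sum(a) - wall) / wall, 0.005)      # shoelace oracle

  ## boundary nodes lie on the stored contours
  lum <- m$nodes[m$boundary$lumen, , drop = FALSE]
  d <- polyline_distance(lum, boundary_ring(ph$undeformed_regions, "lumen"))
  expect_lt(max(d), 1e-6)

  ## per-region loops are closed cycles of boundary nodes
  for (l in names(m$region_loops)) {
    ids <- m$region_loops[[l]]
    expect_gt(length(ids), 10)
    expect_gt(polygon_area(m$nodes[ids, ]), 0)
  }
})

test_that("refining the mesh leaves mapped contours nearly unchanged", {
  g <- phantom_geometry(lumen_diameter_um = 240, wall_thickness_um = 50,
                        deformation_amplitude_um = 10, chain_spacing_um = 2)
  ph <- generate_cross_section_phantom(g, seed = 8)
  run <- function(edges, def) {
    m <- mesh_cross_section(ph$undeformed_regions,
                            edge_lengths = edges, default_edge = def)
    bn <- sort(unique(c(m$boundary$lumen, m$boundary$outer)))
    ub <- ph$displacement(m$nodes[bn, , drop = FALSE])
    s <- solve_zero_traction(m, data.frame(node = bn, ux = ub[, 1], uy = ub[, 2]),
                             material_spec(1e6), n_increments = 5)
    extract_deformed_region_contours(s)
  }
  coarse <- run(c(A1 = 4, A2 = 4, A3 = 4), 8)
  fine <- run(c(A1 = 2, A2 = 2, A3 = 2), 4)
  for (l in names(coarse$regions)) {
    pc <- region_polygon(coarse, l)
    pf <- region_polygon(fine, l)
    h <- max(max(polyline_distance(pc, pf)),
             max(polyline_distance(pf, pc)))
    expect_lt(h, 0.5)
  }
})
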