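phantom_mesh_bc <- function(seed = 3, edges = c(A1 = 8, A2 = 8, A3 = 8),
                            def = 16, geometry = small_geometry()) {
  ph <- generate_cross_section_phantom(geometry, seed = seed)
  m <- mesh_cross_section(ph$undeformed_regions, edge_lengths = edges,
                          default_edge = def)
  bn <- sort(unique(c(m$boundary$lumen, m$boundary$outer)))
  list(ph = ph, mesh = m, bnodes = bn)
}

test_that("rigid translation is reproduced exactly everywhere", {
  fx <- phantom_mesh_bc()
  bc <- data.frame(node = fx$bnodes, ux = 5, uy = -3)
  s <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 2)
  u <- attr(s, "displacement")
  expect_lt(max(abs(u - matrix(c(5, -3), nrow(u), 2, byrow = TRUE))), 1e-9)
})

test_that("affine boundary data yields an affine interior state", {
  fx <- phantom_mesh_bc()
  A <- matrix(c(0.08, 0.02, -0.01, -0.05), 2, 2)
  uaff <- fx$mesh$nodes %*% t(A)
  bc <- data.frame(node = fx$bnodes, ux = uaff[fx$bnodes, 1],
                   uy = uaff[fx$bnodes, 2])
  s <- solve_zero_traction(fx$mesh, bc, material_spec(1e6),
                           n_increments = 4, tol = 1e-12)
  expect_lt(max(abs(attr(s, "displacement") - uaff)), 1e-8)
})

test_that("uniform stiffness scaling does not move the solution", {
  fx <- phantom_mesh_bc(seed = 5)
  ub <- fx$ph$displacement(fx$mesh$nodes[fx$bnodes, , drop = FALSE])
  bc <- data.frame(node = fx$bnodes, ux = ub[, 1], uy = ub[, 2])
  s1 <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 5)
  s2 <- solve_zero_traction(fx$mesh, bc, material_spec(65), n_increments = 5)
  expect_lt(max(abs(s1$nodes - s2$nodes)), 1e-6)
})

test_that("interior ground-truth displacement is recovered on phantoms", {
  fx <- phantom_mesh_bc(seed = 7)
  ub <- fx$ph$displacement(fx$mesh$nodes[fx$bnodes, , drop = FALSE])
  bc <- data.frame(node = fx$bnodes, ux = ub[, 1], uy = ub[, 2])
  s <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 10)
  truth <- fx$ph$displacement(fx$mesh$nodes)
  err <- sqrt(rowSums((attr(s, "displacement") - truth)^2))
  interior <- setdiff(seq_len(nrow(fx$mesh$nodes)), fx$bnodes)
  amp <- fx$ph$geometry$deformation_amplitude_um
  expect_lt(median(err[interior]) / amp, 0.02)
})

test_that("updated-Lagrangian continuation matches the equilibrium solve", {
  fx <- phantom_mesh_bc(seed = 11)
  ub <- fx$ph$displacement(fx$mesh$nodes[fx$bnodes, , drop = FALSE])
  bc <- data.frame(node = fx$bnodes, ux = ub[, 1], uy = ub[, 2])
  s_tl <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 5)
  s_ul <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 10,
                              rebase = TRUE)
  amp <- fx$ph$geometry$deformation_amplitude_um
  expect_lt(max(abs(s_tl$nodes - s_ul$nodes)) / amp, 0.002)
})

test_that("bc must cover the boundary and inverted meshes are rejected", {
  fx <- phantom_mesh_bc()
  bc <- data.frame(node = fx$bnodes[-1], ux = 0, uy = 0)
  expect_error(solve_zero_traction(fx$mesh, bc), "cover")
})

test_that("extracted contours reproduce the input at zero displacement", {
  fx <- phantom_mesh_bc(seed = 9)
  bc <- data.frame(node = fx$bnodes, ux = 0, uy = 0)
  s <- solve_zero_traction(fx$mesh, bc, material_spec(1e6), n_increments = 1)
  ext <- extract_deformed_region_contours(s)
  for (l in names(ext$regions)) {
    p0 <- fx$mesh$nodes[fx$mesh$region_loops[[l]], , drop = FALSE]
    expect_lt(max(abs(region_polygon(ext, l) - p0)), 1e-9)
    expect_gt(polygon_area(region_polygon(ext, l)), 0)  # closed, oriented
  }

  ## deformed lumen area equals the prescribed deformed lumen polygon area
  ub <- fx$ph$displacement(fx$mesh$nodes[fx$bnodes, , drop = FALSE])
  bc2 <- data.frame(node = fx$bnodes, ux = ub[, 1], uy = ub[, 2])
  s2 <- solve_zero_traction(fx$mesh, bc2, material_spec(1e6), n_increments = 5)
  lum_ids <- order_boundary_loop(fx$mesh, "lumen")
  presc <- fx$mesh$nodes[lum_ids, ] +
    fx$ph$displacement(fx$mesh$nodes[lum_ids, , drop = FALSE])
  got <- s2$nodes[lum_ids, ]
  expect_lt(abs(abs(polygon_area(got)) - abs(polygon_area(presc))) /
              abs(polygon_area(presc)), 0.001)
})
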