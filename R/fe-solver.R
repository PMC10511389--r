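#' Material specification for the zero-traction mapping solve
#'
#' Compressible plane Neo-Hookean material. `C10` may be a single value
#' (uniform stiffness) or a named per-region vector; the shear modulus is
#' `mu = 2 C10`. Because the mapping problem is fully displacement-driven
#' with zero applied tractions, any uniform scaling of `C10` leaves the
#' solution unchanged; only stiffness *contrasts* between regions matter.
#' `nu` is a Poisson-like ratio standing in for near-incompressibility
#' while keeping linear triangles lock-free.
#'
#' @param C10 stiffness coefficient(s), kPa.
#' @param nu Poisson-like ratio in (0, 0.5).
#' @return Object of class `material_spec`.
#' @export
material_spec <- function(C10 = 1e6, nu = 0.45) {
  if (any(C10 <= 0)) stop("C10 must be > 0")
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
  structure(list(C10 = C10, nu = nu), class = "material_spec")
}

#' Tissue-specific stiffness ladder
#'
#' Per-region stiffnesses from tangent moduli of the tissue types: thrombus
#' with red blood cells as the 65 kPa baseline, thrombus without RBCs 2.5x
#' stiffer, intact elastin 10x stiffer, fragmented elastin 15x stiffer.
#'
#' @param base baseline stiffness (kPa) for thrombus with RBCs (A4).
#' @param nu Poisson-like ratio.
#' @return A per-region [material_spec()].
#' @export
material_ladder <- function(base = 65, nu = 0.45) {
  material_spec(C10 = c(A1 = 10, A2 = 10, A3 = 15, A4 = 1, A5 = 2.5) * base,
                nu = nu)
}

mu_lambda_per_element <- function(mesh, mat) {
  C10 <- mat$C10
  if (length(C10) == 1L && is.null(names(C10))) {
    mu <- rep(2 * C10, length(mesh$region))
  } else {
    if (!all(mesh$region %in% names(C10))) {
      stop("material_spec C10 must name every mesh region")
    }
    mu <- 2 * as.numeric(C10[mesh$region])
  }
  ## plane-stress-consistent Lame parameter
  lam <- 2 * mu * mat$nu / (1 - mat$nu)
  list(mu = mu, lam = lam)
}

#' Solve the displacement--zero-traction mapping problem
#'
#' Static equilibrium of a plane compressible Neo-Hookean body whose
#' entire lumen and outer boundary displacement is prescribed and which
#' carries no surface tractions: the load is defined purely through the
#' prescribed deformation, so interior displacements are nearly
#' independent of the constitutive parameters. Solved incrementally with
#' Newton iterations and adaptive increment halving on divergence or
#' element inversion. The computed stresses are artificial by design;
#' only the deformed geometry is meaningful downstream.
#'
#' @param mesh a `vessel_mesh`.
#' @param bc data frame with columns `node`, `ux`, `uy` (um), covering
#'   every lumen and outer boundary node.
#' @param mat a [material_spec()].
#' @param n_increments number of equal boundary-displacement increments.
#' @param tol relative residual tolerance per increment.
#' @param max_iter Newton iteration cap per increment.
#' @param min_increment smallest allowed increment fraction before the
#'   solve is abandoned.
#' @param rebase if `TRUE`, use updated-Lagrangian continuation: the
#'   boundary motion is applied in `n_increments` equal steps and the
#'   element reference configuration is reset to the deformed geometry
#'   after each step. Because only the mapped geometry is used downstream
#'   (the solve's stresses are artificial by construction), this variant
#'   is equivalent for mapping purposes while being far more robust to
#'   the in-plane wrinkling that strongly redistributed registration
#'   displacements can excite in a total-Lagrangian continuation.
#' @param stabilize dimensionless automatic-stabilisation factor. Zero (the
#'   default) solves the pure equilibrium problem. A small positive value
#'   (e.g. 1e-4) adds an artificial spring between each free node and its
#'   increment-start position, scaled by the mean shear stiffness, which
#'   regularises the in-plane wrinkling instabilities that strongly
#'   redistributed boundary displacements can excite; the deformed
#'   geometry changes only at the order of the factor itself.
#' @return The input mesh with deformed `nodes`, plus attributes
#'   `displacement` (n-by-2) and `solve_info` (residual history,
#'   increments used).
#' @export
solve_zero_traction <- function(mesh, bc, mat = material_spec(),
                                n_increments = 10L, tol = 1e-8,
                                max_iter = 30L, min_increment = 1 / 64,
                                stabilize = 0, rebase = FALSE) {
  need <- sort(unique(c(mesh$boundary$lumen, mesh$boundary$outer)))
  if (isTRUE(rebase)) {
    bc <- bc[match(need, bc$node), ]
    cur <- mesh
    t_done <- 0
    dt <- 1 / n_increments
    n_steps <- 0L
    while (t_done < 1 - 1e-12) {
      dt <- min(dt, 1 - t_done)
      bck <- data.frame(node = bc$node, ux = bc$ux * dt, uy = bc$uy * dt)
      stp <- tryCatch(
        solve_zero_traction(cur, bck, mat, n_increments = 1L, tol = tol,
                            max_iter = max_iter, min_increment = 1,
                            stabilize = stabilize, rebase = FALSE),
        error = function(e) NULL)
      if (is.null(stp)) {
        dt <- dt / 2
        if (dt < min_increment / n_increments) {
          stop(sprintf(
            "rebased continuation failed at load fraction %.3f (increment floor reached)",
            t_done + 2 * dt))
        }
        next
      }
      cur <- stp
      t_done <- t_done + dt
      n_steps <- n_steps + 1L
      dt <- min(dt * 2, 1 / n_increments)
    }
    out <- mesh
    out$nodes <- cur$nodes
    attr(out, "displacement") <- cur$nodes - mesh$nodes
    attr(out, "solve_info") <- list(increments = n_steps, rebase = TRUE)
    return(out)
  }
  if (!all(need %in% bc$node)) {
    stop("boundary displacement must cover every lumen and outer boundary node")
  }
  bc <- bc[match(need, bc$node), ]
  nn <- nrow(mesh$nodes)
  X <- mesh$nodes
  tri <- mesh$elements
  ml <- mu_lambda_per_element(mesh, mat)
  mu <- ml$mu; lam <- ml$lam

  ## reference geometry per element
  x1 <- X[tri[, 1], ]; x2 <- X[tri[, 2], ]; x3 <- X[tri[, 3], ]
  d1 <- x2 - x1; d2 <- x3 - x1
  detD <- d1[, 1] * d2[, 2] - d2[, 1] * d1[, 2]
  if (any(detD <= 0)) stop("mesh contains inverted elements")
  A0 <- detD / 2
  ## gradients of the three hat functions (rows of inv(Dm)^T combinations)
  iD11 <- d2[, 2] / detD; iD12 <- -d2[, 1] / detD
  iD21 <- -d1[, 2] / detD; iD22 <- d1[, 1] / detD
  gN <- array(0, c(length(A0), 3, 2))       # gN[, a, J] = dN_a / dX_J
  gN[, 2, 1] <- iD11; gN[, 2, 2] <- iD12
  gN[, 3, 1] <- iD21; gN[, 3, 2] <- iD22
  gN[, 1, 1] <- -iD11 - iD21; gN[, 1, 2] <- -iD12 - iD22

  dof <- function(node, comp) 2L * (node - 1L) + comp
  presc <- c(dof(need, 1L), dof(need, 2L))
  ubc_full <- numeric(2 * nn)
  ubc_full[dof(need, 1L)] <- bc$ux
  ubc_full[dof(need, 2L)] <- bc$uy
  free <- setdiff(seq_len(2 * nn), presc)

  ## assembly index pattern (36 entries per element)
  ne <- nrow(tri)
  ii <- jj <- matrix(0L, ne, 36)
  col <- 0L
  for (a in 1:3) for (i in 1:2) for (b in 1:3) for (k in 1:2) {
    col <- col + 1L
    ii[, col] <- dof(tri[, a], i)
    jj[, col] <- dof(tri[, b], k)
  }

  element_state <- function(u) {
    ## deformation gradient per element: F_iJ = delta_iJ + sum_a u_ai gN_aJ
    ua <- array(0, c(ne, 3, 2))
    for (a in 1:3) ua[, a, ] <- matrix(u[c(dof(tri[, a], 1), dof(tri[, a], 2))], ne, 2)
    F11 <- 1 + ua[, 1, 1] * gN[, 1, 1] + ua[, 2, 1] * gN[, 2, 1] + ua[, 3, 1] * gN[, 3, 1]
    F12 <- ua[, 1, 1] * gN[, 1, 2] + ua[, 2, 1] * gN[, 2, 2] + ua[, 3, 1] * gN[, 3, 2]
    F21 <- ua[, 1, 2] * gN[, 1, 1] + ua[, 2, 2] * gN[, 2, 1] + ua[, 3, 2] * gN[, 3, 1]
    F22 <- 1 + ua[, 1, 2] * gN[, 1, 2] + ua[, 2, 2] * gN[, 2, 2] + ua[, 3, 2] * gN[, 3, 2]
    J <- F11 * F22 - F12 * F21
    list(F = cbind(F11, F12, F21, F22), J = J)
  }

  fidx <- c(dof(tri[, 1], 1L), dof(tri[, 1], 2L),
            dof(tri[, 2], 1L), dof(tri[, 2], 2L),
            dof(tri[, 3], 1L), dof(tri[, 3], 2L))
  internal_force <- function(st) {
    J <- st$J; Fm <- st$F
    ## H = F^{-T}
    H11 <- Fm[, 4] / J; H12 <- -Fm[, 3] / J
    H21 <- -Fm[, 2] / J; H22 <- Fm[, 1] / J
    clJ <- lam * log(J) - mu
    P11 <- mu * Fm[, 1] + clJ * H11
    P12 <- mu * Fm[, 2] + clJ * H12
    P21 <- mu * Fm[, 3] + clJ * H21
    P22 <- mu * Fm[, 4] + clJ * H22
    fv <- c(A0 * (P11 * gN[, 1, 1] + P12 * gN[, 1, 2]),
            A0 * (P21 * gN[, 1, 1] + P22 * gN[, 1, 2]),
            A0 * (P11 * gN[, 2, 1] + P12 * gN[, 2, 2]),
            A0 * (P21 * gN[, 2, 1] + P22 * gN[, 2, 2]),
            A0 * (P11 * gN[, 3, 1] + P12 * gN[, 3, 2]),
            A0 * (P21 * gN[, 3, 1] + P22 * gN[, 3, 2]))
    agg <- rowsum(fv, fidx)
    f <- numeric(2 * nn)
    f[as.integer(rownames(agg))] <- agg[, 1]
    f
  }

  tangent <- function(st) {
    J <- st$J; Fm <- st$F
    H11 <- Fm[, 4] / J; H12 <- -Fm[, 3] / J
    H21 <- -Fm[, 2] / J; H22 <- Fm[, 1] / J
    H <- array(c(H11, H12, H21, H22), c(ne, 2, 2))
    gamma <- mu - lam * log(J)
    vals <- matrix(0, ne, 36)
    ## q[a, i] = sum_J H_iJ gN_aJ
    q <- array(0, c(ne, 3, 2))
    for (a in 1:3) for (i in 1:2) {
      q[, a, i] <- H[, i, 1] * gN[, a, 1] + H[, i, 2] * gN[, a, 2]
    }
    col <- 0L
    for (a in 1:3) for (i in 1:2) for (b in 1:3) for (k in 1:2) {
      col <- col + 1L
      gg <- gN[, a, 1] * gN[, b, 1] + gN[, a, 2] * gN[, b, 2]
      v <- lam * q[, a, i] * q[, b, k] + gamma * q[, a, k] * q[, b, i]
      if (i == k) v <- v + mu * gg
      vals[, col] <- A0 * v
    }
    Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj),
                         x = as.numeric(vals), dims = c(2 * nn, 2 * nn))
  }

  u <- numeric(2 * nn)
  u_prev <- NULL
  dt_prev <- 0
  t_done <- 0
  dt <- 1 / n_increments
  residual_log <- list()
  ## absolute force floor from the problem's own stiffness scale
  f_floor <- 1e-12 * mean(mu) * sqrt(sum(A0))
  n_steps <- 0L
  while (t_done < 1 - 1e-12) {
    dt <- min(dt, 1 - t_done)
    t_try <- t_done + dt
    u_try <- u
    ## secant predictor: carry the interior along the previous increment's
    ## velocity so boundary-layer elements are not crushed at the start
    if (!is.null(u_prev) && dt_prev > 0) {
      u_try[free] <- u[free] + (u[free] - u_prev[free]) * (dt / dt_prev)
    }
    u_try[presc] <- ubc_full[presc] * t_try
    if (any(element_state(u_try)$J <= 0)) {
      u_try <- u                              # fall back: no extrapolation
      u_try[presc] <- ubc_full[presc] * t_try
    }
    ok <- FALSE
    ref_inc <- NULL
    ## energy-descent Newton: the prescribed-displacement problem is the
    ## minimisation of the stored energy (with -log J barrier), so a
    ## Levenberg-damped Newton direction plus an energy line search
    ## converges to a minimiser even across local limit points where pure
    ## residual iteration stalls
    k_s <- stabilize * mean(mu)
    u_anchor <- u_try
    energy <- function(st, uu) {
      if (any(st$J <= 0)) return(Inf)
      I1 <- st$F[, 1]^2 + st$F[, 2]^2 + st$F[, 3]^2 + st$F[, 4]^2
      lj <- log(st$J)
      sum(A0 * (mu / 2 * (I1 - 2) - mu * lj + lam / 2 * lj^2)) +
        k_s / 2 * sum((uu[free] - u_anchor[free])^2)
    }
    tau <- 0
    tau_scale <- mean(mu)
    fail_reason <- "max_iter"
    for (itn in seq_len(max_iter)) {
      st <- element_state(u_try)
      if (any(st$J <= 0)) { fail_reason <- "J<=0 at start"; break }
      f <- internal_force(st)
      if (k_s > 0) f[free] <- f[free] + k_s * (u_try[free] - u_anchor[free])
      rn <- sqrt(sum(f[free]^2))
      if (itn == 1L) ref_inc <- rn
      if (isTRUE(getOption("histostrain.verbose"))) {
        message(sprintf("  t=%.4f it=%d resid=%.3e Jmin=%.3f tau=%.1e",
                        t_try, itn, rn, min(st$J), tau))
      }
      residual_log[[length(residual_log) + 1L]] <-
        c(t = t_try, iter = itn, residual = rn)
      if (rn <= tol * ref_inc + f_floor) { ok <- TRUE; break }
      E0 <- energy(st, u_try)
      K <- tangent(st)
      Kff <- K[free, free, drop = FALSE]
      if (k_s > 0) Kff <- Kff + Matrix::Diagonal(length(free), k_s)
      accepted <- FALSE
      for (damp_try in 1:12) {
        Kd <- if (tau > 0) Kff + Matrix::Diagonal(length(free), tau) else Kff
        du <- tryCatch(as.numeric(Matrix::solve(Kd, -f[free])),
                       error = function(e) NULL)
        if (!is.null(du)) {
          ## descent check, then energy backtracking; near convergence the
          ## energy decrease falls below summation noise, so a residual
          ## reduction is accepted as an alternative criterion
          if (sum(du * f[free]) < 0) {
            step <- 1
            while (step >= 1 / 4096) {
              u_cand <- u_try
              u_cand[free] <- u_try[free] + step * du
              st_c <- element_state(u_cand)
              if (all(st_c$J > 0)) {
                E1 <- energy(st_c, u_cand)
                f_c <- internal_force(st_c)
                if (k_s > 0) f_c[free] <- f_c[free] + k_s * (u_cand[free] - u_anchor[free])
                if (E1 < E0 + 1e-10 * (abs(E0) + 1) ||
                    sqrt(sum(f_c[free]^2)) < 0.7 * rn) {
                  u_try <- u_cand
                  accepted <- TRUE
                  break
                }
              }
              step <- step / 2
            }
          }
        }
        if (accepted) break
        tau <- if (tau == 0) 1e-6 * tau_scale else tau * 10
      }
      if (!accepted) { fail_reason <- sprintf("no acceptable step (rn=%.3e ref=%.3e Jmin=%.4f)", rn, ref_inc, min(st$J)); break }
      tau <- tau / 30   # relax damping as iterations succeed
      if (tau < 1e-8 * tau_scale) tau <- 0
    }
    if (!ok) {
      if (isTRUE(getOption("histostrain.verbose2"))) {
        message(sprintf("increment t=%.4f dt=%.5f FAILED: %s", t_try, dt, fail_reason))
      }
      dt <- dt / 2
      if (dt < min_increment / n_increments) {
        stop(sprintf("Newton solve failed at load fraction %.3f (increment floor reached)",
                     t_try))
      }
      next
    }
    u_prev <- u
    dt_prev <- dt
    u <- u_try
    t_done <- t_try
    n_steps <- n_steps + 1L
    dt <- min(dt * 2, 1 / n_increments)
  }

  um <- matrix(u, ncol = 2, byrow = TRUE)
  out <- mesh
  out$nodes <- X + um
  attr(out, "displacement") <- um
  attr(out, "solve_info") <- list(increments = n_steps,
                                  residuals = do.call(rbind, residual_log))
  out
}

#' Extract deformed tissue-region contours from a solved mesh
#'
#' Traces each region's stored boundary node cycle through the deformed
#' nodal coordinates, discarding the artificial stresses and strains of
#' the mapping solve. Returns closed, consistently oriented contours in
#' the loaded (in vivo) configuration.
#'
#' @param deformed a solved `vessel_mesh` (output of
#'   [solve_zero_traction()]).
#' @return A [tissue_region_set()] in the deformed frame.
#' @export
extract_deformed_region_contours <- function(deformed) {
  loops <- deformed$region_loops
  if (is.null(loops)) stop("mesh carries no region boundary chains")
  chains <- lapply(loops, function(ids) deformed$nodes[ids, , drop = FALSE])
  regions <- stats::setNames(lapply(seq_along(loops), function(k) {
    data.frame(chain = k, rev = FALSE)
  }), names(loops))
  ## boundary rings: reuse node id sets mapped to deformed coordinates
  lum <- deformed$boundary$lumen
  out <- deformed$boundary$outer
  ts <- tissue_region_set(chains, regions,
                          lumen_chains = integer(0), outer_chains = integer(0),
                          closed = rep(TRUE, length(chains)))
  ts$lumen_ring <- deformed$nodes[lum, , drop = FALSE]
  ts$outer_ring <- deformed$nodes[out, , drop = FALSE]
  ts
}
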