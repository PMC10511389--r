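## ---- Delaunay triangulation (Bowyer-Watson) ---------------------------

## circumcircle centre and squared radius of triangles given by index rows
circumcircles <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction with a bounding super-triangle.
#' Insertion order is a fixed pseudo-random permutation, so the result is
#' deterministic for a given point set.
#'
#' @param pts two-column coordinate matrix.
#' @return Integer matrix of triangles (rows of vertex indices into `pts`),
#'   counterclockwise.
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  ctr <- colMeans(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1e-9)
  big <- 50 * span
  sup <- rbind(ctr + c(0, big), ctr + c(-big, -big), ctr + c(big, -big))
  P <- rbind(pts, sup)
  sid <- n + 1:3
  tri <- matrix(sid[c(1, 2, 3)], 1, 3)
  cc <- circumcircles(P, tri)
  alive <- TRUE
  ord <- order(sin(seq_len(n) * 12.9898) * 43758.5453)  # deterministic shuffle
  for (ip in ord) {
    px <- P[ip, 1]; py <- P[ip, 2]
    bad <- alive & ((px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    bidx <- which(bad)
    ## cavity boundary: edges of bad triangles that appear exactly once
    e <- rbind(tri[bidx, c(1, 2), drop = FALSE], tri[bidx, c(2, 3), drop = FALSE],
               tri[bidx, c(3, 1), drop = FALSE])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    keep <- !(ekey %in% ekey[duplicated(ekey)])
    e <- e[keep, , drop = FALSE]
    alive[bidx] <- FALSE
    newt <- cbind(e, ip)
    newcc <- circumcircles(P, newt)
    tri <- rbind(tri, newt)
    cc <- rbind(cc, newcc)
    alive <- c(alive, rep(TRUE, nrow(newt)))
    if (length(alive) > 4 * n + 500 && sum(!alive) > length(alive) / 2) {
      tri <- tri[alive, , drop = FALSE]; cc <- cc[alive, , drop = FALSE]
      alive <- rep(TRUE, nrow(tri))
    }
  }
  tri <- tri[alive, , drop = FALSE]
  tri <- tri[rowSums(matrix(tri %in% sid, nrow(tri), 3)) == 0, , drop = FALSE]
  ## enforce counterclockwise orientation
  a <- (P[tri[, 2], 1] - P[tri[, 1], 1]) * (P[tri[, 3], 2] - P[tri[, 1], 2]) -
    (P[tri[, 3], 1] - P[tri[, 1], 1]) * (P[tri[, 2], 2] - P[tri[, 1], 2])
  flip <- a < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  tri
}

## deterministic sub-voxel jitter (breaks hex-lattice cocircularity)
lattice_jitter <- function(n, scale) {
  u <- (sin(seq_len(n) * 78.233) * 43758.5453) %% 1
  v <- (sin(seq_len(n) * 39.425) * 24634.6345) %% 1
  cbind((u - 0.5), (v - 0.5)) * scale
}

## hexagonal interior lattice clipped to a polygon with a safety margin
hex_interior_points <- function(poly, spacing, margin = 0.65) {
  lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
  dy <- spacing * sqrt(3) / 2
  ys <- seq(lo[2] + dy / 2, hi[2], by = dy)
  if (!length(ys)) return(matrix(numeric(0), 0, 2))
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(lo[1] + off + spacing / 2, hi[1], by = spacing)
    if (!length(xs)) return(NULL)
    cbind(xs, ys[i])
  }))
  if (is.null(pts)) return(matrix(numeric(0), 0, 2))
  pts <- pts + lattice_jitter(nrow(pts), 0.05 * spacing)
  inside <- points_in_polygon(pts, poly)
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) == 0) return(pts)
  d <- nearest_point_distance(pts, poly)
  pts[d >= margin * spacing, , drop = FALSE]
}

## ---- conforming multi-region meshing ----------------------------------

#' Mesh a segmented vessel cross section
#'
#' Builds a conforming linear-triangle mesh of a [tissue_region_set()]:
#' shared boundary chains are resampled once (at the smaller of the two
#' adjacent regions' target edge lengths, so interfaces match exactly),
#' region interiors are filled with a hexagonal lattice at the region's
#' target edge length, and each region is triangulated with
#' [delaunay_triangulate()]. Region boundaries are traced by element
#' edges; elements carry their region label.
#'
#' @param regions a [tissue_region_set()].
#' @param edge_lengths named target mean edge lengths per region label
#'   (um); unnamed regions fall back to `default_edge`. The study design
#'   this emulates meshed elastin regions at about 4 um and all other
#'   regions at about 8.6 um.
#' @param default_edge fallback target edge length (um).
#' @param check_quality verify per-region mean edge length is within 15%
#'   of target (warning otherwise).
#' @return Object of class `vessel_mesh`: `nodes` (n-by-2, um), `elements`
#'   (m-by-3 integer, counterclockwise), `region` (label per element),
#'   `boundary` (ordered lumen/outer node id cycles), `region_loops`
#'   (ordered boundary node cycle per region), `edge_target`.
#' @export
mesh_cross_section <- function(regions, edge_lengths = NULL,
                               default_edge = 8.6, check_quality = TRUE) {
  ts <- regions
  labs <- names(ts$regions)
  h_of <- function(lab) {
    if (!is.null(edge_lengths) && lab %in% names(edge_lengths)) {
      edge_lengths[[lab]]
    } else default_edge
  }
  hr <- vapply(labs, h_of, numeric(1))

  ## regions adjacent to each chain -> conforming chain spacing
  nch <- length(ts$chains)
  chain_h <- rep(Inf, nch)
  for (k in seq_along(labs)) {
    ids <- ts$regions[[labs[k]]]$chain
    chain_h[ids] <- pmin(chain_h[ids], hr[k])
  }
  chain_h[!is.finite(chain_h)] <- default_edge

  chain_nodes <- vector("list", nch)   # resampled coordinates per chain
  node_list <- vector("list", 0)
  node_env <- new.env(hash = TRUE, parent = emptyenv())
  n_nodes <- 0L
  add_nodes <- function(xy) {
    keys <- sprintf("%.6f_%.6f", round(xy[, 1], 6), round(xy[, 2], 6))
    ids <- integer(nrow(xy))
    for (i in seq_len(nrow(xy))) {
      j <- node_env[[keys[i]]]
      if (is.null(j)) {
        n_nodes <<- n_nodes + 1L
        j <- n_nodes
        node_env[[keys[i]]] <- j
        node_list[[j]] <<- xy[i, ]
      }
      ids[i] <- j
    }
    ids
  }
  chain_ids <- vector("list", nch)
  for (ci in seq_len(nch)) {
    xy <- resample_polyline(ts$chains[[ci]], spacing = chain_h[ci],
                            closed = isTRUE(ts$closed[ci]))
    chain_nodes[[ci]] <- xy
    chain_ids[[ci]] <- add_nodes(xy)
  }
  node_xy <- do.call(rbind, node_list)

  elements <- matrix(integer(0), 0, 3)
  el_region <- character(0)
  region_loops <- list()
  for (k in seq_along(labs)) {
    loop <- ts$regions[[labs[k]]]
    bid <- unlist(lapply(seq_len(nrow(loop)), function(i) {
      ids <- chain_ids[[loop$chain[i]]]
      if (loop$rev[i]) ids <- rev(ids)
      ids[-length(ids)]
    }))
    bid <- bid[c(TRUE, diff(bid) != 0)]           # collapse merged junctions
    if (bid[1] == bid[length(bid)]) bid <- bid[-length(bid)]
    region_loops[[labs[k]]] <- bid
    poly <- node_xy[bid, , drop = FALSE]
    interior <- hex_interior_points(poly, hr[k])
    iid <- if (nrow(interior)) add_nodes(interior) else integer(0)
    local_ids <- c(bid, iid)
    node_xy <- do.call(rbind, node_list)
    lp <- node_xy[local_ids, , drop = FALSE]
    tri <- delaunay_triangulate(lp)
    cen <- (lp[tri[, 1], ] + lp[tri[, 2], ] + lp[tri[, 3], ]) / 3
    tri <- tri[points_in_polygon(cen, poly), , drop = FALSE]
    if (nrow(tri) == 0) stop("region ", labs[k], " produced no elements")
    ## conformity: every boundary segment must be an element edge
    ee <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    ekey <- paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    nb <- length(bid)
    bseg <- cbind(seq_len(nb), c(2:nb, 1L))
    bkey <- paste(pmin(bseg[, 1], bseg[, 2]), pmax(bseg[, 1], bseg[, 2]))
    if (!all(bkey %in% ekey)) {
      stop("non-conforming triangulation of region ", labs[k],
           " near boundary vertex ", which(!(bkey %in% ekey))[1])
    }
    elements <- rbind(elements, matrix(local_ids[tri], ncol = 3))
    el_region <- c(el_region, rep(labs[k], nrow(tri)))
  }

  bnd_ids <- function(which_chains) {
    unique(unlist(chain_ids[which_chains]))
  }
  mesh <- structure(list(
    nodes = node_xy, elements = elements, region = el_region,
    boundary = list(lumen = bnd_ids(ts$lumen_chains),
                    outer = bnd_ids(ts$outer_chains)),
    region_loops = region_loops,
    edge_target = stats::setNames(hr, labs)), class = "vessel_mesh")

  if (check_quality) {
    q <- mesh_edge_lengths(mesh)
    for (k in seq_along(labs)) {
      if (abs(q[labs[k]] - hr[k]) > 0.15 * hr[k]) {
        warning(sprintf("region %s mean edge length %.2f um misses target %.2f um by >15%%",
                        labs[k], q[labs[k]], hr[k]))
      }
    }
    a <- element_areas(mesh)
    if (any(a <= 0)) stop("mesh contains inverted elements")
  }
  mesh
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %d nodes, %d elements, regions: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' Per-region mean element edge length
#' @param mesh a `vessel_mesh`.
#' @return Named numeric vector (um).
#' @export
mesh_edge_lengths <- function(mesh) {
  out <- numeric(0)
  for (lab in unique(mesh$region)) {
    tri <- mesh$elements[mesh$region == lab, , drop = FALSE]
    ee <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    ekey <- paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    ee <- ee[!duplicated(ekey), , drop = FALSE]
    len <- sqrt(rowSums((mesh$nodes[ee[, 1], , drop = FALSE] -
                           mesh$nodes[ee[, 2], , drop = FALSE])^2))
    out[lab] <- mean(len)
  }
  out
}

element_areas <- function(mesh, nodes = mesh$nodes) {
  t1 <- mesh$elements[, 1]; t2 <- mesh$elements[, 2]; t3 <- mesh$elements[, 3]
  ((nodes[t2, 1] - nodes[t1, 1]) * (nodes[t3, 2] - nodes[t1, 2]) -
      (nodes[t3, 1] - nodes[t1, 1]) * (nodes[t2, 2] - nodes[t1, 2])) / 2
}
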