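#' Periodic triangulated membrane patch
#'
#' A `trimesh` is a triangulated surface embedded in 3-space, periodic in
#' `x` and `y` (torus topology, Euler characteristic 0) and unbounded in
#' `z`. It is the state of the simulated membrane: vertices are fluid
#' "nodes" of the surface, triangles carry the discrete bending and tension
#' energy, and a small set of frozen vertices pins the patch frame (mimicking
#' adhesion points; by default three equidistant boundary nodes).
#'
#' @param Lx,Ly box edge lengths in nm.
#' @param target_edge requested lattice edge length in nm. The realized
#'   edge lengths deviate slightly because the lattice must tile the box;
#'   if no commensurate lattice within 20% of the target exists the
#'   function errors.
#' @param seed integer stored with the mesh for provenance (the flat ground
#'   state itself is deterministic).
#' @param n_frozen number of equidistant frozen boundary vertices (default 3).
#' @return an object of class `trimesh`: a list with `vertices` (n x 3
#'   matrix, nm), `triangles` (m x 3 integer matrix, consistently oriented),
#'   `frozen` (logical), `Lx`, `Ly`, `target_edge`.
#' @examples
#' m <- build_flat_patch(120, 120, target_edge = 10)
#' mesh_euler(m)  # 0 for a torus
#' @export
build_flat_patch <- function(Lx, Ly, target_edge = 8, seed = 1L,
                             n_frozen = 3L) {
  stopifnot(Lx > 0, Ly > 0, target_edge > 0)
  ry_t <- target_edge * sqrt(3) / 2
  nx <- max(3L, as.integer(round(Lx / target_edge)))
  ny <- max(4L, 2L * as.integer(round(Ly / ry_t / 2)))
  ax <- Lx / nx
  ry <- Ly / ny
  e1 <- ax
  e2 <- sqrt((ax / 2)^2 + ry^2)
  dev <- max(abs(c(e1, e2) - target_edge)) / target_edge
  if (dev > 0.2) {
    stop(sprintf(
      "target_edge %.3g nm is not tileable in a %.3g x %.3g nm box ",
      target_edge, Lx, Ly
    ), sprintf("(realized edges %.3g / %.3g nm deviate %.0f%%)",
               e1, e2, 100 * dev))
  }

  idx <- function(i, j) (j %% ny) * nx + (i %% nx) + 1L
  n <- nx * ny
  V <- matrix(0, n, 3)
  for (j in seq_len(ny) - 1L) {
    shift <- if (j %% 2L == 1L) ax / 2 else 0
    for (i in seq_len(nx) - 1L) {
      V[idx(i, j), 1] <- (i * ax + shift) %% Lx
      V[idx(i, j), 2] <- j * ry
    }
  }
  Tlist <- vector("list", 2L * n)
  k <- 0L
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      if (j %% 2L == 0L) {
        t1 <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
        t2 <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      } else {
        t1 <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
        t2 <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
      }
      Tlist[[k + 1L]] <- t1
      Tlist[[k + 2L]] <- t2
      k <- k + 2L
    }
  }
  Tm <- do.call(rbind, Tlist)
  storage.mode(Tm) <- "integer"

  frozen <- logical(n)
  picks <- (round(seq(0, nx - 1, length.out = n_frozen + 1))[seq_len(n_frozen)])
  frozen[idx(as.integer(picks), 0L)] <- TRUE

  structure(
    list(
      vertices = V, triangles = Tm, frozen = frozen,
      Lx = Lx, Ly = Ly, target_edge = target_edge, seed = as.integer(seed)
    ),
    class = "trimesh"
  )
}

#' @export
print.trimesh <- function(x, ...) {
  e <- nrow(mesh_edges(x))
  cat(sprintf(
    "<trimesh> %d vertices, %d edges, %d triangles (chi = %d), box %.4g x %.4g nm, %d frozen\n",
    nrow(x$vertices), e, nrow(x$triangles),
    nrow(x$vertices) - e + nrow(x$triangles), x$Lx, x$Ly, sum(x$frozen)
  ))
  invisible(x)
}

#' Edge list of a triangulated mesh
#'
#' @param mesh a `trimesh`.
#' @return two-column integer matrix of unique undirected edges (i < j).
#' @export
mesh_edges <- function(mesh) {
  Tm <- mesh$triangles
  E <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  E <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  unique(E)
}

#' Euler characteristic V - E + F
#'
#' Zero for the genus-1 periodic patch, at all times and after any accepted
#' topology move.
#'
#' @param mesh a `trimesh`.
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

# minimum-image displacement (periodic in x, y only)
min_image <- function(d, Lx, Ly) {
  d[, 1] <- d[, 1] - Lx * round(d[, 1] / Lx)
  d[, 2] <- d[, 2] - Ly * round(d[, 2] / Ly)
  d
}

#' Minimum-image distance between points in a periodic box
#'
#' @param a,b matrices (or vectors) of 3D coordinates in nm.
#' @param Lx,Ly periodic box lengths in nm.
#' @export
periodic_distance <- function(a, b, Lx, Ly) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d <- min_image(a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE],
                 Lx, Ly)
  sqrt(rowSums(d^2))
}

#' Total mesh area
#'
#' Sum of triangle areas with minimum-image geometry.
#'
#' @param mesh a `trimesh`.
#' @return area in nm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  p1 <- V[Tm[, 1], , drop = FALSE]
  e1 <- min_image(V[Tm[, 2], , drop = FALSE] - p1, mesh$Lx, mesh$Ly)
  e2 <- min_image(V[Tm[, 3], , drop = FALSE] - p1, mesh$Lx, mesh$Ly)
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Validate mesh topology and constraints
#'
#' Checks that the mesh is a closed oriented 2-manifold of torus topology:
#' every directed edge appears exactly once (consistent orientation), every
#' undirected edge bounds exactly two triangles, there are no duplicate or
#' degenerate triangles, and V - E + F = 0.
#'
#' @param mesh a `trimesh`.
#' @param error if `TRUE` (default) stop on the first violation, otherwise
#'   return `FALSE` invisibly.
#' @return `TRUE` (invisibly) if valid.
#' @export
validate_mesh <- function(mesh, error = TRUE) {
  fail <- function(msg) {
    if (error) stop(msg) else return(invisible(FALSE))
  }
  V <- mesh$vertices
  Tm <- mesh$triangles
  if (any(Tm < 1L) || any(Tm > nrow(V))) return(fail("triangle index out of range"))
  if (any(Tm[, 1] == Tm[, 2] | Tm[, 2] == Tm[, 3] | Tm[, 1] == Tm[, 3])) {
    return(fail("degenerate triangle (repeated vertex)"))
  }
  key <- apply(Tm, 1, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) return(fail("duplicate triangle"))
  de <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  dk <- paste(de[, 1], de[, 2])
  if (anyDuplicated(dk)) return(fail("inconsistent orientation (repeated directed edge)"))
  uk <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  tab <- table(uk)
  if (any(tab != 2L)) return(fail("edge not shared by exactly 2 triangles"))
  if (mesh_euler(mesh) != 0L) return(fail("Euler characteristic != 0"))
  deg <- tabulate(Tm, nbins = nrow(V))
  if (any(deg < 3L)) return(fail("vertex with degree < 3 (or isolated)"))
  invisible(TRUE)
}

#' Construct a topology move
#'
#' @param kind one of `"edge_flip"`, `"vertex_insert"`, `"vertex_remove"`.
#' @param target for `edge_flip` an integer pair (the edge's vertices), for
#'   `vertex_insert` a triangle row index, for `vertex_remove` a vertex index.
#' @param coords optional 3-vector of coordinates (nm) for inserts; defaults
#'   to the target triangle's centroid.
#' @return a `topology_move` object.
#' @export
topology_move <- function(kind = c("edge_flip", "vertex_insert", "vertex_remove"),
                          target, coords = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, target = target, coords = coords),
            class = "topology_move")
}

# triangles containing the (undirected) edge a-b
.tris_with_edge <- function(Tm, a, b) {
  which(
    (Tm[, 1] == a | Tm[, 2] == a | Tm[, 3] == a) &
      (Tm[, 1] == b | Tm[, 2] == b | Tm[, 3] == b)
  )
}

#' Apply a reversible topology move
#'
#' Applies an edge flip, a vertex insertion (triangle split at the centroid
#' or at given coordinates) or a vertex removal (inverse of a centroid
#' split; only 3-coordinated, mobile vertices are removable) to a mesh.
#' All moves preserve manifoldness and the Euler characteristic; insertion
#' increments V by 1 and F by 2, removal does the reverse. Invalid moves
#' (frozen or non-removable target, flips that would duplicate an edge or
#' degenerate a triangle) raise an error and leave the mesh untouched.
#'
#' @param mesh a `trimesh`.
#' @param move a [topology_move()].
#' @return list with elements `mesh` (the new mesh) and `undo` (the
#'   `topology_move` that restores the previous state).
#' @export
apply_topology_move <- function(mesh, move) {
  stopifnot(inherits(move, "topology_move"))
  Tm <- mesh$triangles
  V <- mesh$vertices

  if (move$kind == "edge_flip") {
    a <- move$target[1]
    b <- move$target[2]
    ts <- .tris_with_edge(Tm, a, b)
    if (length(ts) != 2L) stop("edge not found or not interior")
    t1 <- ts[1]
    t2 <- ts[2]
    # c is the off-edge vertex of the triangle in which the edge runs a->b
    ord1 <- Tm[t1, ]
    if (!any(ord1 == a & c(ord1[-1], ord1[1]) == b)) {
      tmp <- t1; t1 <- t2; t2 <- tmp
    }
    cc <- setdiff(Tm[t1, ], c(a, b))
    dd <- setdiff(Tm[t2, ], c(a, b))
    if (length(.tris_with_edge(Tm, cc, dd)) > 0L) {
      stop("flip would duplicate an existing edge")
    }
    deg <- tabulate(Tm, nbins = nrow(V))
    if (deg[a] <= 3L || deg[b] <= 3L) stop("flip would create degree-2 vertex")
    Tm[t1, ] <- c(cc, a, dd)
    Tm[t2, ] <- c(dd, b, cc)
    out <- mesh
    out$triangles <- Tm
    validate_mesh(out)
    return(list(mesh = out, undo = topology_move("edge_flip", c(cc, dd))))
  }

  if (move$kind == "vertex_insert") {
    t <- move$target
    if (t < 1L || t > nrow(Tm)) stop("triangle not found")
    abc <- Tm[t, ]
    p1 <- V[abc[1], ]
    e2 <- min_image(rbind(V[abc[2], ] - p1), mesh$Lx, mesh$Ly)[1, ]
    e3 <- min_image(rbind(V[abc[3], ] - p1), mesh$Lx, mesh$Ly)[1, ]
    xw <- if (is.null(move$coords)) p1 + (e2 + e3) / 3 else move$coords
    xw[1] <- xw[1] %% mesh$Lx
    xw[2] <- xw[2] %% mesh$Ly
    w <- nrow(V) + 1L
    out <- mesh
    out$vertices <- rbind(V, xw)
    rownames(out$vertices) <- NULL
    out$frozen <- c(mesh$frozen, FALSE)
    out$triangles <- rbind(
      Tm[-t, , drop = FALSE],
      c(abc[1], abc[2], w),
      c(abc[2], abc[3], w),
      c(abc[3], abc[1], w)
    )
    storage.mode(out$triangles) <- "integer"
    validate_mesh(out)
    return(list(mesh = out, undo = topology_move("vertex_remove", w)))
  }

  # vertex_remove
  w <- move$target
  if (w < 1L || w > nrow(V)) stop("vertex not found")
  if (mesh$frozen[w]) stop("cannot remove a frozen vertex")
  ts <- which(Tm[, 1] == w | Tm[, 2] == w | Tm[, 3] == w)
  if (length(ts) != 3L) stop("vertex is not removable (degree != 3)")
  # ordered outer ring from the oriented fan
  t0 <- ts[1]
  rot <- Tm[t0, ]
  iw <- which(rot == w)
  a <- rot[(iw %% 3) + 1]
  b <- rot[((iw + 1) %% 3) + 1]
  cc <- setdiff(unique(as.vector(Tm[ts, ])), c(w, a, b))
  if (length(cc) != 1L) stop("vertex fan is not a simple triangle")
  deg <- tabulate(Tm, nbins = nrow(V))
  if (any(deg[c(a, b, cc)] <= 3L)) stop("removal would create degree-2 vertex")
  coords_w <- V[w, ]
  out <- mesh
  out$triangles <- rbind(Tm[-ts, , drop = FALSE], c(a, b, cc))
  # drop vertex w, remap indices
  keep <- setdiff(seq_len(nrow(V)), w)
  remap <- integer(nrow(V))
  remap[keep] <- seq_along(keep)
  out$vertices <- V[keep, , drop = FALSE]
  out$frozen <- mesh$frozen[keep]
  out$triangles <- matrix(remap[out$triangles], ncol = 3)
  storage.mode(out$triangles) <- "integer"
  validate_mesh(out)
  undo_t <- nrow(out$triangles) # the new (a,b,c) triangle is last
  list(mesh = out, undo = topology_move("vertex_insert", undo_t,
                                        coords = coords_w))
}

#' Per-vertex discrete geometry
#'
#' Cotangent-Laplacian mean curvature with barycentric vertex areas. The
#' curvature is signed with respect to the returned outward normal (the
#' area-weighted average of incident triangle normals); vertex areas
#' partition the total mesh area exactly.
#'
#' @param mesh a `trimesh`.
#' @param v optional vertex indices to return (default all).
#' @return data.frame with columns `area` (nm^2), `H` (1/nm), `nx`, `ny`,
#'   `nz` (unit normal).
#' @export
vertex_geometry <- function(mesh, v = NULL) {
  deg <- tabulate(mesh$triangles, nbins = nrow(mesh$vertices))
  if (is.null(v)) v <- seq_len(nrow(mesh$vertices))
  if (any(deg[v] < 3L)) {
    stop("vertex without a complete one-ring (isolated or degree < 3)")
  }
  g <- cpp_vertex_data(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(membrane_params(kappa = 1, gamma = 0))
  )
  data.frame(
    area = g$area[v], H = g$H[v],
    nx = g$normal[v, 1], ny = g$normal[v, 2], nz = g$normal[v, 3]
  )
}
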