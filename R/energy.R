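#' Membrane model parameters
#'
#' Parameters of the discrete Helfrich energy and its constraints. The
#' Hamiltonian is the discretized bending + tension functional
#' \deqn{E = \sum_v [ (\kappa/2)(2H_v)^2 + \gamma ] A_v}
#' with per-vertex mean curvature \eqn{H_v} and area share \eqn{A_v}.
#' Energies are in units of kT, lengths in nm.
#'
#' In fixed-vertex-count runs the tension enters through the explicit
#' `gamma` term. In grand-canonical runs the tension is controlled by the
#' fugacity `z` alone (one unit of `z` per vertex in the statistical
#' weight z^V exp(-E)) and `gamma` should be left at 0 to avoid counting
#' the area cost twice; [calibrate_fugacity()] maps between the two.
#'
#' @param kappa bending rigidity (kT). Default 20.
#' @param gamma explicit surface tension (kT/nm^2). Default 0.
#' @param z fugacity of the implicit lipid reservoir (dimensionless,
#'   relative to a 1 nm^3 reference volume per vertex). Default 1.
#' @param a_min,a_max tether (edge-length) limits in nm, defaults 4 and
#'   12. The band must be wide enough both for grand-canonical insertion
#'   near triangle centroids and for edge flips (whose new diagonal runs
#'   near sqrt(3) times the typical edge): flips keep the surface fluid,
#'   and fluidity is essential for the Helfrich fluctuation spectrum.
#'   Self-avoidance is enforced by the non-bonded hard-core pair checks
#'   and a triangle shape guard, not by the tether geometry alone.
#' @param d_mem membrane node hard-core diameter (nm). Default 5.
#'   Applies to non-bonded membrane pairs; edge-connected neighbours
#'   form the continuous sheet and are constrained by the tether limits
#'   instead (overlapping bonded beads make a smooth surface, as for
#'   filaments).
#' @param d_fil filament node hard-core diameter (nm). Default 10.
#'   Membrane-filament pairs exclude (d_mem + d_fil)/2.
#' @param r_ins,h_ins insertion proposal geometry (nm): new vertices are
#'   proposed uniformly in an oriented cylinder about the target
#'   triangle's centroid - a disk of radius `r_ins` in the triangle
#'   plane (cheap in bending energy) with half-thickness `h_ins` along
#'   the normal. The proposal volume enters the grand-canonical
#'   acceptance ratio; removals require the reverse-insertion region to
#'   contain the vertex.
#' @return a `membrane_params` object.
#' @export
membrane_params <- function(kappa = 20, gamma = 0, z = 1,
                            a_min = 4, a_max = 12, d_mem = 5,
                            d_fil = 10, r_ins = 2.5, h_ins = 0.7) {
  stopifnot(kappa > 0, a_min < a_max, z >= 0, r_ins > 0, h_ins > 0)
  structure(
    list(
      kappa = kappa, gamma = gamma, z = z, a_min = a_min, a_max = a_max,
      d_mem = d_mem, d_fil = d_fil, r_ins = r_ins, h_ins = h_ins
    ),
    class = "membrane_params"
  )
}

# internal: parameter list in the layout the C++ engine expects
.cpp_params <- function(p, gc = FALSE) {
  list(
    kappa = p$kappa, gamma = p$gamma, z = p$z, a_min = p$a_min,
    a_max = p$a_max, d_mem = p$d_mem, d_fil = p$d_fil, r_ins = p$r_ins,
    h_ins = p$h_ins, gc = isTRUE(gc)
  )
}

.fil_list <- function(filaments) {
  lapply(filaments, function(f) {
    list(
      nodes = f$nodes, Lp = f$Lp, delta = f$delta, d = f$d,
      rigid = isTRUE(f$rigid) || !is.finite(f$Lp)
    )
  })
}

#' Total membrane energy
#'
#' Discrete Helfrich bending plus tension energy; optionally decomposed
#' into contributions, and including the pulling-spring energy if a spring
#' is supplied.
#'
#' @param mesh a `trimesh`.
#' @param params a [membrane_params()].
#' @param spring optional [pulling_spring()].
#' @param parts if `TRUE`, return a list with `bending`, `tension`,
#'   `spring` and `total` (kT).
#' @return energy in kT.
#' @export
total_energy <- function(mesh, params, spring = NULL, parts = FALSE) {
  g <- cpp_vertex_data(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params)
  )
  bend <- sum(g$energy) - params$gamma * sum(g$area)
  tens <- params$gamma * sum(g$area)
  spr <- if (is.null(spring)) 0 else pulling_force(mesh, spring)$energy
  if (parts) {
    list(bending = bend, tension = tens, spring = spr,
         total = bend + tens + spr)
  } else {
    bend + tens + spr
  }
}

#' Incremental energy change of a proposed move
#'
#' For a vertex displacement the change is evaluated touching only the
#' one-ring neighbourhood of the displaced vertex (the implementation used
#' inside the Metropolis sampler); for a topology move the mesh delta is
#' evaluated on the affected vertex set. Displacing a frozen vertex is an
#' error.
#'
#' @param mesh a `trimesh`.
#' @param change either `list(vertex = v, to = c(x, y, z))` or a
#'   [topology_move()].
#' @param params a [membrane_params()].
#' @param spring optional [pulling_spring()].
#' @return the energy difference in kT.
#' @export
energy_delta <- function(mesh, change, params, spring = NULL) {
  if (inherits(change, "topology_move")) {
    after <- apply_topology_move(mesh, change)$mesh
    return(total_energy(after, params, spring) -
             total_energy(mesh, params, spring))
  }
  stopifnot(is.list(change), !is.null(change$vertex), !is.null(change$to))
  v <- change$vertex
  if (mesh$frozen[v]) stop("cannot displace a frozen vertex")
  spr <- if (is.null(spring)) NULL else .cpp_spring(spring)
  cpp_energy_delta_disp(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params), as.integer(v), as.numeric(change$to), spr
  )
}

#' Check tether and excluded-volume constraints
#'
#' A configuration passes iff every edge length lies in `[a_min, a_max]`,
#' no non-bonded membrane node pair is closer than `d_mem`
#' (edge-connected neighbours form the continuous sheet and are governed
#' by the tether limits), no membrane-filament node pair is closer than
#' `(d_mem + d_fil)/2`, and no filament-filament node pair is closer
#' than `d_fil` (nodes fewer than 5 apart along the same chain are
#' exempt: consecutive beads overlap by construction to form a smooth
#' excluded tube).
#'
#' @param mesh a `trimesh`.
#' @param params a [membrane_params()].
#' @param filaments list of [filament()] objects.
#' @return list with `ok` (logical) and, when violated, `what` (one of
#'   `"tether"`, `"mem-mem"`, `"mem-fil"`, `"fil-fil"`), the indices
#'   involved and the offending distance (nm).
#' @export
constraint_check <- function(mesh, params, filaments = list()) {
  cpp_constraint_check(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params), .fil_list(filaments)
  )
}

#' Harmonic pulling spring
#'
#' External potential used to pull membrane tubes, as in optical-tweezer
#' experiments: a harmonic spring of given stiffness acts on the mean
#' vertical position of a set of attachment vertices, anchored at a given
#' height.
#'
#' @param vertices integer vertex ids of the attachment set.
#' @param anchor anchor height in nm (measured from the frozen-boundary
#'   plane).
#' @param stiffness spring constant in kT/nm^2 (>= 0).
#' @return a `pulling_spring` object.
#' @export
pulling_spring <- function(vertices, anchor, stiffness) {
  stopifnot(length(vertices) >= 1, stiffness >= 0)
  structure(
    list(vertices = as.integer(vertices), anchor = anchor,
         stiffness = stiffness),
    class = "pulling_spring"
  )
}

.cpp_spring <- function(s) {
  list(ids = s$vertices, anchor = s$anchor, stiffness = s$stiffness)
}

#' Attachment vertices for a centred pulling disk
#'
#' Vertices within `radius` of the patch centre, the default attachment
#' set for tube pulling.
#'
#' @param mesh a `trimesh`.
#' @param radius disk radius in nm (default 10).
#' @export
attachment_disk <- function(mesh, radius = 10) {
  ctr <- c(mesh$Lx / 2, mesh$Ly / 2, 0)
  d <- periodic_distance(
    cbind(mesh$vertices[, 1], mesh$vertices[, 2], 0),
    matrix(ctr, 1), mesh$Lx, mesh$Ly
  )
  which(d <= radius)
}

#' Spring energy and instantaneous pulling force
#'
#' @param mesh a `trimesh`.
#' @param spring a [pulling_spring()].
#' @return list with `energy` (kT), `force` (kT/nm, positive pulling up),
#'   and `extension` (nm, the mean vertical position of the attachment
#'   set). Time-averaging over a run is up to the caller.
#' @export
pulling_force <- function(mesh, spring) {
  ids <- spring$vertices
  if (length(ids) == 0) stop("empty attachment set")
  zbar <- mean(mesh$vertices[ids, 3])
  d <- zbar - spring$anchor
  list(
    energy = 0.5 * spring$stiffness * d^2,
    force = spring$stiffness * (spring$anchor - zbar),
    extension = zbar
  )
}
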