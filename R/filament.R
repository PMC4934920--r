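#' Discretized worm-like-chain filament
#'
#' A filament is an inextensible chain of `n` segments of length `delta`
#' (one node per monomer; 2.7 nm corresponds to the added length per
#' polymerized actin monomer), with bending stiffness expressed through
#' the persistence length `Lp`. The first segment (the base) is fixed in
#' position and orientation for the whole run; the last node is the
#' growing barbed end. Nodes carry a hard-core diameter `d` (overlapping
#' spheres along the chain make a smooth excluded tube).
#'
#' @param base 3-vector, base node position (nm).
#' @param orientation unit 3-vector, base segment direction.
#' @param n initial monomer (segment) count, >= 1.
#' @param delta segment length (nm). Default 2.7.
#' @param Lp persistence length (nm). Default 15000 (15 um, actin).
#'   `Inf` makes the filament rigid.
#' @param d node hard-core diameter (nm). Default 10.
#' @param rigid if `TRUE` the filament never bends (equivalent to
#'   `Lp = Inf`).
#' @return a `filament` object with fields `nodes` ((n+1) x 3 matrix),
#'   `delta`, `Lp`, `d`, `rigid`, `base`, `orientation`.
#' @examples
#' f <- filament(c(0, 0, 0), c(0, 0, 1), n = 10)
#' wlc_bend_energy(f)  # 0: straight ground state
#' @export
filament <- function(base, orientation, n, delta = 2.7, Lp = 15000,
                     d = 10, rigid = FALSE) {
  stopifnot(n >= 1, delta > 0, Lp > 0)
  o <- orientation / sqrt(sum(orientation^2))
  nodes <- t(vapply(0:n, function(i) base + i * delta * o, numeric(3)))
  structure(
    list(
      nodes = nodes, delta = delta, Lp = Lp, d = d,
      rigid = isTRUE(rigid) || !is.finite(Lp),
      base = base, orientation = o
    ),
    class = "filament"
  )
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf(
    "<filament> n = %d monomers, contour %.4g nm, Lp = %.4g nm%s\n",
    n_monomers(x), n_monomers(x) * x$delta, x$Lp,
    if (x$rigid) " (rigid)" else ""
  ))
  invisible(x)
}

#' Monomer count of a filament
#' @param f a `filament`.
#' @export
n_monomers <- function(f) nrow(f$nodes) - 1L

#' Unit tangent vectors of the filament segments
#' @param f a `filament`.
#' @return n x 3 matrix of unit tangents.
#' @export
filament_tangents <- function(f) {
  d <- diff(f$nodes) / f$delta
  d / sqrt(rowSums(d^2))
}

#' Worm-like-chain bending energy
#'
#' The standard discretized WLC Hamiltonian
#' \deqn{E = (L_p/\delta) \sum_i (1 - \hat t_i \cdot \hat t_{i+1})}
#' in kT, with unit tangents of consecutive segments.
#'
#' @param f a `filament`.
#' @return energy in kT (0 for a straight filament).
#' @export
wlc_bend_energy <- function(f) {
  if (n_monomers(f) < 2) return(0)
  cpp_wlc_energy(f$nodes, f$Lp, f$delta)
}

#' Polymerize one monomer
#'
#' Appends one segment collinear with the current terminal tangent: the
#' barbed end grows straight along its instantaneous direction, locking in
#' whatever curvature the chain has at the moment of addition.
#'
#' @param f a `filament`.
#' @return the grown filament.
#' @export
grow <- function(f) {
  n <- n_monomers(f)
  tangent <- (f$nodes[n + 1, ] - f$nodes[n, ]) / f$delta
  f$nodes <- rbind(f$nodes, f$nodes[n + 1, ] + f$delta * tangent)
  rownames(f$nodes) <- NULL
  f
}

#' Depolymerize one monomer
#'
#' Removes the barbed-end node. The base segment can never depolymerize:
#' shrinking a single-monomer filament is an error.
#'
#' @param f a `filament`.
#' @return the shrunk filament.
#' @export
shrink <- function(f) {
  n <- n_monomers(f)
  if (n < 2) stop("cannot shrink: the base segment never depolymerizes")
  f$nodes <- f$nodes[-(n + 1), , drop = FALSE]
  f
}

#' Sample filament configurations by Monte Carlo
#'
#' Crankshaft and pivot (terminal free-rotation) moves with Metropolis
#' acceptance on the WLC bending energy, preserving segment lengths
#' exactly and never touching the base segment. If a membrane mesh is
#' supplied, moves violating the hard-core constraints against the
#' membrane (and between filaments) are rejected.
#'
#' @param filaments a `filament` or list of filaments.
#' @param sweeps number of MC sweeps (one sweep = one attempted move per
#'   segment).
#' @param mesh optional `trimesh` for steric coupling. If `NULL`, a
#'   remote dummy membrane far from the filaments is used so sterics never
#'   trigger (free-filament sampling).
#' @param params a [membrane_params()] (hard-core diameters).
#' @param amplitude rotation amplitude in radians.
#' @param sample_every store filament snapshots every this many sweeps
#'   (0 = none).
#' @param warmup warm-up sweeps with amplitude auto-tuning.
#' @param seed RNG seed.
#' @return list with `filaments` (final states), `snapshots` (list of
#'   per-sample filament node matrices), `acceptance` (fraction) and the
#'   post-warmup `amplitude`.
#' @export
run_filament_mc <- function(filaments, sweeps, mesh = NULL,
                            params = membrane_params(), amplitude = 0.2,
                            sample_every = 0, warmup = 0, seed = 1) {
  if (inherits(filaments, "filament")) filaments <- list(filaments)
  free_mode <- is.null(mesh)
  if (free_mode) {
    zs <- vapply(filaments, function(f) max(abs(f$nodes[, 3])), numeric(1))
    span <- max(1e4, 10 * max(zs, vapply(filaments, function(f) {
      n_monomers(f) * f$delta
    }, numeric(1))))
    mesh <- build_flat_patch(60, 60, target_edge = 10)
    mesh$vertices[, 3] <- span # far above: sterics never trigger
  }
  sch <- list(
    displace = 0, flip = 0, insert = 0, remove = 0,
    amplitude = 1, fil_amplitude = amplitude
  )
  out <- cpp_run_mc(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params, gc = FALSE), sch, .fil_list(filaments), NULL,
    as.integer(sweeps), 0L, as.integer(warmup), warmup > 0,
    as.integer(sample_every), TRUE, seed
  )
  fin <- lapply(seq_along(filaments), function(i) {
    f <- filaments[[i]]
    f$nodes <- out$filaments[[i]]$nodes
    f
  })
  acc <- out$counters$fil_acc / max(1, out$counters$fil_try)
  list(
    filaments = fin,
    snapshots = out$fil_snapshots,
    acceptance = acc,
    amplitude = out$fil_amplitude
  )
}
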