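#' Polymerization kinetics parameters
#'
#' Stochastic (de)polymerization is simulated by kinetic Monte Carlo:
#' reaction times are drawn from an exponential with total rate
#' N_fil (k_on0 + k_off); the reacting filament and channel are chosen in
#' proportion to their rates. A polymerization attempt adds one
#' delta-length segment along the barbed-end tangent and is accepted
#' whenever excluded volume permits, i.e. whenever the fluctuating
#' membrane (and the other filaments) can accommodate the new monomer;
#' otherwise it is a null event (time still advances). Between events,
#' `nu * dt` configurational Monte Carlo sweeps of membrane and filaments
#' are executed, coupling the reaction clock to the quasi-dynamics of the
#' conformational degrees of freedom.
#'
#' Time is measured in units of 1/k_on0 throughout, so `kon0 = 1` is the
#' natural choice; the default `koff = 0.01` reflects typical in-vitro
#' actin conditions k_on0/k_off = 100.
#'
#' @param kon0 bare polymerization attempt rate (1/time).
#' @param koff depolymerization rate (1/time).
#' @param nu configurational sweeps per unit reaction time. The default
#'   is chosen so the slowest resolved membrane modes of a desk-scale
#'   patch equilibrate in a small fraction of 1/k_on0; a sensitivity
#'   check (doubling nu) is part of the test suite.
#' @return a `growth_params` object.
#' @export
growth_params <- function(kon0 = 1, koff = 0.01, nu = 100) {
  stopifnot(kon0 >= 0, koff >= 0, nu > 0)
  structure(list(kon0 = kon0, koff = koff, nu = nu),
            class = "growth_params")
}

#' Run a stochastic growth trajectory
#'
#' Event-driven simulation of filaments polymerizing against the
#' fluctuating membrane. Runs to `max_time` (in units of 1/k_on0) or
#' until a stopping criterion fires: membrane height `stop_height`
#' reached (tube formed; 260 nm is the conventional reporting threshold)
#' or any filament reaching `stop_n` monomers. Deterministic given the
#' seed.
#'
#' @param mesh a `trimesh`.
#' @param params a [membrane_params()] (set `gamma = 0`, control tension
#'   via `z` when `gc = TRUE`).
#' @param filaments list of [filament()]s (at least one).
#' @param growth a [growth_params()].
#' @param max_time maximum simulated time (1/k_on0 units).
#' @param schedule a [move_schedule()].
#' @param gc grand-canonical membrane exchange on (default TRUE: growing
#'   protrusions draw area from the implicit reservoir).
#' @param stop_height stop when membrane height above the frozen plane
#'   reaches this (nm); 0 disables.
#' @param stop_n stop when a filament reaches this monomer count; 0
#'   disables.
#' @param warmup configurational warm-up sweeps before the clock starts.
#' @param tune auto-tune move amplitudes during warm-up.
#' @param snapshot_dt store filament + mesh snapshots every this much
#'   simulated time (0 = none).
#' @param seed RNG seed.
#' @return a `growth_trajectory`: list with `events` (data frame: t,
#'   filament, type (+1 on, -1 off), accepted, nseg, height), `mesh`,
#'   `filaments` (final states), `t_end`, `t_formed` (time the stopping
#'   criterion fired, or NA), `snapshots`, `counters`.
#' @export
run_growth <- function(mesh, params, filaments, growth = growth_params(),
                       max_time = 100, schedule = move_schedule(),
                       gc = TRUE, stop_height = 260, stop_n = 0,
                       warmup = 200, tune = TRUE, snapshot_dt = 0,
                       seed = 1) {
  stopifnot(length(filaments) >= 1)
  cc <- constraint_check(mesh, params, filaments)
  if (!isTRUE(cc$ok)) {
    stop(sprintf(
      "initial state violates constraints: %s (i=%s, j=%s, dist=%.3g nm)",
      cc$what, cc$i, cc$j, cc$dist
    ))
  }
  out <- cpp_run_growth(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params, gc = gc), .cpp_schedule(schedule),
    .fil_list(filaments), growth$kon0, growth$koff, growth$nu,
    max_time, stop_height, as.integer(stop_n), as.integer(warmup),
    isTRUE(tune), snapshot_dt, seed
  )
  out$mesh <- .mesh_from_cpp(out$mesh, mesh)
  out$filaments <- .filaments_from_cpp(out$filaments, filaments)
  class(out) <- "growth_trajectory"
  out
}

#' @export
print.growth_trajectory <- function(x, ...) {
  ev <- x$events
  cat(sprintf(
    "<growth_trajectory> %d events to t = %.4g; %d filaments; %s\n",
    nrow(ev), x$t_end, length(x$filaments),
    if (is.finite(x$t_formed)) sprintf("stopped at t = %.4g", x$t_formed)
    else "ran to max time"
  ))
  invisible(x)
}

#' Per-filament contour length versus time
#'
#' @param traj a `growth_trajectory`.
#' @param delta segment length (nm), default taken from the first
#'   filament.
#' @return data frame (t, filament, n, contour).
#' @export
contour_vs_time <- function(traj, delta = traj$filaments[[1]]$delta) {
  ev <- traj$events
  data.frame(
    t = ev$t, filament = ev$filament, n = ev$nseg,
    contour = ev$nseg * delta
  )
}

#' Effective polymerization acceptance versus monomer count
#'
#' Empirical estimate of k_on(n)/k_on0: among on-events attempted at
#' monomer count n, the fraction accepted. This is the simulation-side
#' observable behind the polymerization-ratchet comparison
#' k_on(n)/k_on0 ~ exp(-f(L) delta / kT) and behind the P_bend oracle for
#' the reduced bundling model.
#'
#' @param traj a `growth_trajectory` (or its `events` data frame).
#' @param filament restrict to one filament id (default: all).
#' @return data frame (n, attempts, accepted, p, se) where `n` is the
#'   monomer count at which addition was attempted.
#' @export
acceptance_by_n <- function(traj, filament = NULL) {
  ev <- if (is.data.frame(traj)) traj else traj$events
  on <- ev[ev$type == 1, ]
  if (!is.null(filament)) on <- on[on$filament %in% filament, ]
  # nseg column is the count AFTER the event: attempted-at n is nseg - acc
  n_at <- on$nseg - on$accepted
  agg <- stats::aggregate(
    cbind(attempts = rep(1, nrow(on)), accepted = on$accepted),
    by = list(n = n_at), FUN = sum
  )
  agg$p <- agg$accepted / agg$attempts
  agg$se <- sqrt(pmax(agg$p * (1 - agg$p), 1e-12) / agg$attempts)
  agg
}
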