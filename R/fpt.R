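#' Tilted-membrane single-filament scenario
#'
#' Reduced model of a remote filament growing beneath the membrane
#' deformation caused by a nascent bundle: the membrane is represented by
#' a static plane at distance `L0` from the filament base along the plane
#' normal, with the filament base oriented at relative angle `theta` from
#' the normal, plus equilibrium height fluctuations of the surrounding
#' patch. (Working in the membrane frame: the plane is horizontal and the
#' filament is tilted; only the relative angle and normal distance
#' matter.)
#'
#' The filament adds monomers freely at rate k_on0 until its straight
#' tip approaches the plane; subsequent additions await a thermal
#' fluctuation opening a gap of one segment length, supplied by the
#' clamped filament's transverse tip mode and by the local membrane
#' height mode. Accepted monomers lock in the acquired curvature, so the
#' reference (ground-state) shape bends progressively toward the plane;
#' once the ground-state tip tangent is (nearly) parallel to the plane,
#' growth is unimpeded again - the absorbing "bent and growing" state.
#'
#' @param theta relative filament-membrane angle in degrees, 0 <= theta
#'   < 90. `theta = 0` is the head-on geometry: transverse tip
#'   fluctuations then give no first-order clearance, there is no bent
#'   escape state and the absorbing index is infinite.
#' @param L0 base-membrane distance along the plane normal (nm).
#' @param kappa,gamma membrane bending rigidity (kT) and tension
#'   (kT/nm^2): set the membrane fluctuation variance.
#' @param Lp,delta filament persistence length and segment length (nm).
#' @param patch_L lateral patch size (nm) whose discrete modes enter the
#'   membrane height variance (long-wavelength cutoff).
#' @param mesh_edge smallest resolved membrane wavelength (nm):
#'   short-wavelength cutoff of the mode sum.
#' @param parallel_tol ground-state tip direction cosine below which the
#'   tip counts as parallel to the plane (absorbing state).
#' @return a `tilt_scenario` object with derived fields `n_c` (largest
#'   monomer count growing unimpeded), `sigma_m2` (membrane height
#'   variance, nm^2).
#' @export
tilt_scenario <- function(theta = 45, L0 = 60, kappa = 20, gamma = 0.01,
                          Lp = 15000, delta = 2.7, patch_L = 140,
                          mesh_edge = 8, parallel_tol = 0.05) {
  stopifnot(theta >= 0, theta < 90, L0 > 0, kappa > 0, Lp > 0, delta > 0)
  th <- theta * pi / 180
  n_c <- floor(L0 / (delta * cos(th)) - 1)
  if (n_c < 1) {
    stop("filament starts in contact with the membrane (L0 too small ",
         "or theta too large)")
  }
  structure(
    list(
      theta = theta, theta_rad = th, L0 = L0, kappa = kappa, gamma = gamma,
      Lp = Lp, delta = delta, patch_L = patch_L, mesh_edge = mesh_edge,
      parallel_tol = parallel_tol, n_c = n_c,
      sigma_m2 = membrane_height_variance(kappa, gamma, patch_L, mesh_edge)
    ),
    class = "tilt_scenario"
  )
}

#' Equilibrium local height variance of a membrane patch
#'
#' Sum of 1/[A (kappa q^4 + gamma q^2)] over the discrete modes of an
#' L x L patch between the patch-size and mesh-resolution cutoffs (kT
#' units). This is the variance of the local height of a thermally
#' fluctuating patch, the membrane's contribution to gap-opening
#' fluctuations.
#'
#' @param kappa bending rigidity (kT).
#' @param gamma tension (kT/nm^2).
#' @param L patch size (nm).
#' @param mesh_edge resolution cutoff (nm).
#' @return variance in nm^2.
#' @export
membrane_height_variance <- function(kappa, gamma, L, mesh_edge = 8) {
  kmax <- max(1L, floor(L / (2 * mesh_edge)))
  k <- seq(-kmax, kmax)
  kx <- rep(k, length(k))
  ky <- rep(k, each = length(k))
  q2 <- (2 * pi / L)^2 * (kx^2 + ky^2)
  q2 <- q2[q2 > 0]
  sum(1 / (L^2 * (kappa * q2^2 + gamma * q2)))
}

# Constrained planar ground state of an n-segment chain clamped at angle
# theta from the plane normal, required to stay below the plane z = L0.
# Returns tangent angles (from the normal) at the optimum.
.ground_state <- function(n, s, phi_init = NULL) {
  th <- s$theta_rad
  if (n == 1) return(th)
  stiff <- s$Lp / s$delta
  # straight chain feasible?
  if (n * s$delta * cos(th) <= s$L0) return(rep(th, n))
  if (s$theta == 0) return(rep(0, n)) # head-on: no downhill bias, stay straight
  m <- n - 1 # free angles phi_2..phi_n
  phi0 <- if (!is.null(phi_init) && length(phi_init) == m) phi_init
          else rep(th, m)
  obj <- function(phi, w) {
    ang <- c(th, phi)
    bend <- stiff * sum(1 - cos(diff(ang)))
    z <- s$delta * cumsum(cos(ang))
    viol <- pmax(0, z - s$L0)
    bend + w * sum(viol^2)
  }
  grad <- function(phi, w) {
    ang <- c(th, phi)
    dphi <- diff(ang)
    z <- s$delta * cumsum(cos(ang))
    viol <- pmax(0, z - s$L0)
    # d(bend)/d(ang_i), i = 2..n
    g <- stiff * (sin(dphi) - c(sin(dphi[-1]), 0))
    # d(penalty)/d(ang_i) = -2 w delta sin(ang_i) sum_{k>=i} viol_k
    tailsum <- rev(cumsum(rev(viol)))
    g <- g - 2 * w * s$delta * sin(ang[-1]) * tailsum[-1]
    g
  }
  w <- 100
  phi <- phi0
  for (it in 1:8) {
    o <- stats::optim(phi, obj, grad, w = w, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-12))
    phi <- o$par
    z <- s$delta * cumsum(cos(c(th, phi)))
    if (max(z - s$L0) < 1e-6 * s$L0) break
    w <- w * 10
  }
  c(th, phi)
}

#' Clearance profile of the growing filament
#'
#' For each monomer count n up to `n_max`, computes the constrained
#' ground-state shape, the clearance the tip must gain to accommodate one
#' more segment under the plane, and the ground-state tip angle. Also
#' identifies the contact index `n_c` (free growth below it) and the
#' absorbing index `n_star` (ground-state tip tangent parallel to the
#' plane within tolerance; `Inf` for the head-on geometry).
#'
#' @param s a [tilt_scenario()].
#' @param n_max largest monomer count to profile (default: up to the
#'   absorbing state, capped at 400).
#' @return data.frame (n, gap, phi_tip, z_tip) with attributes `n_c`
#'   and `n_star`.
#' @export
gap_profile <- function(s, n_max = NULL) {
  stopifnot(inherits(s, "tilt_scenario"))
  cap <- if (is.null(n_max)) 400L else n_max
  rows <- vector("list", cap)
  phi_prev <- NULL
  n_star <- Inf
  for (n in seq_len(cap)) {
    ang <- .ground_state(n, s, phi_prev)
    phi_prev <- c(ang[-1], ang[length(ang)]) # warm start for n+1
    z <- s$delta * cumsum(cos(ang))
    phi_tip <- ang[length(ang)]
    g <- max(0, z[n] + s$delta * cos(phi_tip) - s$L0)
    E_gs <- (s$Lp / s$delta) * sum(1 - cos(diff(ang)))
    rows[[n]] <- data.frame(n = n, gap = g, phi_tip = phi_tip,
                            z_tip = z[n], E_gs = E_gs)
    if (s$theta > 0 && cos(phi_tip) <= s$parallel_tol) {
      n_star <- n
      if (is.null(n_max)) {
        rows <- rows[seq_len(n)]
        break
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_c") <- s$n_c
  attr(out, "n_star") <- n_star
  out
}

#' Required clearance for the next monomer
#'
#' @param n monomer count(s).
#' @param s a [tilt_scenario()].
#' @return list with `clearance` (nm, 0 during free growth), `n_c`, and
#'   `n_star`.
#' @export
required_gap <- function(n, s) {
  prof <- gap_profile(s, n_max = max(n))
  list(
    clearance = prof$gap[n],
    n_c = attr(prof, "n_c"),
    n_star = attr(prof, "n_star")
  )
}

#' Gap-opening probability for monomer addition
#'
#' Equilibrium probability of a fluctuation that lets one more monomer
#' fit under the plane. Two factors multiply: (i) the Gaussian-tail
#' probability that the combined softest-mode fluctuations of the
#' clamped filament (transverse tip mode, variance l^3/(3 Lp) projected
#' onto the plane normal through the ground-state tip angle) and of the
#' membrane (local height mode, [membrane_height_variance()]) open the
#' required clearance; and (ii) the Boltzmann factor of the ground-state
#' bending-energy increment that the accepted monomer locks in - the
#' elastic cost of curving the chain further toward the plane, which is
#' what makes poorly aligned (small theta) filaments exponentially slow
#' to recruit. Returns 1 during free growth (n < n_c) and is monotone
#' non-increasing in the required clearance at fixed elastic increment.
#'
#' @param n monomer count(s).
#' @param s a [tilt_scenario()].
#' @param profile optionally a precomputed [gap_profile()].
#' @return probability in (0, 1].
#' @export
p_bend <- function(n, s, profile = NULL) {
  if (is.null(profile)) profile <- gap_profile(s, n_max = max(n) + 1)
  g <- profile$gap[n]
  phi <- profile$phi_tip[n]
  ell <- n * s$delta
  sigma2 <- (ell^3 / (3 * s$Lp)) * sin(phi)^2 + s$sigma_m2
  dE <- pmax(0, profile$E_gs[pmin(n + 1, nrow(profile))] - profile$E_gs[n])
  p <- 2 * stats::pnorm(g / sqrt(sigma2), lower.tail = FALSE) * exp(-dE)
  ifelse(g <= 0, 1, pmin(1, p))
}

#' Effective polymerization-rate ladder
#'
#' k_on(n) = k_on0 * P_bend(n -> n+1), feeding the birth-death master
#' equation. The state at `n_star` (bent-and-growing) is absorbing.
#'
#' @param s a [tilt_scenario()].
#' @param kon0 bare on-rate (1/time).
#' @param koff off-rate (suppressed out of n = 1: the base never
#'   depolymerizes).
#' @return a `rate_ladder`: list with `kon` (vector over n = 1 ..
#'   n_star - 1), `koff`, `n_c`, `n_star`, `profile`.
#' @export
rate_ladder <- function(s, kon0 = 1, koff = 0.01) {
  prof <- gap_profile(s)
  n_star <- attr(prof, "n_star")
  if (!is.finite(n_star)) {
    stop("no bent escape state for this scenario (theta = 0): ",
         "the absorbing index is infinite")
  }
  kon <- kon0 * p_bend(seq_len(n_star - 1), s, profile = prof)
  structure(
    list(kon = kon, koff = koff, kon0 = kon0, n_c = attr(prof, "n_c"),
         n_star = n_star, profile = prof, scenario = s),
    class = "rate_ladder"
  )
}

#' Solve the growth master equation
#'
#' Birth-death master equation for the monomer-count distribution
#' P(n, t):
#' dP(n)/dt = koff [P(n+1) - P(n)] + kon(n-1) P(n-1) - kon(n) P(n),
#' with a reflecting boundary at n = 1 (no depolymerization of the base
#' segment) and an absorbing boundary at n_star. Probability (including
#' the absorbed mass) is conserved to the solver tolerance (1e-10).
#'
#' @param ladder a [rate_ladder()] (or a list with `kon`, `koff`,
#'   `n_star`).
#' @param P0 initial distribution over n = 1 .. n_star (must sum to 1).
#' @param t_grid increasing time points (first entry taken as t0).
#' @return matrix P with `length(t_grid)` rows and n_star columns
#'   (column n_star is the absorbed mass), with attribute `t`.
#' @export
evolve_master_equation <- function(ladder, P0, t_grid) {
  ns <- ladder$n_star
  kon <- ladder$kon
  koff <- ladder$koff
  if (abs(sum(P0) - 1) > 1e-8) stop("P0 is not normalized")
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be increasing")
  if (length(P0) != ns) stop("P0 must have length n_star")
  n <- ns - 1 # transient states 1..ns-1
  rhs <- function(t, P, parms) {
    up <- kon[1:n] * P[1:n] # n -> n+1
    dP <- numeric(ns)
    dP[1:n] <- -up
    if (n >= 2) {
      dn <- koff * P[2:n] # n -> n-1 (reflecting at 1, absorbing at ns)
      dP[2:n] <- dP[2:n] - dn + up[1:(n - 1)]
      dP[1:(n - 1)] <- dP[1:(n - 1)] + dn
    }
    dP[ns] <- dP[ns] + up[n]
    list(dP)
  }
  sol <- deSolve::ode(
    y = P0, times = t_grid, func = rhs, parms = NULL,
    method = "lsode", rtol = 1e-10, atol = 1e-12, maxsteps = 50000
  )
  P <- unname(sol[, -1, drop = FALSE])
  structure(P, t = sol[, 1])
}

#' First-passage statistics of the bending transition
#'
#' The first-passage-time density p(tau) to the absorbing bent state is
#' the flux into n_star (the time derivative of the absorbed mass),
#' obtained from the master-equation solution; the mean first passage
#' time is computed independently by the standard closed-form recursion
#' for birth-death chains, and the two must agree.
#'
#' @param ladder a [rate_ladder()].
#' @param n0 initial monomer count (default 1).
#' @param t_max integrate to this time (default 40 x the closed-form
#'   MFPT).
#' @param nt time-grid points.
#' @return list with `t`, `p` (density on the grid), `mfpt` (from
#'   integrating the density), `mfpt_closed` (closed-form), `absorbed`
#'   (final absorbed mass).
#' @export
first_passage_stats <- function(ladder, n0 = 1, t_max = NULL, nt = 4000) {
  ns <- ladder$n_star
  mf <- mfpt_closed(ladder, n0)
  if (!is.finite(mf)) {
    warning("MFPT is infinite (a dead rung with koff = 0)")
    return(list(t = numeric(0), p = numeric(0), mfpt = Inf,
                mfpt_closed = Inf, absorbed = 0))
  }
  if (is.null(t_max)) t_max <- 40 * mf
  tg <- seq(0, t_max, length.out = nt)
  P0 <- numeric(ns)
  P0[n0] <- 1
  P <- evolve_master_equation(ladder, P0, tg)
  flux <- ladder$kon[ns - 1] * P[, ns - 1]
  B <- P[, ns]
  # MFPT = integral of the survival function 1 - B(t), plus an
  # exponential-tail correction from the final flux
  surv <- 1 - B
  mfpt <- sum((surv[-1] + surv[-nt]) / 2 * diff(tg))
  tail_rate <- flux[nt] / max(surv[nt], 1e-300)
  if (surv[nt] > 0 && tail_rate > 0) mfpt <- mfpt + surv[nt] / tail_rate
  list(t = tg, p = flux, mfpt = mfpt, mfpt_closed = mf,
       absorbed = B[nt])
}

#' Closed-form mean first passage time of the birth-death ladder
#'
#' Recursion for the expected time h_k to first step from k to k+1 with
#' reflecting bottom: h_1 = 1/kon(1), h_k = (1 + koff h_(k-1))/kon(k);
#' the MFPT from n0 to n_star is the sum of h_k over k = n0 ..
#' n_star - 1.
#'
#' @param ladder a [rate_ladder()].
#' @param n0 starting monomer count.
#' @export
mfpt_closed <- function(ladder, n0 = 1) {
  ns <- ladder$n_star
  kon <- ladder$kon
  koff <- ladder$koff
  if (any(kon == 0) && koff == 0) return(Inf)
  h <- numeric(ns - 1)
  h[1] <- 1 / kon[1]
  if (ns > 2) {
    for (k in 2:(ns - 1)) h[k] <- (1 + koff * h[k - 1]) / kon[k]
  }
  sum(h[n0:(ns - 1)])
}

#' Mean first-passage-time map over tilt angle and distance
#'
#' MFPT of the bending transition for each (theta, L0) pair, computed
#' from the closed-form birth-death sum on the per-scenario rate ladder.
#' The map varies by orders of magnitude across modest parameter
#' changes; theta = 0 columns are infinite (no bent escape state).
#'
#' @param theta_range tilt angles (degrees).
#' @param L0_range base-membrane distances (nm).
#' @param base a [tilt_scenario()] supplying the remaining parameters.
#' @param kon0,koff rates.
#' @param n0 starting monomer count.
#' @return matrix of MFPTs (rows = L0, columns = theta) with dimnames.
#' @export
mfpt_map <- function(theta_range, L0_range, base = tilt_scenario(),
                     kon0 = 1, koff = 0.01, n0 = 1) {
  M <- matrix(NA_real_, length(L0_range), length(theta_range),
              dimnames = list(L0 = L0_range, theta = theta_range))
  for (i in seq_along(L0_range)) {
    for (j in seq_along(theta_range)) {
      if (theta_range[j] == 0) {
        M[i, j] <- Inf
        next
      }
      s <- tilt_scenario(
        theta = theta_range[j], L0 = L0_range[i], kappa = base$kappa,
        gamma = base$gamma, Lp = base$Lp, delta = base$delta,
        patch_L = base$patch_L, mesh_edge = base$mesh_edge,
        parallel_tol = base$parallel_tol
      )
      lad <- rate_ladder(s, kon0 = kon0, koff = koff)
      M[i, j] <- mfpt_closed(lad, n0)
    }
  }
  M
}

#' Stochastic simulation of the rate ladder
#'
#' Continuous-time (Gillespie) realisations of the same birth-death
#' chain, used as an independent oracle for the master-equation solver
#' and its first-passage statistics.
#'
#' @param ladder a [rate_ladder()].
#' @param n0 starting monomer count.
#' @param n_rep number of replicas.
#' @param t_max give up beyond this time (NA returned).
#' @param seed RNG seed.
#' @return vector of first passage times.
#' @export
simulate_ladder_fpt <- function(ladder, n0 = 1, n_rep = 1e4,
                                t_max = Inf, seed = 1) {
  tm <- if (is.finite(t_max)) t_max else 1e12
  cpp_bd_first_passage(
    ladder$kon, ladder$koff, as.integer(n0),
    as.integer(ladder$n_star), as.integer(n_rep), tm, seed
  )
}
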