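#' Tube height, radius and inferred tension
#'
#' The tube height L is the maximum membrane height above the
#' frozen-boundary plane. The radius R is a least-squares (Kasa) circle
#' fit, in the lateral plane, to the membrane vertices with height in
#' [L/3, 2L/3] (the cylindrical mid-section). The tension of a fully
#' grown tube follows from the zero-temperature tube relation
#' gamma = kappa / (2 R^2). When no protrusion stands clear of the
#' thermal roughness of the patch (L below ~4x the robust height spread)
#' the radius is undefined and the metrics are flagged.
#'
#' @param mesh a `trimesh`.
#' @param kappa bending rigidity (kT) used for the tension inference.
#' @return list with `L` (nm), `R` (nm or NA), `gamma` (kT/nm^2 or NA),
#'   `axis` (lateral tube axis position), `has_tube`.
#' @export
tube_metrics <- function(mesh, kappa = 20) {
  V <- mesh$vertices
  z_ref <- if (any(mesh$frozen)) mean(V[mesh$frozen, 3]) else 0
  h <- V[, 3] - z_ref
  L <- max(h)
  no_tube <- list(L = L, R = NA_real_, gamma = NA_real_, axis = c(NA, NA),
                  has_tube = FALSE)
  # a protrusion clearly above thermal roughness, with enough mid-section
  # vertices for a cylinder fit
  if (L < 15) return(no_tube)
  sel <- h >= L / 3 & h <= 2 * L / 3
  if (sum(sel) < 6) return(no_tube)
  # recentre laterally about the apex vertex (periodic-safe)
  apex <- V[which.max(h), 1:2]
  d <- min_image(cbind(V[sel, 1] - apex[1], V[sel, 2] - apex[2], 0),
                 mesh$Lx, mesh$Ly)
  x <- d[, 1]
  y <- d[, 2]
  # Kasa circle fit: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  sol <- tryCatch(qr.solve(A, x^2 + y^2), error = function(e) NULL)
  if (is.null(sol)) {
    return(list(L = L, R = NA_real_, gamma = NA_real_, axis = c(NA, NA),
                has_tube = FALSE))
  }
  R <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  # fit-quality gate: the mid-section must actually look like a cylinder
  resid <- sqrt((x - sol[1])^2 + (y - sol[2])^2) - R
  if (!is.finite(R) || R > min(mesh$Lx, mesh$Ly) / 3 ||
        sqrt(mean(resid^2)) > 0.5 * R) {
    return(no_tube)
  }
  axis <- c((apex[1] + sol[1]) %% mesh$Lx, (apex[2] + sol[2]) %% mesh$Ly)
  list(L = L, R = R, gamma = kappa / (2 * R^2), axis = axis,
       has_tube = TRUE)
}

#' Force-extension curve of a pulled membrane tube
#'
#' Pulls the central attachment disk to a sequence of anchor heights
#' (ascending, each continuing from the previous state), equilibrates,
#' and time-averages the spring force at each held extension. The curve
#' rises from ~0, peaks, then decays toward the asymptotic long-tube
#' plateau f0 = 2 pi sqrt(2 kappa gamma).
#'
#' @param mesh a `trimesh` (flat starting patch).
#' @param params a [membrane_params()] (grand-canonical: `gamma = 0`,
#'   tension set by `z`).
#' @param L_targets anchor heights (nm), ascending.
#' @param stiffness spring constant (kT/nm^2).
#' @param sweeps production sweeps per target.
#' @param warmup equilibration sweeps per target.
#' @param gc use grand-canonical exchange (default TRUE; tubes need to
#'   draw area from the reservoir).
#' @param disk_radius attachment disk radius (nm).
#' @param seed RNG seed.
#' @return data.frame (L_target, L, force, se, stationary, R) where `L`
#'   is the mean measured extension, `se` a block standard error and
#'   `stationary` flags agreement of first/second-half averages within
#'   3 combined errors.
#' @export
force_extension <- function(mesh, params, L_targets, stiffness = 2,
                            sweeps = 4000, warmup = 2000, gc = TRUE,
                            disk_radius = 10, seed = 1) {
  disk <- attachment_disk(mesh, disk_radius)
  state <- mesh
  out <- vector("list", length(L_targets))
  for (i in seq_along(L_targets)) {
    spr <- pulling_spring(disk, L_targets[i], stiffness)
    r <- run_membrane_mc(
      state, params, sweeps = sweeps, gc = gc, spring = spr,
      sample_every = 10, warmup = warmup, tune = i == 1,
      record_every = max(100, sweeps %/% 30), seed = seed + 17 * i
    )
    state <- r$mesh
    # grand-canonical exchange reindexes vertices: carry the remapped
    # attachment set into the next stage
    if (length(r$spring_ids)) disk <- r$spring_ids
    f <- r$samples$force
    nb <- 10
    bm <- tapply(f, cut(seq_along(f), nb, labels = FALSE), mean)
    se <- stats::sd(bm) / sqrt(nb)
    h1 <- mean(f[seq_len(length(f) %/% 2)])
    h2 <- mean(f[-seq_len(length(f) %/% 2)])
    stat_ok <- abs(h1 - h2) <= 3 * se * sqrt(2)
    Rs <- vapply(r$snapshots, function(Vm) {
      tm <- tube_metrics(.mesh_from_V(Vm, state), params$kappa)
      if (isTRUE(tm$has_tube)) tm$R else NA_real_
    }, numeric(1))
    out[[i]] <- data.frame(
      L_target = L_targets[i], L = mean(r$samples$zbar),
      force = mean(f), se = se, stationary = stat_ok,
      R = mean(Rs, na.rm = TRUE)
    )
  }
  res <- do.call(rbind, out)
  attr(res, "final_state") <- state
  res
}

#' Asymptotic tube force and radius at zero temperature
#'
#' The printed closed forms for an ideal membrane tube: radius
#' R0 = sqrt(kappa / (2 gamma)) and plateau pulling force
#' f0 = 2 pi sqrt(2 kappa gamma).
#'
#' @param kappa bending rigidity (kT).
#' @param gamma surface tension (kT/nm^2).
#' @return list with `R0` (nm) and `f0` (kT/nm).
#' @export
tube_closed_forms <- function(kappa, gamma) {
  list(R0 = sqrt(kappa / (2 * gamma)), f0 = 2 * pi * sqrt(2 * kappa * gamma))
}

#' Classify filaments at an analysis frame
#'
#' Three-way taxonomy of a tube-forming run: (i) `bundled` filaments
#' whose barbed end lies within `r_factor * R` of the tube axis and
#' above `h_factor * L`; (ii) `failed` filaments whose barbed-end
#' tangent points away from the membrane (polar angle > `fail_angle`);
#' (iii) `unbundled` remainder. Labels are exhaustive and exclusive
#' (bundled takes precedence). The thresholds are analysis choices, kept
#' configurable.
#'
#' @param filaments list of [filament()]s.
#' @param metrics a [tube_metrics()] result.
#' @param mesh the `trimesh` (for the periodic box and reference plane).
#' @param r_factor,h_factor,fail_angle thresholds (defaults 1.5, 0.5,
#'   90 degrees).
#' @return factor vector with levels bundled/unbundled/failed.
#' @export
classify_filaments <- function(filaments, metrics, mesh, r_factor = 1.5,
                               h_factor = 0.5, fail_angle = 90) {
  z_ref <- if (any(mesh$frozen)) mean(mesh$vertices[mesh$frozen, 3]) else 0
  lab <- vapply(filaments, function(f) {
    n <- nrow(f$nodes)
    tip <- f$nodes[n, ]
    tangent <- (f$nodes[n, ] - f$nodes[n - 1, ])
    tangent <- tangent / sqrt(sum(tangent^2))
    polar <- acos(pmin(1, pmax(-1, tangent[3]))) * 180 / pi
    if (isTRUE(metrics$has_tube)) {
      rdist <- periodic_distance(
        c(tip[1], tip[2], 0), c(metrics$axis, 0), mesh$Lx, mesh$Ly
      )
      if (rdist <= r_factor * metrics$R &&
            (tip[3] - z_ref) >= h_factor * metrics$L) {
        return("bundled")
      }
    }
    if (polar > fail_angle) return("failed")
    "unbundled"
  }, character(1))
  factor(lab, levels = c("bundled", "unbundled", "failed"))
}

#' Alignment profile of filament segments versus height
#'
#' For each height bin [L, L + dL), the norm of the mean unit
#' orientation of the filament segments whose midpoint height falls in
#' the bin: a(L) = |sum_i o_i| / N, between 0 (isotropic or antiparallel)
#' and 1 (perfectly aligned). Empty bins are skipped.
#'
#' @param filaments list of [filament()]s.
#' @param dL bin width (nm), default 10.
#' @param z_ref height reference (frozen-boundary plane), default 0.
#' @return data.frame (L, a, n) with bin lower edges.
#' @export
alignment_profile <- function(filaments, dL = 10, z_ref = 0) {
  segs <- do.call(rbind, lapply(filaments, function(f) {
    d <- diff(f$nodes)
    t_hat <- d / sqrt(rowSums(d^2))
    zmid <- (f$nodes[-1, 3] + f$nodes[-nrow(f$nodes), 3]) / 2 - z_ref
    cbind(zmid, t_hat)
  }))
  bins <- floor(segs[, 1] / dL)
  out <- lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    m <- colSums(segs[sel, 2:4, drop = FALSE])
    data.frame(L = b * dL, a = sqrt(sum(m^2)) / sum(sel), n = sum(sel))
  })
  do.call(rbind, out)
}

#' Random filament layout beneath the membrane
#'
#' `N_fil` filaments anchored at uniformly random lateral positions at
#' `depth` nm below the membrane plane, with polar angles drawn from a
#' half-Gaussian of standard deviation `std` degrees about the membrane
#' normal (std = 0 reproduces the perpendicular ensemble) and uniform
#' azimuths. The layout is rejected and redrawn until free of steric
#' violations between filaments; reproducible from the seed.
#'
#' @param N_fil number of filaments.
#' @param std polar-angle standard deviation (degrees).
#' @param depth base depth below the membrane plane (nm), default 50.
#' @param Lx,Ly lateral box (nm).
#' @param n0 initial monomers per filament.
#' @param delta,Lp,d filament parameters (see [filament()]).
#' @param z_plane membrane plane height (nm), default 0.
#' @param seed RNG seed.
#' @param max_tries placement attempts before giving up.
#' @return list with `filaments`, `table` (data.frame of bases and
#'   angles) and the `seed`.
#' @export
generate_initial_condition <- function(N_fil, std = 0, depth = 50,
                                       Lx = 140, Ly = 140, n0 = 1,
                                       delta = 2.7, Lp = 15000, d = 10,
                                       z_plane = 0, seed = 1,
                                       max_tries = 2000) {
  stopifnot(N_fil >= 1, std >= 0)
  .with_seed(seed, {
    bases <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(bases) < N_fil) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop(sprintf(
          "cannot place %d filaments without overlap in %g x %g box",
          N_fil, Lx, Ly
        ))
      }
      cand <- stats::runif(2) * c(Lx, Ly)
      if (nrow(bases) > 0) {
        dd <- periodic_distance(
          cbind(bases[, 1], bases[, 2], 0),
          matrix(c(cand, 0), 1), Lx, Ly
        )
        if (any(dd < d)) next
      }
      bases <- rbind(bases, cand)
    }
    polar <- abs(stats::rnorm(N_fil, 0, std)) * pi / 180
    azim <- stats::runif(N_fil) * 2 * pi
    fils <- lapply(seq_len(N_fil), function(i) {
      o <- c(sin(polar[i]) * cos(azim[i]), sin(polar[i]) * sin(azim[i]),
             cos(polar[i]))
      filament(c(bases[i, 1], bases[i, 2], z_plane - depth), o, n = n0,
               delta = delta, Lp = Lp, d = d)
    })
    list(
      filaments = fils,
      table = data.frame(
        x = bases[, 1], y = bases[, 2], z = z_plane - depth,
        polar_deg = polar * 180 / pi, azimuth_deg = azim * 180 / pi
      ),
      seed = seed
    )
  })
}

# evaluate expr under a private RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Single rigid-filament polymerization ratchet
#'
#' A rigid filament clamped perpendicular below the membrane polymerizes
#' against the fluctuating patch: attempts succeed whenever a membrane
#' height fluctuation accommodates the next monomer, so the effective
#' rate k_on(n)/k_on0 falls with the membrane restoring force f(L) as
#' exp(-f(L) delta / kT) near equilibrium, and net growth stalls where
#' the acceptance ratio meets k_off/k_on0.
#'
#' @param params a [membrane_params()] with the working fugacity set
#'   (grand-canonical, `gamma = 0`).
#' @param growth a [growth_params()].
#' @param patch_L,target_edge membrane patch geometry (nm).
#' @param depth filament base depth below the membrane plane (nm).
#' @param max_time simulated time (1/k_on0).
#' @param warmup warm-up sweeps.
#' @param seed RNG seed.
#' @return list with `events`, `acceptance` ([acceptance_by_n()]),
#'   `deformation` (function mapping monomer count to the membrane
#'   deformation height L(n), nm), `trajectory` (the raw
#'   `growth_trajectory`).
#' @export
run_ratchet_experiment <- function(params, growth = growth_params(),
                                   patch_L = 140, target_edge = 8,
                                   depth = 40, max_time = 500,
                                   warmup = 500, seed = 1) {
  m <- build_flat_patch(patch_L, patch_L, target_edge)
  f <- filament(c(patch_L / 2, patch_L / 2, -depth), c(0, 0, 1), n = 1,
                Lp = Inf, d = params$d_fil)
  sch <- move_schedule(displace = 1, flip = 1, insert = 0.3, remove = 0.3)
  tr <- run_growth(m, params, list(f), growth, max_time = max_time,
                   schedule = sch, gc = TRUE, stop_height = 0,
                   warmup = warmup, seed = seed)
  offset <- depth - (params$d_mem + params$d_fil) / 2
  list(
    events = tr$events,
    acceptance = acceptance_by_n(tr),
    deformation = function(n) n * f$delta - offset,
    trajectory = tr
  )
}

#' First-passage experiment for the single-filament bending transition
#'
#' Runs replicas of the explicit tilted-filament simulation (see
#' [tilted_filament_setup()]): one semiflexible filament clamped at
#' relative angle theta below a fluctuating membrane held at normal
#' distance L0, with sterically gated kinetic growth, until the filament
#' first reaches `n_abs` monomers. Returns the first passage times and
#' the pooled acceptance fractions per monomer count, the two
#' observables the reduced birth-death model predicts.
#'
#' @param s a [tilt_scenario()].
#' @param n_abs absorbing monomer count (default: the scenario's bent
#'   escape state, capped so the bent filament stays clear of its own
#'   periodic image).
#' @param n_rep replicas.
#' @param growth a [growth_params()].
#' @param params a [membrane_params()].
#' @param max_time per-replica time cap (units of 1/k_on0).
#' @param target_edge mesh lattice edge (nm).
#' @param warmup warm-up sweeps per replica.
#' @param seed RNG seed (one stream per replica derived from it).
#' @return list with `fpt` (vector, NA where capped), `acceptance`
#'   (pooled [acceptance_by_n()] table) and `n_abs`.
#' @export
run_tilt_experiment <- function(s, n_abs = NULL, n_rep = 8,
                                growth = growth_params(),
                                params = membrane_params(),
                                max_time = 2000, target_edge = 8,
                                warmup = 300, seed = 1) {
  setup <- tilted_filament_setup(s, params, target_edge = target_edge)
  if (is.null(n_abs)) {
    prof <- gap_profile(s)
    n_abs <- min(attr(prof, "n_star"), s$n_c + 30)
  }
  fpt <- rep(NA_real_, n_rep)
  evs <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    tr <- run_growth(
      setup$mesh, setup$params, list(setup$filament), growth,
      max_time = max_time, gc = FALSE, stop_height = 0, stop_n = n_abs,
      warmup = warmup, seed = seed + 7919 * r
    )
    if (is.finite(tr$t_formed)) fpt[r] <- tr$t_formed
    evs[[r]] <- tr$events
  }
  acc <- acceptance_by_n(do.call(rbind, evs))
  list(fpt = fpt, acceptance = acc, n_abs = n_abs)
}

#' Frozen-node screening experiment
#'
#' Paired growth trajectories with and without one additional
#' immobilized membrane node at the patch centre, from identical
#' filament layouts (modelling transient adhesion, e.g. to a
#' nucleation-promoting factor, which pins the membrane and screens the
#' membrane-mediated attraction between filaments). For each seed the
#' pair of runs reports the waiting time until the membrane first
#' protrudes to `h_star` and the number of filaments whose barbed end
#' ends up above the frozen-boundary plane.
#'
#' @param n_pairs paired replicas.
#' @param params a [membrane_params()] with the working fugacity.
#' @param patch_L patch size (nm).
#' @param n_fil filaments per run.
#' @param h_star protrusion height threshold (nm).
#' @param max_time per-run time cap (1/k_on0).
#' @param nu sweeps per unit time.
#' @param seed base seed.
#' @return data.frame (seed, frozen, t_wait, n_protruding, h_max).
#' @export
run_screening_experiment <- function(n_pairs = 3, params = NULL,
                                     patch_L = 100, n_fil = 8,
                                     h_star = 12, max_time = 400,
                                     nu = 60, seed = 1) {
  if (is.null(params)) {
    params <- membrane_params(kappa = 20, gamma = 0)
    params$z <- 0.005 # near-tensionless reservoir: protrusions are cheap
  }
  rows <- list()
  for (k in seq_len(n_pairs)) {
    ic <- generate_initial_condition(n_fil, std = 0, depth = 50,
                                     Lx = patch_L, Ly = patch_L,
                                     seed = seed + 131 * k)
    for (frozen_node in c(FALSE, TRUE)) {
      m <- build_flat_patch(patch_L, patch_L, 8)
      if (frozen_node) {
        ctr <- c(patch_L / 2, patch_L / 2, 0)
        dd <- periodic_distance(
          cbind(m$vertices[, 1], m$vertices[, 2], 0),
          matrix(ctr, 1), patch_L, patch_L
        )
        m$frozen[which.min(dd)] <- TRUE
      }
      tr <- run_growth(m, params, ic$filaments,
                       growth_params(1, 0.01, nu = nu),
                       max_time = max_time, gc = TRUE, stop_height = 0,
                       warmup = 300, seed = seed + 131 * k)
      hit <- tr$events$t[tr$events$height >= h_star]
      tips <- vapply(tr$filaments, function(f) f$nodes[nrow(f$nodes), 3],
                     numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed + 131 * k, frozen = frozen_node,
        t_wait = if (length(hit)) min(hit) else Inf,
        n_protruding = sum(tips > 0),
        h_max = max(tr$events$height)
      )
    }
  }
  do.call(rbind, rows)
}

#' Cooperative load-sharing experiment
#'
#' A clustered bundle of `N` rigid filaments grows against the membrane
#' while a lone filament stalls: perfect load sharing gives each bundle
#' member an effective load f0/N and hence a per-filament net rate
#' about exp(-f0 delta/(N kT)) - koff/kon0. Returns the measured
#' per-filament net growth rates for the bundle and for a single
#' filament, plus the load-sharing prediction evaluated with the
#' supplied plateau force.
#'
#' @param N bundle size.
#' @param f0 membrane plateau force (kT/nm) entering the prediction.
#' @param params a [membrane_params()] with the working fugacity.
#' @param patch_L patch size (nm).
#' @param spacing lateral bundle spacing (nm, >= d_fil).
#' @param depth base depth (nm).
#' @param max_time run length (1/k_on0).
#' @param nu sweeps per unit time.
#' @param seed RNG seed.
#' @return list with `rate_bundle`, `rate_single` (monomers per unit
#'   time per filament, net), `rate_eq3` (prediction), `trajectories`.
#' @export
run_loadsharing_experiment <- function(N = 4, f0 = 2 * pi * sqrt(2 * 20 * 0.01),
                                       params = NULL, patch_L = 120,
                                       spacing = 11, depth = 40,
                                       max_time = 250, nu = 60, seed = 1) {
  if (is.null(params)) {
    params <- membrane_params(kappa = 20, gamma = 0)
    params$z <- 0.012 # tube-route working point for gamma = 0.01
  }
  delta <- 2.7
  ctr <- patch_L / 2
  offs <- list(c(0, 0), c(spacing, 0), c(spacing / 2, spacing * 0.87),
               c(-spacing / 2, spacing * 0.87), c(-spacing, 0),
               c(spacing / 2, -spacing * 0.87))
  mk <- function(n_fil) {
    lapply(seq_len(n_fil), function(i) {
      filament(c(ctr + offs[[i]][1], ctr + offs[[i]][2], -depth),
               c(0, 0, 1), n = 1, Lp = Inf, d = params$d_fil)
    })
  }
  run1 <- function(fils, sd) {
    m <- build_flat_patch(patch_L, patch_L, 8)
    run_growth(m, params, fils, growth_params(1, 0.01, nu = nu),
               max_time = max_time, gc = TRUE, stop_height = 0,
               warmup = 300, seed = sd)
  }
  trB <- run1(mk(N), seed)
  trS <- run1(mk(1), seed + 7)
  # steady-state net growth: mean per-filament slope over the second half
  # of the run (the approach to contact and the stall transient excluded)
  rate_of <- function(tr, n_fil) {
    ev <- tr$events
    t_mid <- tr$t_end / 2
    n_mid <- vapply(seq_len(n_fil), function(i) {
      ei <- ev[ev$filament == i & ev$t <= t_mid, ]
      if (nrow(ei)) ei$nseg[nrow(ei)] else 1L
    }, integer(1))
    n_end <- vapply(tr$filaments, n_monomers, integer(1))
    mean(n_end - n_mid) / (tr$t_end - t_mid)
  }
  list(
    rate_bundle = rate_of(trB, N),
    rate_single = rate_of(trS, 1),
    rate_eq3 = exp(-f0 * delta / N) - 0.01,
    trajectories = list(bundle = trB, single = trS)
  )
}

#' Matched membrane + filament realisation of a tilt scenario
#'
#' Builds the explicit-simulation counterpart of a [tilt_scenario()]:
#' a flat periodic patch whose steric wall for filament nodes (the
#' membrane midplane minus the mixed hard-core distance) sits exactly
#' `L0` above the filament base, and a single filament clamped at the
#' relative angle `theta`, bending in the +x direction. Run it with
#' [run_growth()] (fixed vertex count, explicit `gamma`) to measure
#' acceptance fractions and first passage times that the reduced model
#' predicts.
#'
#' @param s a [tilt_scenario()].
#' @param params a [membrane_params()]; `gamma` is set from the
#'   scenario.
#' @param target_edge mesh lattice edge (nm).
#' @param n0 initial monomers.
#' @return list with `mesh`, `filament`, `params`, `wall_offset`.
#' @export
tilted_filament_setup <- function(s, params = membrane_params(),
                                  target_edge = 8, n0 = 1) {
  params$kappa <- s$kappa
  params$gamma <- s$gamma
  m <- build_flat_patch(s$patch_L, s$patch_L, target_edge)
  offset <- (params$d_mem + params$d_fil) / 2
  m$vertices[, 3] <- s$L0 + offset
  th <- s$theta_rad
  base <- c(s$patch_L / 3, s$patch_L / 2, 0)
  f <- filament(base, c(sin(th), 0, cos(th)), n = n0, delta = s$delta,
                Lp = s$Lp, d = params$d_fil)
  list(mesh = m, filament = f, params = params, wall_offset = offset)
}
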