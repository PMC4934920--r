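#' Monte Carlo move schedule
#'
#' Relative attempt frequencies per sweep, in units of the current vertex
#' count V: by default V displacement attempts, V edge-flip attempts and
#' 0.1 V insertion plus 0.1 V removal attempts (insertions and removals
#' are attempted with equal frequency, as detailed balance of the
#' grand-canonical exchange requires). The displacement amplitude can be
#' auto-tuned to a 30-50% acceptance rate during warm-up and is frozen
#' afterwards; tuning during production would violate detailed balance.
#'
#' @param displace,flip,insert,remove attempt frequencies (per vertex per
#'   sweep).
#' @param amplitude vertex displacement amplitude (nm).
#' @param fil_amplitude filament rotation amplitude (radians).
#' @return a `move_schedule` object.
#' @export
move_schedule <- function(displace = 1, flip = 1, insert = 0.1,
                          remove = 0.1, amplitude = 1,
                          fil_amplitude = 0.2) {
  stopifnot(displace >= 0, flip >= 0, insert >= 0, remove >= 0,
            insert == remove)
  structure(
    list(
      displace = displace, flip = flip, insert = insert, remove = remove,
      amplitude = amplitude, fil_amplitude = fil_amplitude
    ),
    class = "move_schedule"
  )
}

.cpp_schedule <- function(s) {
  list(
    displace = s$displace, flip = s$flip, insert = s$insert,
    remove = s$remove, amplitude = s$amplitude,
    fil_amplitude = s$fil_amplitude
  )
}

#' Run membrane (and filament) Monte Carlo
#'
#' Metropolis sampling of the membrane: vertex displacements and edge
#' flips at fixed vertex count, plus grand-canonical vertex
#' insertion/removal when `gc = TRUE`. Displacements and flips are
#' accepted with probability min(1, exp(-dE)) subject to the tether and
#' hard-core constraints; insertions with
#' min(1, z R_prop exp(-dE)) and removals with the reciprocal proposal
#' ratio, which satisfies detailed balance with respect to the
#' grand-canonical weight z^V exp(-E). Frozen vertices are never
#' displaced or removed; their coordinates are bit-identical across the
#' run.
#'
#' @param mesh a `trimesh`.
#' @param params a [membrane_params()]. In grand-canonical runs set
#'   `gamma = 0`; tension is controlled by the fugacity `z`.
#' @param sweeps production sweeps.
#' @param schedule a [move_schedule()].
#' @param gc enable grand-canonical vertex exchange.
#' @param spring optional [pulling_spring()].
#' @param filaments optional list of [filament()]s (moved if
#'   `move_filaments`).
#' @param move_filaments attempt filament crankshaft/pivot moves.
#' @param sample_every record observables every this many sweeps.
#' @param warmup warm-up sweeps (not sampled); displacement amplitude is
#'   tuned during warm-up when `tune = TRUE`.
#' @param tune auto-tune move amplitudes during warm-up.
#' @param record_every store vertex-position snapshots every this many
#'   sweeps (0 = none); used by [measure_spectrum()].
#' @param seed RNG seed (single generator drives the whole run).
#' @return list with `mesh` (final state), `filaments`, `samples` (data
#'   frame: sweep, V, F, area, energy, zbar, force, hmax), `counters`
#'   (move acceptance diagnostics), `amplitude`, `snapshots`.
#' @export
run_membrane_mc <- function(mesh, params, sweeps,
                            schedule = move_schedule(), gc = FALSE,
                            spring = NULL, filaments = list(),
                            move_filaments = length(filaments) > 0,
                            sample_every = 10, warmup = 0, tune = warmup > 0,
                            record_every = 0, seed = 1) {
  spr <- if (is.null(spring)) NULL else .cpp_spring(spring)
  out <- cpp_run_mc(
    mesh$vertices, mesh$triangles, mesh$frozen, mesh$Lx, mesh$Ly,
    .cpp_params(params, gc = gc), .cpp_schedule(schedule),
    .fil_list(filaments), spr, as.integer(sweeps),
    as.integer(sample_every), as.integer(warmup), isTRUE(tune),
    as.integer(record_every), isTRUE(move_filaments), seed
  )
  out$mesh <- .mesh_from_cpp(out$mesh, mesh)
  out$filaments <- .filaments_from_cpp(out$filaments, filaments)
  out
}

.mesh_from_cpp <- function(m, template) {
  structure(
    list(
      vertices = m$vertices, triangles = m$triangles,
      frozen = as.logical(m$frozen), Lx = m$Lx, Ly = m$Ly,
      target_edge = template$target_edge, seed = template$seed
    ),
    class = "trimesh"
  )
}

.filaments_from_cpp <- function(fl, templates) {
  lapply(seq_along(fl), function(i) {
    f <- if (i <= length(templates)) templates[[i]] else {
      structure(list(delta = fl[[i]]$delta, Lp = fl[[i]]$Lp,
                     d = fl[[i]]$d, rigid = fl[[i]]$rigid),
                class = "filament")
    }
    f$nodes <- fl[[i]]$nodes
    f
  })
}

#' Height-fluctuation spectrum of a flat patch
#'
#' Interpolates each stored vertex-position snapshot onto a regular grid
#' (cell-averaged heights, empty cells filled from periodic neighbours),
#' Fourier transforms the height field, and averages the squared mode
#' amplitudes over frames. With the convention h(r) = sum_q h_q exp(iqr),
#' the equilibrium expectation for a tensionless-frame patch is
#' \deqn{\langle |h_q|^2 \rangle = 1 / [A (\kappa q^4 + \gamma q^2)]}
#' in kT units, with A the projected patch area. Errors are block
#' jackknife estimates over frames.
#'
#' @param snapshots list of n x 3 vertex matrices (from
#'   `run_membrane_mc(..., record_every = )`).
#' @param Lx,Ly box lengths (nm).
#' @param grid_n grid points per side (default ~ one per 8 nm).
#' @param n_blocks jackknife blocks (default 10; error bars are flagged
#'   unreliable when fewer than 2 frames per block are available).
#' @return data.frame with columns `kx`, `ky` (integer mode numbers),
#'   `q` (1/nm), `S` (nm^2, the average |h_q|^2), `se` and attribute
#'   `reliable`.
#' @export
measure_spectrum <- function(snapshots, Lx, Ly, grid_n = NULL,
                             n_blocks = 10) {
  if (length(snapshots) < 2) stop("need at least 2 snapshots")
  if (is.null(grid_n)) grid_n <- max(8L, as.integer(floor(min(Lx, Ly) / 8)))
  n <- grid_n
  fields <- lapply(snapshots, function(V) .height_grid(V, Lx, Ly, n))
  mods <- lapply(fields, function(h) {
    hq <- stats::fft(h - mean(h)) / length(h)
    Re(hq * Conj(hq))
  })
  nb <- min(n_blocks, length(mods))
  blocks <- split(seq_along(mods), cut(seq_along(mods), nb, labels = FALSE))
  bmeans <- lapply(blocks, function(ix) Reduce(`+`, mods[ix]) / length(ix))
  Sbar <- Reduce(`+`, mods) / length(mods)
  # jackknife over blocks
  jk <- lapply(seq_len(nb), function(b) {
    Reduce(`+`, bmeans[-b]) / (nb - 1)
  })
  jbar <- Reduce(`+`, jk) / nb
  se2 <- Reduce(`+`, lapply(jk, function(x) (x - jbar)^2)) * (nb - 1) / nb
  kx <- rep(0:(n - 1), n)
  ky <- rep(0:(n - 1), each = n)
  kx <- ifelse(kx > n / 2, kx - n, kx)
  ky <- ifelse(ky > n / 2, ky - n, ky)
  qx <- 2 * pi * kx / Lx
  qy <- 2 * pi * ky / Ly
  out <- data.frame(
    kx = kx, ky = ky, q = sqrt(qx^2 + qy^2),
    S = as.vector(Sbar), se = sqrt(as.vector(se2))
  )
  out <- out[out$q > 0, ]
  out <- out[order(out$q), ]
  attr(out, "reliable") <- length(mods) >= 2 * nb
  attr(out, "A") <- Lx * Ly
  out
}

# cell-average a height field onto an n x n periodic grid
.height_grid <- function(V, Lx, Ly, n) {
  ix <- pmin(floor(V[, 1] / Lx * n), n - 1) + 1
  iy <- pmin(floor(V[, 2] / Ly * n), n - 1) + 1
  idx <- (iy - 1) * n + ix
  s <- tapply(V[, 3], idx, mean)
  h <- matrix(NA_real_, n, n)
  h[as.integer(names(s))] <- s
  # fill empty cells from periodic neighbour means
  while (anyNA(h)) {
    nb2 <- matrix(
      rowMeans(cbind(
        as.vector(.shift(h, 1, 0)), as.vector(.shift(h, -1, 0)),
        as.vector(.shift(h, 0, 1)), as.vector(.shift(h, 0, -1))
      ), na.rm = TRUE),
      n, n
    )
    miss <- is.na(h)
    h[miss] <- nb2[miss]
  }
  h
}

.shift <- function(m, dx, dy) {
  n <- nrow(m)
  m[((seq_len(n) - 1 + dx) %% n) + 1, ((seq_len(n) - 1 + dy) %% n) + 1]
}

#' Fit bending rigidity and tension to a measured spectrum
#'
#' Weighted least squares of 1/S on (q^4, q^2): the continuum prediction
#' gives 1/S = A (kappa q^4 + gamma q^2).
#'
#' @param spec output of [measure_spectrum()].
#' @param q_max fit only modes with q <= q_max (default: lowest decade,
#'   `4 * min(q)`).
#' @param kappa optionally fix kappa (kT) and fit only gamma.
#' @return list with `kappa`, `gamma`, standard errors, and the fit.
#' @export
fit_spectrum <- function(spec, q_max = NULL, kappa = NULL) {
  A <- attr(spec, "A")
  if (is.null(q_max)) q_max <- 4 * min(spec$q)
  d <- spec[spec$q <= q_max & spec$S > 0, ]
  y <- 1 / d$S / A
  w <- (d$S / pmax(d$se, 1e-12))^2 # relative-error weights on 1/S
  if (is.null(kappa)) {
    fit <- stats::lm(y ~ 0 + I(d$q^4) + I(d$q^2), weights = w)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    list(kappa = unname(cf[1]), gamma = unname(cf[2]),
         kappa_se = se[1], gamma_se = se[2], fit = fit)
  } else {
    y2 <- y - kappa * d$q^4
    fit <- stats::lm(y2 ~ 0 + I(d$q^2), weights = w)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    list(kappa = kappa, gamma = unname(cf[1]), kappa_se = NA_real_,
         gamma_se = se[1], fit = fit)
  }
}

#' Calibrate the fugacity-tension mapping
#'
#' For each fugacity z, runs a grand-canonical simulation, measures the
#' surface tension, and fits the incompressible-fluid relation
#' \deqn{z = C \exp(-\gamma / (\rho k_B T))}
#' i.e. ln z linear in gamma with slope -1/rho. Two measurement routes
#' are available: `"tube"` pulls a membrane tube and infers
#' gamma = kappa/(2 R^2) from the equilibrium tube radius (the
#' zero-temperature tube relation); `"spectrum"` fits the low-q height
#' spectrum. Fugacities whose tube is unstable (retracts or never forms)
#' are flagged and excluded from the fit.
#'
#' @param z_values fugacities to calibrate.
#' @param base_params a [membrane_params()]; its `z` and `gamma` are
#'   overridden per point (`gamma = 0` in all grand-canonical runs).
#' @param patch_L patch edge length (nm).
#' @param target_edge lattice edge (nm).
#' @param method `"spectrum"` (default) or `"tube"`. The tube route is
#'   the direct mechanical measurement but its radius is the slowest
#'   relaxing observable at desk scale; the spectrum route equilibrates
#'   much faster and agrees with long tube runs.
#' @param sweeps production sweeps per z.
#' @param warmup warm-up sweeps per z.
#' @param anchor tube-pulling anchor height (nm), tube route only.
#' @param seed RNG seed.
#' @return a `calibration_curve`: data frame of (z, gamma, ok) with
#'   fitted `C`, `rho` and the lm fit as attributes.
#' @export
calibrate_fugacity <- function(z_values, base_params = membrane_params(),
                               patch_L = 140, target_edge = 8,
                               method = c("spectrum", "tube"),
                               sweeps = 30000, warmup = 10000,
                               anchor = 105, seed = 1) {
  method <- match.arg(method)
  rows <- lapply(seq_along(z_values), function(i) {
    z <- z_values[i]
    p <- base_params
    p$z <- z
    p$gamma <- 0
    m <- build_flat_patch(patch_L, patch_L, target_edge)
    if (method == "tube") {
      g <- .measure_gamma_tube(m, p, anchor, sweeps, warmup,
                               seed = seed + 1000 * i)
    } else {
      g <- .measure_gamma_spectrum(m, p, sweeps, warmup,
                                   seed = seed + 1000 * i)
    }
    data.frame(z = z, gamma = g$gamma, ok = g$ok, R = g$R,
               se = if (is.null(g$se)) NA_real_ else g$se)
  })
  out <- do.call(rbind, rows)
  fit_ok <- out$ok & is.finite(out$gamma)
  if (sum(fit_ok) < 2) stop("fewer than 2 stable calibration points")
  fit <- stats::lm(log(z) ~ gamma, data = out[fit_ok, ])
  cf <- stats::coef(fit)
  structure(out,
    C = exp(unname(cf[1])), rho = -1 / unname(cf[2]),
    fit = fit, method = method, class = c("calibration_curve", "data.frame")
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %d points (%s route): C = %.4g, rho = %.4g /nm^2\n",
    nrow(x), attr(x, "method"), attr(x, "C"), attr(x, "rho")
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Shipped fugacity-tension calibration
#'
#' The package's default calibration constants (C, rho) of the
#' incompressible-fluid relation z = C exp(-gamma/rho) for the default
#' membrane parameters (kappa = 20 kT, tether band 4-9 nm, node diameter
#' 5 nm), fitted with [calibrate_fugacity()] (spectrum route, 100 nm
#' patch). Use [fugacity_for_tension()] on the returned object to pick
#' the working fugacity for a desired tension.
#'
#' @return a `calibration_curve` object.
#' @export
default_calibration <- function() {
  df <- .default_cal_df
  fit <- stats::lm(log(z) ~ gamma, data = df[df$ok, ])
  cf <- stats::coef(fit)
  structure(df,
    C = exp(unname(cf[1])), rho = -1 / unname(cf[2]), fit = fit,
    method = "spectrum", class = c("calibration_curve", "data.frame")
  )
}

# measured grand-canonical tension versus fugacity: spectrum route on a
# 100 nm patch, 40k production sweeps per point (regenerate with
# calibrate_fugacity(method = "spectrum"); the methods vignette records
# the protocol)
.default_cal_df <- data.frame(
  z = c(0.0003, 0.0007, 0.0012, 0.0020, 0.0040),
  gamma = c(0.0382, 0.0306, 0.0173, -0.0003, -0.0005),
  ok = TRUE, R = NA_real_,
  se = c(0.0064, 0.0069, 0.0029, 0.0048, 0.0049)
)

#' Predict fugacity from tension (or vice versa) off a calibration curve
#'
#' @param cal a `calibration_curve`.
#' @param gamma tension(s) in kT/nm^2.
#' @export
fugacity_for_tension <- function(cal, gamma) {
  attr(cal, "C") * exp(-gamma / attr(cal, "rho"))
}

#' @rdname fugacity_for_tension
#' @param z fugacity value(s).
#' @export
tension_for_fugacity <- function(cal, z) {
  attr(cal, "rho") * (log(attr(cal, "C")) - log(z))
}

# tube route: pull a tube at fugacity z, measure the mean radius over the
# sampled frames, infer gamma = kappa / (2 R^2)
.measure_gamma_tube <- function(mesh, params, anchor, sweeps, warmup, seed,
                                stiffness = 0.5) {
  disk <- attachment_disk(mesh, radius = 12)
  # more frequent exchange attempts: tube growth is area-supply limited
  sch <- move_schedule(displace = 1, flip = 1, insert = 0.3, remove = 0.3)
  # staged anchor raise lets the reservoir supply tube area gradually
  stages <- seq(15, anchor, by = 15)
  state <- mesh
  for (s in seq_along(stages)) {
    spr <- pulling_spring(disk, stages[s], stiffness)
    r <- run_membrane_mc(state, params, sweeps = warmup, schedule = sch,
                         gc = TRUE, spring = spr, sample_every = 0,
                         warmup = if (s == 1) warmup else 0,
                         seed = seed + s)
    state <- r$mesh
    if (length(r$spring_ids)) disk <- r$spring_ids
  }
  spr <- pulling_spring(disk, anchor, stiffness)
  r <- run_membrane_mc(state, params, sweeps = sweeps, schedule = sch,
                       gc = TRUE, spring = spr, sample_every = 20,
                       record_every = max(50, sweeps %/% 80), seed = seed)
  Rs <- vapply(r$snapshots, function(V) {
    tm <- tube_metrics(.mesh_from_V(V, r$mesh), params$kappa)
    if (isTRUE(tm$has_tube)) tm$R else NA_real_
  }, numeric(1))
  Rs <- utils::tail(Rs, ceiling(length(Rs) / 2)) # discard transient
  Rbar <- mean(Rs, na.rm = TRUE)
  hgt <- mean(utils::tail(r$samples$zbar, 50), na.rm = TRUE)
  ok <- is.finite(Rbar) && mean(is.finite(Rs)) > 0.5 && hgt > 0.5 * anchor
  list(gamma = params$kappa / (2 * Rbar^2), R = Rbar, ok = ok)
}

# rebuild a minimal mesh around a bare vertex-position snapshot (vertex
# count varies under GC, so the template's flags/triangles do not apply;
# the frozen-boundary plane is z = 0 by construction)
.mesh_from_V <- function(V, template) {
  m <- template
  m$vertices <- V
  m$triangles <- matrix(integer(0), 0, 3)
  m$frozen <- logical(nrow(V))
  m
}

# spectrum route: effective tension from the lowest height-fluctuation
# shells of a grand-canonical flat patch, 1/S = A (kappa q^4 + gamma q^2)
# with kappa fixed at its input value (the lowest modes are tension
# dominated when gamma >~ kappa q1^2)
.measure_gamma_spectrum <- function(mesh, params, sweeps, warmup, seed) {
  r <- run_membrane_mc(mesh, params, sweeps = sweeps, gc = TRUE,
                       sample_every = 100,
                       record_every = max(20, sweeps %/% 400),
                       warmup = warmup, seed = seed)
  sp <- measure_spectrum(r$snapshots, mesh$Lx, mesh$Ly)
  A <- mesh$Lx * mesh$Ly
  low <- sp[sp$q <= 2.3 * min(sp$q), ]
  gs <- (1 / (low$S * A) - params$kappa * low$q^4) / low$q^2
  list(gamma = mean(gs), R = NA_real_, ok = is.finite(mean(gs)),
       se = stats::sd(gs) / sqrt(length(gs)))
}
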