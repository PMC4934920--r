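test_that("WLC bending energy follows the discretized Hamiltonian", {
  f <- filament(c(0, 0, 0), c(0, 0, 1), n = 10)
  expect_equal(wlc_bend_energy(f), 0)

  # one joint bent by phi costs (Lp/delta)(1 - cos phi)
  f2 <- filament(c(0, 0, 0), c(0, 0, 1), n = 2, Lp = 15000, delta = 2.7)
  phi <- 0.23
  f2$nodes[3, ] <- f2$nodes[2, ] + 2.7 * c(sin(phi), 0, cos(phi))
  expect_equal(wlc_bend_energy(f2), (15000 / 2.7) * (1 - cos(phi)),
               tolerance = 1e-12)
})

test_that("growth appends along the terminal tangent and shrink inverts it", {
  f <- filament(c(1, 2, 3), c(1, 1, 1) / sqrt(3), n = 4)
  g <- grow(f)
  expect_identical(n_monomers(g), 5L)
  expect_equal(shrink(g)$nodes, f$nodes)
  # straight filament grown 10x stays straight
  g10 <- Reduce(function(x, .) grow(x), 1:10, f)
  expect_equal(wlc_bend_energy(g10), 0, tolerance = 1e-9)
  expect_equal(n_monomers(g10) * f$delta,
               (4 + 10) * f$delta)

  # growth on a bent tip continues parallel to the terminal segment
  fb <- filament(c(0, 0, 0), c(0, 0, 1), n = 3)
  fb$nodes[4, ] <- fb$nodes[3, ] + 2.7 * c(sin(0.4), 0, cos(0.4))
  gb <- grow(fb)
  t_old <- (fb$nodes[4, ] - fb$nodes[3, ]) / 2.7
  t_new <- (gb$nodes[5, ] - gb$nodes[4, ]) / 2.7
  expect_equal(t_new, t_old, tolerance = 1e-12)

  expect_error(shrink(filament(c(0, 0, 0), c(0, 0, 1), n = 1)), "base")
})

test_that("filament Monte Carlo preserves segment lengths and the base exactly", {
  f <- filament(c(0, 0, 0), c(0, 0, 1), n = 30, Lp = 100)
  r <- run_filament_mc(f, sweeps = 4000, amplitude = 0.6, seed = 11)
  g <- r$filaments[[1]]
  expect_gt(r$acceptance, 0.05)
  lens <- sqrt(rowSums(diff(g$nodes)^2))
  expect_equal(lens, rep(f$delta, 30), tolerance = 1e-12)
  expect_identical(g$nodes[1:2, ], f$nodes[1:2, ]) # base segment untouched
  expect_gt(max(abs(g$nodes[-(1:2), ] - f$nodes[-(1:2), ])), 0.5)
})

test_that("a rigid filament never bends", {
  f <- filament(c(0, 0, 0), c(0, 0, 1), n = 20, Lp = Inf)
  r <- run_filament_mc(f, sweeps = 500, seed = 3)
  expect_identical(r$filaments[[1]]$nodes, f$nodes)
})

test_that("sampled tangent correlations match the discrete WLC closed form", {
  Lp <- 50
  delta <- 2.7
  f <- filament(c(0, 0, 0), c(0, 0, 1), n = 40, delta = delta, Lp = Lp)
  r <- run_filament_mc(f, sweeps = 24000, amplitude = 0.8,
                       sample_every = 30, warmup = 2000, seed = 5)
  cors <- vapply(r$snapshots, function(sn) {
    th <- diff(sn[[1]]$nodes) / delta
    vapply(c(1L, 4L, 8L), function(s) {
      i <- 2:(nrow(th) - s)
      mean(rowSums(th[i, , drop = FALSE] * th[i + s, , drop = FALSE]))
    }, numeric(1))
  }, numeric(3))
  cbar <- rowMeans(cors)
  se <- apply(cors, 1, sd) / sqrt(ncol(cors) / 12) # ~12 decorrelated blocks
  # exact single-joint average of the discrete model, powered by separation
  k <- Lp / delta
  c1 <- 1 / tanh(k) - 1 / k
  for (j in seq_along(c(1, 4, 8))) {
    s <- c(1, 4, 8)[j]
    expect_lt(abs(cbar[j] - c1^s), 3 * se[j] + 0.01)
  }
})

test_that("steric gating keeps filaments out of the membrane's excluded zone", {
  m <- build_flat_patch(80, 80, target_edge = 8) # plane z = 0
  f <- filament(c(40, 40, -40), c(0, 0, 1), n = 12, Lp = 30) # floppy
  p <- membrane_params()
  r <- run_filament_mc(f, sweeps = 3000, mesh = m, params = p,
                       amplitude = 1.2, sample_every = 50, seed = 9)
  zmax <- max(vapply(r$snapshots, function(sn) max(sn[[1]]$nodes[, 3]),
                     numeric(1)))
  # mixed hard core (d_mem + d_fil)/2 = 7.5 nm below the membrane plane
  expect_lt(zmax, -7.5 + 1e-9)
})
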