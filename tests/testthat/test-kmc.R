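# remote membrane so sterics never trigger; nu tiny so configurational
# sweeps cost nothing between reactions
remote_setup <- function() {
  m <- build_flat_patch(60, 60, 8)
  m$vertices[, 3] <- 5000
  list(mesh = m, params = membrane_params(kappa = 20, gamma = 0))
}

test_that("reaction times are exponential with the total attempt rate", {
  s <- remote_setup()
  f <- filament(c(30, 30, 0), c(0, 0, 1), n = 1, Lp = Inf)
  g <- growth_params(kon0 = 1, koff = 0.25, nu = 1e-3)
  tr <- run_growth(s$mesh, s$params, list(f), g, max_time = 4000,
                   gc = FALSE, stop_height = 0, warmup = 0, seed = 3)
  ev <- tr$events
  dt <- diff(ev$t)
  expect_gt(nrow(ev), 2000)
  expect_equal(mean(ev$type == 1), 1 / 1.25, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(dt, "pexp", rate = 1.25))
  expect_gt(ks$p.value, 0.01)
  # single channel: mean waiting time 1/kon0
  g2 <- growth_params(kon0 = 2, koff = 0, nu = 1e-3)
  tr2 <- run_growth(s$mesh, s$params, list(f), g2, max_time = 500,
                    gc = FALSE, stop_height = 0, warmup = 0, seed = 4)
  expect_equal(mean(diff(tr2$events$t)), 0.5, tolerance = 0.05)
})

test_that("channel selection follows the rate proportions across filaments", {
  s <- remote_setup()
  fils <- lapply(1:4, function(i) {
    filament(c(12 * i, 30, 0), c(0, 0, 1), n = 1, Lp = Inf)
  })
  g <- growth_params(kon0 = 1, koff = 0.01, nu = 1e-3)
  tr <- run_growth(s$mesh, s$params, fils, g, max_time = 1500,
                   gc = FALSE, stop_height = 0, warmup = 0, seed = 8)
  ev <- tr$events
  expect_equal(mean(ev$type == 1), 100 / 101, tolerance = 0.01)
  tab <- table(ev$filament)
  expect_equal(as.numeric(tab) / nrow(ev), rep(0.25, 4), tolerance = 0.05)
})

test_that("growth is silent at kon0 = 0 and deterministic under a seed", {
  s <- remote_setup()
  f <- filament(c(30, 30, 0), c(0, 0, 1), n = 5, Lp = Inf)
  g0 <- growth_params(kon0 = 1e-12, koff = 0, nu = 1e-3)
  tr <- run_growth(s$mesh, s$params, list(f), g0, max_time = 10,
                   gc = FALSE, stop_height = 0, warmup = 0, seed = 2)
  expect_identical(n_monomers(tr$filaments[[1]]), 5L)

  g <- growth_params(kon0 = 1, koff = 0.01, nu = 1e-3)
  a <- run_growth(s$mesh, s$params, list(f), g, max_time = 200,
                  gc = FALSE, stop_height = 0, warmup = 0, seed = 42)
  b <- run_growth(s$mesh, s$params, list(f), g, max_time = 200,
                  gc = FALSE, stop_height = 0, warmup = 0, seed = 42)
  expect_identical(a$events, b$events)
})

test_that("free filaments accept every polymerization attempt; blocked tips turn to null events", {
  s <- remote_setup()
  f <- filament(c(30, 30, 0), c(0, 0, 1), n = 1, Lp = Inf)
  g <- growth_params(kon0 = 1, koff = 0, nu = 1e-3)
  tr <- run_growth(s$mesh, s$params, list(f), g, max_time = 300,
                   gc = FALSE, stop_height = 0, warmup = 0, seed = 6)
  ev <- tr$events
  free <- ev$nseg * 2.7 < 5000 - 10 # far from the remote wall
  expect_true(all(ev$accepted[ev$type == 1 & free] == 1))

  # a rigid filament pinned just beneath a near membrane is mostly blocked,
  # but its null events still advance the clock
  m2 <- build_flat_patch(60, 60, 8) # plane z = 0
  f2 <- filament(c(30, 30, -12), c(0, 0, 1), n = 1, Lp = Inf)
  tr2 <- run_growth(m2, s$params, list(f2), g, max_time = 300,
                    gc = FALSE, stop_height = 0, warmup = 100, seed = 6)
  acc <- mean(tr2$events$accepted[tr2$events$type == 1])
  expect_lt(acc, 0.5)
  expect_gt(nrow(tr2$events), 100)
  expect_true(all(diff(tr2$events$t) > 0))
})

test_that("event log and contour lengths stay consistent", {
  s <- remote_setup()
  f <- filament(c(30, 30, 0), c(0, 0, 1), n = 3, Lp = Inf)
  g <- growth_params(kon0 = 1, koff = 0.3, nu = 1e-3)
  tr <- run_growth(s$mesh, s$params, list(f), g, max_time = 400,
                   gc = FALSE, stop_height = 0, warmup = 0, seed = 12)
  ev <- tr$events
  # reconstruct n from the accepted events
  dn <- ifelse(ev$type == 1, 1, -1) * ev$accepted
  expect_equal(3 + cumsum(dn), ev$nseg, ignore_attr = TRUE)
  expect_identical(ev$nseg[nrow(ev)], n_monomers(tr$filaments[[1]]))
  cv <- contour_vs_time(tr)
  expect_equal(cv$contour, ev$nseg * 2.7)
})

test_that("the stall height is insensitive to the MC/reaction time-scale coupling", {
  # doubling nu (configurational sweeps per unit reaction time) must leave
  # the single-filament stall point unchanged within counting error
  pz <- membrane_params(kappa = 20, gamma = 0)
  pz$z <- 0.012
  stall_n <- vapply(c(40, 80), function(nu) {
    ra <- run_ratchet_experiment(pz, growth_params(1, 0.01, nu = nu),
                                 patch_L = 80, max_time = 150, seed = 31)
    ev <- ra$events
    mean(tail(ev$nseg, 20))
  }, numeric(1))
  expect_lt(abs(stall_n[1] - stall_n[2]), 4)
})
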