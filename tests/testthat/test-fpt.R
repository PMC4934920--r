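# expose the ground-state solver for the local-minimality property test
.ground_state_angles <- function(n, s) {
  memtube:::.ground_state(n, s)[-1]
}

test_that("clearance profile has free growth, a contact index, and an absorbing state", {
  s <- tilt_scenario(theta = 45, L0 = 60)
  expect_identical(s$n_c, floor(60 / (2.7 * cos(pi / 4)) - 1))
  rg <- required_gap(seq_len(s$n_c), s)
  expect_true(all(rg$clearance == 0)) # free growth below contact
  prof <- gap_profile(s)
  n_star <- attr(prof, "n_star")
  expect_true(is.finite(n_star) && n_star > s$n_c)
  post <- prof[prof$n > s$n_c + 1, ]
  # ground state stays below the plane and the tip turns monotonically
  expect_true(all(post$z_tip <= 60 * (1 + 1e-4)))
  expect_true(all(diff(post$phi_tip) > -1e-8))
  # locked-in curvature costs energy monotonically
  expect_true(all(diff(post$E_gs) > -1e-8))
  # ground state is a constrained local minimum: random small perturbations
  # of the angles never lower the bending energy while staying feasible
  bend <- function(ang) (s$Lp / s$delta) * sum(1 - cos(diff(ang)))
  n <- s$n_c + 8
  ang <- c(s$theta_rad, .ground_state_angles(n, s))
  set.seed(1)
  for (k in 1:25) {
    pert <- ang + c(0, rnorm(n - 1, 0, 1e-3))
    z <- s$delta * cumsum(cos(pert))
    if (all(z <= 60)) expect_gte(bend(pert), bend(ang) - 1e-9)
  }
})

test_that("head-on geometry has growing clearance and no bent escape", {
  s0 <- tilt_scenario(theta = 0, L0 = 40)
  prof <- gap_profile(s0, n_max = s0$n_c + 6)
  expect_true(is.infinite(attr(prof, "n_star")))
  post <- prof$gap[(s0$n_c + 2):(s0$n_c + 6)]
  expect_equal(diff(post), rep(2.7, 4), tolerance = 1e-6)
})

test_that("gap probability is 1 at zero clearance and vanishes for stiff limits", {
  s <- tilt_scenario(45, 60)
  expect_equal(p_bend(2, s), 1)
  # rigid filament under an effectively rigid membrane: no fluctuations
  s_stiff <- tilt_scenario(45, 60, Lp = 1e12, kappa = 1e9, gamma = 1e6)
  prof <- gap_profile(s_stiff, n_max = s_stiff$n_c + 3)
  p <- p_bend(s_stiff$n_c + 2, s_stiff, profile = prof)
  expect_lt(p, 1e-10)
  # monotone: scaling the clearance up lowers the probability
  prof45 <- gap_profile(s, n_max = s$n_c + 5)
  n <- s$n_c + 2
  p1 <- p_bend(n, s, profile = prof45)
  prof_big <- prof45
  prof_big$gap <- prof45$gap * 3
  expect_lt(p_bend(n, s, profile = prof_big), p1)
})

test_that("master equation conserves probability and reproduces closed forms", {
  # frozen chain
  lad0 <- list(kon = rep(0, 9), koff = 0, n_star = 10L)
  P0 <- c(0, 0, 1, rep(0, 7))
  P <- evolve_master_equation(lad0, P0, c(0, 1, 5))
  expect_equal(P[3, ], P0, tolerance = 1e-12)

  # pure birth at constant rate: Poisson counts while absorption is remote
  k <- 0.8
  lad1 <- list(kon = rep(k, 39), koff = 0, n_star = 40L)
  P0 <- c(1, rep(0, 39))
  tg <- c(0, 2, 5)
  P <- evolve_master_equation(lad1, P0, tg)
  for (it in 2:3) {
    expect_equal(sum(P[it, ]), 1, tolerance = 1e-8)
    n_add <- 0:20
    expect_equal(P[it, 1 + n_add], stats::dpois(n_add, k * tg[it]),
                 tolerance = 1e-6)
  }
})

test_that("first passage statistics agree between density, closed form, and simulation", {
  # an arbitrary small ladder
  set.seed(2)
  lad <- list(kon = c(1, 0.5, 0.15, 0.4, 0.07, 0.3, 0.8, 1, 1, 0.6, 0.9),
              koff = 0.05, n_star = 12L)
  fp <- first_passage_stats(lad, n0 = 1)
  expect_equal(fp$mfpt, fp$mfpt_closed, tolerance = 1e-6)
  sims <- simulate_ladder_fpt(lad, n0 = 1, n_rep = 1e5, seed = 7)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - fp$mfpt_closed), 3 * se)
  # density shape vs simulated histogram (coarse bins, chi-square-ish)
  br <- quantile(sims, c(0.2, 0.4, 0.6, 0.8))
  sim_frac <- as.numeric(table(cut(sims, c(0, br, Inf)))) / length(sims)
  dens_frac <- diff(c(0, approx(fp$t, cumsum(fp$p) * diff(fp$t)[1],
                                xout = br)$y, 1))
  expect_equal(sim_frac, dens_frac, tolerance = 0.02)

  # single step: exponential with MFPT 1/k
  lad2 <- list(kon = 0.3, koff = 0, n_star = 2L)
  fp2 <- first_passage_stats(lad2, n0 = 1)
  expect_equal(fp2$mfpt_closed, 1 / 0.3, tolerance = 1e-12)
  mid <- length(fp2$t) %/% 3
  expect_equal(fp2$p[mid], 0.3 * exp(-0.3 * fp2$t[mid]), tolerance = 1e-6)

  # m free steps at rate k
  lad3 <- list(kon = rep(2, 7), koff = 0, n_star = 8L)
  expect_equal(mfpt_closed(lad3, 1), 7 / 2, tolerance = 1e-12)

  # a dead rung with koff = 0 makes the MFPT infinite
  lad4 <- list(kon = c(1, 0, 1), koff = 0, n_star = 4L)
  expect_true(is.infinite(mfpt_closed(lad4, 1)))
})

test_that("the MFPT map is steep in the tilt angle with a divergent head-on column", {
  base <- tilt_scenario(45, 60)
  M <- mfpt_map(c(0, 15, 30, 45), c(50, 70), base)
  expect_true(all(is.infinite(M[, "0"])))
  finite_part <- M[, c("15", "30", "45")]
  # decreasing with theta at fixed L0
  expect_true(all(apply(finite_part, 1, diff) < 0))
  expect_gt(max(finite_part) / min(finite_part), 1e2)
})
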