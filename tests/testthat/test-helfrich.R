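test_that("bending energy vanishes on the flat ground state and the tension term is gamma*A", {
  m <- build_flat_patch(100, 100, target_edge = 8)
  p0 <- membrane_params(kappa = 20, gamma = 0)
  expect_equal(total_energy(m, p0), 0, tolerance = 1e-10)
  p1 <- membrane_params(kappa = 20, gamma = 0.01)
  parts <- total_energy(m, p1, parts = TRUE)
  expect_equal(parts$tension, 0.01 * mesh_area(m), tolerance = 1e-9)
  expect_equal(parts$bending, 0, tolerance = 1e-10)
})

test_that("a closed fine sphere carries the Helfrich energy 8 pi kappa", {
  sp <- icosphere_mesh(3, R = 50)
  p <- membrane_params(kappa = 20, gamma = 0)
  expect_equal(total_energy(sp, p), 8 * pi * 20, tolerance = 0.02)
})

test_that("incremental energy deltas match the full recompute", {
  m <- thermal_patch()
  p <- membrane_params(kappa = 20, gamma = 0.005)
  set.seed(7)
  for (k in 1:10) {
    v <- sample(which(!m$frozen), 1)
    to <- m$vertices[v, ] + runif(3, -0.5, 0.5)
    d_inc <- energy_delta(m, list(vertex = v, to = to), p)
    m2 <- m
    m2$vertices[v, ] <- c(to[1] %% m$Lx, to[2] %% m$Ly, to[3])
    d_full <- total_energy(m2, p) - total_energy(m, p)
    expect_equal(d_inc, d_full, tolerance = 1e-8)
  }
  # null displacement
  v <- which(!m$frozen)[1]
  expect_equal(energy_delta(m, list(vertex = v, to = m$vertices[v, ]), p), 0,
               tolerance = 1e-12)
  # frozen vertices cannot move
  expect_error(
    energy_delta(m, list(vertex = which(m$frozen)[1], to = c(0, 0, 1)), p),
    "frozen"
  )
})

test_that("energy is invariant under rigid translation and relabeling", {
  m <- thermal_patch()
  p <- membrane_params(kappa = 20, gamma = 0.01)
  e0 <- total_energy(m, p)

  m_shift <- m
  m_shift$vertices[, 1] <- (m$vertices[, 1] + 13.7) %% m$Lx
  m_shift$vertices[, 3] <- m$vertices[, 3] + 5
  expect_equal(total_energy(m_shift, p), e0, tolerance = 1e-9)

  set.seed(3)
  perm <- sample(nrow(m$vertices))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  m_perm <- m
  m_perm$vertices <- m$vertices[perm, ]
  m_perm$frozen <- m$frozen[perm]
  m_perm$triangles <- matrix(inv[m$triangles], ncol = 3)
  expect_equal(total_energy(m_perm, p), e0, tolerance = 1e-9)
})

test_that("constraint check applies tether and hard-core rules", {
  m <- build_flat_patch(80, 80, target_edge = 8)
  p <- membrane_params(kappa = 20)
  expect_true(constraint_check(m, p)$ok)

  # two filament nodes at 9 nm with 10 nm hard core overlap
  f1 <- filament(c(20, 20, -30), c(0, 0, 1), n = 1)
  f2 <- filament(c(29, 20, -30), c(0, 0, 1), n = 1)
  cc <- constraint_check(m, p, list(f1, f2))
  expect_false(cc$ok)
  expect_identical(cc$what, "fil-fil")

  # membrane node 7 nm above a filament node: mixed pair excludes 7.5 nm
  f3 <- filament(c(40, 40, -7), c(0, 0, -1), n = 1)
  cc2 <- constraint_check(m, p, list(f3))
  expect_false(cc2$ok)
  expect_identical(cc2$what, "mem-fil")

  # an edge stretched past a_max trips the tether rule
  m2 <- m
  mobile <- which(!m2$frozen)
  m2$vertices[mobile[1], 3] <- 12
  cc3 <- constraint_check(m2, p)
  expect_false(cc3$ok)
  expect_identical(cc3$what, "tether")
})

test_that("pulling spring obeys Hooke's law on the mean attachment height", {
  m <- build_flat_patch(80, 80, target_edge = 8)
  disk <- attachment_disk(m, 10)
  expect_gt(length(disk), 0)

  s0 <- pulling_spring(disk, anchor = 0, stiffness = 1)
  expect_equal(pulling_force(m, s0)$force, 0)

  s1 <- pulling_spring(disk, anchor = 3, stiffness = 1)
  pf <- pulling_force(m, s1)
  expect_equal(pf$force, 3)
  expect_equal(pf$energy, 0.5 * 9)

  expect_error(pulling_force(m, list(vertices = integer(0), anchor = 0,
                                     stiffness = 1)), "empty")
})
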