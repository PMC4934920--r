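test_that("flat patch is a torus-topology triangulation with the right area", {
  m <- build_flat_patch(250, 250, target_edge = 8)
  expect_s3_class(m, "trimesh")
  expect_identical(mesh_euler(m), 0L)
  expect_true(validate_mesh(m))
  expect_equal(mesh_area(m), 250 * 250, tolerance = 0.01)
  expect_true(all(m$vertices[, 3] == 0))
  expect_identical(sum(m$frozen), 3L)
  # vertex areas partition the total exactly
  vg <- vertex_geometry(m)
  expect_equal(sum(vg$area), mesh_area(m), tolerance = 1e-9)
  # determinism
  expect_identical(m, build_flat_patch(250, 250, target_edge = 8))
})

test_that("incommensurate lattices are rejected with a diagnostic", {
  expect_error(build_flat_patch(100, 100, target_edge = 43), "tileable")
})

test_that("topology moves are invertible and keep the Euler bookkeeping", {
  m <- build_flat_patch(80, 80, target_edge = 8)
  nV <- nrow(m$vertices)
  nE <- nrow(mesh_edges(m))
  nF <- nrow(m$triangles)

  ins <- apply_topology_move(m, topology_move("vertex_insert", 5L))
  expect_identical(nrow(ins$mesh$vertices), nV + 1L)
  expect_identical(nrow(mesh_edges(ins$mesh)), nE + 3L)
  expect_identical(nrow(ins$mesh$triangles), nF + 2L)
  expect_identical(mesh_euler(ins$mesh), 0L)

  back <- apply_topology_move(ins$mesh, ins$undo)
  expect_identical(nrow(back$mesh$vertices), nV)
  expect_identical(mesh_euler(back$mesh), 0L)
  expect_equal(mesh_area(back$mesh), mesh_area(m), tolerance = 1e-12)

  e <- mesh_edges(m)[17, ]
  fl <- apply_topology_move(m, topology_move("edge_flip", e))
  expect_identical(dim(fl$mesh$triangles), dim(m$triangles))
  expect_identical(nrow(mesh_edges(fl$mesh)), nE)
  un <- apply_topology_move(fl$mesh, fl$undo)
  expect_identical(mesh_euler(un$mesh), 0L)
})

test_that("invalid topology moves are rejected without touching the mesh", {
  m <- build_flat_patch(80, 80, target_edge = 8)
  frozen_v <- which(m$frozen)[1]
  expect_error(
    apply_topology_move(m, topology_move("vertex_remove", frozen_v)),
    "frozen"
  )
  # 6-coordinated lattice vertex is not removable
  mobile <- which(!m$frozen)[1]
  expect_error(
    apply_topology_move(m, topology_move("vertex_remove", mobile)),
    "removable"
  )
})

test_that("discrete curvature is exact on the flat plane and converges on curved oracles", {
  m <- build_flat_patch(120, 120, target_edge = 7.5)
  vg <- vertex_geometry(m)
  expect_lt(max(abs(vg$H)), 1e-6)

  # sphere: H -> 1/R under refinement
  errs <- vapply(2:3, function(ns) {
    sp <- icosphere_mesh(ns, R = 50)
    mean(vertex_geometry(sp)$H) * 50 - 1
  }, numeric(1))
  expect_lt(abs(errs[2]), 0.01)
  expect_lt(abs(errs[2]), abs(errs[1])) # refinement improves

  # cylinder: H = 1/(2R), uniformly
  cy <- cylinder_mesh(R = 30, Ly = 99, edge = 5.5)
  vg <- vertex_geometry(cy)
  expect_equal(mean(abs(vg$H)), 1 / 60, tolerance = 0.01)
  expect_lt(sd(vg$H), 1e-6)
})

test_that("periodic minimum-image distances are symmetric and metric", {
  set.seed(4)
  Lx <- 70; Ly <- 50
  P <- cbind(runif(30) * Lx, runif(30) * Ly, rnorm(30, 0, 10))
  for (k in 1:40) {
    ijk <- sample(30, 3)
    dab <- periodic_distance(P[ijk[1], ], P[ijk[2], ], Lx, Ly)
    dba <- periodic_distance(P[ijk[2], ], P[ijk[1], ], Lx, Ly)
    dac <- periodic_distance(P[ijk[1], ], P[ijk[3], ], Lx, Ly)
    dcb <- periodic_distance(P[ijk[3], ], P[ijk[2], ], Lx, Ly)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("manifoldness survives a long fuzz of random topology moves", {
  # grand-canonical run on a small patch: ~1e5 flip/insert/removal attempts
  m <- build_flat_patch(60, 60, target_edge = 8, n_frozen = 0)
  p <- membrane_params(kappa = 20, gamma = 0)
  p$z <- 0.01
  r <- run_membrane_mc(m, p, sweeps = 500,
                       schedule = move_schedule(displace = 1, flip = 2,
                                                insert = 1, remove = 1),
                       gc = TRUE, sample_every = 0, warmup = 0, seed = 13)
  cn <- r$counters
  expect_gt(cn$flip_try + cn$ins_try + cn$rem_try, 1e5)
  expect_true(validate_mesh(r$mesh))
  expect_identical(mesh_euler(r$mesh), 0L)
})

test_that("mesh files round-trip through OFF and PLY, and VTK frames are written", {
  m <- build_flat_patch(60, 60, target_edge = 8)
  m$vertices[, 3] <- sin(m$vertices[, 1] / 10) # non-trivial heights

  off <- tempfile(fileext = ".off")
  write_mesh_off(m, off)
  m2 <- read_mesh_off(off, Lx = m$Lx, Ly = m$Ly)
  expect_equal(m2$vertices, m$vertices, ignore_attr = TRUE)
  expect_identical(m2$triangles, m$triangles)

  ply <- tempfile(fileext = ".ply")
  write_mesh_ply(m, ply)
  m3 <- read_mesh_ply(ply)
  expect_equal(m3$vertices, m$vertices, ignore_attr = TRUE)
  expect_identical(m3$frozen, m$frozen)
  expect_equal(m3$Lx, m$Lx)

  vtk <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, vtk)
  head <- readLines(vtk, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "POLYDATA")
})
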