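# a synthetic tube state: ideal cylinder of radius R grafted on a flat
# annulus of scattered points (vertex positions only; tube_metrics does
# not need connectivity)
synthetic_tube <- function(R = 31.6, L = 120, box = 140, n_ring = 24,
                          seed = 1) {
  set.seed(seed)
  zs <- seq(2, L, by = 4)
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-1]
  tube <- do.call(rbind, lapply(zs, function(z) {
    cbind(box / 2 + R * cos(ang + z), box / 2 + R * sin(ang + z), z)
  }))
  flat <- cbind(runif(300) * box, runif(300) * box, rnorm(300, 0, 1.5))
  keep <- periodic_distance(cbind(flat[, 1], flat[, 2], 0),
                            matrix(c(box / 2, box / 2, 0), 1),
                            box, box) > R + 5
  V <- rbind(tube, flat[keep, ])
  structure(
    list(vertices = V, triangles = matrix(integer(0), 0, 3),
         frozen = logical(nrow(V)), Lx = box, Ly = box,
         target_edge = 8, seed = 1L),
    class = "trimesh"
  )
}

test_that("tube metrics recover an ideal cylinder and invert the tension relation", {
  m <- synthetic_tube(R = 31.6, L = 120)
  tm <- tube_metrics(m, kappa = 20)
  expect_true(tm$has_tube)
  expect_equal(tm$L, 118, tolerance = 0.01)
  expect_equal(tm$R, 31.6, tolerance = 0.02)
  expect_equal(tm$gamma, 0.01, tolerance = 0.05) # printed relation R0 = sqrt(kappa/2 gamma)
})

test_that("a flat patch yields no tube and the metrics are flagged", {
  m <- thermal_patch()
  tm <- tube_metrics(m, kappa = 20)
  expect_false(tm$has_tube)
  expect_true(is.na(tm$R))
  expect_lt(tm$L, 15)
})

test_that("filament classification is exhaustive, exclusive, and label-stable", {
  m <- synthetic_tube(R = 30, L = 120)
  tm <- tube_metrics(m, kappa = 20)
  mk_fil <- function(base, tip_dir, n = 30) {
    f <- filament(base, c(0, 0, 1), n = n)
    k <- nrow(f$nodes)
    f$nodes[k, ] <- f$nodes[k - 1, ] + 2.7 * tip_dir
    f
  }
  inside <- filament(c(m$Lx / 2 + 5, m$Ly / 2, 0), c(0, 0, 1), n = 35)
  away <- filament(c(20, 20, -40), c(0, 0, 1), n = 5)
  down <- mk_fil(c(100, 30, -20), c(0, 0, -1))
  lab <- classify_filaments(list(inside, away, down), tm, m)
  expect_identical(as.character(lab), c("bundled", "unbundled", "failed"))
  # permutation invariance
  lab2 <- classify_filaments(list(down, inside, away), tm, m)
  expect_identical(as.character(lab2), c("failed", "bundled", "unbundled"))
})

test_that("alignment profile is 1 for parallel, 0 for antiparallel, small for isotropic", {
  up <- filament(c(0, 0, 0), c(0, 0, 1), n = 4)
  up2 <- filament(c(30, 0, 0), c(0, 0, 1), n = 4)
  a <- alignment_profile(list(up, up2))
  expect_true(all(abs(a$a - 1) < 1e-12))

  dn <- filament(c(30, 0, 4 * 2.7), c(0, 0, -1), n = 4)
  a2 <- alignment_profile(list(up, dn))
  expect_true(all(a2$a < 1e-12))

  # N random isotropic segments: a ~ O(1/sqrt(N))
  set.seed(6)
  N <- 400
  fils <- lapply(seq_len(N), function(i) {
    o <- rnorm(3)
    o <- o / sqrt(sum(o^2))
    f <- filament(c(i, 0, 10), o, n = 1, delta = 1)
    f
  })
  a3 <- alignment_profile(fils, dL = 1e3)
  expect_lt(a3$a[1], 4 / sqrt(N))
})

test_that("random initial conditions honour the angle statistics and sterics", {
  ic0 <- generate_initial_condition(8, std = 0, Lx = 140, Ly = 140, seed = 3)
  expect_true(all(ic0$table$polar_deg == 0))

  ic <- generate_initial_condition(60, std = 20, depth = 50,
                                   Lx = 400, Ly = 400, seed = 3)
  expect_equal(length(ic$filaments), 60L)
  # half-normal polar angles with sigma = 20 degrees
  expect_equal(sd(c(ic$table$polar_deg, -ic$table$polar_deg)), 20,
               tolerance = 0.25)
  expect_true(all(ic$table$z == -50))
  # base pair separations respect the filament hard core (minimum image)
  B <- cbind(ic$table$x, ic$table$y, 0)
  dmin <- min(vapply(seq_len(nrow(B) - 1), function(i) {
    min(periodic_distance(B[(i + 1):nrow(B), , drop = FALSE],
                          B[i, , drop = FALSE], 400, 400))
  }, numeric(1)))
  expect_gt(dmin, 10 - 1e-9)
  # reproducible
  ic2 <- generate_initial_condition(60, std = 20, depth = 50,
                                    Lx = 400, Ly = 400, seed = 3)
  expect_identical(ic$table, ic2$table)
  expect_error(
    generate_initial_condition(200, std = 0, Lx = 50, Ly = 50, seed = 1),
    "overlap"
  )
})

test_that("filament trajectories and manifests are written to disk", {
  f <- filament(c(0, 0, 0), c(0, 0, 1), n = 3)
  csv <- tempfile(fileext = ".csv")
  write_filament_csv(list(list(f), list(grow(f))), csv)
  d <- read.csv(csv)
  expect_identical(names(d), c("frame", "filament", "node", "x", "y", "z"))
  expect_identical(unique(d$frame), c(0L, 1L))
  expect_identical(sum(d$frame == 1L), 5L)

  xyz <- tempfile(fileext = ".xyz")
  write_filaments_xyz(list(f), xyz)
  expect_identical(readLines(xyz, n = 1), "4")

  mf <- tempfile(fileext = ".json")
  write_manifest(list(kappa = 20, seed = 7), mf)
  j <- jsonlite::read_json(mf)
  expect_equal(j$kappa, 20)
  expect_true(!is.null(j$package_version))
})

test_that("yaml configs drive the command-line dispatcher", {
  cfg <- tempfile(fileext = ".yaml")
  out <- file.path(tempdir(), "fpt_cli_test")
  writeLines(c(
    paste0("out_dir: ", out),
    "theta: 45", "L0: 60", "kappa: 20", "gamma: 0.01", "kon0: 1",
    "koff: 0.01", "patch_L: 140"
  ), cfg)
  res <- memtube_main(c("fpt", cfg))
  expect_true(file.exists(file.path(out, "fpt_distribution.csv")))
  expect_true(file.exists(file.path(out, "fpt_summary.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  s <- jsonlite::read_json(file.path(out, "fpt_summary.json"))
  expect_equal(s$mfpt, s$mfpt_closed, tolerance = 1e-5)
})
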