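# shared fixtures, all generated in code

# triangulated icosphere of radius R (subdivided icosahedron), wrapped in a
# far-from-periodic box so the minimum-image convention is inert
icosphere_mesh <- function(nsub = 3, R = 50) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(nsub)) {
    mid <- new.env()
    nV <- V
    nF <- NULL
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      nV <<- rbind(nV, (V[a, ] + V[b, ]) / 2)
      mid[[k]] <- nrow(nV)
      nrow(nV)
    }
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; cc <- F[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nF <- rbind(nF, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    V <- nV
    F <- nF
  }
  V <- V / sqrt(rowSums(V^2)) * R
  storage.mode(F) <- "integer"
  structure(
    list(vertices = V + 20 * R, triangles = F, frozen = logical(nrow(V)),
         Lx = 100 * R, Ly = 100 * R, target_edge = NA_real_,
         seed = 1L),
    class = "trimesh"
  )
}

# open triangulated cylinder, periodic along y, radius R
cylinder_mesh <- function(R = 31.6, Ly = 100, edge = 5) {
  m <- build_flat_patch(2 * pi * R, Ly, target_edge = edge, n_frozen = 0)
  ang <- m$vertices[, 1] / (2 * pi * R) * 2 * pi
  m$vertices <- cbind(1e5 + R * cos(ang), m$vertices[, 2], R * sin(ang))
  m$Lx <- 1e7 # x no longer wraps
  m
}

# a small thermalized flat patch (cached per session)
thermal_patch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_flat_patch(80, 80, target_edge = 8)
      p <- membrane_params(kappa = 20, gamma = 0)
      r <- run_membrane_mc(m, p, sweeps = 1500, warmup = 500,
                           sample_every = 0, seed = 101)
      cache <<- r$mesh
    }
    cache
  }
})
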