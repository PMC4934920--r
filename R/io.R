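#' Write a mesh in OFF format
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mesh from OFF format
#'
#' Periodic box lengths are not part of OFF; supply them (or accept the
#' bounding box of the vertices).
#'
#' @param path input file.
#' @param Lx,Ly periodic box lengths (nm); defaults to the lateral
#'   bounding box.
#' @export
read_mesh_off <- function(path, Lx = NULL, Ly = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hdr[1]
  nf <- hdr[2]
  V <- do.call(rbind, lapply(lines[3:(2 + nv)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])
  }))
  Fm <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(s) {
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L
  }))
  if (is.null(Lx)) Lx <- max(V[, 1]) * (1 + 1 / (2 * sqrt(nv)))
  if (is.null(Ly)) Ly <- max(V[, 2]) * (1 + 1 / (2 * sqrt(nv)))
  m <- structure(
    list(vertices = V, triangles = Fm, frozen = logical(nv),
         Lx = Lx, Ly = Ly, target_edge = NA_real_, seed = NA_integer_),
    class = "trimesh"
  )
  validate_mesh(m)
  m
}

#' Write a mesh in ASCII PLY format
#'
#' Stores the frozen flag as a per-vertex `uchar frozen` property and
#' the box lengths in a comment, so [read_mesh_ply()] round-trips the
#' full state.
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("comment box %.17g %.17g", mesh$Lx, mesh$Ly),
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    "property uchar frozen",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(
    cbind(format(mesh$vertices, digits = 17, trim = TRUE,
                 scientific = FALSE), as.integer(mesh$frozen)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mesh from ASCII PLY
#'
#' @param path input file.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  boxline <- grep("^comment box", hdr, value = TRUE)
  box <- if (length(boxline)) {
    as.numeric(strsplit(boxline, "\\s+")[[1]][3:4])
  } else {
    c(NA, NA)
  }
  vl <- lines[(endh + 1):(endh + nv)]
  Vm <- do.call(rbind, lapply(vl, function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  }))
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  Fm <- do.call(rbind, lapply(fl, function(s) {
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L
  }))
  frozen <- if (ncol(Vm) >= 4) Vm[, 4] > 0 else logical(nv)
  m <- structure(
    list(vertices = Vm[, 1:3, drop = FALSE], triangles = Fm,
         frozen = frozen,
         Lx = if (is.na(box[1])) max(Vm[, 1]) else box[1],
         Ly = if (is.na(box[2])) max(Vm[, 2]) else box[2],
         target_edge = NA_real_, seed = NA_integer_),
    class = "trimesh"
  )
  validate_mesh(m)
  m
}

#' Write a mesh frame in legacy VTK (ASCII PolyData)
#'
#' For visualization of per-frame output in ParaView and friends.
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "membrane frame", "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", nrow(mesh$vertices))
  ), con)
  utils::write.table(format(mesh$vertices, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write filament trajectories as CSV
#'
#' Long-format node table (frame, filament, node, x, y, z); frame
#' indices are 0-based.
#'
#' @param snapshots list of filament-list snapshots (as produced by the
#'   run drivers) or a single filament list.
#' @param path output file.
#' @export
write_filament_csv <- function(snapshots, path) {
  if (!is.null(snapshots$nodes) || inherits(snapshots, "filament")) {
    snapshots <- list(list(snapshots))
  }
  if (length(snapshots) > 0 && !is.null(snapshots[[1]]$nodes)) {
    snapshots <- list(snapshots)
  }
  rows <- lapply(seq_along(snapshots), function(fr) {
    fl <- snapshots[[fr]]
    do.call(rbind, lapply(seq_along(fl), function(i) {
      nd <- fl[[i]]$nodes
      data.frame(
        frame = fr - 1L, filament = i,
        node = seq_len(nrow(nd)) - 1L,
        x = nd[, 1], y = nd[, 2], z = nd[, 3]
      )
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write filaments as a per-frame XYZ file
#'
#' @param filaments list of [filament()]s.
#' @param path output file.
#' @param append append as an additional frame.
#' @export
write_filaments_xyz <- function(filaments, path, append = FALSE) {
  n <- sum(vapply(filaments, function(f) nrow(f$nodes), integer(1)))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", n), "filament nodes (nm)"), con)
  for (i in seq_along(filaments)) {
    nd <- filaments[[i]]$nodes
    writeLines(sprintf("F%d %.6f %.6f %.6f", i, nd[, 1], nd[, 2], nd[, 3]),
               con)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration driving the command-line experiments;
#' see the files under `inst/examples/` for the available keys of each
#' experiment type.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a run manifest
#'
#' JSON record of all parameters, seeds and package version alongside
#' the outputs of a run, for provenance.
#'
#' @param params named list of everything worth recording.
#' @param path output file.
#' @export
write_manifest <- function(params, path) {
  params$package_version <- as.character(utils::packageVersion("memtube"))
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
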