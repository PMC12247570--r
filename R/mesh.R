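#' Build a subdivided icosahedral sphere mesh
#'
#' Generates a closed triangulated sphere by recursive midpoint subdivision of
#' a regular icosahedron, projecting every vertex onto the sphere of the
#' requested radius.  The result is the synthetic stand-in for a cortical
#' surface: it carries per-vertex outward unit normals (the dipolar moment of
#' each source) and per-vertex areas (one third of the area of the incident
#' triangles), the two ingredients of the dipolar forward model.
#'
#' @param subdivisions Number of midpoint subdivision rounds (0 keeps the
#'   icosahedron; each round quadruples the face count).  Values above 7 are
#'   rejected as a resource guard.
#' @param radius Sphere radius in mm.
#' @param center Numeric length-3 center position in mm.
#' @return An object of class `triangle_mesh`: list with `vertices` (n x 3,
#'   mm), `triangles` (m x 3, 1-based indices), `normals` (n x 3, unit),
#'   `areas` (length n, mm^2), `center`, `radius`.
#' @examples
#' m <- build_icosphere(1, radius = 50)
#' nrow(m$vertices)  # 42
#' @export
build_icosphere <- function(subdivisions = 4, radius = 70,
                            center = c(0, 0, 0)) {
  stopifnot(subdivisions >= 0, radius > 0, length(center) == 3)
  if (subdivisions > 7) {
    stop("subdivisions > 7 rejected: mesh would exceed the intended scale")
  }
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # counter-clockwise when seen from outside
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- new.env(hash = TRUE, parent = emptyenv())
    verts <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_key[[key]]
      if (!is.null(idx)) return(idx)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      verts[[length(verts) + 1L]] <<- p
      idx <- nv + length(verts)
      edge_key[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(cc, ca, bc)
      nf[4 * k, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- nf
  }

  vertices <- sweep(v * radius, 2, center, "+")
  mesh <- structure(
    list(vertices = vertices, triangles = f, center = center,
         radius = radius),
    class = "triangle_mesh")
  mesh$normals <- mesh_vertex_normals(mesh)
  mesh$areas <- mesh_vertex_areas(mesh)
  mesh
}

#' Per-triangle areas and outward face normals
#' @param mesh A `triangle_mesh`.
#' @return List with `area` (length m) and `normal` (m x 3, unit).
#' @keywords internal
mesh_face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / nrm)
}

#' Vertex normals as area-weighted incident-face normals, unit length
#' @param mesh A `triangle_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  fg <- mesh_face_geometry(mesh)
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3)
  f <- mesh$triangles
  w <- fg$normal * fg$area
  for (j in 1:3) {
    acc[, 1] <- acc[, 1] + tabulate_weighted(f[, j], w[, 1], n)
    acc[, 2] <- acc[, 2] + tabulate_weighted(f[, j], w[, 2], n)
    acc[, 3] <- acc[, 3] + tabulate_weighted(f[, j], w[, 3], n)
  }
  acc / sqrt(rowSums(acc^2))
}

#' Vertex areas: one third of the summed incident-triangle areas
#' @param mesh A `triangle_mesh`.
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
mesh_vertex_areas <- function(mesh) {
  fg <- mesh_face_geometry(mesh)
  n <- nrow(mesh$vertices)
  a <- numeric(n)
  f <- mesh$triangles
  for (j in 1:3) a <- a + tabulate_weighted(f[, j], fg$area / 3, n)
  a
}

# sum `w` into bins given by `idx` (1..n)
tabulate_weighted <- function(idx, w, n) {
  as.vector(unname(vapply(split(w, factor(idx, levels = seq_len(n))), sum,
                          numeric(1))))
}

#' Undirected edge list of a triangle mesh with Euclidean lengths
#' @param mesh A `triangle_mesh`.
#' @return Data frame with columns `from`, `to`, `length` (mm), each edge once.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  data.frame(from = e[, 1], to = e[, 2], length = d)
}

#' Geodesic distance matrix on the mesh edge graph
#'
#' Geodesic distances are approximated by shortest paths along mesh edges with
#' Euclidean edge weights.  On the desk-scale meshes used here (thousands of
#' vertices) the full matrix is computed once and reused by the parcellation,
#' the local coupling kernel, and region growing.
#'
#' @param mesh A `triangle_mesh`.
#' @return Dense n x n symmetric distance matrix (mm).
#' @export
mesh_geodesics <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
                                     vertices = data.frame(
                                       name = seq_len(nrow(mesh$vertices))))
  d <- igraph::distances(g, weights = e$length)
  ord <- as.integer(igraph::V(g)$name)
  d[order(ord), order(ord)]
}

#' Mean edge length of a mesh (mm)
#' @param mesh A `triangle_mesh`.
#' @return Scalar mean edge length.
#' @export
mesh_mean_edge_length <- function(mesh) mean(mesh_edges(mesh)$length)

#' Write / read a triangle mesh as ASCII PLY plus a vertex-attribute table
#'
#' The PLY file stores vertex coordinates and faces; the companion plain-text
#' table (`<path>.attr.tsv`) stores per-vertex normals and areas so the mesh
#' round-trips with its forward-model attributes.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output PLY path.
#' @return `write_mesh_ply` returns `path` invisibly; `read_mesh_ply` returns
#'   a `triangle_mesh`.
#' @export
write_mesh_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", m),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 10), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  attr_tab <- data.frame(nx = mesh$normals[, 1], ny = mesh$normals[, 2],
                         nz = mesh$normals[, 3], area = mesh$areas)
  write.table(attr_tab, paste0(path, ".attr.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")
  n <- as.integer(sub("element vertex ", "",
                      grep("^element vertex", lines, value = TRUE)))
  m <- as.integer(sub("element face ", "",
                      grep("^element face", lines, value = TRUE)))
  vtx <- do.call(rbind, lapply(lines[hdr_end + seq_len(n)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  fc <- do.call(rbind, lapply(lines[hdr_end + n + seq_len(m)], function(l)
    as.integer(strsplit(l, " ")[[1]])[2:4] + 1L))
  mesh <- structure(list(vertices = vtx, triangles = fc,
                         center = colMeans(vtx), radius = NA_real_),
                    class = "triangle_mesh")
  attr_path <- paste0(path, ".attr.tsv")
  if (file.exists(attr_path)) {
    at <- read.table(attr_path, header = TRUE, sep = "\t")
    mesh$normals <- as.matrix(at[, c("nx", "ny", "nz")])
    mesh$areas <- at$area
  } else {
    mesh$normals <- mesh_vertex_normals(mesh)
    mesh$areas <- mesh_vertex_areas(mesh)
  }
  mesh
}
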