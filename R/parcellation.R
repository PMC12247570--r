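#' Parcellate a mesh into contiguous regions
#'
#' Emulates an anatomical atlas at desk scale: region seeds are picked by
#' farthest-point sampling on the geodesic distance matrix and grown by
#' nearest-seed assignment, which yields contiguous, roughly equal-area
#' regions.  Any small disconnected fragment left by distance ties is
#' reassigned to the neighbouring region with the longest shared boundary, so
#' every region is edge-connected on the mesh graph.  Subcortical structures
#' are represented as point sources on an interior shell, each its own region
#' with an id following the cortical ids.
#'
#' @param mesh A `triangle_mesh`.
#' @param n_regions Number of cortical regions (1..n_vertices).
#' @param seed Integer seed; the parcellation is reproducible bit-for-bit.
#' @param n_subcortical Number of subcortical point nodes (placed on a shell
#'   at 40% of the mesh radius).
#' @param geo Optional precomputed geodesic matrix from [mesh_geodesics()].
#' @return An object of class `parcellation`: `region_label` (per vertex,
#'   1..n_regions), `n_regions`, `subcortical` (data frame: region, x, y, z),
#'   `barycenters` (n_regions x 3, cortical, mm), `n_total` regions overall.
#' @export
parcellate_mesh <- function(mesh, n_regions, seed = 1L, n_subcortical = 0L,
                            geo = NULL) {
  nv <- nrow(mesh$vertices)
  stopifnot(n_regions >= 1, n_regions <= nv)
  if (is.null(geo)) geo <- mesh_geodesics(mesh)
  set.seed(seed)

  seeds <- integer(n_regions)
  seeds[1] <- sample.int(nv, 1)
  if (n_regions > 1) {
    dmin <- geo[, seeds[1]]
    for (k in 2:n_regions) {
      seeds[k] <- which.max(dmin)
      dmin <- pmin(dmin, geo[, seeds[k]])
    }
  }
  lab <- apply(geo[, seeds, drop = FALSE], 1, which.min)

  lab <- repair_contiguity(mesh, lab, n_regions)
  if (any(tabulate(lab, n_regions) == 0)) {
    stop("internal error: empty region after assignment")
  }

  bary <- t(vapply(seq_len(n_regions), function(r)
    colMeans(mesh$vertices[lab == r, , drop = FALSE]), numeric(3)))

  sub <- NULL
  if (n_subcortical > 0) {
    # even placement on an interior shell, jittered deterministically
    u <- seq(0, 1, length.out = n_subcortical + 2)[2:(n_subcortical + 1)]
    th <- 2 * pi * u + runif(n_subcortical, 0, 0.3)
    z <- runif(n_subcortical, -0.5, 0.5)
    r_shell <- 0.4 * mesh$radius
    pos <- cbind(r_shell * sqrt(1 - z^2) * cos(th),
                 r_shell * sqrt(1 - z^2) * sin(th),
                 r_shell * z)
    pos <- sweep(pos, 2, mesh$center, "+")
    sub <- data.frame(region = n_regions + seq_len(n_subcortical),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }

  structure(list(region_label = lab, n_regions = n_regions,
                 subcortical = sub, barycenters = bary,
                 n_total = n_regions + n_subcortical),
            class = "parcellation")
}

# reassign disconnected fragments of each region to the neighbour region
# sharing the most boundary edges
repair_contiguity <- function(mesh, lab, n_regions) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  adj <- vector("list", nv)
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(n_regions)) {
      members <- which(lab == r)
      if (length(members) == 0) next
      comp <- region_components(members, adj)
      if (length(comp) <= 1) next
      sizes <- lengths(comp)
      keep <- which.max(sizes)
      for (ci in seq_along(comp)) {
        if (ci == keep) next
        frag <- comp[[ci]]
        nbr_labs <- unlist(lapply(frag, function(vv) lab[adj[[vv]]]))
        nbr_labs <- nbr_labs[nbr_labs != r]
        if (length(nbr_labs) == 0) next
        tgt <- as.integer(names(which.max(table(nbr_labs))))
        lab[frag] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# connected components of a vertex subset on the adjacency list
region_components <- function(members, adj) {
  in_set <- logical(length(adj))
  in_set[members] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (v0 in members) {
    if (seen[v0]) next
    queue <- v0
    seen[v0] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

#' Region adjacency on the mesh
#' @param mesh A `triangle_mesh`.
#' @param parcellation A `parcellation`.
#' @return Logical n_regions x n_regions matrix; TRUE where two cortical
#'   regions share at least one mesh edge.
#' @export
region_adjacency <- function(mesh, parcellation) {
  e <- mesh_edges(mesh)
  lab <- parcellation$region_label
  a <- matrix(FALSE, parcellation$n_regions, parcellation$n_regions)
  la <- lab[e$from]; lb <- lab[e$to]
  cross <- la != lb
  for (k in which(cross)) {
    a[la[k], lb[k]] <- TRUE
    a[lb[k], la[k]] <- TRUE
  }
  a
}

#' Grow a half-size subregion from the region barycenter
#'
#' Starting from the vertex nearest the region barycenter, vertices of the
#' region are added in order of geodesic distance until the accumulated vertex
#' area crosses half the full region area.
#'
#' @param mesh A `triangle_mesh`.
#' @param parcellation A `parcellation`.
#' @param region Cortical region id.
#' @param geo Optional precomputed geodesic matrix.
#' @return Integer vector of vertex indices (subset of the region's vertices).
#' @export
grow_half_region <- function(mesh, parcellation, region, geo = NULL) {
  stopifnot(region >= 1, region <= parcellation$n_regions)
  members <- which(parcellation$region_label == region)
  if (length(members) < 2) stop("region has fewer than 2 vertices")
  bary <- parcellation$barycenters[region, ]
  d_bary <- sqrt(colSums((t(mesh$vertices[members, , drop = FALSE]) - bary)^2))
  start <- members[which.min(d_bary)]
  if (is.null(geo)) geo <- mesh_geodesics(mesh)
  ord <- members[order(geo[start, members])]
  areas <- mesh$areas[ord]
  target <- sum(areas) / 2
  n_take <- which(cumsum(areas) >= target)[1]
  ord[seq_len(n_take)]
}
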