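#' Place depth electrodes in the synthetic brain
#'
#' Entry points are spread over the surface by farthest-point sampling from a
#' seeded random start (emulating an implantation that covers the sampled
#' territory).  Each electrode advances from its entry point on an oblique
#' trajectory — aimed inward but tilted away from the radial direction — so
#' that, as with real trajectories through folded cortex, the contact array
#' stays within one to a few centimetres of the surface and samples two to
#' three regions rather than burying its deep contacts at the sphere center.
#' Contact centers are spaced 3.5 mm apart (2 mm contact length + 1.5 mm
#' gap), starting 1 mm beneath the entry point, indexed distal-to-proximal
#' along the trajectory.  Bipolar channels are the ordered pairs of adjacent
#' contacts within an electrode.
#'
#' @param mesh A `triangle_mesh`.
#' @param n_electrodes Number of electrodes.
#' @param contacts_per_electrode Contacts per electrode (>= 2; clinically
#'   10-18).
#' @param seed Integer seed.
#' @param obliquity Range of the sine of the angle between the trajectory
#'   and the inward radial direction; larger values keep the array closer to
#'   the surface.
#' @param entries Optional vertex indices for the entry points (one per
#'   electrode), e.g. from [implantation_entries()]; spread over the surface
#'   by farthest-point sampling when omitted.
#' @return An object of class `sensor_array`: `contacts` data frame
#'   (electrode, contact, x, y, z), `bipolar` data frame (electrode, from, to
#'   as global contact row indices), `n_contacts`, `n_bipolar`.
#' @export
place_electrodes <- function(mesh, n_electrodes = 5,
                             contacts_per_electrode = 10, seed = 1L,
                             obliquity = c(0.5, 0.8), entries = NULL) {
  stopifnot(contacts_per_electrode >= 2)
  spacing <- 3.5
  depth0 <- 1
  max_depth <- depth0 + (contacts_per_electrode - 1) * spacing
  diam <- 2 * max(sqrt(rowSums(sweep(mesh$vertices, 2, mesh$center)^2)))
  if (max_depth > diam) stop("electrode longer than mesh diameter")
  set.seed(seed)
  if (is.null(entries)) {
    # spread entries by farthest-point sampling
    entries <- integer(n_electrodes)
    entries[1] <- sample.int(nrow(mesh$vertices), 1)
    if (n_electrodes > 1) {
      dmin <- sqrt(rowSums(sweep(mesh$vertices, 2,
                                 mesh$vertices[entries[1], ])^2))
      for (k in 2:n_electrodes) {
        entries[k] <- which.max(dmin)
        dmin <- pmin(dmin, sqrt(rowSums(sweep(mesh$vertices, 2,
                                              mesh$vertices[entries[k], ])^2)))
      }
    }
  }
  stopifnot(length(entries) == n_electrodes)
  rows <- list()
  for (el in seq_len(n_electrodes)) {
    entry <- mesh$vertices[entries[el], ]
    inward <- mesh$center - entry
    inward <- inward / sqrt(sum(inward^2))
    perp <- if (abs(inward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- perp - sum(perp * inward) * inward
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(inward[2] * e1[3] - inward[3] * e1[2],
            inward[3] * e1[1] - inward[1] * e1[3],
            inward[1] * e1[2] - inward[2] * e1[1])
    sphi <- runif(1, obliquity[1], obliquity[2])
    az <- runif(1, 0, 2 * pi)
    tangent <- cos(az) * e1 + sin(az) * e2
    dirv <- sqrt(1 - sphi^2) * inward + sphi * tangent
    depth <- depth0 + spacing * (seq_len(contacts_per_electrode) - 1)
    # contact 1 is the deepest (distal tip)
    depth <- rev(depth)
    pos <- sweep(outer(depth, dirv), 2, entry, "+")
    rows[[el]] <- data.frame(electrode = el,
                             contact = seq_len(contacts_per_electrode),
                             x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  contacts <- do.call(rbind, rows)
  bip <- do.call(rbind, lapply(seq_len(n_electrodes), function(el) {
    idx <- which(contacts$electrode == el)
    data.frame(electrode = el, from = idx[-length(idx)], to = idx[-1])
  }))
  structure(list(contacts = contacts, bipolar = bip,
                 n_contacts = nrow(contacts), n_bipolar = nrow(bip)),
            class = "sensor_array")
}

#' Hypothesis-driven electrode entry points
#'
#' Clinically, depth electrodes are implanted to test the epileptogenic-zone
#' hypothesis, so the regions of interest are well sampled by construction.
#' This helper emulates that: it greedily selects adjacent region pairs
#' covering as many distinct cortical regions as possible (two new regions
#' per electrode when available) and returns, for each pair, the mesh vertex
#' nearest the midpoint of the two barycenters — an entry point on the
#' boundary, from which one electrode samples both regions.
#'
#' @param mesh A `triangle_mesh`.
#' @param parcellation A `parcellation`.
#' @param n_electrodes Number of electrodes.
#' @param seed Integer seed (shuffles the candidate pairs).
#' @return Integer vector of entry vertex indices (length `n_electrodes`).
#' @export
implantation_entries <- function(mesh, parcellation, n_electrodes, seed = 1L) {
  adj <- region_adjacency(mesh, parcellation)
  set.seed(seed)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  chosen <- matrix(integer(0), 0, 2)
  used <- integer(0)
  taken <- rep(FALSE, nrow(pairs))
  for (need_new in c(2, 1, 0)) {
    for (k in seq_len(nrow(pairs))) {
      if (nrow(chosen) >= n_electrodes) break
      if (taken[k]) next
      pr <- pairs[k, ]
      if (sum(!(pr %in% used)) >= need_new) {
        chosen <- rbind(chosen, pr)
        used <- union(used, pr)
        taken[k] <- TRUE
      }
    }
  }
  if (nrow(chosen) < n_electrodes) stop("not enough adjacent region pairs")
  vapply(seq_len(n_electrodes), function(i) {
    mid <- (parcellation$barycenters[chosen[i, 1], ] +
            parcellation$barycenters[chosen[i, 2], ]) / 2
    which.min(colSums((t(mesh$vertices) - mid)^2))
  }, integer(1))
}

#' Contact positions as a matrix
#' @param sensors A `sensor_array`.
#' @return n_contacts x 3 matrix (mm).
#' @export
contact_positions <- function(sensors) {
  as.matrix(sensors$contacts[, c("x", "y", "z")])
}

#' Write / read contacts as TSV
#' @param sensors A `sensor_array`.
#' @param path TSV path.
#' @return `write_contacts_tsv` returns `path` invisibly;
#'   `read_contacts_tsv` returns a `sensor_array`.
#' @export
write_contacts_tsv <- function(sensors, path) {
  write.table(sensors$contacts, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_contacts_tsv
#' @export
read_contacts_tsv <- function(path) {
  contacts <- read.table(path, header = TRUE, sep = "\t")
  bip <- do.call(rbind, lapply(unique(contacts$electrode), function(el) {
    idx <- which(contacts$electrode == el)
    data.frame(electrode = el, from = idx[-length(idx)], to = idx[-1])
  }))
  structure(list(contacts = contacts, bipolar = bip,
                 n_contacts = nrow(contacts), n_bipolar = nrow(bip)),
            class = "sensor_array")
}
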