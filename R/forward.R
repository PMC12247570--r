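#' Dipolar (neural field) gain matrix
#'
#' Treats the brain as an infinite homogeneous volume conductor.  Each
#' cortical vertex is a current dipole of unit moment along its surface
#' normal, weighted by its vertex area: the gain from vertex `i` to contact
#' `k` is `a_i/(4 pi sigma) * Q_i . (r_k - x_i) / |r_k - x_i|^3`.  Subcortical
#' point nodes have no defined orientation and use the orientation-free
#' inverse-square (neural mass) form with a nominal source area.
#'
#' @param mesh A `triangle_mesh`.
#' @param sensors A `sensor_array`.
#' @param subcortical Optional data frame of subcortical nodes
#'   (`region, x, y, z`), appended as extra source columns.
#' @param sigma Homogeneous conductivity (arbitrary units).
#' @param min_distance Guard distance (mm): any source closer than this to a
#'   contact is rejected (re-seed the electrode placement).
#' @param subcortical_area Nominal source area for subcortical point nodes
#'   (mm^2); use [subcortical_source_area()] so both forward models share the
#'   same value.  Defaults to the mean vertex area when unspecified.
#' @return A `gain_matrix` object: `g` (contacts x sources), `montage`
#'   ("monopolar"), `model` ("nfm").
#' @export
nfm_gain <- function(mesh, sensors, subcortical = NULL, sigma = 1,
                     min_distance = 0.5, subcortical_area = NULL) {
  stopifnot(sigma > 0)
  rk <- contact_positions(sensors)
  x <- mesh$vertices
  g <- matrix(0, nrow(rk), nrow(x) + NROW(subcortical))
  for (k in seq_len(nrow(rk))) {
    dvec <- sweep(x, 2, rk[k, ], "-") * -1   # r_k - x_i
    dn <- sqrt(rowSums(dvec^2))
    if (any(dn < min_distance)) {
      stop("contact within ", min_distance,
           " mm of a cortical source; re-seed electrode placement")
    }
    g[k, seq_len(nrow(x))] <-
      mesh$areas / (4 * pi * sigma) * rowSums(mesh$normals * dvec) / dn^3
  }
  if (!is.null(subcortical) && nrow(subcortical) > 0) {
    a_nom <- subcortical_area %||% mean(mesh$areas)
    sp <- as.matrix(subcortical[, c("x", "y", "z")])
    for (k in seq_len(nrow(rk))) {
      dn <- sqrt(rowSums(sweep(sp, 2, rk[k, ], "-")^2))
      if (any(dn < min_distance)) stop("contact too close to a subcortical source")
      g[k, nrow(x) + seq_len(nrow(sp))] <- a_nom / (4 * pi * sigma * dn^2)
    }
  }
  structure(list(g = g, montage = "monopolar", model = "nfm"),
            class = "gain_matrix")
}

#' Nominal source area for subcortical point nodes
#'
#' The mean total area of a cortical region; used by both forward models so
#' subcortical gain entries share one scale.
#'
#' @param mesh A `triangle_mesh`.
#' @param parcellation A `parcellation`.
#' @return Scalar area (mm^2).
#' @export
subcortical_source_area <- function(mesh, parcellation) {
  sum(mesh$areas) / parcellation$n_regions
}

#' Orientation-maximizing (neural mass) gain matrix
#'
#' Point-like regions cannot carry a meaningful dipole orientation, so the
#' neural mass forward model assumes for every vertex the orientation that
#' maximizes its dipolar gain (pointing straight at the contact), collapsing
#' the dipole to an inverse-square law: the gain of region `i` at contact `k`
#' is `1/(4 pi sigma) * sum_{j in region i} a_j / |r_k - x_j|^2`.
#'
#' @param mesh A `triangle_mesh`.
#' @param parcellation A `parcellation`.
#' @param sensors A `sensor_array`.
#' @param sigma Homogeneous conductivity.
#' @param min_distance Source-contact guard distance (mm).
#' @return A `gain_matrix` (contacts x regions, subcortical included),
#'   `model = "nmm"`.
#' @export
nmm_gain <- function(mesh, parcellation, sensors, sigma = 1,
                     min_distance = 0.5) {
  stopifnot(sigma > 0)
  rk <- contact_positions(sensors)
  x <- mesh$vertices
  lab <- parcellation$region_label
  n_reg <- parcellation$n_total
  g <- matrix(0, nrow(rk), n_reg)
  for (k in seq_len(nrow(rk))) {
    dn2 <- rowSums(sweep(x, 2, rk[k, ], "-")^2)
    if (any(dn2 < min_distance^2)) {
      stop("contact within ", min_distance,
           " mm of a cortical source; re-seed electrode placement")
    }
    contrib <- mesh$areas / (4 * pi * sigma * dn2)
    g[k, seq_len(parcellation$n_regions)] <-
      tabulate_weighted(lab, contrib, parcellation$n_regions)
  }
  if (!is.null(parcellation$subcortical)) {
    sub <- parcellation$subcortical
    a_nom <- subcortical_source_area(mesh, parcellation)
    sp <- as.matrix(sub[, c("x", "y", "z")])
    for (k in seq_len(nrow(rk))) {
      dn2 <- rowSums(sweep(sp, 2, rk[k, ], "-")^2)
      g[k, sub$region] <- a_nom / (4 * pi * sigma * dn2)
    }
  }
  structure(list(g = g, montage = "monopolar", model = "nmm"),
            class = "gain_matrix")
}

#' Project simulated source activity to SEEG contacts
#'
#' `SEEG_k(t) = sum_i g_{k,i} (q1_i(t) - u1_i(t))`: the measurement is the
#' gain-weighted sum of the instantaneous node observables.
#'
#' @param obs Sources x samples observable matrix (`q1 - u1` per node).
#' @param gain A `gain_matrix` with matching source dimension.
#' @param dt Sampling interval of the simulation (ms).
#' @return A `seeg_recording`: `signal` (contacts x samples), `montage`,
#'   `dt` (ms).
#' @export
project_to_seeg <- function(obs, gain, dt = 0.1) {
  if (ncol(gain$g) != nrow(obs)) stop("source dimension mismatch")
  structure(list(signal = gain$g %*% obs, montage = gain$montage, dt = dt),
            class = "seeg_recording")
}

#' Bipolar montage
#'
#' Differences of adjacent contacts within each electrode (`contact j+1 -
#' contact j`); common signal on a pair cancels.  Works on recordings and on
#' gain matrices.
#'
#' @param x A `seeg_recording` (monopolar) or `gain_matrix` (monopolar).
#' @param sensors A `sensor_array` providing the pairs.
#' @return Object of the same class with `montage = "bipolar"` and one row
#'   per adjacent pair.
#' @export
bipolar_montage <- function(x, sensors) {
  if (x$montage != "monopolar") stop("input already bipolar")
  bp <- sensors$bipolar
  if (inherits(x, "seeg_recording")) {
    x$signal <- x$signal[bp$to, , drop = FALSE] -
      x$signal[bp$from, , drop = FALSE]
  } else {
    x$g <- x$g[bp$to, , drop = FALSE] - x$g[bp$from, , drop = FALSE]
  }
  x$montage <- "bipolar"
  x
}

#' Globally max-abs-normalize a gain matrix
#' @param gain A `gain_matrix`.
#' @return The gain scaled so its largest absolute entry is 1.
#' @export
normalize_gain <- function(gain) {
  gain$g <- gain$g / max(abs(gain$g))
  gain
}

#' Similarity between the two forward models for one region
#'
#' For a region of interest, the field-model gain vector is the sum of its
#' vertices' bipolar gain columns (valid when all vertices of the region
#' share one waveform, as with zero local coupling), the mass-model vector is
#' the region's bipolar gain column; both are rectified (absolute value),
#' max-normalized, and Pearson-correlated across bipolar contacts.
#'
#' @param nmm_bip,nfm_bip Bipolar `gain_matrix` objects (`nmm` over regions,
#'   `nfm` over vertices and subcortical sources).
#' @param region Region id.
#' @param parcellation A `parcellation`.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
gain_correlation <- function(nmm_bip, nfm_bip, region, parcellation) {
  if (nmm_bip$montage != "bipolar" || nfm_bip$montage != "bipolar") {
    stop("gain correlation is defined on bipolar gains")
  }
  vs <- which(parcellation$region_label == region)
  v_nfm <- abs(rowSums(nfm_bip$g[, vs, drop = FALSE]))
  v_nmm <- abs(nmm_bip$g[, region])
  if (max(v_nfm) == 0 || max(v_nmm) == 0) stop("zero-variance gain vector")
  v_nfm <- v_nfm / max(v_nfm)
  v_nmm <- v_nmm / max(v_nmm)
  if (sd(v_nfm) == 0 || sd(v_nmm) == 0) stop("zero-variance gain vector")
  cor(v_nmm, v_nfm)
}
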