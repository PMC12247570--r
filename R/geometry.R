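#' Build a complete synthetic brain geometry bundle
#'
#' Convenience constructor tying together the mesh, parcellation (with
#' subcortical point nodes), connectome, sensor array, and the precomputed
#' geodesic distance matrix.  Defaults give the desk-scale geometry used
#' throughout: an icosphere at subdivision 4 (2562 vertices, radius 70 mm),
#' 20 cortical regions, 4 subcortical nodes, and 5 electrodes of 10 contacts.
#'
#' @param subdivisions Icosphere subdivision level.
#' @param radius Sphere radius (mm).
#' @param n_regions Cortical region count.
#' @param n_subcortical Subcortical point-node count.
#' @param n_electrodes,contacts_per_electrode Sensor layout.
#' @param decay_length Connectome distance-decay length (mm).
#' @param seed Master seed for all geometry randomness.
#' @return An object of class `brain_geometry`: `mesh`, `parcellation`,
#'   `connectome`, `sensors`, `geo` (geodesic matrix), `node_region` (per
#'   dynamical node: vertices then subcortical), `n_nodes`, `n_regions_total`.
#' @export
build_geometry <- function(subdivisions = 4, radius = 70, n_regions = 20,
                           n_subcortical = 4, n_electrodes = 8,
                           contacts_per_electrode = 10, decay_length = 12,
                           seed = 1L) {
  mesh <- build_icosphere(subdivisions, radius)
  geo <- mesh_geodesics(mesh)
  parc <- parcellate_mesh(mesh, n_regions, seed = seed,
                          n_subcortical = n_subcortical, geo = geo)
  conn <- generate_connectome(parc, decay_length = decay_length,
                              seed = seed + 1L)
  entries <- implantation_entries(mesh, parc, n_electrodes, seed = seed + 2L)
  sens <- place_electrodes(mesh, n_electrodes = n_electrodes,
                           contacts_per_electrode = contacts_per_electrode,
                           seed = seed + 2L, entries = entries)
  nv <- nrow(mesh$vertices)
  node_region <- c(parc$region_label,
                   if (!is.null(parc$subcortical)) parc$subcortical$region)
  structure(list(mesh = mesh, parcellation = parc, connectome = conn,
                 sensors = sens, geo = geo, node_region = node_region,
                 n_vertices = nv,
                 n_nodes = length(node_region),
                 n_regions_total = parc$n_total,
                 seed = seed),
            class = "brain_geometry")
}

#' Build an epileptogenic-network spatial configuration
#'
#' Assigns the three excitability levels to the network: -1.6 for
#' epileptogenic-zone (EZ) nodes (seize autonomously), -2.1 for
#' propagation-zone (PZ) nodes (seize only under network input), -3.6 for
#' non-involved nodes.  With `half_size = TRUE` only the half-area subregion
#' grown from the EZ region barycenter receives the EZ value at vertex level;
#' the region-level (neural mass) excitability is unaffected by the flag.
#'
#' @param geometry A `brain_geometry`.
#' @param ez Integer set of EZ cortical region ids (nonempty).
#' @param pz Integer set of PZ cortical region ids (disjoint from `ez`;
#'   may be empty).
#' @param half_size If TRUE, restrict each EZ region to its half-area
#'   subregion at vertex level.
#' @param lc Local coupling label: one of "none" (neural mass), 0, 2, 4.
#' @param gc Global coupling scale; defaults to 1 when `pz` is empty and must
#'   be adjusted (see [adjust_global_coupling()]) otherwise.
#' @param config_type Optional catalogue label ("ez_single", "ez_half",
#'   "ez_multi", "ez_pz").
#' @return An object of class `spatial_config` with the vertex-level and
#'   region-level excitability maps and coupling scalars.
#' @export
make_configuration <- function(geometry, ez, pz = integer(0),
                               half_size = FALSE, lc = "none", gc = NULL,
                               config_type = NULL) {
  parc <- geometry$parcellation
  if (length(ez) == 0) stop("EZ set must be nonempty")
  if (length(intersect(ez, pz)) > 0) stop("EZ and PZ must be disjoint")
  n_cort <- parc$n_regions
  if (any(c(ez, pz) > n_cort) || any(c(ez, pz) < 1)) {
    stop("EZ/PZ must be cortical region ids (subcortical EZ/PZ unsupported)")
  }
  if (is.null(gc)) gc <- 1.0
  lc_label <- if (identical(lc, "none")) "lc_none" else paste0("lc_", lc)
  lc_value <- if (identical(lc, "none")) 0 else as.numeric(lc)

  u0_levels <- c(ez = -1.6, pz = -2.1, niz = -3.6)

  # region-level map (neural mass nodes)
  u0_region <- rep(u0_levels[["niz"]], geometry$n_regions_total)
  u0_region[ez] <- u0_levels[["ez"]]
  u0_region[pz] <- u0_levels[["pz"]]

  # vertex-level map (neural field nodes: vertices then subcortical)
  lab <- parc$region_label
  u0_vertex <- rep(u0_levels[["niz"]], geometry$n_vertices)
  for (r in ez) {
    if (half_size) {
      vs <- grow_half_region(geometry$mesh, parc, r, geo = geometry$geo)
    } else {
      vs <- which(lab == r)
    }
    u0_vertex[vs] <- u0_levels[["ez"]]
  }
  for (r in pz) u0_vertex[which(lab == r)] <- u0_levels[["pz"]]
  n_sub <- geometry$n_regions_total - n_cort
  u0_field <- c(u0_vertex, rep(u0_levels[["niz"]], n_sub))

  structure(list(ez = sort(ez), pz = sort(pz), half_size = half_size,
                 lc = lc_label, lc_value = lc_value, gc = gc,
                 u0_field = u0_field, u0_region = u0_region,
                 u0_levels = u0_levels,
                 config_type = config_type %||%
                   if (length(pz) > 0) "ez_pz"
                   else if (half_size) "ez_half"
                   else if (length(ez) > 1) "ez_multi" else "ez_single"),
            class = "spatial_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a spatial configuration as JSON
#' @param config A `spatial_config`.
#' @param path JSON path.
#' @return `write_config_json` returns `path` invisibly; `read_config_json`
#'   returns the list of scalar fields (maps are rebuilt from the geometry
#'   with [make_configuration()]).
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(
    list(ez = config$ez, pz = config$pz, half_size = config$half_size,
         lc = config$lc, gc = config$gc, config_type = config$config_type),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
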