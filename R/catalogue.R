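#' Deterministic seed derivation
#'
#' Hashes the master seed together with arbitrary labels into a 31-bit
#' integer, so every catalogue cell gets its own reproducible seed that is a
#' pure function of the master seed and the cell identity.
#'
#' @param master Master integer seed.
#' @param ... Labels (config id, condition, stage, ...).
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  s <- paste(master, paste(unlist(list(...)), collapse = "|"), sep = "|")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Experiment configuration for a catalogue run
#'
#' Collects every knob of the scaled-down study: geometry, the configuration
#' catalogue (counts of the four spatial-configuration types), the simulated
#' conditions, integration and feature parameters, inversion settings, and
#' the master seed.  Serializes round-trip to JSON.
#'
#' @param seed Master seed.
#' @param subdivisions,radius,n_regions,n_subcortical,n_electrodes,
#'   contacts_per_electrode,decay_length Geometry parameters.
#' @param n_single,n_half,n_multi,n_ezpz Catalogue counts per type.
#' @param conditions Condition labels.
#' @param dt,n_samples Integration grid (ms).
#' @param n_feature Feature samples.
#' @param n_seeds Inversion seeds per cell.
#' @return A named list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, subdivisions = 4, radius = 70,
                              n_regions = 20, n_subcortical = 4,
                              n_electrodes = 8, contacts_per_electrode = 10,
                              decay_length = 12,
                              n_single = 8, n_half = 0, n_multi = 0,
                              n_ezpz = 0,
                              conditions = c("lc_none", "lc_0", "lc_2",
                                             "lc_4"),
                              dt = 0.1, n_samples = 20000,
                              n_feature = 512, n_seeds = 10) {
  structure(list(seed = seed, subdivisions = subdivisions, radius = radius,
                 n_regions = n_regions, n_subcortical = n_subcortical,
                 n_electrodes = n_electrodes,
                 contacts_per_electrode = contacts_per_electrode,
                 decay_length = decay_length,
                 n_single = n_single, n_half = n_half, n_multi = n_multi,
                 n_ezpz = n_ezpz, conditions = conditions,
                 dt = dt, n_samples = n_samples, n_feature = n_feature,
                 n_seeds = n_seeds),
            class = "experiment_config")
}

# short content hash of an experiment config (provenance tag on artifacts)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", derive_seed(0, s))
}

#' Build the configuration catalogue on a geometry
#'
#' Draws the spatial configurations of the study: single-region EZ,
#' half-size single-region EZ, multi-region EZ, and EZ plus one-to-two
#' mesh-adjacent PZ regions.  Clinically, depth electrodes are implanted to
#' test the epileptogenic-zone hypothesis, so the EZ is always well sampled
#' by the implantation; the desk-scale analogue is to place the EZ in the
#' best-implanted regions, ranked by each region's maximum absolute bipolar
#' mass-model gain.  PZ regions are sampled among the mesh neighbours of the
#' EZ region.  For EZ+PZ configurations the global coupling is adjusted with
#' [adjust_global_coupling()] so the PZ is recruited (and only it);
#' configurations with an empty PZ keep the default coupling of 1.
#'
#' @param geometry A `brain_geometry`.
#' @param cfg An `experiment_config`.
#' @param gains Precomputed [prepare_gains()] output (built here if NULL).
#' @param adjust_gc If FALSE, skip the coupling search (for tests).
#' @return Named list of `spatial_config` objects, keys `cfg001`, ...
#' @export
build_catalogue <- function(geometry, cfg, gains = NULL, adjust_gc = TRUE) {
  n_cort <- geometry$parcellation$n_regions
  set.seed(derive_seed(cfg$seed, "catalogue"))
  adj <- region_adjacency(geometry$mesh, geometry$parcellation)
  configs <- list()
  add <- function(config) configs[[sprintf("cfg%03d", length(configs) + 1)]] <<- config

  if (is.null(gains)) gains <- prepare_gains(geometry)
  sampling_score <- apply(abs(gains$nmm_bip$g[, seq_len(n_cort),
                                              drop = FALSE]), 2, max)
  ez_pool <- order(sampling_score, decreasing = TRUE)
  for (k in seq_len(cfg$n_single)) {
    add(make_configuration(geometry, ez = ez_pool[k],
                           config_type = "ez_single"))
  }
  for (k in seq_len(cfg$n_half)) {
    add(make_configuration(geometry, ez = ez_pool[k], half_size = TRUE,
                           config_type = "ez_half"))
  }
  for (k in seq_len(cfg$n_multi)) {
    pool <- ez_pool[seq_len(min(10, n_cort))]
    ez <- sample(pool, sample(2:4, 1))
    add(make_configuration(geometry, ez = ez, config_type = "ez_multi"))
  }
  # EZ+PZ configurations: both networks belong to the clinical hypothesis
  # and are therefore implanted, so pairs are drawn among mesh-adjacent
  # members of the well-sampled pool (EZ = the better-sampled member);
  # remaining slots fall back to the best-sampled neighbour of a pool EZ
  if (cfg$n_ezpz > 0) {
    pool <- ez_pool[seq_len(min(10, n_cort))]
    cand <- which(adj & upper.tri(adj), arr.ind = TRUE)
    cand <- cand[cand[, 1] %in% pool & cand[, 2] %in% pool, , drop = FALSE]
    score2 <- pmin(sampling_score[cand[, 1]], sampling_score[cand[, 2]])
    cand <- cand[order(score2, decreasing = TRUE), , drop = FALSE]
    used_ez <- integer(0)
    n_done <- 0
    for (i in seq_len(nrow(cand))) {
      if (n_done >= cfg$n_ezpz) break
      pr <- cand[i, ]
      ez <- pr[which.max(sampling_score[pr])]
      pz <- setdiff(pr, ez)
      if (ez %in% used_ez) next
      # occasionally extend to a second adjacent pool PZ
      if (sample(1:2, 1) == 2) {
        extra <- setdiff(intersect(which(adj[ez, ]), pool), c(ez, pz))
        if (length(extra) > 0) {
          pz <- c(pz, extra[which.max(sampling_score[extra])])
        }
      }
      add(make_configuration(geometry, ez = ez, pz = sort(pz),
                             config_type = "ez_pz"))
      used_ez <- c(used_ez, ez)
      n_done <- n_done + 1
    }
    k <- 0
    while (n_done < cfg$n_ezpz && k < n_cort) {
      k <- k + 1
      ez <- ez_pool[k]
      if (ez %in% used_ez) next
      nbrs <- which(adj[ez, ])
      if (length(nbrs) == 0) next
      pz <- nbrs[which.max(sampling_score[nbrs])]
      add(make_configuration(geometry, ez = ez, pz = pz,
                             config_type = "ez_pz"))
      used_ez <- c(used_ez, ez)
      n_done <- n_done + 1
    }
  }
  if (adjust_gc) {
    for (id in names(configs)) {
      if (length(configs[[id]]$pz) > 0) {
        configs[[id]]$gc <- adjust_global_coupling(configs[[id]], geometry,
                                                   n_samples = 20000)
      }
    }
  }
  configs
}

#' Precompute the forward gains of a geometry
#'
#' @param geometry A `brain_geometry`.
#' @return List: `nfm` / `nmm` (monopolar `gain_matrix`), `nfm_bip` /
#'   `nmm_bip` (bipolar), `inv` (rectified normalized inversion gain).
#' @export
prepare_gains <- function(geometry) {
  a_sub <- subcortical_source_area(geometry$mesh, geometry$parcellation)
  nfm <- nfm_gain(geometry$mesh, geometry$sensors,
                  subcortical = geometry$parcellation$subcortical,
                  subcortical_area = a_sub)
  nmm <- nmm_gain(geometry$mesh, geometry$parcellation, geometry$sensors)
  nfm_bip <- bipolar_montage(nfm, geometry$sensors)
  nmm_bip <- bipolar_montage(nmm, geometry$sensors)
  list(nfm = nfm, nmm = nmm, nfm_bip = nfm_bip, nmm_bip = nmm_bip,
       inv = inversion_gain(nmm_bip))
}

#' Run one catalogue cell (configuration x condition)
#'
#' Simulates the configuration under the condition (neural mass for
#' `lc_none`, neural field otherwise, with the condition's local coupling),
#' projects to SEEG through the matching forward model, extracts data
#' features, runs the multi-seed MAP inversion, and scores the recovered
#' network against the ground truth with the precision-maximizing sweep.
#'
#' @param config A `spatial_config`.
#' @param condition One of `"lc_none"`, `"lc_0"`, `"lc_2"`, `"lc_4"`.
#' @param geometry A `brain_geometry`.
#' @param gains From [prepare_gains()].
#' @param cfg An `experiment_config`.
#' @param config_id Cell label used for seed derivation.
#' @param kernel Optional precomputed local kernel.
#' @param p2 Inversion parameters.
#' @return List with the metrics row (`gof`, `precision`, `recall`, `f1`,
#'   `threshold`, `gain_r`, seizing-set validity) and the `inversion_result`.
#' @export
run_cell <- function(config, condition, geometry, gains, cfg,
                     config_id = "cfg", kernel = NULL,
                     p2 = reduced2d_parameters()) {
  config$lc <- condition
  config$lc_value <- if (condition == "lc_none") 0 else
    as.numeric(sub("lc_", "", condition))
  mode <- if (condition == "lc_none") "mass" else "field"
  gain <- if (mode == "mass") gains$nmm else gains$nfm
  sim <- simulate_epileptor(config, geometry, mode = mode, dt = cfg$dt,
                            n_samples = cfg$n_samples, kernel = kernel,
                            gain = gain$g)
  seiz <- seizing_regions(sim)
  expected <- sort(union(config$ez, config$pz))
  rec <- structure(list(signal = sim$seeg, montage = "monopolar",
                        dt = cfg$dt), class = "seeg_recording")
  feats <- extract_features(bipolar_montage(rec, geometry$sensors),
                            n = cfg$n_feature)
  inv <- run_inversion(feats, gains$inv, geometry$connectome,
                       n_seeds = cfg$n_seeds,
                       seed_base = derive_seed(cfg$seed, config_id,
                                               condition),
                       p2 = p2)
  rep <- sweep_threshold(inv$u0_median, expected)
  gain_r <- if (length(config$ez) == 1 && length(config$pz) == 0) {
    gain_correlation(gains$nmm_bip, gains$nfm_bip, config$ez,
                     geometry$parcellation)
  } else NA_real_
  list(metrics = data.frame(config_id = config_id,
                            config_type = config$config_type,
                            condition = condition,
                            gof = inv$sim_gof,
                            precision = rep$precision, recall = rep$recall,
                            f1 = rep$f1, threshold = rep$threshold,
                            gain_r = gain_r,
                            seizing_ok = identical(seiz, expected),
                            gc = config$gc),
       inversion = inv)
}

#' Run the whole experiment catalogue
#'
#' Loops over every (configuration, condition) cell: verifies or adjusts the
#' coupling (at catalogue build), simulates, projects, extracts features,
#' inverts, and evaluates.  Cell artifacts are written under `out_dir` (JSON
#' per cell, tagged with the configuration hash) and completed cells are
#' skipped on rerun; stage failures are recorded per cell and the study
#' continues.
#'
#' @param cfg An `experiment_config`.
#' @param out_dir Optional output directory for per-cell JSON artifacts.
#' @param geometry Optional prebuilt geometry (built from `cfg` otherwise).
#' @param catalogue Optional prebuilt catalogue.
#' @param progress If TRUE, prints one line per cell.
#' @return A `study_summary`: `reports` (data frame of metric rows),
#'   `errors` (per failed cell), `config_hash`, `cfg`.
#' @export
run_catalogue <- function(cfg, out_dir = NULL, geometry = NULL,
                          catalogue = NULL, progress = FALSE) {
  hash <- config_hash(cfg)
  if (is.null(geometry)) {
    geometry <- build_geometry(subdivisions = cfg$subdivisions,
                               radius = cfg$radius,
                               n_regions = cfg$n_regions,
                               n_subcortical = cfg$n_subcortical,
                               n_electrodes = cfg$n_electrodes,
                               contacts_per_electrode =
                                 cfg$contacts_per_electrode,
                               decay_length = cfg$decay_length,
                               seed = derive_seed(cfg$seed, "geometry"))
  }
  gains <- prepare_gains(geometry)
  if (is.null(catalogue)) catalogue <- build_catalogue(geometry, cfg, gains)
  needs_kernel <- any(cfg$conditions %in% c("lc_2", "lc_4"))
  kernel <- if (needs_kernel) {
    build_local_kernel(geometry$mesh, geo = geometry$geo)
  } else NULL
  p2 <- reduced2d_parameters()
  rows <- list()
  errors <- list()
  for (id in names(catalogue)) {
    for (cond in cfg$conditions) {
      cell_file <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("%s_%s_%s.json", hash, id, cond))
      } else NULL
      if (!is.null(cell_file) && file.exists(cell_file)) {
        rows[[paste(id, cond)]] <-
          as.data.frame(jsonlite::read_json(cell_file,
                                            simplifyVector = TRUE))
        next
      }
      res <- tryCatch(
        run_cell(catalogue[[id]], cond, geometry, gains, cfg,
                 config_id = id, kernel = kernel, p2 = p2),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(id, cond)]] <- conditionMessage(res)
        next
      }
      rows[[paste(id, cond)]] <- res$metrics
      if (!is.null(cell_file)) {
        dir.create(dirname(cell_file), recursive = TRUE,
                   showWarnings = FALSE)
        jsonlite::write_json(as.list(res$metrics), cell_file,
                             auto_unbox = TRUE, digits = NA)
      }
      if (progress) {
        message(sprintf("%s %s: gof=%.2f f1=%.2f", id, cond,
                        res$metrics$gof, res$metrics$f1))
      }
    }
  }
  structure(list(reports = do.call(rbind, rows), errors = errors,
                 config_hash = hash, cfg = cfg),
            class = "study_summary")
}

#' Summary tables of a study
#'
#' Median of each evaluation metric per configuration type and condition
#' (the structure of the study's group-results figure) and, when gain
#' correlations are present, the binned gain-similarity summary.
#'
#' @param study A `study_summary` from [run_catalogue()].
#' @param out_dir Optional directory to write `medians.csv`,
#'   `medians.md`, and `gain_similarity.csv`.
#' @return List `medians` (data frame), `gain_similarity` (or NULL).
#' @export
study_report <- function(study, out_dir = NULL) {
  rp <- study$reports
  metrics <- c("gof", "precision", "recall", "f1")
  med <- NULL
  if (!is.null(rp) && nrow(rp) > 0) {
    combos <- unique(rp[, c("config_type", "condition")])
    med <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sub <- rp[rp$config_type == combos$config_type[i] &
                rp$condition == combos$condition[i], ]
      cbind(combos[i, ],
            as.data.frame(as.list(vapply(metrics, function(m)
              median(sub[[m]]), numeric(1)))))
    }))
    rownames(med) <- NULL
  } else {
    med <- data.frame(config_type = character(0), condition = character(0),
                      gof = numeric(0), precision = numeric(0),
                      recall = numeric(0), f1 = numeric(0))
  }
  gs <- NULL
  if (!is.null(rp) && any(!is.na(rp$gain_r))) {
    rec <- rp[!is.na(rp$gain_r), ]
    rec$r <- rec$gain_r
    gs <- correlation_analysis(rec)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(med, file.path(out_dir, "medians.csv"), row.names = FALSE)
    writeLines(markdown_table(med), file.path(out_dir, "medians.md"))
    if (!is.null(gs)) {
      write.csv(gs$bins, file.path(out_dir, "gain_similarity.csv"),
                row.names = FALSE)
    }
  }
  list(medians = med, gain_similarity = gs)
}

# minimal markdown rendering of a data frame
markdown_table <- function(df) {
  if (nrow(df) == 0) {
    return(c(paste("|", paste(names(df), collapse = " | "), "|"),
             paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")))
  }
  fmt <- function(x) if (is.numeric(x)) sprintf("%.3f", x) else as.character(x)
  cells <- vapply(seq_len(nrow(df)), function(i)
    paste("|", paste(vapply(df[i, ], fmt, character(1)), collapse = " | "),
          "|"), character(1))
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    cells)
}
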