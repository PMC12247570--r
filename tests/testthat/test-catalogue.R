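test_that("derived seeds are deterministic 31-bit integers", {
  s1 <- derive_seed(1, "cfg001", "lc_none")
  s2 <- derive_seed(1, "cfg001", "lc_none")
  s3 <- derive_seed(1, "cfg001", "lc_0")
  s4 <- derive_seed(2, "cfg001", "lc_none")
  expect_identical(s1, s2)
  expect_false(s1 == s3)
  expect_false(s1 == s4)
  expect_true(s1 >= 1 && s1 < 2^31)
  expect_type(s1, "integer")
})

test_that("experiment config serializes round trip", {
  cfg <- experiment_config(seed = 5, n_single = 3, n_seeds = 4)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back[names(cfg)], unclass(cfg), tolerance = 0)
})

test_that("catalogue respects counts, pools, and coupling defaults", {
  g <- test_geometry()
  cfg <- experiment_config(seed = 2, subdivisions = 2, n_regions = 8,
                           n_subcortical = 2, n_electrodes = 3,
                           contacts_per_electrode = 6,
                           n_single = 3, n_half = 1, n_ezpz = 1,
                           n_seeds = 2)
  cat <- build_catalogue(g, cfg, adjust_gc = FALSE)
  expect_length(cat, 5)
  types <- vapply(cat, `[[`, character(1), "config_type")
  expect_equal(as.integer(table(types)[c("ez_single", "ez_half", "ez_pz")]),
               c(3L, 1L, 1L))
  singles <- cat[types == "ez_single"]
  expect_true(all(vapply(singles, function(x) x$gc, numeric(1)) == 1))
  ezpz <- cat[[which(types == "ez_pz")]]
  adj <- region_adjacency(g$mesh, g$parcellation)
  expect_true(all(adj[ezpz$ez, ezpz$pz]))
})

test_that("a tiny study runs end to end, deterministically and resumably", {
  cfg <- experiment_config(seed = 3, subdivisions = 2, n_regions = 8,
                           n_subcortical = 2, n_electrodes = 3,
                           contacts_per_electrode = 6,
                           n_single = 2, conditions = "lc_none",
                           n_seeds = 2)
  out1 <- run_catalogue(cfg)
  expect_equal(nrow(out1$reports), 2)
  expect_true(all(c("gof", "precision", "recall", "f1") %in%
                  names(out1$reports)))
  out2 <- run_catalogue(cfg)
  expect_identical(out1$reports, out2$reports)

  # resumable: second run against the same artifact dir re-reads the cells
  dir <- tempfile("cells")
  out3 <- run_catalogue(cfg, out_dir = dir)
  files <- list.files(dir)
  expect_length(files, 2)
  expect_true(all(startsWith(files, out3$config_hash)))
  before <- file.mtime(file.path(dir, files))
  out4 <- run_catalogue(cfg, out_dir = dir)
  expect_identical(file.mtime(file.path(dir, files)), before)
  expect_equal(out4$reports$f1, out3$reports$f1)
})

test_that("study report tabulates medians and handles empty studies", {
  empty <- structure(list(reports = NULL, errors = list(),
                          config_hash = "x", cfg = NULL),
                     class = "study_summary")
  rep0 <- study_report(empty)
  expect_equal(nrow(rep0$medians), 0)

  fake <- structure(list(reports = data.frame(
    config_id = c("a", "b", "a", "b"),
    config_type = "ez_single",
    condition = rep(c("lc_none", "lc_0"), each = 2),
    gof = c(0.8, 0.9, 0.5, 0.6), precision = 1, recall = 1,
    f1 = c(1, 1, 0.5, 1), threshold = -2, gain_r = c(NA, NA, 0.5, 0.9),
    seizing_ok = TRUE, gc = 1), errors = list(), config_hash = "x",
    cfg = NULL), class = "study_summary")
  dir <- tempfile("rep")
  rep1 <- study_report(fake, out_dir = dir)
  expect_equal(rep1$medians$gof[rep1$medians$condition == "lc_none"], 0.85)
  expect_equal(rep1$medians$f1[rep1$medians$condition == "lc_0"], 0.75)
  expect_true(file.exists(file.path(dir, "medians.csv")))
  expect_true(file.exists(file.path(dir, "medians.md")))
  # recomputation from the per-cell rows matches the table
  md <- read.csv(file.path(dir, "medians.csv"))
  expect_equal(md$gof[md$condition == "lc_0"],
               median(fake$reports$gof[fake$reports$condition == "lc_0"]))
})
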