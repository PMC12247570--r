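test_that("dipolar gain follows the printed formula", {
  # one vertex at the origin-ish with a known normal; contact on the ray
  m <- build_icosphere(1, radius = 30)
  s <- place_electrodes(m, 2, 4, seed = 3)
  gm <- nfm_gain(m, s)
  expect_equal(dim(gm$g), c(s$n_contacts, nrow(m$vertices)))
  # hand evaluation: a/(4 pi sigma) * Q.(r-x)/|r-x|^3 for one entry
  k <- 3; i <- 11
  rv <- unlist(s$contacts[k, c("x", "y", "z")])
  dvec <- rv - m$vertices[i, ]
  hand <- m$areas[i] / (4 * pi) * sum(m$normals[i, ] * dvec) /
    sqrt(sum(dvec^2))^3
  expect_equal(gm$g[k, i], hand, tolerance = 1e-12)

  # orthogonal normal gives zero; flipping the normal negates the entry
  m2 <- m
  m2$normals[i, ] <- -m2$normals[i, ]
  gm2 <- nfm_gain(m2, s)
  expect_equal(gm2$g[k, i], -gm$g[k, i])
  perp <- c(-dvec[2], dvec[1], 0)
  m3 <- m
  m3$normals[i, ] <- perp / sqrt(sum(perp^2))
  gm3 <- nfm_gain(m3, s)
  expect_lt(abs(gm3$g[k, i]), 1e-15)
})

test_that("contact on the normal ray at 10 mm gives a/(400 pi sigma)", {
  m <- build_icosphere(2, radius = 50)
  i <- 7
  target <- m$vertices[i, ] + 10 * m$normals[i, ]
  s <- structure(list(contacts = data.frame(electrode = 1, contact = 1,
                                            x = target[1], y = target[2],
                                            z = target[3]),
                      bipolar = data.frame(electrode = integer(0),
                                           from = integer(0),
                                           to = integer(0)),
                      n_contacts = 1, n_bipolar = 0),
                 class = "sensor_array")
  gm <- nfm_gain(m, s)
  expect_equal(gm$g[1, i], m$areas[i] / (4 * pi * 100), tolerance = 1e-12)
})

test_that("mass gain is the orientation-maximizing inverse-square sum", {
  g <- test_geometry()
  gm <- nmm_gain(g$mesh, g$parcellation, g$sensors)
  # single entry by hand
  k <- 2; r <- 5
  rv <- unlist(g$sensors$contacts[k, c("x", "y", "z")])
  vs <- which(g$parcellation$region_label == r)
  hand <- sum(g$mesh$areas[vs] /
              (4 * pi * colSums((t(g$mesh$vertices[vs, ]) - rv)^2)))
  expect_equal(gm$g[k, r], hand, tolerance = 1e-12)
})

test_that("mass gain dominates the summed field gain, with equality when
           normals point at the contact", {
  g <- test_geometry()
  nfm <- nfm_gain(g$mesh, g$sensors,
                  subcortical = g$parcellation$subcortical,
                  subcortical_area = subcortical_source_area(
                    g$mesh, g$parcellation))
  nmm <- nmm_gain(g$mesh, g$parcellation, g$sensors)
  lab <- g$parcellation$region_label
  for (k in seq_len(g$sensors$n_contacts)) {
    for (r in seq_len(g$parcellation$n_regions)) {
      s_nfm <- sum(nfm$g[k, which(lab == r)])
      expect_lte(abs(s_nfm), nmm$g[k, r] + 1e-12)
    }
  }
  # forcing every normal toward contact k collapses the dipole to the
  # inverse-square law
  k <- 4
  rv <- unlist(g$sensors$contacts[k, c("x", "y", "z")])
  m2 <- g$mesh
  dir <- sweep(-m2$vertices, 2, rv, "+")   # r_k - x_i
  m2$normals <- dir / sqrt(rowSums(dir^2))
  nfm2 <- nfm_gain(m2, g$sensors)
  for (r in seq_len(g$parcellation$n_regions)) {
    expect_equal(sum(nfm2$g[k, which(lab == r)]), nmm$g[k, r],
                 tolerance = 1e-12)
  }
})

test_that("projection is the linear gain-weighted sum of observables", {
  g <- test_geometry()
  nmm <- nmm_gain(g$mesh, g$parcellation, g$sensors)
  n_src <- ncol(nmm$g)
  obs <- matrix(rnorm(n_src * 10), n_src, 10)
  rec <- project_to_seeg(obs, nmm)
  expect_equal(rec$signal, nmm$g %*% obs)
  expect_equal(project_to_seeg(0 * obs, nmm)$signal, 0 * rec$signal)
  expect_equal(project_to_seeg(2 * obs, nmm)$signal, 2 * rec$signal)
  one <- matrix(0, n_src, 3); one[4, ] <- 1
  expect_equal(project_to_seeg(one, nmm)$signal,
               matrix(nmm$g[, 4], ncol = 1)[, c(1, 1, 1)])
  expect_error(project_to_seeg(obs[-1, ], nmm), "mismatch")
})

test_that("bipolar montage differences adjacent contacts and cancels
           common signal", {
  g <- test_geometry()
  n_c <- g$sensors$n_contacts
  common <- matrix(rep(rnorm(20), each = n_c), n_c, 20)
  rec <- as_recording(common, montage = "monopolar")
  bip <- bipolar_montage(rec, g$sensors)
  expect_equal(nrow(bip$signal), g$sensors$n_bipolar)
  expect_true(all(abs(bip$signal) < 1e-12))
  expect_error(bipolar_montage(bip, g$sensors), "bipolar")
  # linear-in-index potential gives a constant difference per pair
  idx <- matrix(g$sensors$contacts$contact, n_c, 5)
  bip2 <- bipolar_montage(as_recording(idx, montage = "monopolar"),
                          g$sensors)
  expect_true(all(bip2$signal == 1))
})

test_that("gain correlation matches a direct Pearson computation", {
  g <- test_geometry()
  gains <- prepare_gains(g)
  r <- 3
  val <- gain_correlation(gains$nmm_bip, gains$nfm_bip, r, g$parcellation)
  expect_gte(val, -1)
  expect_lte(val, 1)
  # direct formula evaluation
  vs <- which(g$parcellation$region_label == r)
  a <- abs(rowSums(gains$nfm_bip$g[, vs, drop = FALSE]))
  b <- abs(gains$nmm_bip$g[, r])
  a <- a / max(a); b <- b / max(b)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(val, hand, tolerance = 1e-12)
  # identical vectors give exactly one
  fake <- gains$nmm_bip
  fake$g[, r] <- rowSums(gains$nfm_bip$g[, vs, drop = FALSE])
  expect_equal(gain_correlation(fake, gains$nfm_bip, r, g$parcellation), 1)
})
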