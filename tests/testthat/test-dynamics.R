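test_that("firing rate is the stated Heaviside step (equality fires)", {
  expect_equal(firing_rate(-2, -1), 0)
  expect_equal(firing_rate(-1, -1), 1)
  expect_equal(firing_rate(5, -1), 1)
})

test_that("piecewise nonlinearities match hand evaluation and are continuous", {
  expect_equal(epileptor_f1(-1, 0, 0), -4)           # (-1)^3 - 3(-1)^2
  expect_equal(epileptor_f1(0, 2, 3), 0)             # both branches vanish
  expect_equal(epileptor_f1(1e-12, 2, 3), (2 - 0.6 * (3 - 4)^2) * 1e-12)
  expect_equal(epileptor_f2(-0.25), 0)
  expect_equal(epileptor_f2(0), 1.5)                 # 6 * (0 + 0.25)
  expect_equal(epileptor_f2(-0.3), 0)
})

test_that("auxiliary state reproduces the exponential-kernel integral", {
  # oracle: direct quadrature of g(t) = int_0^t exp(-(t-s)/tau12) a12 u1(s) ds
  # on a prescribed u1(t), vs the ODE form dg/dt = -g/tau12 + a12 u1
  par <- epileptor_parameters()
  h <- 0.01
  tt <- seq(0, 50, by = h)
  u1 <- -2 + 0.5 * sin(0.3 * tt)
  f <- par$a12 * u1
  # trapezoid quadrature of the convolution at the final time
  tend <- tt[length(tt)]
  w <- exp(-(tend - tt) / par$tau12) * f
  g_quad <- (sum(w) - (w[1] + w[length(w)]) / 2) * h
  # RK4 on the scalar ODE with the same prescribed input
  g <- 0
  u1f <- approxfun(tt, u1)
  for (k in seq_len(length(tt) - 1)) {
    t0 <- tt[k]
    rhs <- function(t, g) -g / par$tau12 + par$a12 * u1f(t)
    k1 <- rhs(t0, g)
    k2 <- rhs(t0 + h / 2, g + h / 2 * k1)
    k3 <- rhs(t0 + h / 2, g + h / 2 * k2)
    k4 <- rhs(t0 + h, g + h * k3)
    g <- g + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(g, g_quad, tolerance = 1e-6)
})

test_that("interictal equilibrium is a fixed point and stays interictal", {
  st <- interictal_state(-3.6)
  expect_lt(max(abs(epileptor_deriv_node(st, -3.6))), 1e-6)
  # an isolated node at -3.6 started there does not seize over 2000 ms
  W <- matrix(0, 1, 1)
  g <- toy_mass_geometry(W)
  cfg <- toy_mass_config(-3.6, ez = integer(0), gc = 0)
  sim <- simulate_epileptor(cfg, g, mode = "mass")
  expect_true(is.na(sim$onset[1]))
})

test_that("isolated-node taxonomy holds on a 3-node toy", {
  # u0 = -1.6 seizes alone; -2.1 only under coupling; -3.6 never
  W <- matrix(c(0, 1, 0.2,
                1, 0, 0.2,
                0.2, 0.2, 0), 3, 3)
  g <- toy_mass_geometry(W)
  cfg <- toy_mass_config(c(-1.6, -2.1, -3.6), ez = 1, pz = 2, gc = 2)
  rep <- verify_configuration(cfg, g)
  expect_true(rep$pass)
  expect_equal(rep$uncoupled_seizing, 1)
  expect_equal(rep$coupled_seizing, c(1, 2))

  # a NIZ node seizing (here: labelled NIZ but excitably epileptogenic)
  bad <- toy_mass_config(c(-1.6, -2.1, -1.6), ez = 1, pz = 2, gc = 2)
  rep2 <- verify_configuration(bad, g)
  expect_false(rep2$pass)
  expect_true(3 %in% rep2$offending)

  # a PZ region seizing uncoupled (labelled PZ but autonomous)
  bad2 <- toy_mass_config(c(-1.6, -1.6, -3.6), ez = 1, pz = 2, gc = 2)
  rep3 <- verify_configuration(bad2, g)
  expect_false(rep3$pass)
})

test_that("critical excitability matches the knee oracle and the published value", {
  crit <- critical_excitability()
  # closed-form knee: u0 = -4/3 - (1 + 64/27 - 32/9 + 3.1)/4
  knee <- -4 / 3 - (1 + 64 / 27 - 32 / 9 + 3.1) / 4
  expect_equal(crit, knee, tolerance = 1e-3)
  expect_lt(abs(crit - (-2.062)), 1e-3)
  expect_lt(abs(crit - (-2.05)), 0.02)  # reported threshold of the model
})

test_that("simulated isolated 2D node seizes above and rests below critical", {
  crit <- critical_excitability()
  tr_hi <- simulate_2d_node(crit + 0.05, t_end = 20000)
  tr_lo <- simulate_2d_node(crit - 0.05, t_end = 20000)
  expect_true(any(tr_hi[, "u1"] > 0))
  expect_false(any(tr_lo[, "u1"] > 0))
  # brute-force bisection agrees with the closed form
  expect_lt(abs(critical_excitability_bisection(tol = 0.005) - crit), 0.01)
})

test_that("integration is deterministic and blow-ups abort", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g <- toy_mass_geometry(W)
  cfg <- toy_mass_config(c(-1.6, -3.6), ez = 1)
  s1 <- simulate_epileptor(cfg, g, mode = "mass", record_nodes = 1:2)
  s2 <- simulate_epileptor(cfg, g, mode = "mass", record_nodes = 1:2)
  expect_identical(s1$obs, s2$obs)
  expect_equal(s1$time[length(s1$time)], 2000)  # 20000 samples at 0.1 ms
})

test_that("RK4 step error scales at fourth order on a smooth segment", {
  # short pre-onset segment of a quiescent perturbed node (no branch or
  # threshold crossings): halving dt must cut the error by about 2^4
  W <- matrix(0, 1, 1)
  g <- toy_mass_geometry(W)
  cfg <- toy_mass_config(-3.0, ez = integer(0), gc = 0)
  run <- function(dt) {
    s <- simulate_epileptor(cfg, g, mode = "mass", dt = dt,
                            n_samples = round(50 / dt), record_nodes = 1)
    s$obs[1, ncol(s$obs)]
  }
  # note: dt must stay inside the RK4 stability region of the stiff fast
  # subsystem (|lambda| ~ 30 near deep rest), hence the small steps
  ref <- run(0.003125)
  e1 <- abs(run(0.05) - ref)
  e2 <- abs(run(0.025) - ref)
  expect_gt(e1 / e2, 8)   # ~16 expected, allow slack
})

test_that("field and mass dynamics agree exactly when local coupling is off", {
  g <- test_geometry()
  cfg <- make_configuration(g, ez = 3, lc = 0)
  simf <- simulate_epileptor(cfg, g, mode = "field",
                             record_nodes = seq_len(g$n_nodes))
  simm <- simulate_epileptor(cfg, g, mode = "mass",
                             record_nodes = seq_len(g$n_regions_total))
  md <- 0
  for (i in seq_len(g$n_vertices)) {
    r <- g$node_region[i]
    md <- max(md, max(abs(simf$obs[i, ] - simm$obs[r, ])))
  }
  expect_lt(md, 1e-9)
})

test_that("local kernel respects cutoff, normalization, and symmetry", {
  m <- test_mesh_ico3()
  geo <- mesh_geodesics(m)
  K <- build_local_kernel(m, cutoff = 15, geo = geo)
  tw <- methods::as(K, "TsparseMatrix")
  expect_true(all(geo[cbind(tw@i + 1, tw@j + 1)] <= 15))
  pos_sums <- Matrix::rowSums(pmax(K, 0))
  expect_true(all(abs(pos_sums - 1) < 1e-9))
  expect_true(all(Matrix::diag(K) > 0))  # self-weight included
  # near-symmetry on a uniform sphere mesh
  D <- as.matrix(K)
  asym <- max(abs(D - t(D))) / max(abs(D))
  expect_lt(asym, 0.05)
  expect_error(build_local_kernel(m, cutoff = 1, geo = geo), "mean edge")
})

test_that("onset latencies order EZ before PZ and speed up with local coupling", {
  g <- test_geometry()
  K <- build_local_kernel(g$mesh, cutoff = 25, geo = g$geo)
  adj <- region_adjacency(g$mesh, g$parcellation)
  ez <- 3
  pz <- which(adj[ez, ])[1]
  cfg <- make_configuration(g, ez = ez, pz = pz, gc = 6)
  cfg2 <- cfg; cfg2$lc_value <- 2; cfg2$lc <- "lc_2"
  cfg4 <- cfg; cfg4$lc_value <- 4; cfg4$lc <- "lc_4"
  s2 <- simulate_epileptor(cfg2, g, mode = "field", kernel = K)
  s4 <- simulate_epileptor(cfg4, g, mode = "field", kernel = K)
  lab <- g$node_region[seq_len(g$n_vertices)]
  # EZ leads PZ
  expect_lt(min(s2$onset[lab == ez], na.rm = TRUE),
            min(s2$onset[lab == pz], na.rm = TRUE))
  # stronger local coupling does not slow PZ recruitment (individual
  # vertices can reorder through the kernel's inhibitory lobe, so the
  # claim is about the region's first recruitment)
  pz_idx <- which(lab == pz)
  both <- pz_idx[!is.na(s2$onset[pz_idx]) & !is.na(s4$onset[pz_idx])]
  expect_gt(length(both), 0)
  expect_lte(min(s4$onset[both]), min(s2$onset[both]) + 1e-9)
})

test_that("global coupling search recruits the PZ and only the PZ", {
  # the PZ link must be weak enough that unit coupling does not already
  # recruit it, so the search has room to move
  W <- matrix(c(0, 0.004, 0.001,
                0.004, 0, 0.001,
                0.001, 0.001, 0), 3, 3)
  g <- toy_mass_geometry(W)
  cfg <- toy_mass_config(c(-1.6, -2.1, -3.6), ez = 1, pz = 2)
  expect_equal(adjust_global_coupling(toy_mass_config(c(-1.6, -3.6, -3.6),
                                                      ez = 1), g), 1.0)
  gc <- adjust_global_coupling(cfg, g)
  cfg$gc <- gc
  expect_true(verify_configuration(cfg, g)$pass)
  # doubling the connectome weights roughly halves the required coupling
  g2 <- toy_mass_geometry(2 * W)
  gc2 <- adjust_global_coupling(cfg, g2)
  expect_lt(abs(gc2 - gc / 2) / (gc / 2), 0.5)
})
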