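# small fixed generative setup shared by the inversion tests; the gain is
# SEEG-like (each channel dominated by one region)
toy_inversion_setup <- function(R = 6, K = 8, seed = 11) {
  set.seed(seed)
  C <- matrix(runif(R * R, 0, 0.1), R, R)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  C <- C / max(C)
  conn <- structure(list(weights = C), class = "connectome")
  G <- matrix(0.02, K, R)
  for (k in seq_len(K)) G[k, ((k - 1) %% R) + 1] <- 1
  list(conn = conn, G = G, times = seq(100, 2000, length.out = 128))
}

test_that("log posterior matches a hand-summed toy computation", {
  s <- toy_inversion_setup(R = 2, K = 1)
  p2 <- reduced2d_parameters()
  times <- c(500, 1000)
  th <- list(u0 = c(-3.0, -3.4), gc = 0.8, amp = 0.5, off = 0.1, lfl = -2)
  y <- matrix(c(0.2, 0.6), 1, 2)
  yhat <- predict_features(th, s$G, s$conn, times, p2)
  pr <- p2$prior
  hand <- -0.5 * sum(((y - yhat) / p2$sigma_obs)^2) -
    0.5 * sum(((th$u0 - pr$u0[1]) / pr$u0[2])^2) -
    0.5 * ((th$gc - pr$gc[1]) / pr$gc[2])^2 -
    0.5 * ((th$amp - pr$amp[1]) / pr$amp[2])^2 -
    0.5 * ((th$off - pr$off[1]) / pr$off[2])^2 -
    0.5 * ((th$lfl - pr$lfl[1]) / pr$lfl[2])^2
  lp <- log_posterior(th, y, s$G, s$conn, times = times, p2 = p2)
  expect_equal(as.numeric(lp), hand, tolerance = 1e-9)
})

test_that("log posterior decreases as the residual grows", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  th <- list(u0 = rep(-3.6, 6), gc = 1, amp = 0.5, off = 0, lfl = -2)
  base <- predict_features(th, s$G, s$conn, s$times, p2)
  lp0 <- as.numeric(log_posterior(th, base, s$G, s$conn, s$times, p2))
  lp1 <- as.numeric(log_posterior(th, base + 0.05, s$G, s$conn, s$times, p2))
  lp2 <- as.numeric(log_posterior(th, base + 0.2, s$G, s$conn, s$times, p2))
  expect_gt(lp0, lp1)
  expect_gt(lp1, lp2)
})

test_that("adjoint gradient matches finite differences", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  set.seed(3)
  y <- matrix(runif(8 * 128), 8, 128)
  R <- 6
  pack <- function(t) c(t$u0, t$gc, t$amp, t$off, t$lfl)
  unpack <- function(v) list(u0 = v[1:R], gc = v[R + 1], amp = v[R + 2],
                             off = v[R + 3], lfl = v[R + 4])
  # quiescent random points: all regions below threshold, so the posterior
  # is smooth in a finite-difference neighbourhood
  for (rep in 1:3) {
    th <- list(u0 = rnorm(R, -3.6, 0.3), gc = rnorm(1, 1, 0.3),
               amp = abs(rnorm(1, 1, 0.3)), off = rnorm(1, 0, 0.3),
               lfl = rnorm(1, -2, 0.5))
    lp <- log_posterior(th, y, s$G, s$conn, s$times, p2)
    gr <- attr(lp, "gradient")
    v0 <- pack(th)
    fd <- vapply(seq_along(v0), function(i) {
      vp <- v0; vp[i] <- vp[i] + 1e-6
      vm <- v0; vm[i] <- vm[i] - 1e-6
      (as.numeric(log_posterior(unpack(vp), y, s$G, s$conn, s$times, p2)) -
       as.numeric(log_posterior(unpack(vm), y, s$G, s$conn, s$times, p2))) /
        2e-6
    }, numeric(1))
    expect_lt(max(abs(gr - fd) / pmax(abs(fd), 1)), 1e-5)
  }
})

test_that("same seed reproduces the same estimate", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  truth <- list(u0 = c(-1.6, rep(-3.6, 5)), gc = 1, amp = 0.4, off = 0.05,
                lfl = -3)
  y <- predict_features(truth, s$G, s$conn, s$times, p2)
  e1 <- map_estimate(y, s$G, s$conn, seed = 9, times = s$times, p2 = p2)
  e2 <- map_estimate(y, s$G, s$conn, seed = 9, times = s$times, p2 = p2)
  expect_identical(e1$u0, e2$u0)
  expect_identical(e1$gof, e2$gof)
})

test_that("noiseless single-EZ features are recovered by multi-seed MAP", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  truth <- list(u0 = c(-1.6, rep(-3.6, 5)), gc = 1, amp = 0.4, off = 0.05,
                lfl = -3)
  y <- predict_features(truth, s$G, s$conn, s$times, p2)
  inv <- run_inversion(y, s$G, s$conn, n_seeds = 8, seed_base = 40,
                       times = s$times, p2 = p2)
  # the true EZ region tops the posterior-median ranking, and the best
  # seed recovers the generating parameters essentially exactly
  expect_equal(which.max(inv$u0_median), 1)
  best <- inv$estimates[[which.max(inv$gof)]]
  expect_gt(best$gof, 0.95)
  expect_lt(abs(best$u0[1] - (-1.6)), 0.3)
  expect_equal(max(best$u0[-1]), -3.6, tolerance = 0.1)
})

test_that("zero observations pull the estimate to the prior modes", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  y <- matrix(0, 8, 128)
  est <- map_estimate(y, s$G, s$conn, seed = 5, times = s$times, p2 = p2)
  expect_true(all(abs(est$u0 - (-3.6)) < 0.35))
  expect_equal(est$gof, 0)   # zero-variance observations carry no fit
})

test_that("goodness of fit is the pooled explained-variance ratio", {
  y <- matrix(c(0, 1, 0.5, 0.5), 2, 2)
  expect_equal(goodness_of_fit(y, y), 1)
  expect_equal(goodness_of_fit(y, matrix(rowMeans(y), 2, 2)), 0)
  # one-contact hand computation: SS_tot = 0.5, SS_res = 0.25
  yo <- matrix(c(0, 1), 1, 2)
  yp <- matrix(c(0, 0.5), 1, 2)
  expect_equal(goodness_of_fit(yo, yp), 0.5)
  expect_error(goodness_of_fit(matrix(1, 1, 3), matrix(1, 1, 3)),
               "zero observed variance")
  expect_error(goodness_of_fit(yo, matrix(0, 2, 2)), "shape")
})

test_that("seed selection keeps the strict above-third-quartile set", {
  expect_length(vepres:::select_above_q3(seq_len(50) / 50), 12)
  expect_length(vepres:::select_above_q3(seq_len(10) / 10), 2)
  # all-equal values fall back to one representative seed
  expect_length(vepres:::select_above_q3(rep(0.4, 10)), 1)
})

test_that("posterior histograms integrate to one and medians feed selection", {
  s <- toy_inversion_setup()
  p2 <- reduced2d_parameters()
  truth <- list(u0 = c(-1.6, rep(-3.6, 5)), gc = 1, amp = 0.4, off = 0.05,
                lfl = -3)
  y <- predict_features(truth, s$G, s$conn, s$times, p2)
  inv <- run_inversion(y, s$G, s$conn, n_seeds = 6, seed_base = 7,
                       times = s$times, p2 = p2)
  dens <- inv$u0_histogram$density
  for (j in seq_len(ncol(dens))) {
    expect_equal(sum(dens[, j]) * 0.1, 1, tolerance = 1e-9)
  }
  # selected-seed median GOF is at least the all-seed median
  expect_gte(inv$sim_gof, median(inv$gof))
})
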