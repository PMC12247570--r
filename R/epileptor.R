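#' Default parameters of the 5D Epileptor
#'
#' All parameters and state variables are in arbitrary units; time is in ms.
#' `gamma11`, `gamma22`, `gamma12` weight the three local (within-surface)
#' coupling terms; `theta*` are firing-rate thresholds; `tau0` sets the slow
#' permittivity time scale, `tau2` the spike-wave time scale, and `tau12`,
#' `a12` govern the exponential-kernel drive from the fast to the spike-wave
#' population.
#'
#' @return Named list of model constants.
#' @export
epileptor_parameters <- function() {
  list(I1 = 3.1, I2 = 0.8,
       gamma11 = 0.17, gamma22 = 0.32, gamma12 = 0.03,
       theta11 = -1, thetaGC = -1, theta22 = -0.5, theta12 = -1,
       tau0 = 2857 / 2, tau2 = 10, tau12 = 100, a12 = 3)
}

#' Heaviside firing rate
#'
#' `S(u, theta)` is 0 for `u < theta` and 1 otherwise (equality fires).
#'
#' @param u Activity value(s).
#' @param theta Threshold.
#' @return 0/1 vector.
#' @export
firing_rate <- function(u, theta) as.numeric(u >= theta)

#' Piecewise fast-subsystem nonlinearities
#'
#' `epileptor_f1` switches between a cubic (resting branch, `u1 < 0`) and a
#' spike-wave-coupled branch; `epileptor_f2` is the rectified-linear drive of
#' the spike-wave filter.  Both are continuous at their switch points.
#'
#' @param u1,q1,v State values.
#' @return Function value(s).
#' @export
epileptor_f1 <- function(u1, q1, v) {
  ifelse(u1 < 0, u1^3 - 3 * u1^2, (q1 - 0.6 * (v - 4)^2) * u1)
}

#' @rdname epileptor_f1
#' @export
epileptor_f2 <- function(q1) ifelse(q1 < -0.25, 0, 6 * (q1 + 0.25))

#' Time derivative of one uncoupled 5D Epileptor node
#'
#' Reference (R-level) implementation of the single-node vector field with the
#' auxiliary state `g` realizing the exponential-kernel integral
#' (`dg/dt = -g/tau12 + a12 u1`).  Used for equilibrium residuals and as an
#' independent oracle in tests; network simulations use the compiled
#' integrator.
#'
#' @param state Numeric length-6 vector `(u1, u2, v, q1, q2, g)`.
#' @param u0 Node excitability.
#' @param par Parameter list from [epileptor_parameters()].
#' @param I_ext Additional constant input to the fast population.
#' @return Length-6 derivative vector.
#' @export
epileptor_deriv_node <- function(state, u0, par = epileptor_parameters(),
                                 I_ext = 0) {
  u1 <- state[1]; u2 <- state[2]; v <- state[3]
  q1 <- state[4]; q2 <- state[5]; g <- state[6]
  c(u2 - epileptor_f1(u1, q1, v) - v + par$I1 + I_ext,
    1 - 5 * u1^2 - u2,
    (4 * (u1 - u0) - v) / par$tau0,
    -q2 + q1 - q1^3 + par$I2 + 0.002 * g - 0.3 * (v - 3.5),
    (-q2 + epileptor_f2(q1)) / par$tau2,
    -g / par$tau12 + par$a12 * u1)
}

#' Interictal equilibrium of the uncoupled Epileptor
#'
#' Solves the resting fixed point in closed form: with no coupling,
#' `u2* = 1 - 5 u1*^2`, `v* = 4 (u1* - u0)`, `g* = tau12 a12 u1*`, and `u1*`
#' is the leftmost real root of the cubic `1 - u1^3 - 2 u1^2 - 4(u1 - u0) +
#' I1 = 0` (identical to the 2D-reduction equilibrium); `q1*` then solves its
#' own cubic on the resting branch (`q1 < -0.25`, `q2* = f2(q1*)`).
#'
#' @param u0 Excitability (default -3.6, the non-involved level: every node
#'   starts interictally, far from seizure onset).
#' @param par Parameter list.
#' @return Length-6 equilibrium state `(u1, u2, v, q1, q2, g)`.
#' @export
interictal_state <- function(u0 = -3.6, par = epileptor_parameters()) {
  u1 <- equilibrium_2d(u0, par)[["u1"]]
  u2 <- 1 - 5 * u1^2
  v <- 4 * (u1 - u0)
  g <- par$tau12 * par$a12 * u1
  cq <- par$I2 + 0.002 * g - 0.3 * (v - 3.5)
  # resting branch: q2 = 0, q1 - q1^3 + cq = 0
  r <- polyroot(c(cq, 1, 0, -1))
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  r <- r[r < -0.25]
  if (length(r) == 0) stop("no resting-branch equilibrium for q1")
  q1 <- r[1]
  st <- c(u1, u2, v, q1, 0, g)
  res <- epileptor_deriv_node(st, u0, par)
  if (max(abs(res)) > 1e-8) stop("equilibrium residual too large")
  st
}

#' Equilibrium of the 2D Epileptor reduction
#'
#' @param u0 Excitability.
#' @param par Parameter list (only `I1` used).
#' @return Named vector `c(u1 = ..., v = ...)`: leftmost real fixed point.
#' @export
equilibrium_2d <- function(u0, par = epileptor_parameters()) {
  r <- polyroot(c(1 + par$I1 + 4 * u0, -4, -2, -1))
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  u1 <- r[1]
  c(u1 = u1, v = 4 * (u1 - u0))
}

#' Critical excitability of an isolated Epileptor node
#'
#' The uncoupled 2D reduction loses its stable resting state when its fixed
#' point reaches the left knee of the fast nullcline `v = 1 - u1^3 - 2 u1^2 +
#' I1`.  The knee sits at `u1 = -4/3`; the `1/tau0` trace term of the Jacobian
#' shifts the actual loss of stability marginally (trace zero at
#' `-3 u1^2 - 4 u1 = 1/tau0`).  The returned threshold solves
#' `u0 = u1k - (1 - u1k^3 - 2 u1k^2 + I1)/4` at the trace-corrected knee.
#' Nodes with `u0` above this value seize autonomously; below it they have a
#' single stable fixed point.
#'
#' @param par Parameter list.
#' @return Critical excitability (about -2.062).
#' @export
critical_excitability <- function(par = epileptor_parameters()) {
  u1k <- (-4 - sqrt(16 - 12 / par$tau0)) / 6
  u1k - (1 - u1k^3 - 2 * u1k^2 + par$I1) / 4
}

#' Simulate one isolated 2D-reduction node
#'
#' Fixed-step Euler at `h = 0.1` (well inside the stability limit of the fast
#' subsystem), starting from the resting equilibrium for `u0 = -3.6`.
#'
#' @param u0 Node excitability.
#' @param t_end Duration in model time units.
#' @param h Euler step.
#' @param par Parameter list.
#' @return Matrix with columns `t`, `u1`.
#' @export
simulate_2d_node <- function(u0, t_end = 20000, h = 0.1,
                             par = epileptor_parameters()) {
  eq <- equilibrium_2d(-3.6, par)
  n <- ceiling(t_end / h)
  u1 <- predict2d_cpp(u0, 0, matrix(0, 1, 1), par$thetaGC, par$I1, par$tau0,
                      h, seq_len(n), eq[["u1"]], eq[["v"]])
  cbind(t = h * seq_len(n), u1 = as.vector(u1))
}

#' Bisection bracket of the seize/rest transition of an isolated 2D node
#'
#' Brute-force confirmation of [critical_excitability()]: bisects `u0` on the
#' predicate "`u1` crosses 0 within `t_end`" for a simulated isolated node.
#'
#' @param lower,upper Initial bracket.
#' @param tol Bracket width at which to stop.
#' @param t_end Simulation horizon per probe (model time units).
#' @return The bracket midpoint.
#' @export
critical_excitability_bisection <- function(lower = -2.5, upper = -1.7,
                                            tol = 0.005, t_end = 40000) {
  seizes <- function(u0) any(simulate_2d_node(u0, t_end)[, "u1"] > 0)
  if (seizes(lower) || !seizes(upper)) stop("bracket does not straddle")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (seizes(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Build the local coupling kernel on the cortical surface
#'
#' A Laplacian-of-Gaussian ("mexican hat") profile over geodesic distance,
#' `w(d) = (1 - d^2/(2 sigma^2)) exp(-d^2/(2 sigma^2))` with `sigma =
#' cutoff/3`, truncated at the cutoff (default 10 mm), self-weight included.
#' Each row is scaled so its positive lobe sums to 1, which makes the local
#' coupling scale comparable across mesh resolutions.  One kernel serves the
#' three local terms of the model.
#'
#' @param mesh A `triangle_mesh`.
#' @param cutoff Truncation distance (mm); must exceed the mean edge length.
#' @param geo Optional precomputed geodesic matrix.
#' @param sigma Gaussian width (mm); default `cutoff/3`.
#' @return Sparse `dgCMatrix` (n_vertices x n_vertices).
#' @export
build_local_kernel <- function(mesh, cutoff = 10, geo = NULL,
                               sigma = cutoff / 3) {
  if (is.null(geo)) geo <- mesh_geodesics(mesh)
  if (any(is.infinite(geo))) stop("mesh has disconnected components")
  if (cutoff <= mesh_mean_edge_length(mesh)) {
    stop("cutoff must exceed the mean edge length")
  }
  idx <- which(geo <= cutoff, arr.ind = TRUE)
  d <- geo[idx]
  w <- (1 - d^2 / (2 * sigma^2)) * exp(-d^2 / (2 * sigma^2))
  W <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = w,
                            dims = dim(geo))
  pos_sum <- Matrix::rowSums(pmax(W, 0))
  Matrix::Diagonal(x = 1 / pos_sum) %*% W
}

# pad a vertex kernel with zero rows/cols for subcortical nodes
pad_kernel <- function(W, n_nodes) {
  nv <- nrow(W)
  if (nv == n_nodes) return(W)
  tw <- methods::as(W, "TsparseMatrix")
  Matrix::sparseMatrix(i = tw@i + 1L, j = tw@j + 1L, x = tw@x,
                       dims = c(n_nodes, n_nodes))
}

#' Simulate the Epileptor network for one spatial configuration
#'
#' Classic fixed-step fourth-order Runge-Kutta integration of the full 5D
#' Epileptor network (plus the auxiliary exponential-kernel state), either in
#' `"field"` mode (every cortical vertex a node, local coupling through the
#' kernel, subcortical point nodes without local terms) or `"mass"` mode (one
#' node per region, no local coupling).  All nodes start at the interictal
#' equilibrium computed for `u0 = -3.6` with no coupling, so the network
#' begins interictally, far from seizure onset.  The run is deterministic and
#' bitwise reproducible.
#'
#' @param config A `spatial_config`.
#' @param geometry A `brain_geometry`.
#' @param mode `"field"` or `"mass"`.
#' @param dt Integration step (ms).
#' @param n_samples Number of samples (duration = `dt * n_samples` ms).
#' @param kernel Optional precomputed vertex kernel (field mode); built at the
#'   default 10 mm cutoff if missing.
#' @param gain Optional gain matrix (contacts x nodes); if given, the SEEG
#'   projection is accumulated during integration and returned.
#' @param record_nodes Integer node indices whose observable `q1 - u1` and
#'   `u1` traces are stored (can be large; default none).
#' @param record_u1 If FALSE, store only the observable for the recorded
#'   nodes (halves the memory of whole-network recordings).
#' @param onset_threshold `u1` level whose first crossing defines a node's
#'   seizure onset (default 0, the right knee of the fast subsystem).
#' @param par Parameter list.
#' @return An object of class `simulation_result`: `time` (ms), `onset`
#'   latencies per node (ms, NA if the node never crosses), `seeg`
#'   (contacts x samples, if `gain` given), `obs`/`u1` (recorded traces),
#'   `condition` label, `mode`, `dt`, and bookkeeping fields.
#' @export
simulate_epileptor <- function(config, geometry, mode = c("field", "mass"),
                               dt = 0.1, n_samples = 20000, kernel = NULL,
                               gain = NULL, record_nodes = integer(0),
                               record_u1 = TRUE, onset_threshold = 0,
                               par = epileptor_parameters()) {
  mode <- match.arg(mode)
  nreg <- geometry$n_regions_total
  if (mode == "mass") {
    u0 <- config$u0_region
    node_region <- seq_len(nreg)
    local_on <- rep(0, nreg)
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nreg, nreg))
    use_W <- FALSE
    lc <- 0
  } else {
    u0 <- config$u0_field
    node_region <- geometry$node_region
    n_nodes <- geometry$n_nodes
    local_on <- c(rep(1, geometry$n_vertices),
                  rep(0, n_nodes - geometry$n_vertices))
    lc <- config$lc_value
    if (lc > 0) {
      if (is.null(kernel)) {
        kernel <- build_local_kernel(geometry$mesh, geo = geometry$geo)
      }
      W <- pad_kernel(kernel, n_nodes)
      use_W <- TRUE
    } else {
      W <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n_nodes, n_nodes))
      use_W <- FALSE
    }
  }
  n <- length(u0)
  init <- matrix(rep(interictal_state(-3.6, par), each = n), n, 6)
  use_gain <- !is.null(gain)
  if (use_gain && ncol(gain) != n) stop("gain column count != node count")
  res <- epi_simulate_cpp(u0, par, lc, config$gc, W, use_W,
                          geometry$connectome$weights,
                          as.integer(node_region) - 1L, local_on, init,
                          dt, as.integer(n_samples),
                          if (use_gain) gain else matrix(0, 0, 0), use_gain,
                          as.integer(record_nodes) - 1L, record_u1,
                          onset_threshold)
  if (!res$ok) stop("state blow-up during integration (|u1| > 1e3)")
  structure(list(time = dt * seq_len(n_samples), dt = dt,
                 condition = config$lc, mode = mode,
                 onset = as.vector(res$onset),
                 seeg = res$seeg, obs = res$obs, u1 = res$u1,
                 record_nodes = record_nodes,
                 node_region = node_region, n_nodes = n,
                 final_state = res$final_state),
            class = "simulation_result")
}

#' Per-node seizure onset latencies
#'
#' First time `u1` exceeds the onset threshold; nodes that never cross map to
#' `NA`.  Latencies are recorded online during integration at the threshold
#' passed to [simulate_epileptor()]; pass recorded `u1` traces to re-threshold.
#'
#' @param result A `simulation_result`.
#' @param threshold Optional new threshold (requires recorded `u1`).
#' @return Numeric vector of latencies (ms) per node, NA when absent.
#' @export
onset_latencies <- function(result, threshold = NULL) {
  if (is.null(threshold)) return(result$onset)
  if (is.null(result$u1)) stop("re-thresholding needs recorded u1 traces")
  lat <- rep(NA_real_, nrow(result$u1))
  for (i in seq_len(nrow(result$u1))) {
    k <- which(result$u1[i, ] > threshold)
    if (length(k) > 0) lat[i] <- result$time[k[1]]
  }
  lat
}

# region ids that seized in a simulation (any node of the region crossed)
seizing_regions <- function(result) {
  sort(unique(as.integer(result$node_region[!is.na(result$onset)])))
}

#' Verify that a configuration behaves as designed
#'
#' Runs the network uncoupled (local and global coupling zero) and coupled
#' (the configuration's couplings) and checks the designed taxonomy: without
#' coupling only EZ regions seize; with coupling only EZ and PZ regions seize.
#'
#' @param config A `spatial_config`.
#' @param geometry A `brain_geometry`.
#' @param mode Simulation mode for the checks (default `"mass"`; the
#'   region-resolution dynamics are what the couplings were designed against).
#' @param dt,n_samples Integration grid.
#' @return List with `pass`, `uncoupled_seizing`, `coupled_seizing`,
#'   `expected_uncoupled`, `expected_coupled`, and `offending` region ids.
#' @export
verify_configuration <- function(config, geometry, mode = "mass", dt = 0.1,
                                 n_samples = 20000) {
  unc <- config
  unc$gc <- 0
  unc$lc_value <- 0
  r_unc <- simulate_epileptor(unc, geometry, mode = mode, dt = dt,
                              n_samples = n_samples)
  r_cpl <- simulate_epileptor(config, geometry, mode = mode, dt = dt,
                              n_samples = n_samples)
  s_unc <- seizing_regions(r_unc)
  s_cpl <- seizing_regions(r_cpl)
  exp_unc <- sort(as.integer(config$ez))
  exp_cpl <- sort(as.integer(union(config$ez, config$pz)))
  offending <- sort(unique(c(setdiff(s_unc, exp_unc), setdiff(exp_unc, s_unc),
                             setdiff(s_cpl, exp_cpl),
                             setdiff(exp_cpl, s_cpl))))
  list(pass = identical(s_unc, exp_unc) && identical(s_cpl, exp_cpl),
       uncoupled_seizing = s_unc, coupled_seizing = s_cpl,
       expected_uncoupled = exp_unc, expected_coupled = exp_cpl,
       offending = offending)
}

#' Adjust the global coupling so the propagation zone is recruited
#'
#' Grid search over integer couplings in `[1, 16]` followed by bisection
#' refinement; returns the smallest tested value for which every PZ region
#' seizes and no non-involved region seizes (region-resolution dynamics).
#' Configurations with an empty PZ short-circuit to 1.
#'
#' @param config A `spatial_config` (PZ nonempty unless short-circuited).
#' @param geometry A `brain_geometry`.
#' @param gc_range Search interval.
#' @param refine_tol Bisection stopping width.
#' @param dt,n_samples Integration grid.
#' @return The selected global coupling scale.
#' @export
adjust_global_coupling <- function(config, geometry, gc_range = c(1, 16),
                                   refine_tol = 0.25, dt = 0.1,
                                   n_samples = 20000) {
  if (length(config$pz) == 0) return(1.0)
  expected <- sort(as.integer(union(config$ez, config$pz)))
  admissible <- function(gc) {
    cfg <- config
    cfg$gc <- gc
    r <- simulate_epileptor(cfg, geometry, mode = "mass", dt = dt,
                            n_samples = n_samples)
    identical(seizing_regions(r), expected)
  }
  grid <- seq(gc_range[1], gc_range[2], by = 1)
  hit <- NA_real_
  for (g in grid) {
    if (admissible(g)) { hit <- g; break }
  }
  if (is.na(hit)) stop("no admissible global coupling in range")
  lo <- max(gc_range[1], hit - 1)
  hi <- hit
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    if (admissible(mid)) hi <- mid else lo <- mid
  }
  hi
}
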