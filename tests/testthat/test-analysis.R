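test_that("the analytic front profile has the expected values and limits", {
  for (c in c(1, 2, 5)) {
    expect_equal(fisher_analytic_profile(0, c, order = 1), 0.5)
    expect_equal(fisher_analytic_profile(-1e6, c, order = 1), 1)
    expect_equal(fisher_analytic_profile(1e6, c, order = 1), 0)
  }
  # logistic closed form at quarter height
  expect_equal(fisher_analytic_profile(2 * log(3), 2, order = 0), 0.25)
  # the order-1 correction is a genuine O(1/c^2) perturbation
  z <- seq(-10, 10, by = 0.1)
  d <- fisher_analytic_profile(z, 2, 1) - fisher_analytic_profile(z, 2, 0)
  expect_gt(max(abs(d)), 0)
  expect_lt(max(abs(d)), 1 / 4)
})

synthetic_wave_trajectory <- function(speed, nx = 120, h = 0.5,
                                      times = seq(0, 10, by = 0.5)) {
  mesh <- build_rectangular_mesh(nx, 2, h)
  values <- array(NA_real_, c(nrow(mesh$coords), 1, length(times)),
                  dimnames = list(NULL, "U", NULL))
  for (k in seq_along(times))
    values[, 1, k] <- 1 / (1 + exp(mesh$coords[, 1] - speed * times[k] - 5))
  structure(list(times = times, values = values, species = "U",
                 mesh = mesh, cell_records = NULL), class = "rd_trajectory")
}

test_that("wave-speed measurement recovers constructed front speeds", {
  w <- measure_wave_speed(synthetic_wave_trajectory(2))
  expect_equal(w$speed, 2, tolerance = 0.01)
  w <- measure_wave_speed(synthetic_wave_trajectory(0))
  expect_equal(w$speed, 0, tolerance = 1e-10)
  # no crossing anywhere -> measurement error
  flat <- synthetic_wave_trajectory(2)
  flat$values[] <- 0.1
  expect_error(measure_wave_speed(flat), "crossing")
})

test_that("L2 convergence scores follow the capped-RMS convention", {
  x <- seq(0, 1, length.out = 50)
  expect_equal(l2_convergence_score(x, x), 0)
  expect_equal(l2_convergence_score(x, x, failed = TRUE), 1.0)
  for (delta in c(0.1, 0.3, 0.7))
    expect_equal(l2_convergence_score(x + delta, x), min(delta, 0.5))
  expect_error(l2_convergence_score(x, x[-1]), "lengths differ")
})

test_that("Schnakenberg steady states solve the rate equations", {
  expect_equal(schnakenberg_steady_state(pattern_params()),
               c(U = 1.0, V = 0.9))
  ss <- schnakenberg_steady_state(oscillation_params())
  expect_equal(unname(ss), c(0.9091, 1.8150), tolerance = 1e-4)
  for (p in list(pattern_params(), oscillation_params())) {
    sys <- schnakenberg_system(p)
    ss <- schnakenberg_steady_state(p)
    expect_equal(unname(evaluate_rates(sys, unname(ss))), c(0, 0),
                 tolerance = 1e-12)
  }
  # with no V production, V* collapses and U* = k1 / k_minus1
  p0 <- pattern_params(); p0$k2 <- 1e-300
  ss <- schnakenberg_steady_state(p0)
  expect_equal(unname(ss[["V"]]), 0, tolerance = 1e-290)
  expect_equal(ss[["U"]], p0$k1 / p0$k_minus1, tolerance = 1e-12)
})

test_that("the Hopf locus matches direct trace evaluation and a brute-force scan", {
  hp <- hopf_point(2.2, 1.5, 1.0)
  expect_equal(round(hp$k1, 2), 0.61)
  expect_equal(round(hp$U, 2), 0.96)
  expect_true(hp$hopf)

  tr_at <- function(k1, k_minus1 = 2.2, k2 = 1.5, k3 = 1.0) {
    U <- (k1 + k2) / k_minus1
    -k_minus1 + 2 * k2 / U - k3 * U^2
  }
  expect_gt(tr_at(0.5), 0)   # oscillatory side
  expect_lt(tr_at(1.0), 0)   # stable side

  # brute-force scan of the Jacobian eigenvalue real parts over k1
  k1_grid <- seq(0.01, 2, by = 1e-4)
  re_max <- vapply(k1_grid, function(k1) {
    p <- schnakenberg_params(k1, 2.2, 1.5, 1.0)
    max(Re(eigen(rdcell:::.schnakenberg_jacobian(p),
                 only.values = TRUE)$values))
  }, 0)
  crossing <- k1_grid[max(which(re_max > 0))]
  expect_equal(hp$k1, crossing, tolerance = 1e-3)
})

test_that("the Turing band matches the dispersion quadratic and its preconditions", {
  tb <- turing_band(pattern_params())
  expect_true(tb$turing)
  expect_lt(tb$trace, 0)
  expect_gt(tb$det, 0)
  # roots of 40 q^4 - 31 q^2 + 1 = 0
  expect_equal(tb$band, sort((31 + c(-1, 1) * sqrt(801)) / 80),
               tolerance = 1e-12)
  # growth rate vanishes at the endpoints and is positive strictly inside
  for (q2 in tb$band)
    expect_lt(abs(rdcell:::.dispersion_growth(pattern_params(), q2)), 1e-10)
  inside <- seq(tb$band[1] * 1.05, tb$band[2] * 0.95, length.out = 7)
  for (q2 in inside)
    expect_gt(rdcell:::.dispersion_growth(pattern_params(), q2), 0)

  # oscillatory-regime parameters fail the stability precondition
  tb <- turing_band(oscillation_params())
  expect_false(tb$turing)
  expect_length(tb$band, 0)
  # equal diffusivities cannot destabilize a stable state
  p <- schnakenberg_params(1.0, 1.0, 0.9, 1.0, D_U = 1, D_V = 1)
  expect_false(turing_band(p)$turing)
  # a large diffusivity ratio opens a band for the patterning kinetics
  p <- pattern_params(); p$D_V <- 1e6
  expect_true(turing_band(p)$turing)
})

test_that("spatial summaries reduce uniform and two-valued fields correctly", {
  model <- diffusion_only_model(nx = 3, ny = 3, value = 2, t_end = 0.05,
                                dt = 0.05)
  traj <- run_simulation(model)
  s <- spatial_summary(traj)
  expect_equal(s$mean, rep(2, nrow(s)))
  expect_equal(s$min, s$max)
  traj$values[, 1, 1] <- rep(c(0, 1), each = 8)
  s <- spatial_summary(traj)
  expect_equal(s$mean[1], 0.5)
  expect_equal(s$min[1], 0)
  expect_equal(s$max[1], 1)
})
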