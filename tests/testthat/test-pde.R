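test_that("assembled stiffness matches the hand-computed unit-square operator", {
  m <- build_rectangular_mesh(1, 1, 1)
  f <- domain_field(matrix("B", 1, 1), c(B = "Bulk"),
                    data.frame(subdomain = "Bulk", species = "A", D = 1))
  m <- assign_labels(m, f)
  ops <- assemble_operators(m, f, "A")
  K <- as.matrix(ops$stiffness$A)
  # frozen element-by-element integral of D * grad(phi_i) . grad(phi_j)
  # for the two unit right triangles (nodes: ll, lr, ul, ur)
  expected <- matrix(c(1, -0.5, -0.5, 0,
                       -0.5, 1, 0, -0.5,
                       -0.5, 0, 1, -0.5,
                       0, -0.5, -0.5, 1), 4, 4, byrow = TRUE)
  expect_equal(K, expected, ignore_attr = TRUE)
  expect_equal(ops$mass, c(1 / 3, 1 / 6, 1 / 6, 1 / 3), ignore_attr = TRUE)
})

test_that("stiffness rows sum to zero and vanish for D = 0", {
  f0 <- domain_field(matrix("B", 1, 1), c(B = "Bulk"),
                     data.frame(subdomain = "Bulk", species = "A", D = 0))
  m <- assign_labels(build_rectangular_mesh(6, 5, 0.5), f0)
  ops <- assemble_operators(m, f0, "A")
  expect_equal(sum(abs(ops$stiffness$A)), 0)

  f1 <- f0; f1$diffusivity$D <- 2.5
  ops <- assemble_operators(m, f1, "A")
  expect_equal(max(abs(Matrix::rowSums(ops$stiffness$A))), 0,
               tolerance = 1e-12)
  expect_error(assemble_operators(m, f1, c("A", "Missing")),
               "Missing.*Bulk|no diffusivity")
})

test_that("a uniform field under zero-flux diffusion is a fixed point", {
  model <- diffusion_only_model(nx = 8, ny = 8, value = 3.5, dt = 0.05,
                                t_end = 0.5)
  traj <- run_simulation(model)
  expect_equal(traj$values[, 1, length(traj$times)],
               rep(3.5, 81), tolerance = 1e-12)
})

test_that("zero-flux diffusion conserves total lumped mass over 1000 steps", {
  model <- diffusion_only_model(nx = 15, ny = 15, dt = 0.01, t_end = 10,
                                value = 1, perturb = 0.9)
  model$seed <- 3L
  traj <- run_simulation(model)
  m0 <- total_lumped_mass(traj, 1)
  m1 <- total_lumped_mass(traj, length(traj$times))
  expect_lt(abs(m1 - m0) / m0, 1e-10)
})

test_that("the implicit diffusion step obeys the discrete maximum principle", {
  set.seed(5)
  model <- diffusion_only_model(nx = 10, ny = 10, dt = 0.1, t_end = 0.1)
  stepper <- make_stepper(model$mesh, model$field, "A", model$settings)
  for (i in 1:5) {
    U <- matrix(stats::runif(121, 0, 10), ncol = 1)
    U1 <- stepper$diffuse_step(U)
    expect_gte(min(U1), min(U) - 1e-10)
    expect_lte(max(U1), max(U) + 1e-10)
  }
})

test_that("diffusion of a Gaussian converges to the heat kernel at order >= 1.8", {
  # manufactured solution on a large domain: u0 = exp(-r^2 / (4 t0)) evolves
  # to (t0/(t0+t)) exp(-r^2 / (4 (t0+t))) for D = 1
  t0 <- 2; t_run <- 1
  err_for <- function(h) {
    n <- round(40 / h)
    model <- diffusion_only_model(nx = n, ny = n, h = h,
                                  dt = 0.1 * h^2, t_end = t_run)
    mesh <- model$mesh
    r2 <- (mesh$coords[, 1] - 20)^2 + (mesh$coords[, 2] - 20)^2
    U <- matrix(exp(-r2 / (4 * t0)), ncol = 1)
    stepper <- make_stepper(mesh, model$field, "A", model$settings)
    steps <- round(t_run / model$settings$dt)
    for (s in seq_len(steps)) U <- stepper$diffuse_step(U)
    exact <- (t0 / (t0 + t_run)) * exp(-r2 / (4 * (t0 + t_run)))
    sqrt(sum(nodal_volume_share(mesh) * (U[, 1] - exact)^2))
  }
  e1 <- err_for(1); e2 <- err_for(0.5)
  expect_gt(log2(e1 / e2), 1.8)
})

test_that("Dirichlet boundaries pin the boundary values", {
  model <- diffusion_only_model(nx = 8, ny = 8, value = 0, dt = 0.05,
                                t_end = 2, bc = "dirichlet", bc_value = 2)
  traj <- run_simulation(model)
  final <- traj$values[, 1, length(traj$times)]
  expect_equal(final[model$mesh$on_boundary],
               rep(2, sum(model$mesh$on_boundary)), tolerance = 1e-10)
  # interior fills in from the boundary: positive, bounded by the pinned
  # value, and strictly above its zero initial state
  expect_true(all(final > 0) && all(final <= 2 + 1e-10))
  center <- which.min((model$mesh$coords[, 1] - 4)^2 +
                        (model$mesh$coords[, 2] - 4)^2)
  expect_gt(final[center], traj$values[center, 1, 1])
})

test_that("periodic boundaries identify opposite edges", {
  model <- diffusion_only_model(nx = 10, ny = 6, dt = 0.02, t_end = 0.5,
                                value = 1, perturb = 0.5, bc = "periodic")
  model$seed <- 9L
  traj <- run_simulation(model)
  U <- traj$values[, 1, length(traj$times)]
  mesh <- model$mesh
  left <- which(mesh$coords[, 1] == 0)
  right <- which(mesh$coords[, 1] == mesh$extent[["width"]])
  expect_equal(U[left], U[right], tolerance = 1e-12)
  bottom <- which(mesh$coords[, 2] == 0)
  top <- which(mesh$coords[, 2] == mesh$extent[["height"]])
  expect_equal(U[bottom], U[top], tolerance = 1e-12)
})

test_that("a nonzero Neumann influx adds mass at the boundary flux rate", {
  flux <- 0.2
  model <- diffusion_only_model(nx = 10, ny = 10, dt = 0.01, t_end = 1,
                                value = 0, bc = "neumann", bc_value = flux)
  traj <- run_simulation(model)
  m0 <- total_lumped_mass(traj, 1)
  m1 <- total_lumped_mass(traj, length(traj$times))
  perimeter <- 4 * 10
  expect_equal(m1 - m0, flux * perimeter * 1, tolerance = 1e-8)
})

test_that("homogeneous reaction steady states are fixed points of the full scheme", {
  p <- pattern_params()
  ss <- schnakenberg_steady_state(p)
  model <- schnakenberg_model("pattern", width = 10, height = 10, h = 1,
                              dt = 0.05, t_end = 2, sampling_interval = 2,
                              perturb = 0)
  model$field$initial$value <- unname(ss[c("U", "V")])
  traj <- run_simulation(model)
  expect_equal(traj$values[, , length(traj$times)], traj$values[, , 1],
               tolerance = 1e-10)
})

test_that("simulations are bitwise reproducible under a fixed seed", {
  model <- schnakenberg_model("pattern", width = 12, height = 12, h = 1,
                              dt = 0.05, t_end = 1, sampling_interval = 0.5,
                              seed = 4)
  t1 <- run_simulation(model)
  t2 <- run_simulation(model)
  expect_identical(t1$values, t2$values)
  t3 <- run_simulation(model, seed = 5)
  expect_false(identical(t1$values, t3$values))
})

test_that("the Fisher-KPP front moves monotonically rightward", {
  model <- fisher_kpp_model(width = 30, height = 4, h = 1, dt = 0.05,
                            t_end = 8, sampling_interval = 0.5)
  traj <- run_simulation(model)
  w <- measure_wave_speed(traj)
  fronts <- w$front[is.finite(w$front)]
  expect_true(all(diff(fronts) > -1e-9))
  expect_gt(length(fronts), 10)
})

test_that("domain-only runs return no cell records", {
  model <- diffusion_only_model(nx = 4, ny = 4, t_end = 0.05, dt = 0.05)
  traj <- run_simulation(model)
  expect_null(traj$cell_records)
})
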