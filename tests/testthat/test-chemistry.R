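test_that("the grammar parses the canonical reaction forms", {
  rx <- parse_reaction_line("MassActionReaction: 2U + V -> 3U ; k = 1.0")
  expect_equal(rx$reactants, c(U = 2, V = 1))
  expect_equal(rx$products, c(U = 3))
  expect_equal(rx$params[["k"]], 1.0)
  expect_false(rx$reversible)

  rx <- parse_reaction_line(
    "ZerothOrderReversibleReaction: <-> U ; k_f = 0.5, k_r = 2.2")
  sys <- reaction_system("U", list(rx))
  # production/removal pair: dU/dt = k_f - k_r * U
  expect_equal(unname(evaluate_rates(sys, 0)), 0.5)
  expect_equal(unname(evaluate_rates(sys, 1)), 0.5 - 2.2)

  rx <- parse_reaction_line(
    "MichaelisMentenReaction: S -> P ; k_cat = 2, K_M = 0.5, enzyme = E")
  sys <- reaction_system(c("S", "P", "E"), list(rx))
  d <- evaluate_rates(sys, c(S = 1, P = 0, E = 3))
  expect_equal(unname(d[["S"]]), -2 * 3 * 1 / (0.5 + 1))
  expect_equal(d[["P"]], -d[["S"]])
  expect_equal(d[["E"]], 0)
})

test_that("malformed reaction lines are rejected with informative errors", {
  expect_error(parse_reaction_line("MassActionReaction 2U + V -> 3U"),
               "missing ':'")
  expect_error(parse_reaction_line("MassActionReaction: 2U -> 3U"),
               "missing ';'")
  expect_error(parse_reaction_line("MassActionReaction: 2U = 3U ; k = 1"),
               "'->'")
  expect_error(parse_reaction_line("NoSuchLaw: U -> V ; k = 1"),
               "unknown rate law")
  expect_error(parse_reaction_line("MassActionReaction: 2.5U -> V ; k = 1"),
               "non-integer")
  expect_error(parse_reaction_line("MassActionReaction: U -> V ; k = -1"),
               "negative")
  expect_error(parse_reaction_line("MassActionReaction: U -> V ; k_f = 1"),
               "missing parameter")
  expect_error(parse_reaction_line("MassActionReaction: U <-> V ; k = 1", line = 7),
               "line 7")
  expect_null(parse_reaction_line("# just a comment"))
})

test_that("Schnakenberg rates match hand-substituted values", {
  sys <- schnakenberg_system(pattern_params())
  expect_equal(evaluate_rates(sys, c(1, 1)), c(U = 0.1, V = -0.1))
  expect_equal(evaluate_rates(sys, c(1.0, 0.9)), c(U = 0, V = 0),
               tolerance = 1e-15)
  # at zero concentration only the zeroth-order productions survive
  expect_equal(evaluate_rates(sys, c(0, 0)), c(U = 0.1, V = 0.9))
  expect_error(evaluate_rates(sys, c(-0.1, 1)), "negative")
})

test_that("vectorized rate evaluation matches an independent brute-force oracle", {
  set.seed(11)
  for (trial in 1:12) {
    gen <- random_reaction_lines(sample(2:5, 1), sample(1:6, 1))
    rxs <- lapply(gen$lines, parse_reaction_line)
    sys <- reaction_system(gen$species, rxs)
    conc <- stats::setNames(stats::runif(length(gen$species), 0, 2),
                            gen$species)
    expect_equal(unname(evaluate_rates(sys, unname(conc))),
                 unname(brute_force_derivatives(rxs, gen$species, conc)),
                 tolerance = 1e-12)
  }
})

test_that("balanced mass-action stoichiometry conserves total concentration", {
  rx <- parse_reaction_line("MassActionReaction: 2 A + B -> A + 2 B ; k = 0.7")
  sys <- reaction_system(c("A", "B"), list(rx))
  for (conc in list(c(1, 1), c(2, 0.3), c(0.1, 5)))
    expect_equal(sum(evaluate_rates(sys, conc)), 0, tolerance = 1e-14)
})

test_that("the reversible law reduces to the irreversible law at k_r = 0", {
  fwd <- reaction_system(c("A", "B"), list(
    parse_reaction_line("MassActionReaction: 2 A -> B ; k = 0.8")))
  rev <- reaction_system(c("A", "B"), list(
    parse_reaction_line(
      "MassActionReversibleReaction: 2 A <-> B ; k_f = 0.8, k_r = 0")))
  for (conc in list(c(1, 1), c(0.5, 2)))
    expect_equal(evaluate_rates(rev, conc), evaluate_rates(fwd, conc))
})

test_that("serialize/parse round-trips every reaction of the exemplars", {
  for (name in c("fisher_kpp", "schnakenberg_pattern")) {
    dir <- withr::local_tempdir()
    cfg <- write_exemplar(name, dir)
    model <- load_model(cfg)
    for (sys in model$field$reactions) {
      for (rx in sys$reactions) {
        rx2 <- parse_reaction_line(serialize_reaction(rx), context = rx$context)
        expect_equal(rx2, rx)
      }
    }
  }
})

test_that("user-registered rate laws participate in evaluation", {
  register_rate_law("HillReaction", function(reaction, conc) {
    n <- reaction$params[["n"]]; K <- reaction$params[["K"]]
    reaction$params[["vmax"]] * conc[, "A"]^n / (K^n + conc[, "A"]^n)
  })
  rx <- parse_reaction_line("HillReaction: A -> B ; vmax = 2, n = 2, K = 1")
  sys <- reaction_system(c("A", "B"), list(rx))
  d <- evaluate_rates(sys, c(A = 1, B = 0))
  expect_equal(unname(d[["B"]]), 2 * 1 / (1 + 1))
})

test_that("well-mixed integration reproduces closed-form kinetics", {
  prod <- reaction_system("U", list(
    parse_reaction_line("ZerothOrderReaction: -> U ; k = 1")))
  ts <- integrate_well_mixed(prod, 0, t_end = 1, dt = 0.01)
  expect_equal(ts$values[nrow(ts$values), "U"], 1, tolerance = 0.01,
               ignore_attr = TRUE)

  decay <- reaction_system("U", list(
    parse_reaction_line("MassActionReaction: U -> ; k = 1")))
  ts <- integrate_well_mixed(decay, 1, t_end = 2, dt = 0.01)
  expect_equal(unname(ts$values[, "U"]), exp(-ts$times), tolerance = 1e-6)
})

test_that("well-mixed Schnakenberg trajectories agree with an implicit ODE solver", {
  skip_if_not_installed("deSolve")
  p <- oscillation_params()
  sys <- schnakenberg_system(p)
  ts <- integrate_well_mixed(sys, c(0.91, 1.67), t_end = 20, dt = 0.005,
                             sampling_interval = 0.5)
  ref <- deSolve::ode(
    y = c(U = 0.91, V = 1.67), times = ts$times,
    func = function(t, y, parms) {
      list(c(p$k1 - p$k_minus1 * y[1] + p$k3 * y[2] * y[1]^2,
             p$k2 - p$k3 * y[2] * y[1]^2))
    }, parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(ts$values[, "U"]), unname(ref[, "U"]),
               tolerance = 1e-5)
  expect_equal(unname(ts$values[, "V"]), unname(ref[, "V"]),
               tolerance = 1e-5)
})
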