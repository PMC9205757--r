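simple_cell <- function(transport = list(), membrane = list(),
                        conc = c(S_cell = 0), pos = c(1, 1), id = 1L) {
  new_cell(id, "T", pos, conc, transport = transport, membrane = membrane)
}

test_that("cells bind to the nearest node with lowest-index tie-breaking", {
  mesh <- build_rectangular_mesh(3, 3, 1)
  pop <- cell_population(list(
    simple_cell(pos = c(2, 1), id = 1L),      # exactly on a node
    simple_cell(pos = c(0.5, 0.5), id = 2L),  # square center: 4-way tie
    simple_cell(pos = c(1.2, 2.2), id = 3L),
    simple_cell(pos = c(1.2, 2.2), id = 4L))) # shares a node with cell 3
  b <- bind_cells(pop, mesh)
  expect_equal(b[[1]]$node, 1 * 4 + 2 + 1)    # (ix=2, iy=1)
  expect_equal(b[[2]]$node, 1)                # lowest index of the tie
  expect_equal(b[[3]]$node, b[[4]]$node)
  expect_equal(b[[1]]$share, nodal_volume_share(mesh, b[[1]]$node))
  pop$cells[[1]]$pos <- c(5, 1)
  expect_error(bind_cells(pop, mesh), "outside")
})

test_that("transport exchange conserves total amount at any share", {
  rx <- parse_reaction_line("MassActionReaction: S -> S_cell ; k = 1",
                            context = "transport")
  for (share in c(1, 0.37)) {
    bulk <- c(S = 1)
    cell <- simple_cell(transport = list(rx))
    total0 <- bulk[["S"]] * share + cell$conc[["S_cell"]]
    for (i in 1:100) {
      res <- apply_transport(cell, bulk, share, 0.01)
      bulk <- res$bulk
      cell <- res$cell
    }
    expect_gt(cell$conc[["S_cell"]], 0)
    expect_lt(bulk[["S"]], 1)
    total1 <- bulk[["S"]] * share + cell$conc[["S_cell"]]
    expect_equal(total1, total0, tolerance = 1e-12)
  }
})

test_that("transport flux vanishes for zero substrate or zero rate", {
  rx <- parse_reaction_line("MassActionReaction: S -> S_cell ; k = 1",
                            context = "transport")
  res <- apply_transport(simple_cell(transport = list(rx)), c(S = 0), 1, 0.1)
  expect_equal(res$bulk[["S"]], 0)
  expect_equal(res$cell$conc[["S_cell"]], 0)
  rx0 <- parse_reaction_line("MassActionReaction: S -> S_cell ; k = 0",
                             context = "transport")
  res <- apply_transport(simple_cell(transport = list(rx0)), c(S = 2), 1, 0.1)
  expect_equal(res$bulk[["S"]], 2)
  expect_equal(res$cell$conc[["S_cell"]], 0)
})

test_that("reversible transport reverses below equilibrium", {
  # secretion: k_f = 0 uptake, k_r = 1 outflow from the cell
  rx <- parse_reaction_line(
    "MassActionReversibleTransportReaction: E <-> E_cell ; k_f = 0, k_r = 1",
    context = "transport")
  cell <- simple_cell(transport = list(rx), conc = c(E_cell = 1))
  bulk <- c(E = 0)
  res <- apply_transport(cell, bulk, 0.5, 0.01)
  expect_lt(res$cell$conc[["E_cell"]], 1)
  expect_gt(res$bulk[["E"]], 0)
  expect_equal(res$bulk[["E"]] * 0.5 + res$cell$conc[["E_cell"]], 1,
               tolerance = 1e-12)
})

test_that("membrane reactions share one rate and exchange no species", {
  # outer: -> A (bulk gains), inner: B -> (cell loses), shared rate k * B
  rx <- parse_reaction_line(
    "MassActionCoupledMembrane:  -> A | B ->  ; k = 2",
    context = "membrane")
  cell <- simple_cell(membrane = list(rx), conc = c(B = 1))
  res <- apply_membrane(cell, c(A = 0), share = 1, dt = 0.01)
  expect_equal(res$bulk[["A"]], 2 * 1 * 0.01)   # k * B * dt
  expect_equal(res$cell$conc[["B"]], 1 - 0.02)
  expect_false("B" %in% names(res$bulk))
  expect_false("A" %in% names(res$cell$conc))
  # zero rate and empty membrane set are identities
  rx0 <- parse_reaction_line("MassActionCoupledMembrane: -> A | B -> ; k = 0",
                             context = "membrane")
  res <- apply_membrane(simple_cell(membrane = list(rx0), conc = c(B = 1)),
                        c(A = 3), 1, 0.1)
  expect_equal(res$bulk[["A"]], 3)
  expect_equal(res$cell$conc[["B"]], 1)
  res <- apply_membrane(simple_cell(conc = c(B = 1)), c(A = 3), 1, 0.1)
  expect_equal(res$bulk[["A"]], 3)
})

test_that("coupled simulation conserves bulk + cell totals over 1000 steps", {
  # one diffusing species exchanged with one stationary inert cell
  field <- domain_field(
    matrix("B", 1, 1), c(B = "Bulk"),
    diffusivity = data.frame(subdomain = "Bulk", species = "S", D = 0.5),
    boundary = data.frame(species = "S", kind = "neumann", value = 0),
    initial = data.frame(subdomain = "Bulk", species = "S", value = 1,
                         perturb = 0))
  rx <- parse_reaction_line(
    "MassActionReversibleTransportReaction: S <-> S_cell ; k_f = 1, k_r = 0.5",
    context = "transport")
  cell <- new_cell(1L, "T", c(5.3, 4.7), c(S_cell = 0),
                   transport = list(rx))
  pop <- cell_population(list(cell))
  model <- rd_model(build_rectangular_mesh(10, 10, 1), field, "S",
                    solver_settings(0.01, 10, 10), population = pop)
  traj <- run_simulation(model)
  shares <- nodal_volume_share(model$mesh)
  total <- function(k) {
    cr <- traj$cell_records
    sum(shares * traj$values[, 1, k]) +
      sum(cr$S_cell[cr$time == traj$times[k]])
  }
  expect_equal(total(length(traj$times)), total(1), tolerance = 1e-10)
  # equilibrium pull: cell content approaches k_f/k_r * bulk at its node
  cr <- traj$cell_records
  expect_gt(cr$S_cell[nrow(cr)], 0.5)
})

test_that("coupling only changes the bound node's bulk values", {
  field <- domain_field(
    matrix("B", 1, 1), c(B = "Bulk"),
    diffusivity = data.frame(subdomain = "Bulk", species = "S", D = 0),
    boundary = data.frame(species = "S", kind = "neumann", value = 0),
    initial = data.frame(subdomain = "Bulk", species = "S", value = 1,
                         perturb = 0))
  rx <- parse_reaction_line("MassActionTransportReaction: S -> S_cell ; k = 1",
                            context = "transport")
  pop <- cell_population(list(new_cell(1L, "T", c(2, 2), c(S_cell = 0),
                                       transport = list(rx))))
  model <- rd_model(build_rectangular_mesh(4, 4, 1), field, "S",
                    solver_settings(0.1, 0.1, 0.1), population = pop)
  traj <- run_simulation(model)
  U <- traj$values[, 1, 2]
  bound <- 2 * 5 + 2 + 1
  expect_lt(U[bound], 1)
  expect_equal(U[-bound], rep(1, 24))
})

test_that("zero coupling decouples cells from the bulk exactly", {
  p <- pattern_params()
  field <- domain_field(
    matrix("B", 1, 1), c(B = "Bulk"),
    diffusivity = data.frame(subdomain = "Bulk", species = c("U", "V"),
                             D = c(1, 40)),
    reactions = list(Bulk = schnakenberg_system(p)),
    boundary = data.frame(species = c("U", "V"), kind = "neumann", value = 0),
    initial = data.frame(subdomain = "Bulk", species = c("U", "V"),
                         value = c(1, 1), perturb = 1))
  srn <- reaction_system("X", list(
    parse_reaction_line("MassActionReaction: X -> ; k = 1", context = "cell")))
  rx0 <- parse_reaction_line("MassActionTransportReaction: U -> X ; k = 0",
                             context = "transport")
  mk <- function(pop) {
    m <- rd_model(build_rectangular_mesh(8, 8, 1), field, c("U", "V"),
                  solver_settings(0.05, 2, 1), population = pop, seed = 2)
    run_simulation(m)
  }
  cell <- new_cell(1L, "T", c(4, 4), c(X = 1), srn = srn,
                   transport = list(rx0))
  with_cells <- mk(cell_population(list(cell)))
  domain_only <- mk(NULL)
  expect_equal(with_cells$values, domain_only$values, tolerance = 1e-14)
  # and the cell followed its own independent exponential decay
  cr <- with_cells$cell_records
  expect_equal(cr$X[cr$time == 2], exp(-2), tolerance = 1e-6)
})
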