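# Shared fixture builders and independent oracles.

# independent brute-force rate evaluator: explicit loops, no shared code
# with the package's vectorized path
brute_force_derivatives <- function(reactions, species, conc) {
  deriv <- stats::setNames(numeric(length(species)), species)
  for (rx in reactions) {
    side_product <- function(side) {
      p <- 1
      for (nm in names(side)) p <- p * conc[[nm]]^side[[nm]]
      p
    }
    rate <- if (rx$law == "zeroth_order") {
      if ("k" %in% names(rx$params)) rx$params[["k"]]
      else rx$params[["k_f"]] - rx$params[["k_r"]]
    } else if (rx$law == "mass_action_irreversible") {
      r <- rx$params[["k"]] * side_product(rx$reactants)
      for (sp in rx$spectators) r <- r * conc[[sp]]
      r
    } else if (rx$law == "mass_action_reversible") {
      r <- rx$params[["k_f"]] * side_product(rx$reactants) -
        rx$params[["k_r"]] * side_product(rx$products)
      for (sp in rx$spectators) r <- r * conc[[sp]]
      r
    } else if (rx$law == "michaelis_menten") {
      s0 <- conc[[names(rx$reactants)[1]]]
      rx$params[["k_cat"]] * conc[[rx$enzyme]] * s0 /
        (rx$params[["K_M"]] + s0)
    } else stop("unknown law in oracle")
    for (nm in names(rx$reactants))
      deriv[[nm]] <- deriv[[nm]] - rx$reactants[[nm]] * rate
    for (nm in names(rx$products))
      deriv[[nm]] <- deriv[[nm]] + rx$products[[nm]] * rate
  }
  deriv
}

# random mass-action system written through the grammar (exercises the
# parser on every generated case)
random_reaction_lines <- function(n_species, n_reactions) {
  species <- LETTERS[seq_len(n_species)]
  lines <- character(n_reactions)
  for (j in seq_len(n_reactions)) {
    law <- sample(c("MassActionReaction", "MassActionReversibleReaction",
                    "ZerothOrderReaction"), 1L)
    mk_side <- function(min_terms = 0L) {
      k <- sample(min_terms:2L, 1L)
      if (k == 0L) return("")
      picks <- sample(species, k)
      coefs <- sample(1:2, k, replace = TRUE)
      paste(paste(coefs, picks), collapse = " + ")
    }
    if (law == "ZerothOrderReaction") {
      lines[j] <- sprintf("ZerothOrderReaction: -> %s ; k = %.6f",
                          sample(species, 1L), stats::runif(1, 0.1, 2))
    } else if (law == "MassActionReaction") {
      lines[j] <- sprintf("MassActionReaction: %s -> %s ; k = %.6f",
                          mk_side(1L), mk_side(0L), stats::runif(1, 0.1, 2))
    } else {
      lines[j] <- sprintf(
        "MassActionReversibleReaction: %s <-> %s ; k_f = %.6f, k_r = %.6f",
        mk_side(1L), mk_side(1L), stats::runif(1, 0.1, 2),
        stats::runif(1, 0.1, 2))
    }
  }
  list(species = species, lines = lines)
}

# minimal one-species pure-diffusion model used in conservation and
# maximum-principle tests
diffusion_only_model <- function(nx = 20, ny = 20, h = 1, D = 1,
                                 dt = 0.01, t_end = 1,
                                 value = 1, perturb = 0, bc = "neumann",
                                 bc_value = 0) {
  field <- domain_field(
    matrix("B", 1, 1), c(B = "Bulk"),
    diffusivity = data.frame(subdomain = "Bulk", species = "A", D = D),
    boundary = data.frame(species = "A", kind = bc, value = bc_value),
    initial = data.frame(subdomain = "Bulk", species = "A",
                         value = value, perturb = perturb))
  rd_model(build_rectangular_mesh(nx, ny, h), field, "A",
           solver_settings(dt, t_end, t_end))
}

total_lumped_mass <- function(traj, sample, species = 1) {
  sum(nodal_volume_share(traj$mesh) * traj$values[, species, sample])
}

oscillation_params <- function() schnakenberg_params(0.5, 2.2, 1.5, 1.0,
                                                     D_U = 0.5, D_V = 0.5)
pattern_params <- function() schnakenberg_params(0.1, 1.0, 0.9, 1.0,
                                                 D_U = 1, D_V = 40)
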