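# In-memory model construction.  The file interface (load_model /
# write_exemplar) and the programmatic exemplar constructors below both
# produce the same rd_model structure consumed by run_simulation().

#' Assemble and validate a model specification
#'
#' @param mesh An `rd_mesh` (labels are attached here if absent).
#' @param field An `rd_domain_field`.
#' @param species Character vector of bulk species (the PDE count).
#' @param settings [solver_settings()].
#' @param population Optional `rd_population` of cell agents.
#' @param seed Integer RNG seed (initial perturbations, daughter placement).
#' @param name Model name used in output.
#' @return A validated `rd_model`.
#' @export
rd_model <- function(mesh, field, species, settings, population = NULL,
                     seed = 0L, name = "model") {
  if (anyNA(mesh$labels)) mesh <- assign_labels(mesh, field)
  problems <- character(0)
  subs <- unique(unname(field$key[mesh$labels]))
  for (sp in species) for (sub in subs) {
    ok <- tryCatch({field_diffusivity(field, sp, sub); TRUE},
                   error = function(e) FALSE)
    if (!ok) problems <- c(problems, sprintf(
      "no diffusivity for species '%s' in subdomain '%s'", sp, sub))
  }
  for (sub in names(field$reactions)) {
    sys <- field$reactions[[sub]]
    extra <- setdiff(sys$species, species)
    if (length(extra)) problems <- c(problems, sprintf(
      "subdomain '%s' reactions use unknown bulk species: %s",
      sub, paste(extra, collapse = ", ")))
  }
  if (!is.null(field$boundary)) {
    extra <- setdiff(field$boundary$species, species)
    if (length(extra)) problems <- c(problems, sprintf(
      "boundary conditions name unknown species: %s",
      paste(extra, collapse = ", ")))
  }
  if (!is.null(population)) {
    w <- mesh$extent[["width"]]; hgt <- mesh$extent[["height"]]
    for (cl in population$cells) {
      if (cl$pos[1] < 0 || cl$pos[1] > w || cl$pos[2] < 0 || cl$pos[2] > hgt)
        problems <- c(problems, sprintf(
          "cell %d placed outside the domain at (%g, %g)",
          cl$id, cl$pos[1], cl$pos[2]))
    }
  }
  if (length(problems))
    stop(paste(c("invalid model specification:", problems),
               collapse = "\n  - "), call. = FALSE)
  structure(list(mesh = mesh, field = field, species = species,
                 settings = settings, population = population,
                 seed = as.integer(seed), name = name),
            class = "rd_model")
}

#' @exportS3Method base::print
print.rd_model <- function(x, ...) {
  cat(sprintf("rd_model '%s': %d bulk species (%s), dt = %g, t_end = %g\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              x$settings$dt, x$settings$t_end))
  print(x$mesh)
  if (!is.null(x$population))
    cat(sprintf("  %d cells (%s)\n", length(x$population$cells),
                paste(unique(vapply(x$population$cells, `[[`, "", "type")),
                      collapse = ", ")))
  invisible(x)
}

#' Fisher-KPP invasion model
#'
#' One species `U` with logistic growth `r U (1 - U / kappa)` (encoded as
#' the mass-action pair `U -> 2U` at rate `r` and `2U -> U` at rate
#' `r / kappa`), diffusivity `D`, zero-flux boundaries, and a unit strip of
#' invader on `0 < x < 1` spanning the full height.  Defaults use the unit
#' parameter set `D = r = kappa = 1`, for which the minimum front speed is
#' `2 * sqrt(r * D) = 2`.
#'
#' @param width,height Domain extent; the wave travels along x.
#' @param h Mesh spacing.
#' @param dt,t_end,sampling_interval Solver settings.
#' @param D,r,kappa Model parameters.
#' @param U0 Initial concentration inside the strip.
#' @param seed RNG seed (unused here: no perturbation).
#' @return An `rd_model`.
#' @export
fisher_kpp_model <- function(width = 100, height = 10, h = 1,
                             dt = 0.01, t_end = 40,
                             sampling_interval = 0.5,
                             D = 1, r = 1, kappa = 1, U0 = 1, seed = 0L) {
  ncols <- max(2L, as.integer(round(width)))
  grid <- matrix("B", 1L, ncols)
  grid[1L, 1L] <- "S"   # strip cell of unit width at the left edge
  key <- c(S = "Strip", B = "Bulk")
  logistic <- reaction_system("U", list(
    parse_reaction_line(sprintf("MassActionReaction: U -> 2 U ; k = %.17g", r)),
    parse_reaction_line(sprintf("MassActionReaction: 2 U -> U ; k = %.17g",
                                r / kappa))))
  field <- domain_field(
    grid, key,
    diffusivity = data.frame(subdomain = c("Strip", "Bulk"),
                             species = "U", D = D),
    reactions = list(Strip = logistic, Bulk = logistic),
    boundary = data.frame(species = "U", kind = "neumann", value = 0),
    initial = data.frame(subdomain = c("Strip", "Bulk"), species = "U",
                         value = c(U0, 0), perturb = 0))
  mesh <- build_rectangular_mesh(round(width / h), round(height / h), h)
  rd_model(mesh, field, "U",
           solver_settings(dt, t_end, sampling_interval),
           seed = seed, name = "fisher_kpp")
}

#' Schnakenberg reaction-diffusion model
#'
#' Two diffusing species with the three-reaction Schnakenberg network on a
#' square domain, zero-flux boundaries, and uniformly perturbed initial
#' conditions (`Uniform(-1, 1)` per node, floored at zero).  The two
#' bundled parameter sets are the oscillatory regime
#' (`k1 = 0.5, k_minus1 = 2.2, k2 = 1.5, k3 = 1, D_U = D_V = 0.5`,
#' initial `(0.91, 1.67)`) and the Turing patterning regime
#' (`k1 = 0.1, k_minus1 = 1, k2 = 0.9, k3 = 1, D_U = 1, D_V = 40`,
#' initial `(1, 1)`).
#'
#' @param case `"oscillation"` or `"pattern"`.
#' @param width,height,h Domain extent and mesh spacing.
#' @param dt,t_end,sampling_interval Solver settings.
#' @param seed RNG seed for the initial perturbation.
#' @param perturb Perturbation half-width (1 in both regimes).
#' @return An `rd_model`.
#' @export
schnakenberg_model <- function(case = c("pattern", "oscillation"),
                               width = 100, height = 100, h = 1,
                               dt = 0.05, t_end = 200,
                               sampling_interval = 1,
                               seed = 0L, perturb = 1) {
  case <- match.arg(case)
  p <- if (case == "oscillation")
    schnakenberg_params(0.5, 2.2, 1.5, 1.0, D_U = 0.5, D_V = 0.5)
  else
    schnakenberg_params(0.1, 1.0, 0.9, 1.0, D_U = 1, D_V = 40)
  init <- if (case == "oscillation") c(U = 0.91, V = 1.67) else c(U = 1, V = 1)
  grid <- matrix("B", 1L, 1L)
  key <- c(B = "Bulk")
  field <- domain_field(
    grid, key,
    diffusivity = data.frame(subdomain = "Bulk", species = c("U", "V"),
                             D = c(p$D_U, p$D_V)),
    reactions = list(Bulk = schnakenberg_system(p)),
    boundary = data.frame(species = c("U", "V"), kind = "neumann", value = 0),
    initial = data.frame(subdomain = "Bulk", species = c("U", "V"),
                         value = unname(init), perturb = perturb))
  mesh <- build_rectangular_mesh(round(width / h), round(height / h), h)
  m <- rd_model(mesh, field, c("U", "V"),
                solver_settings(dt, t_end, sampling_interval),
                seed = seed, name = paste0("schnakenberg_", case))
  m$params <- p
  m
}

# shared cell-type definition tables of the cooperator-cheater exemplar
.cc_cell_type <- function(type) {
  srn <- c(
    "MassActionReaction: ES -> E + S ; k = 1",
    "MassActionReaction: S + NAD + ADP -> Precursor + NADH + ATP ; k = 1",
    "MassActionReversibleReaction: NADH + ADP + O2 <-> NAD + H2O + ATP ; k_f = 1, k_r = 1",
    "MassActionReaction: Precursor + ATP -> Biomass + ADP ; k = 1")
  if (type == "Cooperator")
    srn <- c(srn, "MassActionReaction: Precursor + ATP -> E + ADP ; k = 1")
  transport <- c(
    "MassActionTransportReaction: ES -> ES ; k = 1",
    "MassActionReversibleTransportReaction: O2 <-> O2 ; k_f = 1, k_r = 1",
    "MassActionReversibleTransportReaction: E <-> E ; k_f = 0.1, k_r = 1")
  conc <- data.frame(
    species = c("ES", "E", "S", "NAD", "NADH", "ADP", "ATP", "O2", "H2O",
                "Precursor", "Biomass"),
    value = c(0, if (type == "Cooperator") 1 else 0, 0, 1, 0, 1, 0.5, 0.5,
              0, 0, 0.5),
    perturb = 0)
  thresholds <- data.frame(species = "Biomass", max = 1, min = 0)
  list(srn = srn, transport = transport, membrane = character(0),
       conc = conc, thresholds = thresholds)
}

.build_cc_cell <- function(id, type, pos, rho) {
  def <- .cc_cell_type(type)
  species <- def$conc$species
  srn_rx <- lapply(def$srn, parse_reaction_line, context = "cell")
  new_cell(id, type, pos,
           conc = stats::setNames(def$conc$value, species),
           srn = reaction_system(species, srn_rx),
           transport = lapply(def$transport, parse_reaction_line,
                              context = "transport"),
           membrane = lapply(def$membrane, parse_reaction_line,
                             context = "membrane"),
           thresholds = def$thresholds, rho = rho)
}

#' Cooperator-cheater public-goods model
#'
#' Two cell types seeded at the domain center share a toy metabolism
#' (substrate freeing from the enzyme-substrate complex, fermentative and
#' respiratory carrier recycling, biomass synthesis); only the cooperator
#' additionally invests precursor and ATP into producing the scavenging
#' enzyme (the cheater's corresponding rate is zero).  The bulk carries the
#' diffusing species `E`, `S`, `ES`, `O2`, with enzyme-substrate binding
#' and enzyme decay as bulk reactions and a Neumann influx replenishing
#' substrate and oxygen at the boundary.  All printed rate constants are 1;
#' the remaining values (domain size, diffusivities, influxes, thresholds)
#' are documented package defaults.
#'
#' @param width,height,h Domain extent and mesh spacing.
#' @param dt,t_end,sampling_interval Solver settings (the written exemplar
#'   fixture uses `t_end = 10000`; see [write_exemplar()]).
#' @param influx Neumann boundary influx of `S` and `O2`.
#' @param rho Division fraction.
#' @param seed RNG seed.
#' @return An `rd_model` with a two-cell population.
#' @export
cooperator_cheater_model <- function(width = 20, height = 20, h = 1,
                                     dt = 0.02, t_end = 40,
                                     sampling_interval = 1,
                                     influx = 0.05, rho = 0.5, seed = 0L) {
  grid <- matrix("B", 1L, 1L)
  key <- c(B = "Bulk")
  species <- c("E", "S", "ES", "O2")
  bulk <- reaction_system(species, list(
    parse_reaction_line(
      "MassActionReversibleReaction: ES <-> E + S ; k_f = 1, k_r = 1"),
    parse_reaction_line("MassActionReaction: E -> ; k = 1")))
  field <- domain_field(
    grid, key,
    diffusivity = data.frame(subdomain = "Bulk", species = species,
                             D = c(0.1, 1, 0.1, 1)),
    reactions = list(Bulk = bulk),
    boundary = data.frame(species = species, kind = "neumann",
                          value = c(0, influx, 0, influx)),
    initial = data.frame(subdomain = "Bulk", species = species,
                         value = c(0, 0.5, 0, 1), perturb = 0))
  mesh <- build_rectangular_mesh(round(width / h), round(height / h), h)
  cx <- width / 2; cy <- height / 2
  cells <- list(
    .build_cc_cell(1L, "Cooperator", c(cx - 1, cy), rho),
    .build_cc_cell(2L, "Cheater", c(cx + 1, cy), rho))
  pop <- cell_population(cells, spring_cutoff = 1.5, spring_stiffness = 1,
                         origin = c(cx - 1, cy))
  rd_model(mesh, field, species,
           solver_settings(dt, t_end, sampling_interval),
           population = pop, seed = seed, name = "cooperator_cheater")
}
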