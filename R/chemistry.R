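# Chemical species, reactions, the reaction-file grammar and rate evaluation.
#
# Reaction grammar (EBNF), one reaction per line, "#" starts a comment:
#
#   line      = law , ":" , equation , ";" , params ;
#   equation  = side , ( "->" | "<->" ) , side ;            (membrane files:
#   membrane  = side , arrow , side , "|" , side , arrow , side ;)
#   side      = [ term , { "+" , term } ] ;                 empty side = 0
#   term      = [ integer ] , species ;
#   species   = letter | "_" , { letter | digit | "_" } ;
#   params    = [ param , { "," , param } ] ;
#   param     = name , "=" , ( number | species ) ;
#
# Token-valued parameters are reserved for "enzyme" (Michaelis-Menten) and
# "spectator" (may repeat); all other parameters must be non-negative numbers.

.law_aliases <- c(
  zeroth_order                      = "zeroth_order",
  mass_action_irreversible          = "mass_action_irreversible",
  mass_action_reversible            = "mass_action_reversible",
  michaelis_menten                  = "michaelis_menten",
  ZerothOrderReaction               = "zeroth_order",
  ZerothOrderReversibleReaction     = "mass_action_reversible",
  MassActionReaction                = "mass_action_irreversible",
  MassActionReversibleReaction      = "mass_action_reversible",
  MichaelisMentenReaction           = "michaelis_menten",
  # coupling-context aliases, accepted where unambiguous
  ZerothOrderTransportIntoCell      = "zeroth_order",
  MassActionTransportReaction       = "mass_action_irreversible",
  MassActionReversibleTransportReaction = "mass_action_reversible",
  ZerothOrderCoupledMembrane        = "zeroth_order",
  MassActionCoupledMembrane         = "mass_action_irreversible",
  MassActionReversibleCoupledMembrane = "mass_action_reversible"
)

.law_registry <- new.env(parent = emptyenv())

#' Register a user-defined kinetic rate law
#'
#' Extension hook mirroring the simulator's pluggable rate-law catalogue.
#' The registered function receives the parsed reaction (with fields
#' `params`, `reactants`, `products`, `spectators`, `enzyme`) and a numeric
#' concentration matrix (rows = evaluation points, columns = species, named),
#' and must return one non-negative-or-real rate per row.
#'
#' @param name Law name as written in reaction files.
#' @param fn `function(reaction, conc)` returning a rate vector.
#' @export
register_rate_law <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .law_registry)
  invisible(name)
}

#' Define a chemical species with its physical properties
#'
#' Name and per-subdomain diffusivity drive the simulation; mass, valence
#' and Gibbs formation energy are stored and exposed but do not modify rates
#' in this version (an extension point).
#'
#' @param name Species token.
#' @param diffusivity Named numeric vector, subdomain -> D (>= 0); may be
#'   empty for cell-only species.
#' @param mass,valence,gibbs_formation_energy Optional scalars.
#' @return `rd_species` object.
#' @export
chemical_species <- function(name, diffusivity = numeric(),
                             mass = NA_real_, valence = NA_integer_,
                             gibbs_formation_energy = NA_real_) {
  stopifnot(is.character(name), nzchar(name))
  if (any(diffusivity < 0)) stop("diffusivity must be >= 0", call. = FALSE)
  structure(list(name = name, diffusivity = diffusivity, mass = mass,
                 valence = valence,
                 gibbs_formation_energy = gibbs_formation_energy),
            class = "rd_species")
}

.parse_side <- function(text, where) {
  text <- trimws(text)
  if (!nzchar(text)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^\\s*([0-9]*\\.?[0-9]*)\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*$", tm))[[1]]
    if (length(m) == 0L)
      stop(sprintf("%s: cannot parse reaction term '%s'", where, trimws(tm)),
           call. = FALSE)
    coef_txt <- m[2]
    if (nzchar(coef_txt)) {
      coef <- suppressWarnings(as.numeric(coef_txt))
      if (is.na(coef) || coef != round(coef) || grepl(".", coef_txt, fixed = TRUE))
        stop(sprintf("%s: non-integer stoichiometric coefficient '%s'",
                     where, coef_txt), call. = FALSE)
    } else coef <- 1
    sp <- m[3]
    out[sp] <- if (sp %in% names(out)) out[[sp]] + coef else coef
  }
  out
}

.parse_params <- function(text, where) {
  text <- trimws(text)
  params <- numeric(0)
  enzyme <- NA_character_
  spectators <- character(0)
  if (nzchar(text)) {
    for (piece in strsplit(text, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(piece, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop(sprintf("%s: malformed parameter '%s' (expected name = value)",
                     where, trimws(piece)), call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "enzyme") {
        enzyme <- val
      } else if (key %in% c("spectator", "spectators")) {
        spectators <- c(spectators, val)
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num))
          stop(sprintf("%s: parameter '%s' is not numeric", where, key),
               call. = FALSE)
        if (num < 0)
          stop(sprintf("%s: parameter '%s' is negative", where, key),
               call. = FALSE)
        params[key] <- num
      }
    }
  }
  list(params = params, enzyme = enzyme, spectators = spectators)
}

.parse_equation <- function(eqn, where) {
  if (grepl("<->", eqn, fixed = TRUE)) {
    sides <- strsplit(eqn, "<->", fixed = TRUE)[[1]]
    reversible <- TRUE
  } else if (grepl("->", eqn, fixed = TRUE)) {
    sides <- strsplit(eqn, "->", fixed = TRUE)[[1]]
    reversible <- FALSE
  } else {
    stop(sprintf("%s: missing '->' or '<->' in reaction equation", where),
         call. = FALSE)
  }
  if (length(sides) > 2L)
    stop(sprintf("%s: more than one arrow in reaction equation", where),
         call. = FALSE)
  if (length(sides) == 1L) sides <- c(sides, "")
  list(reactants = .parse_side(sides[1], where),
       products = .parse_side(sides[2], where),
       reversible = reversible)
}

.check_law <- function(law, reversible, params, where) {
  needed <- switch(law,
    zeroth_order = if (reversible) c("k_f", "k_r") else "k",
    mass_action_irreversible = "k",
    mass_action_reversible = c("k_f", "k_r"),
    michaelis_menten = c("k_cat", "K_M"),
    character(0))
  missing <- setdiff(needed, names(params))
  if (length(missing))
    stop(sprintf("%s: rate law is missing parameter(s) %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (law == "mass_action_reversible" && !reversible)
    stop(sprintf("%s: reversible rate law requires '<->'", where),
         call. = FALSE)
  if (law %in% c("mass_action_irreversible", "michaelis_menten") && reversible)
    stop(sprintf("%s: irreversible rate law used with '<->'", where),
         call. = FALSE)
}

#' Parse one line of the reaction grammar
#'
#' A line has the form `"RateLaw: equation ; name = value, ..."`.  The
#' context decides how the two sides of the equation are interpreted: in
#' `bulk` and `cell` files both sides name species of the local system; in
#' `transport` files the left-hand side names bulk species and the
#' right-hand side names intracellular species; `membrane` lines carry two
#' equations separated by `"|"` (an outer, bulk-facing reaction and an
#' inner, cell-facing one) that share a single rate.
#'
#' @param text One reaction line (comments and blank lines yield `NULL`).
#' @param context One of `"bulk"`, `"cell"`, `"transport"`, `"membrane"`.
#' @param line Optional line number used in error messages.
#' @return An `rd_reaction` (or `rd_membrane_reaction`) object, or `NULL`
#'   for blank/comment lines.
#' @export
parse_reaction_line <- function(text,
                                context = c("bulk", "cell", "transport",
                                            "membrane"),
                                line = NA_integer_) {
  context <- match.arg(context)
  where <- if (is.na(line)) "reaction line" else sprintf("reaction line %d", line)
  text <- sub("#.*$", "", text)
  if (!nzchar(trimws(text))) return(NULL)

  colon <- regexpr(":", text, fixed = TRUE)
  if (colon < 0)
    stop(sprintf("%s: missing ':' rate delimiter", where), call. = FALSE)
  law_name <- trimws(substr(text, 1L, colon - 1L))
  rest <- substr(text, colon + 1L, nchar(text))
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0)
    stop(sprintf("%s: missing ';' reaction delimiter", where), call. = FALSE)
  eqn_text <- substr(rest, 1L, semi - 1L)
  par_text <- substr(rest, semi + 1L, nchar(rest))

  if (!law_name %in% names(.law_aliases) &&
      !exists(law_name, envir = .law_registry, inherits = FALSE))
    stop(sprintf("%s: unknown rate law '%s'", where, law_name), call. = FALSE)
  law <- if (law_name %in% names(.law_aliases)) .law_aliases[[law_name]]
         else law_name

  pp <- .parse_params(par_text, where)

  if (context == "membrane") {
    halves <- strsplit(eqn_text, "|", fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      stop(sprintf("%s: membrane reaction needs exactly one '|' delimiter",
                   where), call. = FALSE)
    outer <- .parse_equation(halves[1], where)
    inner <- .parse_equation(halves[2], where)
    .check_law(law, outer$reversible, pp$params, where)
    return(structure(list(
      law = law, outer = outer, inner = inner,
      reversible = outer$reversible,
      params = pp$params, enzyme = pp$enzyme, spectators = pp$spectators,
      context = "membrane"), class = "rd_membrane_reaction"))
  }

  eq <- .parse_equation(eqn_text, where)
  if (law != "zeroth_order" &&
      length(eq$reactants) == 0L && length(eq$products) == 0L)
    stop(sprintf("%s: reaction has no species on either side", where),
         call. = FALSE)
  .check_law(law, eq$reversible, pp$params, where)
  if (law == "michaelis_menten") {
    if (length(eq$reactants) == 0L)
      stop(sprintf("%s: Michaelis-Menten reaction needs a substrate", where),
           call. = FALSE)
    if (is.na(pp$enzyme))
      stop(sprintf("%s: Michaelis-Menten reaction needs 'enzyme = <species>'",
                   where), call. = FALSE)
  }
  structure(list(
    law = law,
    reactants = eq$reactants, products = eq$products,
    reversible = eq$reversible,
    params = pp$params, enzyme = pp$enzyme, spectators = pp$spectators,
    context = context), class = "rd_reaction")
}

#' Parse a reaction file (one reaction per line)
#' @param path File path.
#' @inheritParams parse_reaction_line
#' @return List of parsed reactions.
#' @export
parse_reaction_file <- function(path, context = "bulk") {
  if (!file.exists(path))
    stop(sprintf("reaction file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    rx <- tryCatch(parse_reaction_line(lines[i], context, line = i),
                   error = function(e) stop(sprintf("%s: %s", path,
                                                    conditionMessage(e)),
                                            call. = FALSE))
    if (!is.null(rx)) out[[length(out) + 1L]] <- rx
  }
  out
}

#' Serialize a reaction back to its grammar line
#' @param reaction An `rd_reaction` or `rd_membrane_reaction`.
#' @return A single string that reparses to an identical reaction.
#' @export
serialize_reaction <- function(reaction) {
  law_name <- switch(reaction$law,
    zeroth_order = "ZerothOrderReaction",
    mass_action_irreversible = "MassActionReaction",
    mass_action_reversible = "MassActionReversibleReaction",
    michaelis_menten = "MichaelisMentenReaction",
    reaction$law)
  side_txt <- function(side) {
    if (length(side) == 0L) return("")
    paste(ifelse(side == 1, names(side),
                 paste0(side, " ", names(side))), collapse = " + ")
  }
  arrow <- if (isTRUE(reaction$reversible)) "<->" else "->"
  eqn <- if (inherits(reaction, "rd_membrane_reaction")) {
    paste(
      paste(side_txt(reaction$outer$reactants), arrow,
            side_txt(reaction$outer$products)),
      "|",
      paste(side_txt(reaction$inner$reactants), arrow,
            side_txt(reaction$inner$products)))
  } else {
    paste(side_txt(reaction$reactants), arrow, side_txt(reaction$products))
  }
  par_bits <- character(0)
  if (length(reaction$params))
    par_bits <- paste(names(reaction$params), "=", reaction$params)
  if (!is.na(reaction$enzyme))
    par_bits <- c(par_bits, paste("enzyme =", reaction$enzyme))
  if (length(reaction$spectators))
    par_bits <- c(par_bits, paste("spectator =", reaction$spectators))
  sprintf("%s: %s ; %s", law_name, trimws(eqn), paste(par_bits, collapse = ", "))
}

#' Assemble a reaction system
#'
#' Binds an ordered species list to a list of parsed reactions and
#' precompiles index structures for fast rate evaluation.
#'
#' @param species Character vector of species names, or list of
#'   [chemical_species()] objects.
#' @param reactions List of `rd_reaction` objects.
#' @return An `rd_reaction_system`.
#' @export
reaction_system <- function(species, reactions = list()) {
  if (is.list(species) && all(vapply(species, inherits, TRUE, "rd_species"))) {
    props <- species
    species <- vapply(props, `[[`, "", "name")
  } else {
    species <- as.character(species)
    props <- NULL
  }
  if (anyDuplicated(species))
    stop("reaction_system: duplicated species names", call. = FALSE)
  n <- length(species)
  compiled <- vector("list", length(reactions))
  S <- matrix(0, nrow = n, ncol = length(reactions),
              dimnames = list(species, NULL))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    if (inherits(rx, "rd_membrane_reaction"))
      stop("reaction_system: membrane reactions belong to cells, not bulk/cell systems",
           call. = FALSE)
    used <- c(names(rx$reactants), names(rx$products), rx$spectators,
              if (!is.na(rx$enzyme)) rx$enzyme)
    missing <- setdiff(used, species)
    if (length(missing))
      stop(sprintf("reaction_system: species %s not in the species list",
                   paste(shQuote(missing), collapse = ", ")), call. = FALSE)
    ri <- match(names(rx$reactants), species)
    pi <- match(names(rx$products), species)
    compiled[[j]] <- list(
      law = rx$law,
      params = rx$params,
      reactant_idx = ri, reactant_nu = unname(rx$reactants),
      product_idx = pi, product_nu = unname(rx$products),
      spectator_idx = match(rx$spectators, species),
      enzyme_idx = if (is.na(rx$enzyme)) NA_integer_
                   else match(rx$enzyme, species),
      custom = if (rx$law %in% .law_aliases) NULL
               else get(rx$law, envir = .law_registry),
      raw = rx)
    if (length(ri)) S[ri, j] <- S[ri, j] - rx$reactants
    if (length(pi)) S[pi, j] <- S[pi, j] + rx$products
  }
  structure(list(species = species, species_props = props,
                 reactions = reactions, compiled = compiled, S = S),
            class = "rd_reaction_system")
}

#' @exportS3Method base::print
print.rd_reaction_system <- function(x, ...) {
  cat(sprintf("rd_reaction_system: %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              length(x$reactions)))
  for (rx in x$reactions) cat("  ", serialize_reaction(rx), "\n")
  invisible(x)
}

# rates per reaction; C is an m x n matrix with columns ordered as
# system$species.  Returns an m x n_reactions matrix.
.reaction_rate_matrix <- function(system, C) {
  m <- nrow(C)
  nr <- length(system$compiled)
  R <- matrix(0, m, nr)
  for (j in seq_len(nr)) {
    r <- system$compiled[[j]]
    if (!is.null(r$custom)) {
      Cn <- C
      colnames(Cn) <- system$species
      R[, j] <- r$custom(r$raw, Cn)
      next
    }
    R[, j] <- switch(r$law,
      zeroth_order = {
        if (length(r$params) && "k" %in% names(r$params)) r$params[["k"]]
        else r$params[["k_f"]] - r$params[["k_r"]]
      },
      mass_action_irreversible = {
        p <- rep(r$params[["k"]], m)
        for (t in seq_along(r$reactant_idx))
          p <- p * C[, r$reactant_idx[t]]^r$reactant_nu[t]
        for (s in r$spectator_idx) p <- p * C[, s]
        p
      },
      mass_action_reversible = {
        fw <- rep(r$params[["k_f"]], m)
        for (t in seq_along(r$reactant_idx))
          fw <- fw * C[, r$reactant_idx[t]]^r$reactant_nu[t]
        bw <- rep(r$params[["k_r"]], m)
        for (t in seq_along(r$product_idx))
          bw <- bw * C[, r$product_idx[t]]^r$product_nu[t]
        for (s in r$spectator_idx) {
          fw <- fw * C[, s]; bw <- bw * C[, s]
        }
        fw - bw
      },
      michaelis_menten = {
        S0 <- C[, r$reactant_idx[1]]
        E <- C[, r$enzyme_idx]
        r$params[["k_cat"]] * E * S0 / (r$params[["K_M"]] + S0)
      },
      stop(sprintf("unknown rate law '%s'", r$law), call. = FALSE))
  }
  R
}

#' Evaluate reaction-rate source terms
#'
#' Computes the time derivative of every species' concentration under the
#' system's reactions: mass-action rates are `k * prod(c_i^nu_i)` over
#' reactants (times any spectator concentrations), reversible rates are
#' `k_f * prod(reactants) - k_r * prod(products)` (an empty side contributes
#' a factor 1, so `<-> U` yields `k_f - k_r * U`), and Michaelis-Menten
#' rates are `k_cat * E * S / (K_M + S)`.  The derivative of species `s` is
#' the stoichiometry-weighted sum of reaction rates.
#'
#' @param system An `rd_reaction_system`.
#' @param concentrations Non-negative numeric vector (one value per species,
#'   in system order) or an m x n matrix of m states.
#' @return Derivative vector (or matrix) matching the input shape.
#' @export
evaluate_rates <- function(system, concentrations) {
  stopifnot(inherits(system, "rd_reaction_system"))
  vec <- is.null(dim(concentrations))
  C <- if (vec) matrix(concentrations, nrow = 1L) else as.matrix(concentrations)
  if (ncol(C) != length(system$species))
    stop("evaluate_rates: concentration length does not match species count",
         call. = FALSE)
  if (any(C < 0))
    stop("evaluate_rates: negative concentration", call. = FALSE)
  D <- .reaction_rate_matrix(system, C) %*% t(system$S)
  if (vec) stats::setNames(as.vector(D), system$species) else D
}

# one RK4 step of the pure reaction ODE; stage inputs are floored at zero so
# stiff kinetics cannot push an evaluation below the physical range, and the
# result is clipped at zero (see the methods vignette on the guard).
.rk4_step <- function(system, C, dt) {
  f <- function(X) .reaction_rate_matrix(system, pmax(X, 0)) %*% t(system$S)
  k1 <- f(C)
  k2 <- f(C + (dt / 2) * k1)
  k3 <- f(C + (dt / 2) * k2)
  k4 <- f(C + dt * k3)
  pmax(C + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4), 0)
}

#' Integrate a well-mixed reaction system
#'
#' Advances the pure ODE system (no diffusion) with the fixed-step explicit
#' fourth-order Runge-Kutta scheme used for nodal and intracellular
#' kinetics, with a non-negativity guard clipping concentrations at zero.
#'
#' @param system An `rd_reaction_system`.
#' @param initial Initial concentration vector (system species order).
#' @param t_end End time (`>= dt`).
#' @param dt Time step (`> 0`).
#' @param sampling_interval Time between recorded samples (defaults to
#'   `dt`); rounded to a whole number of steps.
#' @return An `rd_timeseries`: list with `times` and a samples x species
#'   `values` matrix.
#' @export
integrate_well_mixed <- function(system, initial, t_end, dt,
                                 sampling_interval = dt) {
  stopifnot(dt > 0, t_end >= dt)
  every <- max(1L, round(sampling_interval / dt))
  n_steps <- ceiling(t_end / dt - 1e-12)
  C <- matrix(as.numeric(initial), nrow = 1L)
  keep <- seq(0L, n_steps, by = every)
  values <- matrix(NA_real_, length(keep), length(system$species),
                   dimnames = list(NULL, system$species))
  values[1L, ] <- C
  k <- 2L
  for (step in seq_len(n_steps)) {
    C <- .rk4_step(system, C, dt)
    if (!all(is.finite(C)))
      stop(sprintf("integrate_well_mixed: solver failure (non-finite state at t = %g)",
                   step * dt), call. = FALSE)
    if (k <= length(keep) && step == keep[k]) {
      values[k, ] <- C
      k <- k + 1L
    }
  }
  structure(list(times = keep * dt, values = values,
                 species = system$species),
            class = "rd_timeseries")
}
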