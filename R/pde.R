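# Finite-element reaction-diffusion solver.
#
# Linear (P1) triangular elements on the structured mesh, lumped mass.
# Time stepping is IMEX: the reaction source is advanced explicitly at the
# nodes (one RK4 step of the local ODE system per time step, using the
# node's subdomain reaction file), then diffusion is advanced implicitly
# (backward Euler), species by species:
#
#   (M + dt K_s) u^{n+1} = M u* + dt b_s,   u* = reaction substep of u^n
#
# Zero-flux Neumann conditions are natural; a nonzero Neumann flux enters as
# the boundary source b_s = value * half-edge-length share; Dirichlet
# conditions pin boundary nodes by symmetric elimination; periodic
# conditions identify opposite-edge nodes before factorization.

#' Assemble diffusion operators for every species
#'
#' Builds the per-species stiffness operator from linear-basis gradients,
#' with the element diffusivity taken from the element's subdomain (the
#' label of the element's lower-left node), plus the shared lumped mass
#' diagonal.
#'
#' @param mesh A labelled `rd_mesh` (see [assign_labels()]).
#' @param field An `rd_domain_field` supplying the diffusivity table.
#' @param species Character vector of bulk species.
#' @return List with `stiffness` (named list of sparse matrices, one per
#'   species), `mass` (lumped nodal-volume vector) and `edge_share`
#'   (boundary half-edge lengths, for Neumann sources).
#' @export
assemble_operators <- function(mesh, field, species) {
  stopifnot(inherits(mesh, "rd_mesh"))
  if (anyNA(mesh$elem_label))
    stop("assemble_operators: mesh has no subdomain labels; run assign_labels first",
         call. = FALSE)
  elem_sub <- unname(field$key[mesh$elem_label])
  subs <- unique(elem_sub)
  el <- mesh$elements
  p1 <- mesh$coords[el[, 1], , drop = FALSE]
  p2 <- mesh$coords[el[, 2], , drop = FALSE]
  p3 <- mesh$coords[el[, 3], , drop = FALSE]
  # gradients of the three linear basis functions
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2])
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1])
  area <- mesh$elem_area
  n <- nrow(mesh$coords)

  stiffness <- vector("list", length(species))
  names(stiffness) <- species
  for (sp in species) {
    Dv <- numeric(length(subs))
    for (k in seq_along(subs))
      Dv[k] <- field_diffusivity(field, sp, subs[k])
    D_e <- Dv[match(elem_sub, subs)]
    if (all(D_e == 0)) {
      stiffness[[sp]] <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(n, n))
      next
    }
    coef <- D_e / (4 * area)
    ival <- vector("list", 9L); jval <- vector("list", 9L)
    xval <- vector("list", 9L)
    k <- 1L
    for (a in 1:3) for (bb in 1:3) {
      ival[[k]] <- el[, a]
      jval[[k]] <- el[, bb]
      xval[[k]] <- coef * (b[, a] * b[, bb] + cc[, a] * cc[, bb])
      k <- k + 1L
    }
    stiffness[[sp]] <- Matrix::sparseMatrix(
      i = unlist(ival), j = unlist(jval), x = unlist(xval), dims = c(n, n))
  }
  list(stiffness = stiffness,
       mass = nodal_volume_share(mesh),
       edge_share = boundary_edge_share(mesh))
}

# boundary-condition spec for one species with zero-flux default
.species_bc <- function(field, sp) {
  bc <- field$boundary
  if (!is.null(bc)) {
    hit <- which(bc$species == sp)
    if (length(hit))
      return(list(kind = bc$kind[hit[1L]], value = bc$value[hit[1L]]))
  }
  list(kind = "neumann", value = 0)
}

# periodic identification: right edge -> left edge, top edge -> bottom edge
.periodic_map <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  ix <- round(mesh$coords[, 1] / mesh$spacing)
  iy <- round(mesh$coords[, 2] / mesh$spacing)
  mix <- ifelse(ix == nx, 0L, ix)
  miy <- ifelse(iy == ny, 0L, iy)
  as.integer(miy * (nx + 1L) + mix + 1L)
}

#' Prepare an IMEX time stepper
#'
#' Factorizes the per-species implicit diffusion systems once (for the fixed
#' time step) and groups nodes by subdomain for the nodal reaction substep.
#'
#' @param mesh Labelled `rd_mesh`.
#' @param field `rd_domain_field`.
#' @param species Bulk species vector (column order of the field state).
#' @param settings List with at least `dt`; see [solver_settings()].
#' @return A stepper object with a `$step(U)` function advancing the
#'   node x species concentration matrix by one `dt`.
#' @export
make_stepper <- function(mesh, field, species, settings) {
  dt <- settings$dt
  stopifnot(dt > 0)
  ops <- assemble_operators(mesh, field, species)
  n <- nrow(mesh$coords)
  m <- ops$mass

  # reaction groups: nodes sharing a subdomain evaluate that subdomain's
  # reaction system in one vectorized RK4 step
  node_sub <- unname(field$key[mesh$labels])
  groups <- list()
  for (sub in unique(node_sub)) {
    sys <- field$reactions[[sub]]
    if (is.null(sys) || length(sys$reactions) == 0L) next
    cols <- match(sys$species, species)
    if (anyNA(cols))
      stop(sprintf("subdomain '%s' reacts species absent from the bulk species list: %s",
                   sub, paste(setdiff(sys$species, species), collapse = ", ")),
           call. = FALSE)
    groups[[length(groups) + 1L]] <-
      list(nodes = which(node_sub == sub), sys = sys, cols = cols)
  }

  ctx <- vector("list", length(species))
  names(ctx) <- species
  for (sp in species) {
    bc <- .species_bc(field, sp)
    K <- ops$stiffness[[sp]]
    if (bc$kind == "periodic") {
      map <- .periodic_map(mesh)
      reps <- sort(unique(map))
      red <- match(map, reps)
      Tm <- Matrix::sparseMatrix(i = seq_len(n), j = red, x = 1,
                                 dims = c(n, length(reps)))
      Kr <- Matrix::t(Tm) %*% K %*% Tm
      mr <- as.vector(Matrix::t(Tm) %*% m)
      A <- Kr * dt + Matrix::Diagonal(x = mr)
      fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
      ctx[[sp]] <- list(kind = "periodic", Tm = Tm, red = red, fac = fac,
                        source = numeric(length(reps)))
    } else if (bc$kind == "dirichlet") {
      A <- K * dt + Matrix::Diagonal(x = m)
      pinned <- which(mesh$on_boundary)
      Acol <- A[, pinned, drop = FALSE]
      A[pinned, ] <- 0
      A[, pinned] <- 0
      A <- A + Matrix::sparseMatrix(i = pinned, j = pinned, x = 1,
                                    dims = dim(A))
      fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
      ctx[[sp]] <- list(kind = "dirichlet", fac = fac, pinned = pinned,
                        Acol = Acol, value = bc$value)
    } else {
      A <- K * dt + Matrix::Diagonal(x = m)
      fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
      ctx[[sp]] <- list(kind = "neumann", fac = fac,
                        source = bc$value * ops$edge_share)
    }
  }

  react_step <- function(U) {
    for (g in groups) {
      U[g$nodes, g$cols] <-
        .rk4_step(g$sys, U[g$nodes, g$cols, drop = FALSE], dt)
    }
    U
  }

  diffuse_step <- function(U) {
    for (s in seq_along(species)) {
      cx <- ctx[[s]]
      u <- U[, s]
      if (cx$kind == "periodic") {
        rhs <- as.vector(Matrix::t(cx$Tm) %*% (m * u))
        ur <- as.vector(Matrix::solve(cx$fac, rhs, system = "A"))
        U[, s] <- ur[cx$red]
      } else if (cx$kind == "dirichlet") {
        rhs <- m * u
        rhs <- rhs - as.vector(cx$Acol %*% rep(cx$value, length(cx$pinned)))
        rhs[cx$pinned] <- cx$value
        U[, s] <- as.vector(Matrix::solve(cx$fac, rhs, system = "A"))
      } else {
        rhs <- m * u + dt * cx$source
        U[, s] <- as.vector(Matrix::solve(cx$fac, rhs, system = "A"))
      }
    }
    U
  }

  list(species = species, dt = dt, mass = m, ops = ops,
       step = function(U, t = NA_real_) {
         U <- react_step(U)
         U <- diffuse_step(U)
         if (!all(is.finite(U)))
           stop(sprintf("pde step: non-finite field at t = %g", t),
                call. = FALSE)
         U
       },
       react_step = react_step, diffuse_step = diffuse_step)
}

#' Solver settings
#' @param dt Time step.
#' @param t_end End time.
#' @param sampling_interval Time between recorded samples.
#' @param scheme Time-stepping scheme; only `"imex"` is implemented.
#' @return Validated settings list.
#' @export
solver_settings <- function(dt = 0.01, t_end = 1, sampling_interval = dt,
                            scheme = "imex") {
  if (!(dt > 0 && dt <= sampling_interval + 1e-12 &&
        sampling_interval <= t_end + 1e-12))
    stop("solver_settings: need 0 < dt <= sampling_interval <= t_end",
         call. = FALSE)
  list(dt = dt, t_end = t_end, sampling_interval = sampling_interval,
       scheme = match.arg(scheme, "imex"))
}

# initial node x species field from the per-subdomain initial table;
# perturbation half-widths draw Uniform(-a, a) per node from the current RNG
# stream, and the result is floored at zero.
.initial_field <- function(mesh, field, species) {
  n <- nrow(mesh$coords)
  U <- matrix(0, n, length(species), dimnames = list(NULL, species))
  init <- field$initial
  if (is.null(init)) return(U)
  node_sub <- unname(field$key[mesh$labels])
  for (r in seq_len(nrow(init))) {
    sp <- init$species[r]
    if (!sp %in% species) next
    nodes <- which(node_sub == init$subdomain[r])
    U[nodes, sp] <- init$value[r]
    a <- init$perturb[r]
    if (!is.null(a) && is.finite(a) && a > 0)
      U[nodes, sp] <- U[nodes, sp] + stats::runif(length(nodes), -a, a)
  }
  pmax(U, 0)
}

#' Run a full simulation from a model specification
#'
#' Executes the four-phase loop per time step: (1) intracellular reaction
#' networks of every cell, (2) the bulk reaction-diffusion step, (3)
#' transport and membrane coupling between each cell and its bound mesh
#' node, (4) cell rules (death, threshold division) and spring-force
#' position updates.  Domain-only models skip phases 1, 3 and 4.
#'
#' @param model An `rd_model` from [load_model()] or built in code (a list
#'   with `mesh`, `field`, `species`, `settings`, optional `population`,
#'   `seed`).
#' @param seed Integer seed overriding `model$seed`.
#' @return An `rd_trajectory`: list with `times`, `values` (node x species
#'   x sample array), `species`, `mesh`, and `cell_records` (data frame, or
#'   `NULL` for domain-only runs).
#' @export
run_simulation <- function(model, seed = NULL) {
  mesh <- model$mesh
  field <- model$field
  species <- model$species
  settings <- model$settings
  if (is.null(seed)) seed <- if (!is.null(model$seed)) model$seed else 0L
  set.seed(as.integer(seed))

  U <- .initial_field(mesh, field, species)
  stepper <- make_stepper(mesh, field, species, settings)
  dt <- settings$dt
  n_steps <- ceiling(settings$t_end / dt - 1e-12)
  every <- max(1L, round(settings$sampling_interval / dt))
  keep <- seq(0L, n_steps, by = every)

  values <- array(NA_real_, dim = c(nrow(U), ncol(U), length(keep)),
                  dimnames = list(NULL, species, NULL))
  values[, , 1L] <- U

  pop <- model$population
  has_cells <- !is.null(pop) && length(pop$cells) > 0L
  if (has_cells) {
    # initial intracellular perturbations (perturb flag of the per-type
    # concentration table) draw from the same seeded stream
    pop$cells <- lapply(pop$cells, function(cl) {
      if (!is.null(cl$perturb)) {
        for (nm in names(cl$perturb)) {
          a <- cl$perturb[[nm]]
          if (is.finite(a) && a > 0)
            cl$conc[[nm]] <- max(cl$conc[[nm]] +
                                   stats::runif(1L, -a, a), 0)
        }
        cl$perturb <- NULL
      }
      cl
    })
  }
  cell_records <- if (has_cells) list() else NULL
  record_cells <- function(t) {
    rows <- lapply(pop$cells, function(cl) {
      base <- data.frame(time = t, id = cl$id, type = cl$type,
                         x = cl$pos[1], y = cl$pos[2],
                         stringsAsFactors = FALSE)
      cbind(base, as.data.frame(as.list(cl$conc)))
    })
    cell_records[[length(cell_records) + 1L]] <<- rows
  }
  if (has_cells) record_cells(0)

  k <- 2L
  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    if (has_cells && length(pop$cells)) {
      # (1) intracellular reactions
      pop$cells <- lapply(pop$cells, step_intracellular, dt = dt)
    }
    # (2) bulk reaction-diffusion
    U <- withCallingHandlers(
      stepper$step(U, t_now),
      error = function(e) stop(sprintf("bulk phase: %s", conditionMessage(e)),
                               call. = FALSE))
    if (has_cells && length(pop$cells)) {
      # (3) coupling, in cell-id order at shared nodes
      bindings <- bind_cells(pop, mesh)
      ord <- order(vapply(pop$cells, `[[`, 0L, "id"))
      for (ci in ord) {
        bd <- bindings[[ci]]
        res <- apply_coupling(pop$cells[[ci]], U[bd$node, ], bd$share,
                              dt, species)
        U[bd$node, ] <- res$bulk
        pop$cells[[ci]] <- res$cell
      }
      # (4) cell rules and positions
      pop <- apply_cell_rules(pop, mesh)
      pop <- update_positions(pop, dt, mesh = mesh)
    }
    if (k <= length(keep) && step == keep[k]) {
      values[, , k] <- U
      if (has_cells) record_cells(t_now)
      k <- k + 1L
    }
  }

  records <- NULL
  if (has_cells && length(cell_records)) {
    flat <- unlist(cell_records, recursive = FALSE)
    if (length(flat)) {
      cols <- unique(unlist(lapply(flat, names)))
      flat <- lapply(flat, function(df) {
        for (cn in setdiff(cols, names(df))) df[[cn]] <- NA_real_
        df[cols]
      })
      records <- do.call(rbind, flat)
      rownames(records) <- NULL
    }
  }

  structure(list(times = keep * dt, values = values, species = species,
                 mesh = mesh, cell_records = records,
                 final_population = if (has_cells) pop else NULL),
            class = "rd_trajectory")
}

#' @exportS3Method base::print
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("rd_trajectory: %d samples over t = [%g, %g], %d nodes, species %s\n",
              length(x$times), min(x$times), max(x$times),
              dim(x$values)[1], paste(x$species, collapse = ", ")))
  if (!is.null(x$cell_records))
    cat(sprintf("  cell records: %d rows, %d cells at final sample\n",
                nrow(x$cell_records),
                length(unique(x$cell_records$id[x$cell_records$time ==
                                                  max(x$cell_records$time)]))))
  invisible(x)
}
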