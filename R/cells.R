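# Point-like cell agents: intracellular reaction networks, threshold
# division with concentration partitioning, threshold death, and Hookean
# spring position updates (overdamped, unit drag).

#' Create a cell agent
#'
#' @param id Unique integer id.
#' @param type Cell type name (matches the per-type model directory).
#' @param position Numeric `(x, y)` inside the bulk domain.
#' @param conc Named numeric vector of intracellular concentrations (>= 0).
#' @param srn Intracellular [reaction_system()] (the subcellular reaction
#'   network), or `NULL` for an inert cell.
#' @param transport List of transport reactions (context `"transport"`).
#' @param membrane List of membrane reaction pairs (context `"membrane"`).
#' @param thresholds Data frame with columns `species`, `max`, `min`:
#'   reaching `max` triggers division, falling below `min` triggers death.
#' @param rho Division fraction in (0, 1): the parent keeps `rho` of every
#'   species, the daughter receives `1 - rho`.
#' @return An `rd_cell`.
#' @export
new_cell <- function(id, type, position, conc, srn = NULL,
                     transport = list(), membrane = list(),
                     thresholds = NULL, rho = 0.5) {
  stopifnot(length(position) == 2L, all(conc >= 0),
            rho > 0, rho < 1)
  if (!is.null(thresholds)) {
    stopifnot(all(c("species", "max", "min") %in% names(thresholds)),
              all(thresholds$min <= thresholds$max))
  }
  structure(list(id = as.integer(id), type = type,
                 pos = as.numeric(position), conc = conc, srn = srn,
                 transport = transport, membrane = membrane,
                 thresholds = thresholds, rho = rho),
            class = "rd_cell")
}

#' Create a cell population
#' @param cells List of [new_cell()] objects (unique ids).
#' @param spring_cutoff Interaction cutoff length of the Hookean spring
#'   force; the rest length is `spring_cutoff / 2`.
#' @param spring_stiffness Spring constant (force per unit length).
#' @param origin `(x, y)` offset of the cell layer relative to the domain.
#' @return An `rd_population`.
#' @export
cell_population <- function(cells, spring_cutoff = 1.5,
                            spring_stiffness = 1.0, origin = c(0, 0)) {
  ids <- vapply(cells, `[[`, 0L, "id")
  if (anyDuplicated(ids)) stop("cell ids must be unique", call. = FALSE)
  structure(list(cells = cells, spring_cutoff = spring_cutoff,
                 spring_stiffness = spring_stiffness, origin = origin,
                 next_id = if (length(ids)) max(ids) + 1L else 1L),
            class = "rd_population")
}

#' Advance a cell's intracellular reaction network by one time step
#' @param cell An `rd_cell`.
#' @param dt Time step (> 0).
#' @return The cell with updated concentrations.
#' @export
step_intracellular <- function(cell, dt) {
  stopifnot(dt > 0)
  if (is.null(cell$srn) || length(cell$srn$reactions) == 0L) return(cell)
  C <- matrix(cell$conc[cell$srn$species], nrow = 1L)
  C <- .rk4_step(cell$srn, C, dt)
  if (!all(is.finite(C)))
    stop(sprintf("intracellular solver failure in cell %d", cell$id),
         call. = FALSE)
  cell$conc[cell$srn$species] <- as.vector(C)
  cell
}

#' Does a cell meet its division trigger?
#'
#' True iff any thresholded species' concentration has reached its maximum
#' threshold.
#' @param cell An `rd_cell`.
#' @export
check_division <- function(cell) {
  th <- cell$thresholds
  if (is.null(th) || nrow(th) == 0L) return(FALSE)
  vals <- cell$conc[th$species]
  vals[is.na(vals)] <- 0
  any(vals >= th$max)
}

#' Does a cell meet its death trigger?
#'
#' True iff any thresholded species' concentration has fallen below its
#' minimum threshold.
#' @param cell An `rd_cell`.
#' @export
check_death <- function(cell) {
  th <- cell$thresholds
  if (is.null(th) || nrow(th) == 0L) return(FALSE)
  vals <- cell$conc[th$species]
  vals[is.na(vals)] <- 0
  any(vals < th$min)
}

#' Divide a cell
#'
#' The parent keeps fraction `rho` of every intracellular species and the
#' daughter receives `1 - rho` (totals are conserved exactly).  The daughter
#' inherits the parent's type, reactions and thresholds, takes a fresh id,
#' and is placed at distance `displacement` from the parent at a uniformly
#' random angle drawn from the current RNG stream.
#'
#' @param cell The dividing `rd_cell`.
#' @param new_id Integer id for the daughter.
#' @param displacement Daughter placement distance (one mesh spacing in a
#'   full simulation).
#' @return List with `parent` and `daughter` cells.
#' @export
divide_cell <- function(cell, new_id, displacement = 1.0) {
  theta <- stats::runif(1L, 0, 2 * pi)
  daughter <- cell
  daughter$id <- as.integer(new_id)
  daughter$conc <- cell$conc * (1 - cell$rho)
  daughter$pos <- cell$pos + displacement * c(cos(theta), sin(theta))
  cell$conc <- cell$conc * cell$rho
  list(parent = cell, daughter = daughter)
}

# death then division for a whole population; daughters are displaced by one
# mesh spacing and clamped inside the domain
apply_cell_rules <- function(pop, mesh) {
  if (!length(pop$cells)) return(pop)
  alive <- !vapply(pop$cells, check_death, TRUE)
  pop$cells <- pop$cells[alive]
  new_cells <- list()
  for (i in seq_along(pop$cells)) {
    if (check_division(pop$cells[[i]])) {
      res <- divide_cell(pop$cells[[i]], pop$next_id,
                         displacement = mesh$spacing)
      pop$next_id <- pop$next_id + 1L
      res$daughter$pos <- .clamp_position(res$daughter$pos, mesh)
      pop$cells[[i]] <- res$parent
      new_cells[[length(new_cells) + 1L]] <- res$daughter
    }
  }
  pop$cells <- c(pop$cells, new_cells)
  pop
}

.clamp_position <- function(pos, mesh) {
  pmin(pmax(pos, c(0, 0)), c(mesh$extent[["width"]], mesh$extent[["height"]]))
}

#' Update cell positions under pairwise Hookean spring forces
#'
#' Cells closer than `spring_cutoff` interact through a linear spring of
#' rest length `spring_cutoff / 2`: overlapping cells repel, cells between
#' the rest length and the cutoff attract.  Motion is overdamped with unit
#' drag, `position <- position + dt * sum(forces)`, and positions are
#' clamped inside the domain when a mesh is supplied.
#'
#' @param pop An `rd_population`.
#' @param dt Time step (> 0).
#' @param mesh Optional `rd_mesh` used to clamp positions.
#' @return The population with updated positions.
#' @export
update_positions <- function(pop, dt, mesh = NULL) {
  stopifnot(dt > 0)
  n <- length(pop$cells)
  if (n < 2L) return(pop)
  P <- t(vapply(pop$cells, `[[`, numeric(2), "pos"))
  F <- matrix(0, n, 2L)
  cutoff <- pop$spring_cutoff
  rest <- cutoff / 2
  kS <- pop$spring_stiffness
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- P[j, ] - P[i, ]
      r <- sqrt(sum(d * d))
      if (r >= cutoff || r == 0) next
      # force on j along +d when stretched beyond rest length is attractive
      f <- kS * (r - rest) * d / r
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  for (i in seq_len(n)) {
    pos <- P[i, ] + dt * F[i, ]
    if (!is.null(mesh)) pos <- .clamp_position(pos, mesh)
    pop$cells[[i]]$pos <- pos
  }
  pop
}
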