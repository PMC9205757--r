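# Bulk-cell coupling: each cell is bound to its nearest mesh node and
# exchanges chemicals with that node's lumped volume share.  Transport
# reactions move amount across the membrane (conservatively); membrane
# reactions advance a paired outer/inner reaction with one shared rate and
# exchange no species.
#
# Unit convention: the cell state is an amount-like concentration in a unit
# cell volume, so a transported amount R*dt changes the cell concentration
# by R*dt and the bulk nodal concentration by R*dt / volume_share.

#' Bind every cell to its nearest mesh node
#'
#' Ties (a cell equidistant from several nodes) are broken toward the
#' lowest node index; several cells may share one node.
#'
#' @param pop An `rd_population`.
#' @param mesh An `rd_mesh`.
#' @return List of bindings, one per cell (in `pop$cells` order), each with
#'   `cell_id`, `node` and `share` (the node's lumped volume share).
#' @export
bind_cells <- function(pop, mesh) {
  shares <- nodal_volume_share(mesh)
  h <- mesh$spacing
  nx <- mesh$nx; ny <- mesh$ny
  lapply(pop$cells, function(cl) {
    x <- cl$pos[1]; y <- cl$pos[2]
    if (x < 0 || y < 0 || x > mesh$extent[["width"]] ||
        y > mesh$extent[["height"]])
      stop(sprintf("cell %d lies outside the domain at (%g, %g)",
                   cl$id, x, y), call. = FALSE)
    ix_cand <- unique(pmin(pmax(c(floor(x / h), ceiling(x / h)), 0), nx))
    iy_cand <- unique(pmin(pmax(c(floor(y / h), ceiling(y / h)), 0), ny))
    cand <- expand.grid(ix = ix_cand, iy = iy_cand)
    idx <- as.integer(cand$iy * (nx + 1L) + cand$ix + 1L)
    d2 <- (cand$ix * h - x)^2 + (cand$iy * h - y)^2
    best <- min(d2)
    node <- min(idx[d2 <= best + 1e-12])
    list(cell_id = cl$id, node = node, share = shares[node])
  })
}

# joint concentration lookup: cell namespace first, then bulk
.joint_conc <- function(names_, cell_conc, bulk_conc) {
  out <- numeric(length(names_))
  for (k in seq_along(names_)) {
    nm <- names_[k]
    out[k] <- if (nm %in% names(cell_conc)) cell_conc[[nm]]
              else if (nm %in% names(bulk_conc)) bulk_conc[[nm]]
              else 0
  }
  out
}

.lk <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0

# shared rate of a coupling reaction evaluated on the joint (bulk, cell)
# state; `bulk_side`/`cell_side` are the stoichiometries driving the forward
# rate, `bulk_rev`/`cell_rev` those driving the reverse rate.
.coupling_rate <- function(law, params, bulk_conc, cell_conc,
                           bulk_side, cell_side, bulk_rev, cell_rev,
                           spectators, enzyme) {
  prod_side <- function(bs, cs) {
    p <- 1
    for (k in seq_along(bs)) p <- p * max(.lk(bulk_conc, names(bs)[k]), 0)^bs[k]
    for (k in seq_along(cs)) p <- p * max(.lk(cell_conc, names(cs)[k]), 0)^cs[k]
    p
  }
  spect <- 1
  for (sp in spectators)
    spect <- spect * max(.joint_conc(sp, cell_conc, bulk_conc), 0)
  switch(law,
    zeroth_order = {
      if ("k" %in% names(params)) params[["k"]]
      else params[["k_f"]] - params[["k_r"]]
    },
    mass_action_irreversible =
      params[["k"]] * prod_side(bulk_side, cell_side) * spect,
    mass_action_reversible =
      (params[["k_f"]] * prod_side(bulk_side, cell_side) -
       params[["k_r"]] * prod_side(bulk_rev, cell_rev)) * spect,
    michaelis_menten = {
      subs <- c(names(bulk_side), names(cell_side))[1]
      S0 <- .joint_conc(subs, cell_conc, bulk_conc)
      E <- .joint_conc(enzyme, cell_conc, bulk_conc)
      params[["k_cat"]] * E * S0 / (params[["K_M"]] + S0)
    },
    stop(sprintf("unsupported coupling rate law '%s'", law), call. = FALSE))
}

# apply a candidate (d_bulk, d_cell) update, rescaling the whole step so no
# concentration goes below zero (conservation is preserved because both
# sides are scaled by the same factor)
.apply_clipped <- function(bulk_conc, cell_conc, d_bulk, d_cell) {
  for (nm in setdiff(names(d_bulk), names(bulk_conc))) bulk_conc[[nm]] <- 0
  for (nm in setdiff(names(d_cell), names(cell_conc))) cell_conc[[nm]] <- 0
  alpha <- 1
  for (nm in names(d_bulk)) {
    if (d_bulk[[nm]] < 0 && bulk_conc[[nm]] + d_bulk[[nm]] < 0)
      alpha <- min(alpha, bulk_conc[[nm]] / -d_bulk[[nm]])
  }
  for (nm in names(d_cell)) {
    if (d_cell[[nm]] < 0 && cell_conc[[nm]] + d_cell[[nm]] < 0)
      alpha <- min(alpha, cell_conc[[nm]] / -d_cell[[nm]])
  }
  for (nm in names(d_bulk))
    bulk_conc[[nm]] <- max(bulk_conc[[nm]] + alpha * d_bulk[[nm]], 0)
  for (nm in names(d_cell))
    cell_conc[[nm]] <- max(cell_conc[[nm]] + alpha * d_cell[[nm]], 0)
  list(bulk = bulk_conc, cell = cell_conc)
}

#' Apply a cell's transport reactions to its bound node
#'
#' Transport reactions are written with bulk species on the left-hand side
#' and intracellular species on the right.  The shared rate `R` is evaluated
#' on the joint state; over one step the cell gains `nu * R * dt` of each
#' right-hand species while the bulk node loses the stoichiometric amount,
#' scaled by `1 / volume_share`, so that total amount
#' (bulk concentration x share + cell amount) is conserved for balanced
#' exchanges.  Updates that would drive a concentration negative are
#' rescaled to stop at zero.
#'
#' @param cell An `rd_cell` carrying transport reactions.
#' @param bulk_conc Named concentration vector at the bound node.
#' @param share The node's lumped volume share (> 0).
#' @param dt Time step.
#' @return List with updated `bulk` (named vector) and `cell`.
#' @export
apply_transport <- function(cell, bulk_conc, share, dt) {
  for (rx in cell$transport) {
    R <- .coupling_rate(rx$law, rx$params, bulk_conc, cell$conc,
                        bulk_side = rx$reactants, cell_side = numeric(0),
                        bulk_rev = numeric(0), cell_rev = rx$products,
                        spectators = rx$spectators, enzyme = rx$enzyme)
    d_bulk <- -rx$reactants * R * dt / share
    d_cell <- rx$products * R * dt
    res <- .apply_clipped(bulk_conc, cell$conc, d_bulk, d_cell)
    bulk_conc <- res$bulk
    cell$conc <- res$cell
  }
  list(bulk = bulk_conc, cell = cell)
}

#' Apply a cell's membrane reactions to its bound node
#'
#' Each membrane line carries an outer (bulk-facing) and an inner
#' (cell-facing) reaction separated by `"|"`.  One shared rate, computed
#' from the reaction law over the union of outer and inner reactants,
#' advances the outer stoichiometry on the bulk node (scaled by the volume
#' share) and the inner stoichiometry on the cell.  No species crosses the
#' membrane.
#'
#' @inheritParams apply_transport
#' @export
apply_membrane <- function(cell, bulk_conc, share, dt) {
  for (rx in cell$membrane) {
    R <- .coupling_rate(rx$law, rx$params, bulk_conc, cell$conc,
                        bulk_side = rx$outer$reactants,
                        cell_side = rx$inner$reactants,
                        bulk_rev = rx$outer$products,
                        cell_rev = rx$inner$products,
                        spectators = rx$spectators, enzyme = rx$enzyme)
    d_bulk <- (.net_stoich(rx$outer)) * R * dt / share
    d_cell <- (.net_stoich(rx$inner)) * R * dt
    res <- .apply_clipped(bulk_conc, cell$conc, d_bulk, d_cell)
    bulk_conc <- res$bulk
    cell$conc <- res$cell
  }
  list(bulk = bulk_conc, cell = cell)
}

.net_stoich <- function(side) {
  nm <- union(names(side$reactants), names(side$products))
  out <- stats::setNames(numeric(length(nm)), nm)
  out[names(side$reactants)] <- out[names(side$reactants)] - side$reactants
  out[names(side$products)] <- out[names(side$products)] + side$products
  out
}

# transport then membrane for one cell at its bound node; used by the
# simulation loop (phase 3)
apply_coupling <- function(cell, bulk_conc, share, dt, species) {
  bc <- stats::setNames(as.numeric(bulk_conc), species)
  res <- apply_transport(cell, bc, share, dt)
  res2 <- apply_membrane(res$cell, res$bulk, share, dt)
  list(bulk = res2$bulk[species], cell = res2$cell)
}
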