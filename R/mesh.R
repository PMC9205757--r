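#' Build a structured triangulated rectangular mesh
#'
#' Constructs the finite-element mesh used for all bulk simulations: a
#' uniform grid of `(nx+1) x (ny+1)` nodes covering the rectangle
#' `[0, nx*spacing] x [0, ny*spacing]`, with every grid square split into two
#' linear triangles along its lower-left to upper-right diagonal.
#'
#' Node indexing is row-major from the lower-left origin: node `i` sits at
#' `(ix * spacing, iy * spacing)` with `i = iy * (nx + 1) + ix + 1` and
#' `ix = 0, ..., nx`, `iy = 0, ..., ny`.  Both triangles of a square list the
#' square's lower-left node first and run counter-clockwise, so
#' `elements[, 1]` always names the lower-left corner of the parent square.
#'
#' @param nx,ny Number of grid squares in x and y (positive integers).
#' @param spacing Grid step `h` in domain length units (positive).
#' @return An object of class `rd_mesh`: a list with `nx`, `ny`, `spacing`,
#'   `extent` (width, height), `coords` (n x 2 matrix of node positions),
#'   `elements` (ne x 3 integer matrix of counter-clockwise node indices),
#'   `elem_area`, `on_boundary` (logical per node), and `labels` /
#'   `elem_label` (filled by [assign_labels()], `NA` until then).
#' @seealso [assign_labels()], [nodal_volume_share()]
#' @examples
#' m <- build_rectangular_mesh(2, 1, 1.0)
#' nrow(m$coords)      # 6 nodes
#' sum(m$elem_area)    # total area 2
#' @export
build_rectangular_mesh <- function(nx, ny, spacing) {
  if (length(nx) != 1L || length(ny) != 1L || length(spacing) != 1L ||
      !is.finite(nx) || !is.finite(ny) || !is.finite(spacing) ||
      nx < 1 || ny < 1 || spacing <= 0 || nx != round(nx) || ny != round(ny)) {
    stop("build_rectangular_mesh: nx, ny must be integers >= 1 and spacing > 0",
         call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  h <- as.numeric(spacing)

  xs <- rep(seq(0L, nx), times = ny + 1L) * h
  ys <- rep(seq(0L, ny), each = nx + 1L) * h
  coords <- cbind(x = xs, y = ys)
  n_nodes <- (nx + 1L) * (ny + 1L)

  # two triangles per grid square, diagonal lower-left -> upper-right
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  ll <- iy * (nx + 1L) + ix + 1L
  lr <- ll + 1L
  ul <- ll + (nx + 1L)
  ur <- ul + 1L
  elements <- rbind(
    cbind(ll, lr, ur),  # lower triangle
    cbind(ll, ur, ul)   # upper triangle
  )
  # interleave so the two triangles of a square are adjacent in memory
  ord <- as.vector(rbind(seq_len(nx * ny), seq_len(nx * ny) + nx * ny))
  elements <- elements[ord, , drop = FALSE]
  dimnames(elements) <- NULL
  storage.mode(elements) <- "integer"

  on_boundary <- coords[, 1] == 0 | coords[, 2] == 0 |
    coords[, 1] == nx * h | coords[, 2] == ny * h

  structure(list(
    nx = nx, ny = ny, spacing = h,
    extent = c(width = nx * h, height = ny * h),
    coords = coords,
    elements = elements,
    elem_area = rep(h * h / 2, nrow(elements)),
    on_boundary = on_boundary,
    labels = rep(NA_character_, n_nodes),
    elem_label = rep(NA_character_, nrow(elements))
  ), class = "rd_mesh")
}

#' @exportS3Method base::print
print.rd_mesh <- function(x, ...) {
  cat(sprintf(
    "rd_mesh: %d x %d squares (h = %g), %d nodes, %d triangles, area %g\n",
    x$nx, x$ny, x$spacing, nrow(x$coords), nrow(x$elements),
    sum(x$elem_area)))
  if (!anyNA(x$labels)) {
    tab <- table(x$labels)
    cat("  subdomain labels:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a domain field
#'
#' The domain field carries the spatial look-up data of a model: the
#' subdomain label grid (a character matrix, rows running top to bottom as
#' written in the topology CSV), the key mapping label tokens to subdomain
#' names, per-(species, subdomain) isotropic diffusivities, the per-subdomain
#' bulk reaction systems, boundary-condition specs and initial conditions.
#'
#' @param label_grid Character matrix of subdomain tokens; the first row is
#'   the top of the domain.
#' @param key Named character vector mapping token -> subdomain name.
#' @param diffusivity Data frame with columns `subdomain`, `species`, `D`
#'   (D >= 0); subdomains are named by their key names, not tokens.
#' @param reactions Named list of [reaction_system()] objects, one per
#'   subdomain name (a subdomain may be absent, meaning no bulk reactions
#'   there).
#' @param boundary Data frame with columns `species`, `kind`
#'   (`"neumann"`, `"dirichlet"` or `"periodic"`) and `value`; one row per
#'   species.  Missing species default to zero-flux Neumann.
#' @param initial Data frame with columns `subdomain`, `species`, `value`,
#'   `perturb` (perturbation half-width; 0 means no perturbation).
#' @return An object of class `rd_domain_field`.
#' @export
domain_field <- function(label_grid, key, diffusivity,
                         reactions = list(), boundary = NULL,
                         initial = NULL) {
  label_grid <- as.matrix(label_grid)
  storage.mode(label_grid) <- "character"
  if (any(is.na(label_grid)) || length(label_grid) == 0L)
    stop("domain_field: label_grid must be a non-empty character matrix",
         call. = FALSE)
  unknown <- setdiff(unique(as.vector(label_grid)), names(key))
  if (length(unknown))
    stop(sprintf("domain_field: label(s) %s missing from the domain key",
                 paste(shQuote(unknown), collapse = ", ")), call. = FALSE)
  diffusivity <- as.data.frame(diffusivity)
  need <- c("subdomain", "species", "D")
  if (!all(need %in% names(diffusivity)))
    stop("domain_field: diffusivity needs columns subdomain, species, D",
         call. = FALSE)
  if (any(diffusivity$D < 0))
    stop("domain_field: diffusivities must be >= 0", call. = FALSE)
  bad_sub <- setdiff(diffusivity$subdomain, unname(key))
  if (length(bad_sub))
    stop(sprintf("domain_field: diffusion table names unknown subdomain(s) %s",
                 paste(shQuote(bad_sub), collapse = ", ")), call. = FALSE)
  if (!is.null(boundary)) {
    boundary <- as.data.frame(boundary)
    stopifnot(all(c("species", "kind", "value") %in% names(boundary)))
    bad <- setdiff(boundary$kind, c("neumann", "dirichlet", "periodic"))
    if (length(bad))
      stop(sprintf("domain_field: unknown boundary condition kind %s",
                   paste(shQuote(bad), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(initial)) initial <- as.data.frame(initial)
  structure(list(
    label_grid = label_grid,
    key = key,
    diffusivity = diffusivity,
    reactions = reactions,
    boundary = boundary,
    initial = initial
  ), class = "rd_domain_field")
}

#' Look up a diffusivity for a species in a subdomain
#' @param field An `rd_domain_field`.
#' @param species,subdomain Tokens naming the species and subdomain.
#' @return The scalar diffusion coefficient.
#' @keywords internal
field_diffusivity <- function(field, species, subdomain) {
  d <- field$diffusivity
  hit <- d$species == species & d$subdomain == subdomain
  if (!any(hit))
    stop(sprintf(
      "no diffusivity configured for species '%s' in subdomain '%s'",
      species, subdomain), call. = FALSE)
  d$D[which(hit)[1L]]
}

#' Attach subdomain labels to mesh nodes
#'
#' The label grid is stretched to the mesh extent; each node takes the label
#' of the closed topology cell containing it, with points on a cell boundary
#' resolved toward the lower-left cell.  Element labels (used to pick the
#' element diffusivity during assembly) are taken from each element's
#' lower-left node.
#'
#' @param mesh An `rd_mesh`.
#' @param field An `rd_domain_field` (or a bare character matrix plus `key`).
#' @return The mesh with `labels` and `elem_label` filled in.
#' @export
assign_labels <- function(mesh, field) {
  stopifnot(inherits(mesh, "rd_mesh"))
  grid <- field$label_grid
  key <- field$key
  nr <- nrow(grid); nc <- ncol(grid)
  cw <- mesh$extent[["width"]] / nc
  ch <- mesh$extent[["height"]] / nr
  eps <- 1e-9
  # closed-cell membership with ties toward the lower-left cell
  col <- pmin(pmax(ceiling(mesh$coords[, 1] / cw - eps), 1L), nc)
  row_from_bottom <- pmin(pmax(ceiling(mesh$coords[, 2] / ch - eps), 1L), nr)
  row <- nr - row_from_bottom + 1L
  labels <- grid[cbind(row, col)]
  unknown <- setdiff(unique(labels), names(key))
  if (length(unknown))
    stop(sprintf("assign_labels: label(s) %s missing from the domain key",
                 paste(shQuote(unknown), collapse = ", ")), call. = FALSE)
  mesh$labels <- labels
  mesh$elem_label <- labels[mesh$elements[, 1]]
  mesh
}

#' Lumped nodal volume share
#'
#' Returns, for each requested node, one third of the summed areas of the
#' triangles containing it: the diagonal of the lumped finite-element mass
#' operator.  The shares over all nodes partition the domain area, and this
#' is the `volume' assigned to a point-like cell bound to a node, i.e. the
#' conversion factor between a nodal concentration and a chemical amount.
#'
#' @param mesh An `rd_mesh`.
#' @param node_index Node index (1-based) or vector of indices; `NULL`
#'   (default) returns the share of every node.
#' @return Numeric vector of areas.
#' @export
nodal_volume_share <- function(mesh, node_index = NULL) {
  stopifnot(inherits(mesh, "rd_mesh"))
  n <- nrow(mesh$coords)
  shares <- numeric(n)
  contrib <- rep(mesh$elem_area / 3, 3L)
  idx <- as.vector(mesh$elements)
  agg <- rowsum(contrib, idx)
  shares[as.integer(rownames(agg))] <- agg[, 1]
  if (is.null(node_index)) return(shares)
  if (any(node_index < 1 | node_index > n | node_index != round(node_index)))
    stop(sprintf("nodal_volume_share: node index out of range 1..%d", n),
         call. = FALSE)
  shares[node_index]
}

#' Half-edge length share of boundary nodes
#'
#' Used to discretize nonzero Neumann fluxes: a prescribed boundary flux
#' enters a boundary node weighted by half the total length of the boundary
#' edges adjacent to it.
#' @return Numeric vector over all nodes (zero for interior nodes).
#' @keywords internal
boundary_edge_share <- function(mesh) {
  h <- mesh$spacing
  n <- nrow(mesh$coords)
  share <- numeric(n)
  on_b <- mesh$on_boundary
  # on a structured rectangle every boundary node has exactly two adjacent
  # boundary edges of length h (corners: one per side)
  share[on_b] <- h
  share
}
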