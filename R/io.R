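# File-based model interface.
#
# A model directory holds a "key = value" configuration file plus plain-text
# tables: DomainTopology.csv (matrix of subdomain tokens, first row = top of
# the domain), DomainKey.csv ("token,name" lines), Diffusion.csv
# (subdomain,species,D), InitialConditions.csv
# (subdomain,species,value,perturb), BoundaryConditions.csv
# (species,bc_type,bc_value), BulkReactions.csv (subdomain,file) pointing at
# per-subdomain reaction TXT files.  Cell-coupled models add a Cells/
# directory with CellLayerTopology.csv (numeric ids, 0 = empty),
# CellLayerKey.csv (id,type), and one subdirectory per cell type holding
# InitialCellConcentrations.csv, SpeciesThreshold.csv, Srn.txt,
# TransportReactions.txt and MembraneReactions.txt.

.read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("config %s: malformed line '%s' (expected key = value)",
                   path, ln), call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- val
  }
  out
}

.cfg_num <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) as.numeric(cfg[[key]])
  else if (!is.null(default)) default
  else stop(sprintf("config: missing required key '%s'", key), call. = FALSE)
}

.cfg_chr <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]]
  else if (!is.null(default)) default
  else stop(sprintf("config: missing required key '%s'", key), call. = FALSE)
}

.read_label_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(lines, ","), trimws)
  if (length(unique(lengths(rows))) != 1L)
    stop(sprintf("%s: topology rows have unequal lengths", path),
         call. = FALSE)
  do.call(rbind, rows)
}

.read_key_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",")
  stats::setNames(vapply(parts, function(p) trimws(p[2]), ""),
                  vapply(parts, function(p) trimws(p[1]), ""))
}

#' Load and validate a model directory
#'
#' Parses the configuration file and every referenced table and reaction
#' file into a validated [rd_model()].  All detected problems (missing
#' files, unknown species or subdomains, malformed reaction lines,
#' mismatched PDE count) are collected and reported together in one error.
#'
#' @param config_path Path to the configuration file; all other paths are
#'   resolved relative to its directory.
#' @param overrides Named list of configuration overrides (e.g.
#'   `list(end_time = 40, element_spacing = 0.5)`).
#' @return An `rd_model`.
#' @export
load_model <- function(config_path, overrides = list()) {
  if (!file.exists(config_path))
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  root <- dirname(config_path)
  cfg <- .read_config(config_path)
  for (k in names(overrides)) cfg[[k]] <- as.character(overrides[[k]])
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(root, p)

  need_file <- function(key, default = NULL) {
    p <- rel(.cfg_chr(cfg, key, default))
    if (!file.exists(p)) {
      note(sprintf("missing file for %s: %s", key, p))
      NULL
    } else p
  }

  sim_type <- .cfg_chr(cfg, "simulation_type", "domain_only")
  if (!sim_type %in% c("domain_only", "cell_coupled"))
    note(sprintf("unknown simulation_type '%s'", sim_type))

  topo_path <- need_file("domain_topology_file", "DomainTopology.csv")
  key_path <- need_file("domain_key_file", "DomainKey.csv")
  diff_path <- need_file("diffusion_file", "Diffusion.csv")
  init_path <- need_file("initial_conditions_file", "InitialConditions.csv")
  bc_path <- need_file("boundary_conditions_file", "BoundaryConditions.csv")
  rxmap_path <- need_file("bulk_reactions_file", "BulkReactions.csv")
  if (length(problems))
    stop(paste(c("model validation failed:", problems), collapse = "\n  - "),
         call. = FALSE)

  grid <- .read_label_grid(topo_path)
  key <- .read_key_file(key_path)
  unknown <- setdiff(unique(as.vector(grid)), names(key))
  if (length(unknown))
    note(sprintf("topology label(s) %s missing from the domain key",
                 paste(shQuote(unknown), collapse = ", ")))

  diffusion <- utils::read.csv(diff_path, stringsAsFactors = FALSE,
                               strip.white = TRUE)
  names(diffusion) <- c("subdomain", "species", "D")[seq_along(names(diffusion))]
  species <- unique(diffusion$species)
  n_pdes <- .cfg_num(cfg, "number_of_pdes", length(species))
  if (n_pdes != length(species))
    note(sprintf("number_of_pdes is %g but the diffusion table defines %d species (%s)",
                 n_pdes, length(species), paste(species, collapse = ", ")))

  initial <- utils::read.csv(init_path, stringsAsFactors = FALSE,
                             strip.white = TRUE)
  names(initial) <- c("subdomain", "species", "value",
                      "perturb")[seq_along(names(initial))]
  bad <- setdiff(initial$species, species)
  if (length(bad))
    note(sprintf("initial conditions name unknown species: %s",
                 paste(bad, collapse = ", ")))

  bcs <- utils::read.csv(bc_path, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  names(bcs) <- c("species", "kind", "value")[seq_along(names(bcs))]
  bad <- setdiff(bcs$species, species)
  if (length(bad))
    note(sprintf("boundary conditions name unknown species: %s",
                 paste(bad, collapse = ", ")))
  bad <- setdiff(bcs$kind, c("neumann", "dirichlet", "periodic"))
  if (length(bad))
    note(sprintf("unknown boundary condition kind(s): %s",
                 paste(bad, collapse = ", ")))

  rxmap <- utils::read.csv(rxmap_path, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  names(rxmap) <- c("subdomain", "file")[seq_along(names(rxmap))]
  reactions <- list()
  for (r in seq_len(nrow(rxmap))) {
    p <- rel(rxmap$file[r])
    if (!file.exists(p)) {
      note(sprintf("missing bulk reaction file for subdomain '%s': %s",
                   rxmap$subdomain[r], p))
      next
    }
    rx <- tryCatch(parse_reaction_file(p, "bulk"),
                   error = function(e) {note(conditionMessage(e)); NULL})
    if (is.null(rx)) next
    sys <- tryCatch(reaction_system(species, rx),
                    error = function(e) {
                      note(sprintf("subdomain '%s': %s", rxmap$subdomain[r],
                                   conditionMessage(e)))
                      NULL})
    if (!is.null(sys)) reactions[[rxmap$subdomain[r]]] <- sys
  }

  population <- NULL
  if (sim_type == "cell_coupled") {
    res <- .load_cell_layer(cfg, rel, note)
    population <- res
  }

  if (length(problems))
    stop(paste(c("model validation failed:", problems), collapse = "\n  - "),
         call. = FALSE)

  field <- domain_field(grid, key, diffusion, reactions, bcs, initial)
  h <- .cfg_num(cfg, "element_spacing", 1)
  width <- .cfg_num(cfg, "domain_width")
  height <- .cfg_num(cfg, "domain_height")
  mesh <- build_rectangular_mesh(round(width / h), round(height / h), h)
  settings <- solver_settings(
    dt = .cfg_num(cfg, "time_step", 0.01),
    t_end = .cfg_num(cfg, "end_time"),
    sampling_interval = .cfg_num(cfg, "sampling_rate",
                                 .cfg_num(cfg, "time_step", 0.01)))
  model <- rd_model(mesh, field, species, settings, population = population,
                    seed = as.integer(.cfg_num(cfg, "rng_seed", 0)),
                    name = basename(normalizePath(root)))
  model$output_dir <- .cfg_chr(cfg, "output_directory", "output")
  model$config <- cfg
  model
}

.load_cell_layer <- function(cfg, rel, note) {
  root <- rel(.cfg_chr(cfg, "cell_file_root", "Cells"))
  if (!dir.exists(root)) {
    note(sprintf("missing cell directory: %s", root))
    return(NULL)
  }
  topo_p <- file.path(root, "CellLayerTopology.csv")
  key_p <- file.path(root, "CellLayerKey.csv")
  for (p in c(topo_p, key_p)) if (!file.exists(p)) {
    note(sprintf("missing cell layer file: %s", p))
    return(NULL)
  }
  grid <- .read_label_grid(topo_p)
  key <- .read_key_file(key_p)
  spacing <- .cfg_num(cfg, "cell_grid_spacing", 1)
  origin <- c(.cfg_num(cfg, "cell_mesh_origin_x", 0),
              .cfg_num(cfg, "cell_mesh_origin_y", 0))
  rho <- .cfg_num(cfg, "division_fraction", 0.5)

  types <- list()
  for (id in setdiff(unique(as.vector(grid)), "0")) {
    if (!id %in% names(key)) {
      note(sprintf("cell id '%s' missing from CellLayerKey.csv", id))
      next
    }
    type <- key[[id]]
    tdir <- file.path(root, type)
    if (!dir.exists(tdir)) {
      note(sprintf("missing cell type directory: %s", tdir))
      next
    }
    conc_p <- file.path(tdir, "InitialCellConcentrations.csv")
    th_p <- file.path(tdir, "SpeciesThreshold.csv")
    if (!file.exists(conc_p)) {
      note(sprintf("missing file: %s", conc_p)); next
    }
    conc <- utils::read.csv(conc_p, stringsAsFactors = FALSE,
                            strip.white = TRUE)
    names(conc) <- c("species", "value", "perturb")[seq_along(names(conc))]
    thresholds <- NULL
    if (file.exists(th_p)) {
      thresholds <- utils::read.csv(th_p, stringsAsFactors = FALSE,
                                    strip.white = TRUE)
      names(thresholds) <- c("species", "max", "min")[seq_along(names(thresholds))]
    }
    read_rx <- function(fname, context) {
      p <- file.path(tdir, fname)
      if (!file.exists(p)) return(list())
      tryCatch(parse_reaction_file(p, context),
               error = function(e) {note(conditionMessage(e)); list()})
    }
    srn_rx <- read_rx("Srn.txt", "cell")
    srn <- NULL
    if (length(srn_rx)) {
      sp <- unique(c(conc$species, unlist(lapply(srn_rx, function(r)
        c(names(r$reactants), names(r$products), r$spectators,
          if (!is.na(r$enzyme)) r$enzyme)))))
      srn <- tryCatch(reaction_system(sp, srn_rx),
                      error = function(e) {note(conditionMessage(e)); NULL})
    }
    types[[type]] <- list(
      conc = stats::setNames(conc$value, conc$species),
      perturb = stats::setNames(conc$perturb, conc$species),
      thresholds = thresholds, srn = srn,
      transport = read_rx("TransportReactions.txt", "transport"),
      membrane = read_rx("MembraneReactions.txt", "membrane"))
  }

  cells <- list()
  next_id <- 1L
  nr <- nrow(grid)
  for (r in seq_len(nr)) for (cl in seq_len(ncol(grid))) {
    id <- grid[r, cl]
    if (id == "0" || !id %in% names(key)) next
    type <- key[[id]]
    if (is.null(types[[type]])) next
    def <- types[[type]]
    pos <- origin + c((cl - 1) * spacing, (nr - r) * spacing)
    cell <- new_cell(next_id, type, pos, conc = def$conc, srn = def$srn,
                     transport = def$transport, membrane = def$membrane,
                     thresholds = def$thresholds, rho = rho)
    if (any(def$perturb > 0)) cell$perturb <- def$perturb
    cells[[next_id]] <- cell
    next_id <- next_id + 1L
  }
  if (!length(cells)) return(NULL)
  cell_population(cells,
                  spring_cutoff = .cfg_num(cfg, "linear_force_cutoff", 1.5),
                  spring_stiffness = .cfg_num(cfg, "spring_stiffness", 1),
                  origin = origin)
}

# ---------------------------------------------------------------------------
# exemplar writer

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.write_domain_files <- function(model, out_dir, extra = character(0)) {
  field <- model$field
  writeLines(apply(field$label_grid, 1, paste, collapse = ","),
             file.path(out_dir, "DomainTopology.csv"))
  writeLines(paste(names(field$key), unname(field$key), sep = ","),
             file.path(out_dir, "DomainKey.csv"))
  .write_csv(field$diffusivity, file.path(out_dir, "Diffusion.csv"))
  .write_csv(field$initial, file.path(out_dir, "InitialConditions.csv"))
  .write_csv(field$boundary, file.path(out_dir, "BoundaryConditions.csv"))
  rxmap <- data.frame(subdomain = character(0), file = character(0))
  for (sub in names(field$reactions)) {
    fname <- sprintf("Reactions_%s.txt", sub)
    writeLines(vapply(field$reactions[[sub]]$reactions, serialize_reaction, ""),
               file.path(out_dir, fname))
    rxmap <- rbind(rxmap, data.frame(subdomain = sub, file = fname))
  }
  .write_csv(rxmap, file.path(out_dir, "BulkReactions.csv"))

  st <- model$settings
  cfg <- c(
    sprintf("simulation_type = %s",
            if (is.null(model$population)) "domain_only" else "cell_coupled"),
    "output_directory = output",
    sprintf("end_time = %g", st$t_end),
    sprintf("time_step = %g", st$dt),
    sprintf("sampling_rate = %g", st$sampling_interval),
    sprintf("number_of_pdes = %d", length(model$species)),
    sprintf("domain_width = %g", model$mesh$extent[["width"]]),
    sprintf("domain_height = %g", model$mesh$extent[["height"]]),
    sprintf("element_spacing = %g", model$mesh$spacing),
    "domain_topology_file = DomainTopology.csv",
    "domain_key_file = DomainKey.csv",
    "diffusion_file = Diffusion.csv",
    "initial_conditions_file = InitialConditions.csv",
    "boundary_conditions_file = BoundaryConditions.csv",
    "bulk_reactions_file = BulkReactions.csv",
    sprintf("rng_seed = %d", model$seed),
    extra)
  writeLines(cfg, file.path(out_dir, "config.txt"))
  file.path(out_dir, "config.txt")
}

#' Write a bundled exemplar model directory
#'
#' Emits a complete, loadable model directory for one of the bundled
#' exemplars: `fisher_kpp` (unit-parameter invasion wave),
#' `schnakenberg_oscillation` / `schnakenberg_pattern` (the two
#' Schnakenberg regimes) or `cooperator_cheater` (the public-goods cell
#' model, written with its long default end time of 10000).
#'
#' @param name Exemplar name.
#' @param out_dir Output directory (created if needed).
#' @return The path of the written configuration file, invisibly.
#' @export
write_exemplar <- function(name = c("fisher_kpp", "schnakenberg_oscillation",
                                    "schnakenberg_pattern",
                                    "cooperator_cheater"),
                           out_dir) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "fisher_kpp") {
    model <- fisher_kpp_model()
    cfg <- .write_domain_files(model, out_dir)
  } else if (name == "schnakenberg_oscillation") {
    model <- schnakenberg_model("oscillation", dt = 0.05, t_end = 500,
                                sampling_interval = 1)
    cfg <- .write_domain_files(model, out_dir)
  } else if (name == "schnakenberg_pattern") {
    model <- schnakenberg_model("pattern")
    cfg <- .write_domain_files(model, out_dir)
  } else {
    model <- cooperator_cheater_model(t_end = 10000, sampling_interval = 10)
    extra <- c(
      "cell_file_root = Cells",
      sprintf("cell_mesh_origin_x = %g", model$population$origin[1]),
      sprintf("cell_mesh_origin_y = %g", model$population$origin[2]),
      "cell_grid_spacing = 2",
      sprintf("linear_force_cutoff = %g", model$population$spring_cutoff),
      sprintf("spring_stiffness = %g", model$population$spring_stiffness),
      "division_fraction = 0.5")
    cfg <- .write_domain_files(model, out_dir, extra)
    cells_dir <- file.path(out_dir, "Cells")
    dir.create(cells_dir, showWarnings = FALSE)
    writeLines("1,2", file.path(cells_dir, "CellLayerTopology.csv"))
    writeLines(c("1,Cooperator", "2,Cheater"),
               file.path(cells_dir, "CellLayerKey.csv"))
    for (type in c("Cooperator", "Cheater")) {
      tdir <- file.path(cells_dir, type)
      dir.create(tdir, showWarnings = FALSE)
      def <- .cc_cell_type(type)
      .write_csv(def$conc, file.path(tdir, "InitialCellConcentrations.csv"))
      .write_csv(def$thresholds, file.path(tdir, "SpeciesThreshold.csv"))
      writeLines(def$srn, file.path(tdir, "Srn.txt"))
      writeLines(def$transport, file.path(tdir, "TransportReactions.txt"))
      writeLines(def$membrane, file.path(tdir, "MembraneReactions.txt"))
    }
  }
  invisible(cfg)
}
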