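# Model files (YAML), end-to-end yield scans, and tabular outputs.
#
# Units policy: energies in kB*T (beta = 1 unless stated), lengths in the
# sphere diameter d (toy/protein systems) or the cage radius R,
# concentrations in the inverse cubic length unit. Output tables carry the
# Monte Carlo seed and sample count of every row.

#' Bundle species, interactions and candidate structures into a model
#'
#' @param species named list of [building_block()]s.
#' @param interactions an [interaction_table()] (or `NULL`).
#' @param repulsion a [repulsion_params()] (or `NULL`).
#' @param structures list of [cluster_structure()]s (the candidate
#'   equilibrium structures, including every monomer).
#' @param extra free-form metadata preserved on round trip.
#' @return object of class `assembly_model`.
#' @export
assembly_model <- function(species, interactions = NULL, repulsion = NULL,
                           structures = list(), extra = list()) {
  stopifnot(is.list(species), length(species) >= 1)
  nm <- names(species)
  if (is.null(nm) || any(!nzchar(nm))) rlang::abort("`species` must be a named list")
  for (s in structures) {
    used <- vapply(s$blocks, function(b) b$block$species_id, character(1))
    miss <- setdiff(used, nm)
    if (length(miss)) {
      rlang::abort(sprintf("structure '%s' references missing species: %s",
                           s$label, paste(miss, collapse = ", ")),
                   class = "assemblyyield_schema_error")
    }
  }
  structure(list(species = species, interactions = interactions,
                 repulsion = repulsion, structures = structures,
                 extra = extra),
            class = "assembly_model")
}

#' Write / read an assembly model as YAML
#'
#' Lossless round trip (floats serialized at 17 significant digits);
#' unknown extra top-level fields in a file are preserved with a warning.
#'
#' @param model an [assembly_model()]; @param path file path.
#' @export
write_model <- function(model, path) {
  ser_block <- function(b) list(
    spheres = apply(b$spheres, 1, as.list, simplify = FALSE),
    sphere_diameters = as.list(b$sphere_diameters),
    patches = if (nrow(b$patches)) apply(b$patches, 1, as.list, simplify = FALSE) else list(),
    patch_types = as.list(b$patch_types),
    isotropic = b$isotropic)
  ser_structure <- function(s) list(
    label = s$label, symmetry_number = s$symmetry_number,
    blocks = lapply(s$blocks, function(bl) list(
      species = bl$block$species_id,
      position = as.list(bl$pose$position),
      orientation = as.list(bl$pose$orientation))))
  doc <- list(
    species = lapply(model$species, ser_block),
    interactions = if (is.null(model$interactions)) NULL else list(
      epsilon = model$interactions$epsilon, alpha = model$interactions$alpha,
      r0 = model$interactions$r0, r_on = model$interactions$r_on,
      r_cut = model$interactions$r_cut,
      pairs = apply(model$interactions$pairs[, c("type_a", "type_b", "p_contact")],
                    1, as.list, simplify = FALSE)),
    repulsion = if (is.null(model$repulsion)) NULL else
      list(A = model$repulsion$A, d = model$repulsion$d),
    structures = lapply(model$structures, ser_structure))
  doc <- c(doc, model$extra)
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("species", "interactions", "repulsion", "structures")
  extra <- doc[setdiff(names(doc), known)]
  if (length(extra)) {
    rlang::warn(paste("unknown model fields preserved:",
                      paste(names(extra), collapse = ", ")))
  }
  if (is.null(doc$species)) {
    rlang::abort("model file is missing the `species` field",
                 class = "assemblyyield_schema_error")
  }
  num_mat <- function(lst) {
    if (length(lst) == 0) return(matrix(numeric(0), ncol = 3))
    do.call(rbind, lapply(lst, function(x) as.numeric(unlist(x))))
  }
  species <- lapply(names(doc$species), function(nm) {
    sp <- doc$species[[nm]]
    building_block(nm, num_mat(sp$spheres),
                   as.numeric(unlist(sp$sphere_diameters)),
                   patches = num_mat(sp$patches),
                   patch_types = as.character(unlist(sp$patch_types)),
                   isotropic = isTRUE(sp$isotropic))
  })
  names(species) <- names(doc$species)
  interactions <- NULL
  if (!is.null(doc$interactions)) {
    it <- doc$interactions
    pairs <- do.call(rbind, lapply(it$pairs, function(p) {
      data.frame(type_a = p$type_a, type_b = p$type_b,
                 p_contact = as.numeric(p$p_contact))
    }))
    interactions <- interaction_table(pairs, epsilon = it$epsilon,
                                      alpha = it$alpha, r0 = it$r0,
                                      r_on = it$r_on, r_cut = it$r_cut)
  }
  repulsion <- if (is.null(doc$repulsion)) NULL else
    repulsion_params(doc$repulsion$A, doc$repulsion$d)
  structures <- lapply(doc$structures, function(st) {
    blocks <- lapply(st$blocks, function(bl) {
      if (is.null(species[[bl$species]])) {
        rlang::abort(sprintf("structure '%s' references missing species '%s'",
                             st$label, bl$species),
                     class = "assemblyyield_schema_error")
      }
      list(block = species[[bl$species]],
           pose = pose(as.numeric(unlist(bl$position)),
                       as.numeric(unlist(bl$orientation))))
    })
    cluster_structure(blocks, symmetry_number = st$symmetry_number,
                      label = st$label)
  })
  assembly_model(species, interactions, repulsion, structures, extra = extra)
}

#' Scan configuration for [run_scan()]
#'
#' @param model an [assembly_model()] or a path to a model file.
#' @param mode `"grand-canonical"` or `"canonical"`.
#' @param beta inverse temperature.
#' @param epsilon_grid vector of global energy scales to sweep.
#' @param totals_grid list of named vectors: per-species total
#'   concentrations (grand-canonical) or counts (canonical), one list
#'   element per grid point.
#' @param n_samples,seed Monte Carlo settings for rotational integrals
#'   (seed is mandatory whenever any structure has oriented blocks).
#' @param volume system volume.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(model, mode = c("grand-canonical", "canonical"),
                        beta = 1, epsilon_grid, totals_grid,
                        n_samples = 1e5, seed = NULL, volume = 1) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "assembly_model"))
  if (length(epsilon_grid) < 1 || length(totals_grid) < 1) {
    rlang::abort("epsilon and totals grids must be nonempty")
  }
  oriented <- any(vapply(model$structures, function(s) {
    any(block_dof(s) == 6L) && n_blocks(s) > 1
  }, logical(1)))
  if (oriented && is.null(seed)) {
    rlang::abort("a `seed` is required: the model has oriented multi-block structures")
  }
  structure(list(model = model, mode = mode, beta = beta,
                 epsilon_grid = epsilon_grid, totals_grid = totals_grid,
                 n_samples = n_samples, seed = seed, volume = volume),
            class = "scan_config")
}

#' Run an end-to-end yield scan
#'
#' For each energy scale in the grid the interface strengths are rescaled,
#' every structure's partition function is recomputed (the Hessian spectrum
#' and rotational Jacobian depend on the potential, so nothing is reused
#' across energy scales), and the ensemble equations are solved at each
#' totals grid point. Deterministic given the seed.
#'
#' @param config a [scan_config()].
#' @return a `yield_scan` tibble: one row per (epsilon, totals point,
#'   structure), with concentration, yield, solver residual, seed and
#'   n_samples.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  model <- config$model
  rows <- list()
  for (eps in config$epsilon_grid) {
    tbl <- if (is.null(model$interactions)) NULL else
      set_epsilon(model$interactions, eps)
    pfs <- lapply(model$structures, function(s) {
      mc <- if (!is.null(config$seed)) {
        mc_config(config$n_samples, config$seed)
      } else NULL
      compute_partition_function(s, tbl, model$repulsion,
                                 beta = config$beta, V = config$volume,
                                 mc = mc, sigma = s$symmetry_number)
    })
    pairs <- Map(function(s, z) list(structure = s, Z = z),
                 model$structures, pfs)
    for (ti in seq_along(config$totals_grid)) {
      totals <- config$totals_grid[[ti]]
      if (config$mode == "grand-canonical") {
        spec <- ensemble_spec(beta = config$beta, volume = config$volume,
                              concentrations = totals)
        sol <- gc_solve(pairs, spec)
        resid <- max(abs(attr(sol, "residuals")))
      } else {
        spec <- ensemble_spec(beta = config$beta, volume = config$volume,
                              counts = totals)
        sol <- canonical_yield(pairs, spec)
        sol$concentration <- NA_real_
        resid <- 0
      }
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        tibble::as_tibble(sol),
        epsilon = eps, totals_id = ti,
        totals = paste(names(totals), totals, sep = "=", collapse = ","),
        residual = resid,
        seed = if (is.null(config$seed)) NA_integer_ else config$seed,
        n_samples = if (is.null(config$seed)) NA_integer_ else
          as.integer(config$n_samples))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("yield_scan", class(out))
  out
}

#' Write a yield table as tab-separated text with a units header
#'
#' @param x a `yield_scan` or `yield_solution` tibble.
#' @param path output path.
#' @export
write_yield_table <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# assemblyyield scan output",
    "# units: energies kB*T; lengths in the model length unit;",
    "#        concentrations in inverse cubic length unit",
    "# MC fields (seed, n_samples) reproduce exactly for the same seed"
  ), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a residue-contact table (TSV)
#'
#' Columns: `chain_a`, `resid_a`, `chain_b`, `resid_b`, `probability`.
#'
#' @param path TSV file path.
#' @return tibble of contacts.
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chain_a", "resid_a", "chain_b", "resid_b", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste("contact table is missing columns:",
                       paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(df)
}
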