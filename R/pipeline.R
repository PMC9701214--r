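# Pipeline: run the three conformational metrics over named conditions
# from one configuration, pooling the landscape fit across conditions (the
# projections are only comparable when every condition shares one scaling
# and basis), and emit a combined machine-readable report.

#' Build an analysis configuration
#'
#' @param conditions Named list; each entry is a list with either file
#'   paths `trajectory` and `reference` (multi-model PDB) or in-memory
#'   `ensemble` and `reference_ensemble` objects, plus an optional `chain`
#'   (default `"A"`).
#' @param regions A `region_set`, or a string parseable by
#'   [parse_regions()]; default [default_loop_regions()].
#' @param donor,acceptor Selection filter lists for the hydride donor and
#'   acceptor atoms, with any of the fields `chain`, `resnum_ranges`,
#'   `atom_names`, `residue_names`, `hetero`.
#' @param threshold Active-pose distance cutoff, Angstroms.
#' @param landscape List of landscape parameters: `bins`, `k`, `seed`,
#'   `mode`.
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(conditions,
                            regions = default_loop_regions(),
                            donor = list(
                              residue_names = "MNA", atom_names = "C4",
                              hetero = TRUE
                            ),
                            acceptor = list(
                              residue_names = "FAD", atom_names = "N5",
                              hetero = TRUE
                            ),
                            threshold = 4.5,
                            landscape = list(
                              bins = 60, k = 3, seed = 0, mode = "raw"
                            ),
                            output_dir = NULL) {
  if (length(conditions) < 1) stop("need at least one condition", call. = FALSE)
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)) ||
    any(names(conditions) == "")) {
    stop("conditions must be uniquely named", call. = FALSE)
  }
  if (is.character(regions)) regions <- parse_regions(regions)
  stopifnot(inherits(regions, "region_set"))
  landscape <- utils::modifyList(
    list(bins = 60, k = 3, seed = 0, mode = "raw"), landscape
  )
  structure(
    list(
      conditions = conditions, regions = regions, donor = donor,
      acceptor = acceptor, threshold = threshold, landscape = landscape,
      output_dir = output_dir
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors [analysis_config()]'s arguments; `regions` may be a
#' `"153-157,177-188,238-242"` style string.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y[intersect(
    names(y),
    c(
      "conditions", "regions", "donor", "acceptor", "threshold",
      "landscape", "output_dir"
    )
  )])
}

# hash over the semantic fields only (output location is not semantic)
config_hash <- function(config) {
  sem <- unclass(config)
  sem$output_dir <- NULL
  rlang::hash(sem)
}

sel_from_filters <- function(x, filters) {
  do.call(select_atoms, c(list(x = x), filters))
}

load_condition <- function(cond) {
  chain <- if (is.null(cond$chain)) "A" else cond$chain
  ens <- if (!is.null(cond$ensemble)) cond$ensemble else read_multimodel_pdb(cond$trajectory)
  ref <- if (!is.null(cond$reference_ensemble)) {
    cond$reference_ensemble
  } else if (!is.null(cond$reference)) {
    read_multimodel_pdb(cond$reference)
  } else {
    subset_frames(ens, 1L)
  }
  list(ensemble = ens, reference = ref, chain = chain)
}

#' Run the full conformational-dynamics analysis
#'
#' Runs the flexibility, hydride-occupancy, and landscape stages for every
#' configured condition. The landscape is always fitted on the pooled
#' conditions of the run. Stage failures are caught, recorded per
#' condition/stage in the report's `failures`, and do not stop the
#' remaining stages.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list with tibbles `flexibility`,
#'   `occupancy`, `landscape_occupancy`, `explained_variance`, a
#'   `failures` tibble, fitted objects under `models`, and a `provenance`
#'   block (config hash, package version, landscape seed, timestamp).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  conds <- names(config$conditions)
  failures <- list()
  note_failure <- function(condition, stage, e) {
    failures[[length(failures) + 1]] <<- tibble::tibble(
      condition = condition, stage = stage, message = conditionMessage(e)
    )
  }

  loaded <- list()
  for (nm in conds) {
    loaded[[nm]] <- tryCatch(
      load_condition(config$conditions[[nm]]),
      error = function(e) {
        note_failure(nm, "load", e)
        NULL
      }
    )
  }

  flex_rows <- list()
  occ_rows <- list()
  flex_models <- list()
  occ_models <- list()
  dihedrals <- list()
  for (nm in conds) {
    lc <- loaded[[nm]]
    if (is.null(lc)) next
    flex_rows[[nm]] <- tryCatch(
      {
        fit_sel <- select_atoms(lc$ensemble, chain = lc$chain, atom_names = "CA")
        reg_sel <- select_atoms(lc$ensemble,
          chain = lc$chain, atom_names = "CA",
          resnum_ranges = regions_as_ranges(config$regions)
        )
        fr <- region_rmsd_series(lc$ensemble, lc$reference, fit_sel, reg_sel)
        flex_models[[nm]] <- fr
        dplyr::mutate(glance(fr), condition = nm, .before = 1)
      },
      error = function(e) {
        note_failure(nm, "flexibility", e)
        NULL
      }
    )
    occ_rows[[nm]] <- tryCatch(
      {
        donor <- sel_from_filters(lc$ensemble, config$donor)
        acceptor <- sel_from_filters(lc$ensemble, config$acceptor)
        ds <- hydride_occupancy(lc$ensemble, donor, acceptor,
          threshold = config$threshold
        )
        occ_models[[nm]] <- ds
        dplyr::mutate(glance(ds), condition = nm, .before = 1)
      },
      error = function(e) {
        note_failure(nm, "hydride", e)
        NULL
      }
    )
    dihedrals[[nm]] <- tryCatch(
      phi_psi_matrix(lc$ensemble, chain = lc$chain, condition = nm),
      error = function(e) {
        note_failure(nm, "landscape", e)
        NULL
      }
    )
  }

  landscape_model <- NULL
  states <- NULL
  landscape_occ <- tibble::tibble(
    condition = character(), state = character(), occupancy = numeric()
  )
  explained <- tibble::tibble(component = integer(), variance = numeric())
  dihedrals <- dihedrals[!vapply(dihedrals, is.null, logical(1))]
  if (length(dihedrals) > 0) {
    ls_par <- config$landscape
    res <- tryCatch(
      {
        landscape_model <- fit_landscape(unname(dihedrals), mode = ls_par$mode)
        states <- kmeans_states(landscape_model, k = ls_par$k, seed = ls_par$seed)
        list(model = landscape_model, states = states)
      },
      error = function(e) {
        note_failure("(pooled)", "landscape", e)
        NULL
      }
    )
    if (!is.null(res)) {
      landscape_occ <- res$states$occupancy
      explained <- tibble::tibble(
        component = seq_along(res$model$explained_variance),
        variance = res$model$explained_variance
      )
    }
  }

  report <- structure(
    list(
      flexibility = dplyr::bind_rows(flex_rows),
      occupancy = dplyr::bind_rows(occ_rows),
      landscape_occupancy = landscape_occ,
      explained_variance = explained,
      failures = if (length(failures) > 0) {
        dplyr::bind_rows(failures)
      } else {
        tibble::tibble(
          condition = character(), stage = character(), message = character()
        )
      },
      models = list(
        flexibility = flex_models, occupancy = occ_models,
        landscape = landscape_model, states = states
      ),
      provenance = list(
        config_hash = config_hash(config),
        package_version = as.character(utils::packageVersion("confdyn")),
        landscape_seed = config$landscape$seed,
        threshold = config$threshold,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "analysis_report"
  )

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write report artifacts (TSV tables + JSON summary)
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$flexibility, file.path(dir, "flexibility_summary.tsv"))
  readr::write_tsv(report$occupancy, file.path(dir, "occupancy_summary.tsv"))
  readr::write_tsv(
    report$landscape_occupancy,
    file.path(dir, "landscape_occupancy.tsv")
  )
  for (nm in names(report$models$flexibility)) {
    readr::write_tsv(
      tidy(report$models$flexibility[[nm]]),
      file.path(dir, paste0("flexibility_", nm, ".tsv"))
    )
  }
  for (nm in names(report$models$occupancy)) {
    readr::write_tsv(
      tidy(report$models$occupancy[[nm]]),
      file.path(dir, paste0("distances_", nm, ".tsv"))
    )
  }
  json <- list(
    flexibility = report$flexibility,
    occupancy = report$occupancy,
    landscape_occupancy = report$landscape_occupancy,
    explained_variance = report$explained_variance,
    failures = report$failures,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n\nLoop flexibility (Angstrom):\n")
  print(x$flexibility)
  cat("\nActive-pose occupancy:\n")
  print(x$occupancy)
  cat("\nConformational state occupancy:\n")
  print(tidyr::pivot_wider(x$landscape_occupancy,
    names_from = "state", values_from = "occupancy"
  ))
  if (nrow(x$failures) > 0) {
    cat("\nFailures:\n")
    print(x$failures)
  }
  invisible(x)
}
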