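#' Parse a run configuration file
#'
#' Reads a YAML configuration describing one experiment, applies defaults and
#' validates it. A seed is mandatory (reproducibility contract); unknown keys
#' are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list of class `thyrodose_config`.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("experiment: table1", "species: man",
#'              "nuclides: I-131", "seed: 1"), cfg)
#' parse_config(cfg)
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config: ",
                                           conditionMessage(e)))
  known <- c("experiment", "seed", "species", "nuclides", "n_histories",
             "output_dir", "distribution", "surface_radius",
             "lumen_diameter", "cell_thickness", "nucleus_diameter",
             "n_surrounding_layers", "diameters", "radii",
             "fractions_in_cells", "placement")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg$experiment <- match.arg(cfg$experiment,
                              c("table1", "sweep", "shells", "layers",
                                "mird-compare", "svalue"))
  if (is.null(cfg$species)) cfg$species <- "man"
  if (is.null(cfg$nuclides)) cfg$nuclides <- c("I-123", "I-125", "I-131")
  if (is.null(cfg$n_histories)) cfg$n_histories <- 1e5
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  if (!is.null(cfg$cell_thickness) && !is.null(cfg$nucleus_diameter) &&
      cfg$nucleus_diameter > cfg$cell_thickness) {
    stop("nucleus_diameter exceeds cell_thickness")
  }
  if (cfg$experiment == "sweep" && is.null(cfg$diameters)) {
    cfg$diameters <- c(10, 20, 50, 100, 150, 200, 300, 400, 500)
  }
  if (cfg$experiment == "svalue" && is.null(cfg$distribution)) {
    cfg$distribution <- "lumen_uniform"
  }
  structure(cfg, class = "thyrodose_config")
}

#' Run a configured experiment
#'
#' Dispatches a parsed configuration to the experiment pipelines, writes the
#' result tables as CSV (Table-1-style scientific notation) and a JSON run
#' manifest that fully determines a rerun.
#'
#' @param config A [parse_config()] result, or a path to a config file.
#' @return Invisibly, a list with `result` (the experiment's data frame or
#'   list) and `files` (paths written).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "thyrodose_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, stem) {
    f <- file.path(config$output_dir, paste0(stem, ".csv"))
    write_results(df, f)
    files <<- c(files, f)
  }
  res <- switch(config$experiment,
    table1 = {
      r <- run_table1(config$species, config$nuclides, config$n_histories,
                      config$seed)
      emit(r, "table1")
      r
    },
    sweep = {
      r <- run_lumen_sweep(config$diameters, config$nuclides,
                           config$n_histories, config$seed)
      emit(r, "lumen_sweep")
      r
    },
    shells = {
      radii <- config$radii
      if (is.null(radii)) {
        outer <- species_preset(config$species)
        radii <- seq(5, outer$lumen_diameter / 2 + outer$cell_thickness, by = 5)
      }
      r <- run_shell_scan(radii, config$nuclides, config$n_histories,
                          config$seed, config$species)
      emit(r, "shell_scan")
      r
    },
    layers = {
      r <- list()
      for (i in seq_along(config$nuclides)) {
        nuc <- config$nuclides[i]
        st <- build_shell_stack(config$species,
                                config$n_surrounding_layers %||%
                                  default_layer_count(config$species, nuc))
        lt <- layer_contributions(st, load_spectrum(nuc),
                                  config$placement %||% "homogeneous",
                                  config$n_histories,
                                  config$seed + 1000L * i)
        emit(lt, paste0("layers_", gsub("-", "", nuc)))
        r[[nuc]] <- lt
      }
      r
    },
    `mird-compare` = {
      r <- run_mird_comparison(config$nuclides,
                               config$fractions_in_cells %||% c(0, 0.25, 0.5, 0.75, 1),
                               config$n_histories, config$seed,
                               config$species)
      emit(r$doses, "mird_comparison")
      r
    },
    svalue = {
      geom <- if (!is.null(config$n_surrounding_layers)) {
        build_shell_stack(config$species, config$n_surrounding_layers)
      } else {
        build_single_follicle(config$species,
                              lumen_diameter = config$lumen_diameter,
                              cell_thickness = config$cell_thickness,
                              nucleus_diameter = config$nucleus_diameter)
      }
      dist <- if (config$distribution == "shell_surface") {
        source_distribution("shell_surface", r = config$surface_radius)
      } else if (config$distribution %in% c("homogeneous", "lumens_only",
                                            "cells_only")) {
        placement_distribution(geom, config$distribution)
      } else {
        source_distribution(config$distribution)
      }
      rows <- list()
      for (i in seq_along(config$nuclides)) {
        sv <- compute_s_value(geom, dist, load_spectrum(config$nuclides[i]),
                              config$n_histories, config$seed + i)
        rows[[i]] <- data.frame(nuclide = config$nuclides[i],
                                total_s = sv$s_total,
                                se = sv$standard_error,
                                beta_s = sv$s_by_component[["beta"]],
                                ce_s = sv$s_by_component[["CE"]],
                                ae_s = sv$s_by_component[["AE"]],
                                stringsAsFactors = FALSE)
      }
      r <- do.call(rbind, rows)
      emit(r, "svalue")
      r
    })
  manifest <- list(
    package = "thyrodose",
    version = as.character(utils::packageVersion("thyrodose")),
    config = unclass(config),
    outputs = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(config$output_dir,
                  paste0(config$experiment, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mf)
  invisible(list(result = res, files = files))
}

#' Write a result table
#'
#' Writes a data frame as CSV (or JSON) with numeric columns rendered in
#' three-significant-figure scientific notation (`1.03E-6` style) for
#' diff-friendly regression files. Percentages and counts are left in plain
#' notation.
#'
#' @param report A data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(report))
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  out <- report
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      nm <- names(out)[j]
      if (grepl("_pct$|^frac|_um$|_layer$", nm)) {
        out[[j]] <- formatC(out[[j]], format = "fg", digits = 4)
      } else {
        out[[j]] <- format_sci(out[[j]])
      }
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write results to ", path)
  invisible(path)
}

#' Three-significant-figure scientific notation
#'
#' @param x Numeric vector.
#' @return Character vector like `"1.03E-6"`.
#' @export
format_sci <- function(x) {
  out <- toupper(sprintf("%.2E", x))
  out <- gsub("E([+-])0(\\d)$", "E\\1\\2", out)
  out[is.na(x)] <- NA_character_
  out
}
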