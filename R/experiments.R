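#' Default number of surrounding follicle layers
#'
#' The number of surrounding layers beyond which the contribution to the
#' central nuclei becomes negligible, per species and nuclide: 2/1/8 for
#' I-123/I-125/I-131 in man, 5/1/10 in mouse, 4/1/16 in rat.
#'
#' @param species `"mouse"`, `"rat"` or `"man"`.
#' @param nuclide_id `"I-123"`, `"I-125"` or `"I-131"`.
#' @return Integer layer count.
#' @export
default_layer_count <- function(species, nuclide_id) {
  tab <- list(man = c("I-123" = 2, "I-125" = 1, "I-131" = 8),
              mouse = c("I-123" = 5, "I-125" = 1, "I-131" = 10),
              rat = c("I-123" = 4, "I-125" = 1, "I-131" = 16))
  if (!species %in% names(tab) || !nuclide_id %in% names(tab[[species]])) {
    stop("no default layer count for ", species, "/", nuclide_id)
  }
  unname(tab[[species]][nuclide_id])
}

#' Single-follicle S-value table
#'
#' S values to the follicle-cell nuclei for each species model and nuclide,
#' with the source homogeneously distributed in the follicle lumen, the
#' follicle cells, or the nuclei themselves, and the AE/CE/beta component
#' breakdown.
#'
#' @param species Character vector of species presets.
#' @param nuclides Character vector of nuclide ids.
#' @param n_histories Decays per configuration.
#' @param seed Integer seed; each configuration derives its own sub-seed, so
#'   the full table is reproducible.
#' @return Data frame with columns `species`, `nuclide`, `source`, `beta_s`,
#'   `beta_pct`, `ce_s`, `ce_pct`, `ae_s`, `ae_pct`, `total_s`, `se`.
#' @export
run_table1 <- function(species = c("mouse", "rat", "man"),
                       nuclides = c("I-123", "I-125", "I-131"),
                       n_histories = 1e5, seed = 1L) {
  sources <- c(lumen = "lumen_uniform", cells = "cells_uniform",
               nuclei = "nuclei_uniform")
  rows <- list()
  run <- 0L
  for (sp in species) {
    geom <- build_single_follicle(sp)
    for (nuc in nuclides) {
      spec <- load_spectrum(nuc)
      for (src in names(sources)) {
        run <- run + 1L
        sv <- compute_s_value(geom, source_distribution(sources[[src]]),
                              spec, n_histories, seed = seed + run)
        rows[[run]] <- data.frame(
          species = sp, nuclide = nuc, source = src,
          beta_s = sv$s_by_component[["beta"]],
          beta_pct = sv$relative_contributions[["beta"]],
          ce_s = sv$s_by_component[["CE"]],
          ce_pct = sv$relative_contributions[["CE"]],
          ae_s = sv$s_by_component[["AE"]],
          ae_pct = sv$relative_contributions[["AE"]],
          total_s = sv$s_total, se = sv$standard_error,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' S value versus follicle lumen diameter
#'
#' Sweeps the lumen diameter with a fixed 10 um cell layer and 8 um nucleus
#' (the human cell dimensions), source homogeneous in the lumen.
#'
#' @param diameters Lumen diameters (um), e.g. 10-500.
#' @param nuclides Nuclide ids.
#' @param n_histories Decays per configuration.
#' @param seed Integer seed.
#' @param cell_thickness,nucleus_diameter Fixed cell dimensions (um).
#' @return Data frame with `diameter_um`, `nuclide`, component S values and
#'   percentages, `total_s`, `se`.
#' @export
run_lumen_sweep <- function(diameters, nuclides = c("I-123", "I-125", "I-131"),
                            n_histories = 1e5, seed = 1L,
                            cell_thickness = 10, nucleus_diameter = 8) {
  if (any(diameters <= 0)) stop("diameters must be positive")
  rows <- list()
  run <- 0L
  for (d in diameters) {
    geom <- build_single_follicle(lumen_diameter = d,
                                  cell_thickness = cell_thickness,
                                  nucleus_diameter = nucleus_diameter)
    for (nuc in nuclides) {
      run <- run + 1L
      sv <- compute_s_value(geom, source_distribution("lumen_uniform"),
                            load_spectrum(nuc), n_histories,
                            seed = seed + run)
      rows[[run]] <- data.frame(
        diameter_um = d, nuclide = nuc,
        beta_s = sv$s_by_component[["beta"]],
        beta_pct = sv$relative_contributions[["beta"]],
        ce_s = sv$s_by_component[["CE"]],
        ce_pct = sv$relative_contributions[["CE"]],
        ae_s = sv$s_by_component[["AE"]],
        ae_pct = sv$relative_contributions[["AE"]],
        total_s = sv$s_total, se = sv$standard_error,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' S value from concentric spherical surface sources
#'
#' Places unit activity on concentric spherical shells of increasing radius
#' in the species model (radius 0 = centre of the central lumen) and reports
#' the S value to the central nuclei, resolving heterogeneous source
#' locations such as the apical cell surface.
#'
#' @param radii Surface radii (um) within the model.
#' @param nuclides Nuclide ids.
#' @param n_histories Decays per radius.
#' @param seed Integer seed.
#' @param species Species preset for the model (default `"man"`).
#' @return Data frame with `radius_um`, `nuclide`, component S values and
#'   percentages, `total_s`, `se`.
#' @export
run_shell_scan <- function(radii, nuclides = c("I-123", "I-125", "I-131"),
                           n_histories = 1e5, seed = 1L, species = "man") {
  rows <- list()
  run <- 0L
  for (nuc in nuclides) {
    spec <- load_spectrum(nuc)
    geom <- build_shell_stack(species, default_layer_count(species, nuc))
    for (r in radii) {
      run <- run + 1L
      dist <- if (r == 0) {
        source_distribution("shell_surface", r = 1e-6)
      } else {
        source_distribution("shell_surface", r = r)
      }
      sv <- compute_s_value(geom, dist, spec, n_histories, seed = seed + run)
      rows[[run]] <- data.frame(
        radius_um = r, nuclide = nuc,
        beta_s = sv$s_by_component[["beta"]],
        beta_pct = sv$relative_contributions[["beta"]],
        ce_s = sv$s_by_component[["CE"]],
        ce_pct = sv$relative_contributions[["CE"]],
        ae_s = sv$s_by_component[["AE"]],
        ae_pct = sv$relative_contributions[["AE"]],
        total_s = sv$s_total, se = sv$standard_error,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple-follicle doses versus the MIRD formalism
#'
#' For each nuclide, builds the species multiple-follicle stack, computes
#' per-compartment S values to the central nuclei, normalises the cumulated
#' specific activity so that the MIRD formalism (at its decay-data mean
#' energy and absorbed fraction 1) gives exactly 1 Gy, and reports the model
#' mean absorbed dose for homogeneous, lumens-only, cells-only and fractional
#' activity placements.
#'
#' @param nuclides Nuclide ids.
#' @param fractions_in_cells Fractions of the cumulated activity placed in
#'   the follicle cells (remainder in the lumens); 0 is lumens-only, 1 is
#'   cells-only.
#' @param n_histories Total decays per nuclide for the per-compartment S
#'   values.
#' @param seed Integer seed.
#' @param species Species preset (default `"man"`).
#' @return A list with `doses` (data frame: `nuclide`, `placement`,
#'   `frac_cells`, `csa_TBq_s_kg` over the whole tissue, `dose_Gy`,
#'   `dose_from_lumens_Gy`, `dose_from_cells_Gy`, `dose_se`,
#'   `pct_vs_mird`) and `layers` (the per-nuclide [layer_contributions()]
#'   tables, for the layer decomposition).
#' @export
run_mird_comparison <- function(nuclides = c("I-123", "I-125", "I-131"),
                                fractions_in_cells = c(0, 0.25, 0.5, 0.75, 1),
                                n_histories = 2e5, seed = 1L,
                                species = "man") {
  doses <- list()
  layers <- list()
  for (i in seq_along(nuclides)) {
    nuc <- nuclides[i]
    st <- build_shell_stack(species, default_layer_count(species, nuc))
    lc <- layer_contributions(st, load_spectrum(nuc), "homogeneous",
                              n_histories, seed = seed + 1000L * i)
    layers[[nuc]] <- lc
    ct <- required_csa(1, mird_mean_energy(nuc))
    placements <- c(list(homogeneous = "homogeneous"),
                    as.list(setNames(fractions_in_cells,
                                     sprintf("cells_%g", fractions_in_cells))))
    for (pl in names(placements)) {
      act <- redistribute_activity(ct, st, placements[[pl]])
      act <- act[match(lc$name, act$name), ]
      d_c <- act$cumulated_activity_Bq_s * lc$s_value
      se_c <- act$cumulated_activity_Bq_s * lc$se
      doses[[length(doses) + 1L]] <- data.frame(
        nuclide = nuc, placement = pl,
        frac_cells = if (is.numeric(placements[[pl]])) placements[[pl]] else NA_real_,
        csa_TBq_s_kg = ct,
        dose_Gy = sum(d_c),
        dose_from_lumens_Gy = sum(d_c[lc$kind == "lumen"]),
        dose_from_cells_Gy = sum(d_c[lc$kind == "cells"]),
        dose_se = sqrt(sum(se_c^2)),
        pct_vs_mird = compare_with_model(1, sum(d_c)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, doses)
  rownames(out) <- NULL
  list(doses = out, layers = layers)
}

#' Fraction of the dose contributed by the central follicle
#'
#' Sums the fractional contributions of the central lumen and the central
#' follicle's own cell layer in a [layer_contributions()] table.
#'
#' @param layer_table Output of [layer_contributions()].
#' @return Percent contribution of the central follicle.
#' @export
central_follicle_fraction <- function(layer_table) {
  sum(layer_table$fraction_pct[layer_table$name %in% c("lumen_1", "cells_1")])
}

#' Fraction of the dose contributed by one surrounding follicle layer
#'
#' @param layer_table Output of [layer_contributions()].
#' @param layer Surrounding layer index (1 = first surrounding layer).
#' @return Percent contribution of that layer (its inner cell shell, lumen
#'   shell and outer cell shell).
#' @export
follicle_layer_fraction <- function(layer_table, layer = 1L) {
  sum(layer_table$fraction_pct[layer_table$follicle_layer == layer])
}
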