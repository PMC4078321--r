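#' Species presets for thyroid follicle dimensions
#'
#' Follicle lumen diameter, follicle-cell layer thickness and follicle-cell
#' nucleus diameter, in micrometres: mouse (50, 6, 4), rat (70, 8, 6) and
#' man (150, 10, 8).
#'
#' @param species One of `"mouse"`, `"rat"`, `"man"`.
#' @return A list with `lumen_diameter`, `cell_thickness`, `nucleus_diameter`.
#' @export
species_preset <- function(species) {
  presets <- list(
    mouse = list(lumen_diameter = 50, cell_thickness = 6, nucleus_diameter = 4),
    rat   = list(lumen_diameter = 70, cell_thickness = 8, nucleus_diameter = 6),
    man   = list(lumen_diameter = 150, cell_thickness = 10, nucleus_diameter = 8)
  )
  if (!species %in% names(presets)) {
    stop("unknown species: ", species, " (use mouse, rat or man)")
  }
  presets[[species]]
}

#' Build a single thyroid follicle model
#'
#' A spherical colloid-filled lumen surrounded by one layer of follicular
#' cells. Six spherical cell nuclei sit symmetrically on the Cartesian axes at
#' the mid-depth of the cell layer; they are the dose targets. All regions are
#' unit-density water. Lengths in micrometres, origin at the follicle centre.
#'
#' @param species Optional species preset (`"mouse"`, `"rat"`, `"man"`);
#'   overridden by explicit dimensions.
#' @param lumen_diameter Lumen diameter (um); 10-500 um in the sweep studies.
#' @param cell_thickness Cell layer thickness (um).
#' @param nucleus_diameter Nucleus diameter (um); must not exceed the cell
#'   layer thickness.
#' @return An object of class `follicle_geometry`.
#' @examples
#' g <- build_single_follicle("man")
#' g$lumen_radius  # 75
#' @export
build_single_follicle <- function(species = NULL, lumen_diameter = NULL,
                                  cell_thickness = NULL, nucleus_diameter = NULL) {
  if (!is.null(species)) {
    p <- species_preset(species)
    if (is.null(lumen_diameter)) lumen_diameter <- p$lumen_diameter
    if (is.null(cell_thickness)) cell_thickness <- p$cell_thickness
    if (is.null(nucleus_diameter)) nucleus_diameter <- p$nucleus_diameter
  }
  if (is.null(lumen_diameter) || is.null(cell_thickness) || is.null(nucleus_diameter)) {
    stop("provide a species preset or all three dimensions")
  }
  if (lumen_diameter <= 0 || cell_thickness <= 0 || nucleus_diameter <= 0) {
    stop("dimensions must be positive")
  }
  if (nucleus_diameter > cell_thickness) {
    stop("nucleus diameter exceeds cell layer thickness: nucleus not contained")
  }
  rl <- lumen_diameter / 2
  rc <- rl + cell_thickness / 2  # nucleus centres at mid-depth of the layer
  centers <- rbind(c(rc, 0, 0), c(-rc, 0, 0),
                   c(0, rc, 0), c(0, -rc, 0),
                   c(0, 0, rc), c(0, 0, -rc))
  structure(
    list(species = species %||% "custom",
         lumen_radius = rl,
         cell_thickness = cell_thickness,
         nucleus_radius = nucleus_diameter / 2,
         nucleus_centers = centers,
         outer_radius = rl + cell_thickness,
         medium_density = 1.0),
    class = "follicle_geometry"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.follicle_geometry <- function(x, ...) {
  cat(sprintf("<follicle_geometry> %s: lumen r = %g um, cells %g um, nucleus r = %g um\n",
              x$species, x$lumen_radius, x$cell_thickness, x$nucleus_radius))
  invisible(x)
}

#' Build a multiple-follicle concentric shell stack
#'
#' Surrounding follicles are approximated by concentric layers around the
#' central follicle: each surrounding layer consists of an inner cell shell,
#' a lumen shell of the species lumen diameter, and an outer cell shell (the
#' outer cell shell of layer k is adjacent to the inner cell shell of layer
#' k+1). Radial intervals are half-open, `[r1, r2)`, with boundary points
#' assigned inward. For man the layer boundaries are 0, 75, 85, 95, 245,
#' 255, 265, 415, ... um.
#'
#' @param species Species preset or a `follicle_geometry` for the central
#'   follicle.
#' @param n_surrounding_layers Number of surrounding follicle layers (>= 0).
#' @return An object of class `shell_stack` with elements `follicle` (the
#'   central [build_single_follicle()] geometry), `shells` (data frame with
#'   `name`, `kind`, `r_inner`, `r_outer`, `follicle_layer`) and
#'   `outer_radius`.
#' @examples
#' st <- build_shell_stack("man", 1)
#' st$shells
#' @export
build_shell_stack <- function(species, n_surrounding_layers) {
  if (n_surrounding_layers < 0) stop("n_surrounding_layers must be >= 0")
  n <- as.integer(n_surrounding_layers)
  fol <- if (inherits(species, "follicle_geometry")) species
         else build_single_follicle(species)
  rl <- fol$lumen_radius
  t <- fol$cell_thickness
  dl <- 2 * rl
  shells <- data.frame(
    name = c("lumen_1", "cells_1"),
    kind = c("lumen", "cells"),
    r_inner = c(0, rl),
    r_outer = c(rl, rl + t),
    follicle_layer = c(0L, 0L),
    stringsAsFactors = FALSE
  )
  r <- rl + t
  for (k in seq_len(n)) {
    idx <- k + 1L
    shells <- rbind(shells, data.frame(
      name = c(sprintf("cells_%da", idx), sprintf("lumen_%d", idx),
               sprintf("cells_%db", idx)),
      kind = c("cells", "lumen", "cells"),
      r_inner = c(r, r + t, r + t + dl),
      r_outer = c(r + t, r + t + dl, r + 2 * t + dl),
      follicle_layer = rep(k, 3L),
      stringsAsFactors = FALSE
    ))
    r <- r + 2 * t + dl
  }
  structure(
    list(follicle = fol, shells = shells, outer_radius = r,
         n_surrounding = n),
    class = "shell_stack"
  )
}

#' @export
print.shell_stack <- function(x, ...) {
  cat(sprintf("<shell_stack> %s central follicle + %d surrounding layers, outer radius %g um\n",
              x$follicle$species, x$n_surrounding, x$outer_radius))
  print(x$shells)
  invisible(x)
}

#' Compartment volumes and masses
#'
#' Analytic sphere/shell volumes for every source compartment of a geometry,
#' with the six nucleus volumes subtracted from the cell layer that contains
#' them and listed as a separate `nuclei` compartment. Masses assume
#' unit-density water (1 um^3 = 1e-15 kg).
#'
#' @param geometry A `follicle_geometry` or `shell_stack`.
#' @return Data frame with `name`, `kind` (`lumen`/`cells`/`nuclei`),
#'   `r_inner`, `r_outer`, `follicle_layer`, `volume_um3`, `mass_kg`.
#' @export
region_volumes <- function(geometry) {
  shell_vol <- function(r1, r2) 4 / 3 * pi * (r2^3 - r1^3)
  if (inherits(geometry, "follicle_geometry")) {
    fol <- geometry
    shells <- data.frame(
      name = c("lumen_1", "cells_1"),
      kind = c("lumen", "cells"),
      r_inner = c(0, fol$lumen_radius),
      r_outer = c(fol$lumen_radius, fol$outer_radius),
      follicle_layer = c(0L, 0L), stringsAsFactors = FALSE
    )
  } else if (inherits(geometry, "shell_stack")) {
    fol <- geometry$follicle
    shells <- geometry$shells
  } else {
    stop("geometry must be a follicle_geometry or shell_stack")
  }
  vol <- shell_vol(shells$r_inner, shells$r_outer)
  nvol <- 6 * 4 / 3 * pi * fol$nucleus_radius^3
  vol[shells$name == "cells_1"] <- vol[shells$name == "cells_1"] - nvol
  out <- rbind(
    data.frame(shells, volume_um3 = vol, stringsAsFactors = FALSE),
    data.frame(name = "nuclei", kind = "nuclei",
               r_inner = fol$lumen_radius, r_outer = fol$outer_radius,
               follicle_layer = 0L, volume_um3 = nvol,
               stringsAsFactors = FALSE)
  )
  out$mass_kg <- out$volume_um3 * UM3_TO_KG
  rownames(out) <- NULL
  out
}

central_follicle <- function(geometry) {
  if (inherits(geometry, "shell_stack")) geometry$follicle else geometry
}

#' Source compartment table
#'
#' [region_volumes()] with the six nucleus volumes merged back into the
#' central cell layer: the activity-placement view of the geometry, in which
#' the cell compartments include the nuclei (a decay in a follicle cell can
#' occur inside its nucleus).
#'
#' @param geometry A `follicle_geometry` or `shell_stack`.
#' @return Data frame like [region_volumes()] without the `nuclei` row.
#' @export
source_compartments <- function(geometry) {
  comp <- region_volumes(geometry)
  nuc <- comp[comp$kind == "nuclei", , drop = FALSE]
  comp <- comp[comp$kind != "nuclei", , drop = FALSE]
  i1 <- comp$name == "cells_1"
  comp$volume_um3[i1] <- comp$volume_um3[i1] + nuc$volume_um3
  comp$mass_kg[i1] <- comp$mass_kg[i1] + nuc$mass_kg
  rownames(comp) <- NULL
  comp
}

#' Source activity distributions
#'
#' Describes where decays occur. Modes: `"lumen_uniform"` (central lumen),
#' `"shell_surface"` (exactly on the sphere of radius `r`), `"cells_uniform"`
#' (central follicle cell layer, the six nucleus volumes excluded),
#' `"nuclei_uniform"` (inside the six nuclei), `"surrounding_lumens"` /
#' `"surrounding_cells"` (all non-central lumen/cell shells of a stack) and
#' `"mixture"` (explicit non-negative activity weights named by compartment,
#' see [region_volumes()]).
#'
#' @param mode Distribution mode.
#' @param r Surface radius (um) for `shell_surface`.
#' @param weights Named non-negative activity weights for `mixture`.
#' @return An object of class `source_distribution`.
#' @export
source_distribution <- function(mode = c("lumen_uniform", "shell_surface",
                                         "cells_uniform", "nuclei_uniform",
                                         "surrounding_lumens",
                                         "surrounding_cells", "mixture"),
                                r = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "shell_surface") {
    if (is.null(r) || r < 0) stop("shell_surface requires a radius r >= 0")
  }
  if (mode == "mixture") {
    if (is.null(weights) || is.null(names(weights)) || any(weights < 0)) {
      stop("mixture requires named non-negative weights")
    }
    if (sum(weights) <= 0) stop("mixture weights must not all be zero")
  }
  structure(list(mode = mode, r = r, weights = weights),
            class = "source_distribution")
}

#' Homogeneous-specific-activity mixture over compartments
#'
#' Builds a `mixture` distribution whose activity weights are proportional to
#' compartment mass within the selected placement, i.e. equal specific
#' activity in every selected compartment: `"homogeneous"` selects all lumen
#' and cell compartments, `"lumens_only"` the lumens, `"cells_only"` the cell
#' shells. The nucleus volumes are part of the central cell layer and carry
#' its specific activity whenever the cells do.
#'
#' @param geometry A `follicle_geometry` or `shell_stack`.
#' @param placement `"homogeneous"`, `"lumens_only"` or `"cells_only"`.
#' @return A `source_distribution` of mode `mixture`.
#' @export
placement_distribution <- function(geometry,
                                   placement = c("homogeneous", "lumens_only",
                                                 "cells_only")) {
  placement <- match.arg(placement)
  comp <- region_volumes(geometry)
  keep <- switch(placement,
                 homogeneous = comp$kind %in% c("lumen", "cells", "nuclei"),
                 lumens_only = comp$kind == "lumen",
                 cells_only  = comp$kind %in% c("cells", "nuclei"))
  w <- setNames(comp$mass_kg * keep, comp$name)
  source_distribution("mixture", weights = w[w > 0])
}

# Resolve a distribution to (compartment names, activity weights) against a
# geometry's compartment table. shell_surface and nuclei handled separately.
distribution_weights <- function(geometry, distribution) {
  comp <- region_volumes(geometry)
  m <- setNames(comp$mass_kg, comp$name)
  w <- switch(distribution$mode,
    lumen_uniform = c(lumen_1 = 1),
    cells_uniform = {
      # the cell compartment includes the six nucleus volumes as source
      nm <- c("cells_1", "nuclei")
      setNames(m[nm], nm)
    },
    nuclei_uniform = c(nuclei = 1),
    surrounding_lumens = {
      nm <- comp$name[comp$kind == "lumen" & comp$follicle_layer > 0]
      if (!length(nm)) stop("no surrounding lumens in this geometry")
      setNames(m[nm], nm)
    },
    surrounding_cells = {
      nm <- comp$name[comp$kind == "cells" & comp$follicle_layer > 0]
      if (!length(nm)) stop("no surrounding cell layers in this geometry")
      setNames(m[nm], nm)
    },
    mixture = {
      bad <- setdiff(names(distribution$weights), comp$name)
      if (length(bad)) stop("unknown compartments in mixture: ",
                            paste(bad, collapse = ", "))
      distribution$weights[distribution$weights > 0]
    },
    stop("distribution mode has no compartment weights: ", distribution$mode)
  )
  if (any(!names(w) %in% comp$name)) stop("compartment not present in geometry")
  w / sum(w)
}

#' Sample decay positions under a source distribution
#'
#' Positions are uniform over the named compartment volumes (activity-weighted
#' for mixtures), exactly on the sphere for `shell_surface`, and exclude the
#' six nucleus volumes for cell compartments. Uses R's global random number
#' stream.
#'
#' @param geometry A `follicle_geometry` or `shell_stack`.
#' @param distribution A [source_distribution()].
#' @param n Number of positions.
#' @return An `n x 3` matrix of positions (um) with a `compartment` attribute
#'   giving each row's source compartment name.
#' @export
sample_source_position <- function(geometry, distribution, n = 1L) {
  fol <- central_follicle(geometry)
  outer <- if (inherits(geometry, "shell_stack")) geometry$outer_radius
           else fol$outer_radius
  if (distribution$mode == "shell_surface") {
    if (distribution$r > outer) {
      stop("surface radius lies outside the model (outer radius ", outer, " um)")
    }
    u <- isotropic_directions(n)
    pts <- u * distribution$r
    attr(pts, "compartment") <- rep("surface", n)
    return(pts)
  }
  w <- distribution_weights(geometry, distribution)
  comp <- region_volumes(geometry)
  rownames(comp) <- comp$name
  cnt <- as.vector(rmultinom(1, n, w))
  pts <- matrix(0, n, 3)
  labs <- rep(names(w), cnt)
  off <- 0L
  for (i in seq_along(w)) {
    k <- cnt[i]
    if (!k) next
    nm <- names(w)[i]
    if (nm == "nuclei") {
      p <- sample_in_nuclei(fol, k)
    } else {
      row <- comp[nm, ]
      p <- sample_in_shell(row$r_inner, row$r_outer, k)
      if (nm == "cells_1") p <- reject_nuclei(p, fol, row$r_inner, row$r_outer, k)
    }
    pts[(off + 1):(off + k), ] <- p
    off <- off + k
  }
  attr(pts, "compartment") <- labs
  pts
}

sample_in_shell <- function(r1, r2, n) {
  r <- (r1^3 + runif(n) * (r2^3 - r1^3))^(1 / 3)
  isotropic_directions(n) * r
}

sample_in_nuclei <- function(fol, n) {
  which_nuc <- sample.int(6L, n, replace = TRUE)
  r <- fol$nucleus_radius * runif(n)^(1 / 3)
  fol$nucleus_centers[which_nuc, , drop = FALSE] + isotropic_directions(n) * r
}

# Rejection of points falling inside any of the six nuclei (cells_uniform
# excludes the nucleus volumes).
reject_nuclei <- function(p, fol, r1, r2, n) {
  for (pass in 1:100) {
    inside <- nucleus_index(p, fol) > 0L
    if (!any(inside)) break
    p[inside, ] <- sample_in_shell(r1, r2, sum(inside))
  }
  p
}

# 0 if outside every nucleus, else the index (1-6) of the containing nucleus.
nucleus_index <- function(p, fol) {
  idx <- integer(nrow(p))
  a2 <- fol$nucleus_radius^2
  for (t in 1:6) {
    d2 <- (p[, 1] - fol$nucleus_centers[t, 1])^2 +
          (p[, 2] - fol$nucleus_centers[t, 2])^2 +
          (p[, 3] - fol$nucleus_centers[t, 3])^2
    idx[idx == 0L & d2 < a2] <- t
  }
  idx
}
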