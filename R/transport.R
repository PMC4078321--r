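#' Electron range in unit-density water
#'
#' Continuous-slowing-down range of an electron of kinetic energy `E` in
#' liquid water at 1.0 g/cm^3. Below 40 keV this is Cole's empirical
#' range-energy relation, `R = 0.0431 (E + 0.367)^1.77 - 0.007` um (E in keV),
#' the classical basis of analytic cellular dosimetry (about 61 nm at 1 keV).
#' Above 40 keV the model continues along a log-log piecewise-linear CSDA
#' table of standard water values, rescaled by ~3% for continuity at the seam,
#' because the low-energy fit overestimates ranges substantially beyond a few
#' hundred keV. The relation is strictly increasing and closed-form
#' invertible; see [inverse_range()].
#'
#' @param E Kinetic energies (keV), non-negative.
#' @return Ranges in micrometres.
#' @examples
#' csda_range(1)    # ~0.068 um
#' csda_range(35)   # ~23 um
#' @export
csda_range <- function(E) csda_range_cpp(as.numeric(E))

#' Inverse of the range-energy relation
#'
#' @param r Ranges (um), non-negative.
#' @return The kinetic energy (keV) whose range is `r`; 0 for `r` below the
#'   zero-energy offset of the relation.
#' @export
inverse_range <- function(r) inverse_range_cpp(as.numeric(r))

#' Collision stopping power implied by the range model
#'
#' `dE/dx = 1 / (dR/dE)`, in keV/um.
#'
#' @param E Kinetic energies (keV).
#' @return Stopping powers (keV/um).
#' @export
stopping_power <- function(E) stopping_power_cpp(as.numeric(E))

#' Residual energy after a path length
#'
#' Energy remaining after an electron of initial energy `E0` has travelled a
#' straight path `s`: `inverse_range(range(E0) - s)`, clamped at zero beyond
#' the range.
#'
#' @param E0 Initial kinetic energies (keV).
#' @param s Path lengths (um). Recycled against `E0`.
#' @return Residual energies (keV).
#' @export
residual_energy <- function(E0, s) {
  n <- max(length(E0), length(s))
  residual_energy_cpp(rep_len(as.numeric(E0), n), rep_len(as.numeric(s), n))
}

#' Energy imparted to target spheres by straight tracks
#'
#' Scores the energy imparted to each target sphere by each emission under
#' straight-track CSDA transport: the deposit in a sphere is the residual
#' energy at chord entry minus the residual energy at chord exit. When the
#' electron falls below `cutoff` its remaining energy is deposited at that
#' point; emissions starting below the cutoff deposit entirely at the origin.
#'
#' @param tracks Data frame or list with origin columns `x`, `y`, `z`,
#'   direction columns `ux`, `uy`, `uz` (unit vectors) and `energy_keV`.
#' @param centers Matrix (n_targets x 3) of target sphere centres (um).
#' @param radius Common target sphere radius (um).
#' @param cutoff Transport cutoff (keV), default 1.
#' @return Matrix (n_tracks x n_targets) of imparted energies (keV).
#' @export
deposit_track <- function(tracks, centers, radius, cutoff = 1) {
  centers <- rbind(centers)
  chord_deposit_cpp(as.numeric(tracks$x), as.numeric(tracks$y),
                    as.numeric(tracks$z), as.numeric(tracks$ux),
                    as.numeric(tracks$uy), as.numeric(tracks$uz),
                    as.numeric(tracks$energy_keV), centers,
                    radius, cutoff)
}

#' Direction-averaged energy deposit in a sphere
#'
#' Expected energy imparted to a sphere of radius `a` whose centre lies at
#' distance `d` from an isotropic point emission of energy `E`: the exact
#' average over emission directions of the straight-track chord deposit. This
#' is the kernel behind the default (expected-track) S-value estimator.
#'
#' @param E Emission energies (keV).
#' @param d Centre distances (um). Recycled against `E`.
#' @param a Sphere radius (um).
#' @return Expected deposits (keV).
#' @export
sphere_expected_deposit <- function(E, d, a) {
  n <- max(length(E), length(d))
  sphere_expected_deposit_cpp(rep_len(as.numeric(E), n),
                              rep_len(as.numeric(d), n), a)
}
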