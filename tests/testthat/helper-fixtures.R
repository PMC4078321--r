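# Shared fixtures: synthetic nuclides and small geometries built in code.

KEV_J <- 1.602176634e-16
UM3_KG <- 1e-15

toy_mono <- function(E, yield = 1, kind = "CE", id = paste0("mono", E)) {
  make_toy_nuclide(lines = data.frame(kind = kind, energy_keV = E,
                                      yield = yield),
                   nuclide_id = id, register = FALSE)
}

nucleus_mass_kg <- function(geom) {
  4 / 3 * pi * geom$nucleus_radius^3 * UM3_KG
}

# Fine-step ray marcher: an independent transport oracle. Steps along the
# path in small increments, losing energy at the local stopping power, and
# scores the loss to whichever sphere contains the current radial position
# (the radial position includes the same detour compression as the package
# transport, z(s) = s (1 - 0.15 s / R0)).
march_track <- function(origin, direction, E0, centers, radius,
                        n_steps = 4000) {
  R0 <- csda_range(E0)
  ds <- R0 / n_steps
  E <- E0
  dep <- numeric(nrow(centers))
  s <- 0
  for (i in seq_len(n_steps)) {
    smid <- s + ds / 2
    dE <- min(stopping_power(residual_energy(E0, smid)) * ds, E)
    z <- smid * (1 - 0.15 * smid / R0)
    pos <- origin + direction * z
    for (t in seq_len(nrow(centers))) {
      if (sum((pos - centers[t, ])^2) < radius^2) {
        dep[t] <- dep[t] + dE
        break
      }
    }
    E <- E - dE
    s <- s + ds
    if (E <= 0) break
  }
  dep
}
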