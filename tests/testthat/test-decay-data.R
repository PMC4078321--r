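test_that("curated spectra reproduce the per-decay summary statistics", {
  i123 <- load_spectrum("I-123")
  i125 <- load_spectrum("I-125")
  i131 <- load_spectrum("I-131")

  # AE counts per decay: 14, 23, 0.7
  expect_equal(total_ae_yield(i123), 14, tolerance = 0.05)
  expect_equal(total_ae_yield(i125), 23, tolerance = 0.05)
  expect_equal(total_ae_yield(i131), 0.7, tolerance = 0.05)

  # sub-1-keV AE energy per decay: 1.25 keV, 2.11 keV, 78.3 eV
  expect_equal(i123$local_energy_sub1kev, 1.25)
  expect_equal(i125$local_energy_sub1kev, 2.11)
  expect_equal(i131$local_energy_sub1kev, 0.0783)

  # mean electron energy per decay; I-125's curated total (~19 keV, the
  # energy balance that reproduces the measured cellular S values) sits
  # above the older summary value of 16.5 keV kept on the MIRD side
  expect_equal(mean_energy_per_decay(i123), 26.7, tolerance = 0.05)
  expect_equal(mean_energy_per_decay(i131), 191.2, tolerance = 0.05)
  expect_equal(mean_energy_per_decay(i125), 19.0, tolerance = 0.02)

  # no stored line below the 1 keV cutoff
  for (sp in list(i123, i125, i131)) {
    expect_true(all(sp$lines$energy_keV >= 1))
  }
})

test_that("unknown nuclides raise an explicit error", {
  expect_error(load_spectrum("I-999"), "not registered")
})

test_that("toy nuclides behave like first-class spectra", {
  one <- make_toy_nuclide(lines = data.frame(kind = "CE", energy_keV = 20,
                                             yield = 1),
                          nuclide_id = "toy20")
  expect_equal(mean_energy_per_decay(one), 20)
  expect_identical(load_spectrum("toy20")$nuclide_id, "toy20")

  loc <- make_toy_nuclide(local_energy = 1.25, register = FALSE)
  expect_equal(mean_energy_per_decay(loc), 1.25)

  two <- make_toy_nuclide(lines = data.frame(kind = c("AE", "CE"),
                                             energy_keV = c(10, 100),
                                             yield = c(2, 0.5)),
                          register = FALSE)
  expect_equal(mean_energy_per_decay(two), 70)

  expect_error(make_toy_nuclide(lines = data.frame(kind = "CE",
                                                   energy_keV = -3,
                                                   yield = 1)),
               "positive")
})

test_that("emission sampling matches the analytic spectrum moments", {
  set.seed(101)
  toy <- toy_mono(50)
  em <- sample_decay_emissions(toy, 1e4)
  n_per <- tabulate(em$electrons$decay, nbins = 1e4)
  # Poisson with mean 1: sample mean within 3 SE of 1
  expect_lt(abs(mean(n_per) - 1), 3 / sqrt(1e4))
  # directions are unit vectors
  nrm <- with(em$electrons, ux^2 + uy^2 + uz^2)
  expect_equal(max(abs(nrm - 1)), 0, tolerance = 1e-10)

  i131 <- load_spectrum("I-131")
  set.seed(102)
  em2 <- thyrodose:::sample_emissions_flat(i131, 2e4)
  # AE count above 1 keV ~ sum of AE line yields
  ae_y <- sum(i131$lines$yield[i131$lines$kind == "AE"])
  n_ae <- sum(em2$kind == 0L)
  expect_lt(abs(n_ae / 2e4 - ae_y), 3 * sqrt(ae_y / 2e4))
  # empirical mean energy within 3 SE of the analytic mean
  etot <- sum(em2$energy) / 2e4 + i131$local_energy_sub1kev
  se <- sd(tapply(em2$energy, factor(em2$decay, levels = 1:2e4), sum),
           na.rm = TRUE) / sqrt(2e4)
  expect_lt(abs(etot - mean_energy_per_decay(i131)), 3 * se + 1)
  # all sampled line (AE/CE) energies at or above the 1 keV cutoff; the
  # continuous beta spectrum extends below it and is deposited locally there
  expect_true(all(em2$energy[em2$kind != 2L] >= 1))
})

test_that("sampling is reproducible under a fixed seed", {
  i125 <- load_spectrum("I-125")
  set.seed(7)
  a <- sample_decay_emissions(i125, 500)
  set.seed(7)
  b <- sample_decay_emissions(i125, 500)
  expect_identical(a, b)
})

test_that("beta density is a normalised allowed-shape distribution", {
  br <- list(endpoint_keV = 606.3, daughter_Z = 54L)
  expect_equal(beta_energy_density(br, 607.3), 0)
  expect_error(beta_energy_density(br, -1), "negative")

  E <- seq(0, 606.3, length.out = 4001)
  f <- beta_energy_density(br, E)
  h <- E[2] - E[1]
  expect_equal(sum((f[-1] + f[-4001]) / 2 * h), 1, tolerance = 1e-6)

  # sampled mean against the quadrature first moment
  set.seed(11)
  x <- thyrodose:::sample_beta_energy(1e5, 606.3, 54L)
  mu <- beta_mean_energy(606.3, 54L)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(1e5))
})
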