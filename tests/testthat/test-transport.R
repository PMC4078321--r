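test_that("range-energy relation matches its anchors and is invertible", {
  # ~61 nm at 1 keV (Cole's low-energy anchor, within 20%)
  expect_equal(csda_range(1), 0.061, tolerance = 0.2)
  # hardest I-125 conversion electrons stay within ~23 um
  expect_lt(csda_range(30.553), 23)
  expect_error(csda_range(-1), "negative")

  E <- c(0.5, 1, 5, 20, 39, 41, 80, 150, 350, 900)
  expect_true(all(diff(csda_range(seq(0.2, 1000, by = 0.2))) > 0))
  expect_equal(inverse_range(csda_range(E)), E, tolerance = 1e-6)
})

test_that("residual energy obeys the CSDA identities", {
  expect_equal(residual_energy(25, 0), 25)
  expect_equal(residual_energy(25, csda_range(25)), 0)
  expect_equal(residual_energy(25, 1e4), 0)
  for (E0 in c(3, 27, 120, 600)) {
    s <- csda_range(E0) * c(0.1, 0.5, 0.9)
    expect_equal(csda_range(residual_energy(E0, s)), csda_range(E0) - s,
                 tolerance = 1e-6)
  }
})

test_that("straight-track chord scoring conserves energy and handles the cutoff", {
  centers <- rbind(c(10, 0, 0))
  tr <- list(x = 0, y = 5, z = 0, ux = 0, uy = 0, uz = 1, energy_keV = 30)
  # track misses the sphere entirely
  expect_equal(deposit_track(tr, centers, 4)[1, 1], 0)

  # sub-cutoff emission inside a target deposits fully at the origin
  tr2 <- list(x = 10, y = 0, z = 0, ux = 1, uy = 0, uz = 0, energy_keV = 0.8)
  expect_equal(deposit_track(tr2, centers, 4)[1, 1], 0.8)

  # emission at the centre of a sphere larger than the range: exactly E0
  big <- rbind(c(0, 0, 0))
  tr3 <- list(x = 0, y = 0, z = 0, ux = 1, uy = 0, uz = 0, energy_keV = 50)
  expect_equal(deposit_track(tr3, big, csda_range(50) + 1)[1, 1], 50)

  # energy conservation with a bounding sphere, including the pointwise
  # cutoff deposit, for a spread of energies
  for (E0 in c(2, 15, 80, 400)) {
    tr4 <- list(x = 1, y = 2, z = 3, ux = 1 / sqrt(2), uy = 1 / sqrt(2),
                uz = 0, energy_keV = E0)
    dep <- deposit_track(tr4, rbind(c(0, 0, 0)), csda_range(E0) + 10)
    expect_equal(dep[1, 1], E0, tolerance = 1e-9)
  }
})

test_that("chord arithmetic agrees with a fine-step ray-marching oracle", {
  set.seed(41)
  centers <- rbind(c(6, 1, 0), c(-4, 3, 2))
  for (i in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    o <- runif(3, -2, 2)
    E0 <- runif(1, 5, 60)
    tr <- list(x = o[1], y = o[2], z = o[3], ux = u[1], uy = u[2], uz = u[3],
               energy_keV = E0)
    fast <- deposit_track(tr, centers, 3, cutoff = 0)
    slow <- march_track(o, u, E0, centers, 3)
    expect_lt(abs(sum(fast) - sum(slow)), 1e-3 * E0)
  }
})

test_that("direction-averaged kernel matches the sampled-direction mean", {
  set.seed(42)
  a <- 4
  for (cfg in list(c(E = 20, d = 9), c(E = 35, d = 2), c(E = 10, d = 12))) {
    n <- 4e4
    u <- thyrodose:::isotropic_directions(n)
    tr <- list(x = numeric(n), y = numeric(n), z = numeric(n),
               ux = u[, 1], uy = u[, 2], uz = u[, 3],
               energy_keV = rep(cfg[["E"]], n))
    dep <- deposit_track(tr, rbind(c(cfg[["d"]], 0, 0)), a, cutoff = 0)
    mc <- mean(dep)
    se <- sd(dep) / sqrt(n)
    expect_lt(abs(mc - sphere_expected_deposit(cfg[["E"]], cfg[["d"]], a)),
              3 * se + 1e-6)
  }
  # full containment limit
  expect_equal(sphere_expected_deposit(5, 0.1, 50), 5)
})
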