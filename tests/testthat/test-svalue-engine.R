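test_that("full self-absorption recovers S = E/m for short-range emitters", {
  man <- build_single_follicle("man")
  m <- nucleus_mass_kg(man)
  toy <- toy_mono(2)  # range ~0.15 um << 4 um nucleus radius
  sv <- compute_s_value(man, source_distribution("nuclei_uniform"), toy,
                        2e4, seed = 5)
  expect_equal(sv$s_total, 2 * KEV_J / m, tolerance = 0.02)
  expect_equal(unname(sv$s_by_component["CE"]), sv$s_total)
})

test_that("results are deterministic under a fixed seed", {
  man <- build_single_follicle("man")
  i125 <- load_spectrum("I-125")
  a <- compute_s_value(man, source_distribution("lumen_uniform"), i125,
                       5e3, seed = 9)
  b <- compute_s_value(man, source_distribution("lumen_uniform"), i125,
                       5e3, seed = 9)
  expect_identical(a, b)
  c <- compute_s_value(man, source_distribution("lumen_uniform"), i125,
                       5e3, seed = 10)
  expect_false(identical(a$s_total, c$s_total))
})

test_that("component decomposition is exhaustive and non-negative", {
  man <- build_single_follicle("man")
  for (nuc in c("I-125", "I-131")) {
    sv <- compute_s_value(man, source_distribution("cells_uniform"),
                          load_spectrum(nuc), 2e4, seed = 12)
    expect_equal(sum(sv$s_by_component), sv$s_total, tolerance = 1e-12)
    expect_equal(sum(sv$relative_contributions), 100, tolerance = 0.1)
    expect_true(all(sv$s_by_component >= 0))
  }
})

test_that("batch standard error shrinks like one over root N", {
  man <- build_single_follicle("man")
  i125 <- load_spectrum("I-125")
  d <- source_distribution("cells_uniform")
  se1 <- se2 <- numeric(8)
  for (r in 1:8) {
    se1[r] <- compute_s_value(man, d, i125, 4e3, seed = 100 + r)$standard_error
    se2[r] <- compute_s_value(man, d, i125, 8e3, seed = 200 + r)$standard_error
  }
  expect_equal(mean(se2) / mean(se1), 1 / sqrt(2), tolerance = 0.25)
})

test_that("Monte Carlo agrees with the deterministic quadrature oracle", {
  mouse <- build_single_follicle("mouse")
  toy <- toy_mono(20)
  q1 <- brute_force_s_value(mouse, source_distribution("cells_uniform"), toy,
                            grid_resolution = 24)
  q2 <- brute_force_s_value(mouse, source_distribution("cells_uniform"), toy,
                            grid_resolution = 48)
  # grid refinement by 2x changes the value by < 0.5%
  expect_equal(q1, q2, tolerance = 5e-3)

  sv <- compute_s_value(mouse, source_distribution("cells_uniform"), toy,
                        1e5, seed = 33)
  expect_lt(abs(sv$s_total - q2), 3 * sv$standard_error)

  # lumen source as a second, independent configuration
  ql <- brute_force_s_value(mouse, source_distribution("lumen_uniform"), toy)
  svl <- compute_s_value(mouse, source_distribution("lumen_uniform"), toy,
                         1e5, seed = 34)
  expect_lt(abs(svl$s_total - ql), 3 * svl$standard_error)

  # self-absorption sanity: quadrature also recovers E/m for short ranges
  q3 <- brute_force_s_value(mouse, source_distribution("nuclei_uniform"),
                            toy_mono(1.5))
  expect_equal(q3, 1.5 * KEV_J / nucleus_mass_kg(mouse), tolerance = 0.03)

  expect_error(
    brute_force_s_value(mouse, source_distribution("lumen_uniform"),
                        load_spectrum("I-131")),
    "line spectra")
  expect_error(
    brute_force_s_value(mouse, source_distribution("lumen_uniform"),
                        toy_mono(300)),
    "too large")
})

test_that("absorbed fractions obey reciprocity in a uniform medium", {
  # two spheres A (r = 3) and B (r = 5), 12 um apart, 20 keV electrons:
  # phi(B<-A)/m_B = phi(A<-B)/m_A, i.e. the expected energy into B per decay
  # in A equals that into A per decay in B scaled by the mass ratio
  set.seed(55)
  n <- 2e4
  pa <- thyrodose:::sample_in_shell(0, 3, n)
  pb <- sweep(thyrodose:::sample_in_shell(0, 5, n), 2, c(12, 0, 0), "+")
  dab <- sphere_expected_deposit(rep(20, n),
                                 sqrt(rowSums(sweep(pa, 2, c(12, 0, 0))^2)), 5)
  dba <- sphere_expected_deposit(rep(20, n), sqrt(rowSums(pb^2)), 3)
  scaled <- mean(dba) * (5 / 3)^3
  se <- sqrt(sd(dab)^2 / n + ((5 / 3)^3 * sd(dba))^2 / n)
  expect_lt(abs(mean(dab) - scaled), 3 * se)
})

test_that("layer contributions sum to 100 percent and honour placements", {
  st <- build_shell_stack("man", 1)
  i125 <- load_spectrum("I-125")
  lc <- layer_contributions(st, i125, "homogeneous", 4e4, seed = 61,
                            min_histories = 2e3)
  expect_equal(sum(lc$fraction_pct), 100, tolerance = 0.5)
  expect_true(all(lc$fraction_pct >= 0))

  lo <- layer_contributions(st, i125, "lumens_only", 2e4, seed = 62,
                            min_histories = 2e3)
  expect_true(all(lo$kind == "lumen"))
  expect_equal(sum(lo$fraction_pct), 100, tolerance = 0.5)

  one <- layer_contributions(build_shell_stack("man", 0), i125, "lumens_only",
                             5e3, seed = 63, min_histories = 2e3)
  expect_equal(one$fraction_pct, 100)
})

test_that("expected-track and analog estimators agree", {
  man <- build_single_follicle("man")
  toy <- toy_mono(30)
  k <- compute_s_value(man, source_distribution("lumen_uniform"), toy,
                       2e4, seed = 71)
  a <- compute_s_value(man, source_distribution("lumen_uniform"), toy,
                       2e5, seed = 72, estimator = "analog")
  expect_lt(abs(k$s_total - a$s_total),
            3 * sqrt(k$standard_error^2 + a$standard_error^2))
})

test_that("engine rejects invalid configurations", {
  man <- build_single_follicle("man")
  toy <- toy_mono(10)
  expect_error(compute_s_value(man, source_distribution("lumen_uniform"),
                               toy, 100), "seed")
  expect_error(
    compute_s_value(man, source_distribution("mixture", weights = c(bogus = 1)),
                    toy, 100, seed = 1),
    "unknown compartment")
  expect_error(
    compute_s_value(man, source_distribution("surrounding_lumens"), toy, 100,
                    seed = 1),
    "no surrounding")
})
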