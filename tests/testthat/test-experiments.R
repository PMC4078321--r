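test_that("the single-follicle table is reproducible and well-formed", {
  r1 <- run_table1(species = "man", nuclides = "I-125", n_histories = 5e3,
                   seed = 3)
  r2 <- run_table1(species = "man", nuclides = "I-125", n_histories = 5e3,
                   seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$source, c("lumen", "cells", "nuclei"))
  expect_named(r1, c("species", "nuclide", "source", "beta_s", "beta_pct",
                     "ce_s", "ce_pct", "ae_s", "ae_pct", "total_s", "se"))
  expect_true(all(r1$total_s > 0))
  expect_equal(r1$beta_pct + r1$ce_pct + r1$ae_pct, rep(100, 3),
               tolerance = 0.1)
})

test_that("S value decreases monotonically with lumen diameter", {
  sw <- run_lumen_sweep(c(10, 50, 150, 500), n_histories = 2e4, seed = 8)
  for (nuc in unique(sw$nuclide)) {
    s <- sw$total_s[sw$nuclide == nuc]
    expect_true(all(diff(s) < 0))
  }
  # smallest lumen: I-125 gives the highest S value; largest: I-131 does
  s10 <- sw[sw$diameter_um == 10, ]
  expect_equal(s10$nuclide[which.max(s10$total_s)], "I-125")
  s500 <- sw[sw$diameter_um == 500, ]
  expect_equal(s500$nuclide[which.max(s500$total_s)], "I-131")
})

test_that("shell sources inside the lumen are silent for I-125 beyond its range", {
  sc <- run_shell_scan(c(40, 74), nuclides = "I-125", n_histories = 1e4,
                       seed = 9)
  # 35 um deep in the lumen: beyond any emitted electron's reach
  expect_equal(sc$total_s[sc$radius_um == 40], 0)
  expect_gt(sc$total_s[sc$radius_um == 74], 0)
})

test_that("mixture doses are superpositions of the endpoint placements", {
  r <- run_mird_comparison(nuclides = "I-125",
                           fractions_in_cells = c(0, 0.5, 1),
                           n_histories = 1e5, seed = 14)
  d <- r$doses
  d0 <- d$dose_Gy[d$placement == "cells_0"]
  d1 <- d$dose_Gy[d$placement == "cells_1"]
  dh <- d$dose_Gy[d$placement == "cells_0.5"]
  se <- sqrt(sum(d$dose_se[d$placement != "homogeneous"]^2))
  expect_lt(abs(dh - (d0 + d1) / 2), 3 * se + 1e-9)
  # compartment contributions add up to the total dose
  expect_equal(d$dose_from_lumens_Gy + d$dose_from_cells_Gy, d$dose_Gy,
               tolerance = 1e-9)
})

test_that("layer-count defaults follow the species/nuclide convergence table", {
  expect_equal(default_layer_count("man", "I-131"), 8)
  expect_equal(default_layer_count("man", "I-125"), 1)
  expect_equal(default_layer_count("mouse", "I-123"), 5)
  expect_equal(default_layer_count("rat", "I-131"), 16)
  expect_error(default_layer_count("man", "I-999"), "no default")
})
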