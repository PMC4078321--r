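test_that("species presets build the published follicle dimensions", {
  man <- build_single_follicle("man")
  expect_equal(man$lumen_radius, 75)
  expect_equal(man$cell_thickness, 10)
  expect_equal(man$nucleus_radius, 4)
  # nucleus centres at the mid-depth of the cell layer: 80 um in man
  expect_equal(unname(sqrt(rowSums(man$nucleus_centers^2))), rep(80, 6))

  mouse <- build_single_follicle("mouse")
  expect_equal(c(mouse$lumen_radius, mouse$cell_thickness,
                 mouse$nucleus_radius), c(25, 6, 2))

  expect_error(build_single_follicle(lumen_diameter = 50, cell_thickness = 6,
                                     nucleus_diameter = 8), "not contained")
  expect_error(species_preset("dog"), "unknown species")
})

test_that("shell stacks reproduce the concentric layer radii", {
  st1 <- build_shell_stack("man", 1)
  expect_equal(st1$shells$r_inner, c(0, 75, 85, 95, 245))
  expect_equal(st1$shells$r_outer, c(75, 85, 95, 245, 255))
  expect_equal(st1$shells$kind, c("lumen", "cells", "cells", "lumen", "cells"))

  st0 <- build_shell_stack("man", 0)
  expect_equal(st0$outer_radius, 85)

  st8 <- build_shell_stack("man", 8)
  expect_equal(st8$outer_radius, 1445)

  expect_error(build_shell_stack("man", -1), ">= 0")
})

test_that("compartment volumes are analytic and partition the model", {
  man <- build_single_follicle("man")
  rv <- region_volumes(man)
  expect_equal(rv$volume_um3[rv$name == "lumen_1"], 4 / 3 * pi * 75^3)
  # exact partition: compartments sum to the outermost sphere
  expect_equal(sum(rv$volume_um3), 4 / 3 * pi * 85^3)

  st <- build_shell_stack("man", 2)
  rv2 <- region_volumes(st)
  expect_equal(sum(rv2$volume_um3), 4 / 3 * pi * st$outer_radius^3)

  # whole-model to lumen mass ratio matches the printed cumulated-specific-
  # activity rescaling 234 -> 267 TBq.s/kg for the I-123 stack
  ratio <- sum(rv2$mass_kg) / sum(rv2$mass_kg[rv2$kind == "lumen"])
  expect_equal(ratio, 267 / 234, tolerance = 0.02)

  # source view: nuclei merged into the central cell layer
  sc <- source_compartments(st)
  expect_false("nuclei" %in% sc$name)
  expect_equal(sum(sc$mass_kg), sum(rv2$mass_kg))
})

test_that("position sampling is uniform over the named compartments", {
  man <- build_single_follicle("man")
  set.seed(21)
  p <- sample_source_position(man, source_distribution("lumen_uniform"), 2e4)
  r <- sqrt(rowSums(p^2))
  expect_true(all(r <= 75))
  # radial CDF of a uniform ball: (r/75)^3
  ks <- suppressWarnings(ks.test(r, function(q) pmin((q / 75)^3, 1)))
  expect_gt(ks$p.value, 0.01)

  s <- sample_source_position(man, source_distribution("shell_surface", r = 75),
                              5e3)
  expect_equal(max(abs(sqrt(rowSums(s^2)) - 75)), 0, tolerance = 1e-9)

  cells <- sample_source_position(man, source_distribution("cells_uniform"),
                                  2e4)
  rc <- sqrt(rowSums(cells^2))
  expect_true(all(rc >= 75 & rc <= 85))
  # the cell compartment includes the six nucleus volumes as source
  frac_in_nuc <- mean(thyrodose:::nucleus_index(cells, man) > 0)
  vfrac <- 6 * (4 / 3 * pi * 4^3) / (4 / 3 * pi * (85^3 - 75^3))
  expect_lt(abs(frac_in_nuc - vfrac), 3 * sqrt(vfrac / 2e4))

  expect_error(
    sample_source_position(man, source_distribution("shell_surface", r = 120), 1),
    "outside the model")
})

test_that("analytic volumes agree with hit-or-miss Monte Carlo", {
  man <- build_single_follicle("man")
  rv <- region_volumes(man)
  set.seed(31)
  n <- 1e5
  p <- matrix(runif(3 * n, -85, 85), ncol = 3)
  r <- sqrt(rowSums(p^2))
  in_model <- r < 85
  in_lumen <- r < 75
  in_nuc <- thyrodose:::nucleus_index(p, man) > 0
  vbox <- 170^3
  for (case in list(list(in_lumen, "lumen_1"),
                    list(in_model & !in_lumen & !in_nuc, "cells_1"),
                    list(in_nuc, "nuclei"))) {
    phat <- mean(case[[1]])
    se <- sqrt(phat * (1 - phat) / n) * vbox
    expect_lt(abs(phat * vbox - rv$volume_um3[rv$name == case[[2]]]), 3 * se)
  }
})
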