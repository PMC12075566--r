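test_that("a uniform cylinder of rings profiles at the analytic radius", {
  toy <- gen_toy_pore(data.frame(z = -10:10, R = 5), atom_vdw = 1.5)
  p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-8, 8),
                    seed = 1)
  expect_true(all(abs(p$profile$radius - 3.5) <= 0.05))
  # reported centers stay essentially on the cylinder axis
  expect_true(all(sqrt(p$profile$cx^2 + p$profile$cy^2) < 0.05))
})

test_that("a single narrow ring sets the minimum radius at its position", {
  R <- ifelse(-10:10 == 0, 3, 5)
  toy <- gen_toy_pore(data.frame(z = -10:10, R = R), atom_vdw = 1.5)
  p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-8, 8),
                    seed = 1)
  expect_equal(p$min_radius, 1.5, tolerance = 0.05)
  expect_lt(abs(p$z_at_min), 0.51)
  expect_equal(p$min_diameter, 2 * p$min_radius)
})

test_that("profiling an empty structure is an error", {
  expect_error(profile_pore(data.frame(x = numeric(), y = numeric(),
                                       z = numeric(), element = character())),
               "no heavy atoms")
})

test_that("removing atoms never shrinks the pore", {
  toy <- gen_toy_pore(data.frame(z = seq(-4, 4, 2), R = c(5, 5, 4, 5, 5)),
                      atom_vdw = 1.5, atoms_per_ring = 16)
  p0 <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-3, 3),
                     seed = 2)
  thinned <- toy$structure[seq(1, nrow(toy$structure), by = 2), ]
  p1 <- profile_pore(thinned, anchor = c(0, 0, 0), z_range = c(-3, 3), seed = 2)
  expect_true(all(p1$profile$radius >= p0$profile$radius - 1e-6))
})

test_that("the reported radius is exactly the clearance at the reported center", {
  toy <- gen_toy_pore(data.frame(z = -5:5, R = 5), atom_vdw = 1.5)
  p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-4, 4),
                    seed = 3)
  xyz <- as.matrix(toy$structure[, c("x", "y", "z")])
  for (k in seq_len(nrow(p$profile))) {
    ctr <- c(p$profile$cx[k], p$profile$cy[k], p$profile$cz[k])
    clearance <- min(sqrt(colSums((t(xyz) - ctr)^2)) - toy$structure$vdw)
    expect_equal(p$profile$radius[k], clearance, tolerance = 1e-9)
  }
})

test_that("profiles are seed-reproducible and seed-stable", {
  toy <- gen_toy_pore(data.frame(z = -6:6, R = 5), atom_vdw = 1.5)
  p1 <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-5, 5),
                     seed = 4)
  p2 <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-5, 5),
                     seed = 4)
  expect_identical(p1$profile, p2$profile)
  p3 <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-5, 5),
                     seed = 99)
  expect_lt(max(abs(p1$profile$radius - p3$profile$radius)), 0.1)
})

test_that("zone boundaries isolate the constriction of a W-shaped profile", {
  R <- ifelse(abs(-10:10) <= 2, 3.2, 6)
  toy <- gen_toy_pore(data.frame(z = -10:10, R = R), atom_vdw = 1.5)
  p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-9, 9),
                    seed = 5)
  zones <- zone_boundaries_from_profile(p)
  expect_setequal(names(zones), c("bottom", "middle", "top"))
  expect_true(zones$middle[1] <= -1.5 && zones$middle[2] >= 1.5)
  expect_identical(assign_zone(c(0, 0, 0), zones), "middle")

  # V-shaped: middle collapses to the configured neighborhood of the minimum
  Rv <- 5 - 2.8 * pmax(0, 1 - abs(-10:10) / 8)
  toyv <- gen_toy_pore(data.frame(z = -10:10, R = Rv), atom_vdw = 1.5)
  pv <- profile_pore(toyv$structure, anchor = c(0, 0, 0), z_range = c(-8, 8),
                     seed = 5)
  zv <- zone_boundaries_from_profile(pv, min_halfwidth = 1.0)
  expect_lt(diff(zv$middle), diff(zones$middle) + 3)
  expect_true(zv$middle[1] <= pv$z_at_min && pv$z_at_min <= zv$middle[2])
})

test_that("a flat profile falls back to a single zone", {
  toy <- gen_toy_pore(data.frame(z = -5:5, R = 5), atom_vdw = 1.5)
  p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-4, 4),
                    seed = 6)
  expect_warning(z <- zone_boundaries_from_profile(p), "single zone")
  expect_identical(names(z), "middle")
})
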