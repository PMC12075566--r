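test_that("noise-free actives sit exactly on the ground truth", {
  sp <- planted_spec(seed = 2, sigma = 0, n_actives = 5, n_decoys_per_active = 0)
  ps <- gen_planted_set(sp)
  for (fs in ps$actives) {
    m <- match_to_hypothesis(fs, ps$truth, rmsd_max = Inf)
    expect_equal(m$rmsd, 0, tolerance = 1e-8)
  }
})

test_that("active noise propagates to best-match RMSD at the expected scale", {
  rmsds <- unlist(lapply(1:10, function(s) {
    ps <- gen_planted_set(planted_spec(seed = s, sigma = 0.2, n_actives = 2,
                                       n_decoys_per_active = 0))
    vapply(ps$actives, function(fs)
      match_to_hypothesis(fs, ps$truth, rmsd_max = Inf)$rmsd, numeric(1))
  }))
  expect_gt(mean(rmsds), 0.1)
  expect_lt(mean(rmsds), 0.4)
})

test_that("decoys never match the ground truth within the screening gate", {
  sp <- planted_spec(seed = 6, sigma = 0.2, n_actives = 2, n_decoys_per_active = 15)
  ps <- gen_planted_set(sp)
  n_passing <- sum(vapply(ps$decoys, function(fs)
    !is.null(match_to_hypothesis(fs, ps$truth, rmsd_max = 1.0)), logical(1)))
  expect_identical(n_passing, 0L)
})

test_that("generators are byte-identical under a fixed seed", {
  a <- gen_planted_set(planted_spec(seed = 9, n_actives = 3, n_decoys_per_active = 2))
  b <- gen_planted_set(planted_spec(seed = 9, n_actives = 3, n_decoys_per_active = 2))
  expect_identical(a, b)

  t1 <- gen_toy_pore(data.frame(z = 0:3, R = 5), seed = 4)
  t2 <- gen_toy_pore(data.frame(z = 0:3, R = 5), seed = 4)
  expect_identical(t1, t2)

  p1 <- gen_toy_poseset(6, 4, seed = 8)
  p2 <- gen_toy_poseset(6, 4, seed = 8)
  expect_identical(p1, p2)
})

test_that("a custom planted distance matrix is honored and infeasible ones rejected", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3; D[1, 3] <- D[3, 1] <- 4; D[2, 3] <- D[3, 2] <- 5
  sp <- planted_spec("APR", distances = D, sigma = 0, n_actives = 2,
                     n_decoys_per_active = 0, seed = 1)
  got <- as.matrix(dist(sp$positions))
  expect_equal(sort(got[upper.tri(got)]), c(3, 4, 5), tolerance = 1e-6)

  bad <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3)
  expect_error(planted_spec("APR", distances = bad), "infeasible|symmetric")
})

test_that("toy pore analytic profile matches its construction rules", {
  toy <- gen_toy_pore(data.frame(z = -3:3, R = 5), atom_vdw = 1.5)
  expect_true(all(toy$analytic$radius == 3.5))
  R <- c(5, 5, 3, 5, 5)
  toy2 <- gen_toy_pore(data.frame(z = -2:2, R = R), atom_vdw = 1.5)
  expect_equal(min(toy2$analytic$radius), 1.5)
  expect_error(gen_toy_pore(data.frame(z = 0:1, R = c(5, 1)), atom_vdw = 1.5),
               "exceed")
})

test_that("profiler error against the analytic cylinder stays within the discretization bound", {
  # angular discretization study: with the axis-tracking probe, even coarse
  # rings cage the probe at the ring center (the center is the in-plane
  # clearance maximum by symmetry), so the error is dominated by the axial
  # ring spacing and must shrink below 0.1 A at 24 atoms per ring
  rings <- data.frame(z = -4:4, R = 5)
  err_for <- function(n) {
    toy <- gen_toy_pore(rings, atom_vdw = 1.5, atoms_per_ring = n, seed = 2)
    p <- profile_pore(toy$structure, anchor = c(0, 0, 0), z_range = c(-3, 3),
                      step = 0.25, seed = 2)
    max(abs(p$profile$radius - 3.5))
  }
  e_coarse <- err_for(3L)
  e_fine <- err_for(24L)
  expect_gte(e_coarse, e_fine)
  expect_lt(e_fine, 0.1)
})

test_that("toy pose sets reproduce their planted contact fractions exactly", {
  toy <- gen_toy_poseset(3, 2, planted_frequencies = c(1, 0.5, 0), seed = 1)
  cp <- contact_frequency(toy$pose_set)
  expect_equal(cp$frequency, c(1, 0.5, 0))
  expect_identical(cp$category, toy$truth$category)

  big <- gen_toy_poseset(50, 36, seed = 13)
  cpb <- contact_frequency(big$pose_set)
  expect_equal(setNames(cpb$frequency, cpb$residue),
               setNames(big$truth$frequency, big$truth$residue))
  expect_error(gen_toy_poseset(3, 0), "at least one pose")
})
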