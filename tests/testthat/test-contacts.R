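toy_receptor_3res <- function() {
  data.frame(chain = "A", resno = 1:3, resname = "GLY", atom = "CA",
             element = "C",
             x = 0, y = 0, z = c(0, 6, 12), stringsAsFactors = FALSE)
}

one_atom_pose <- function(id, at, charge = 0L) {
  list(ligand_id = id, coords = matrix(at, 1), elements = "C",
       charges = charge)
}

test_that("contact counting follows plain distance arithmetic", {
  ps <- pose_set(toy_receptor_3res(),
                 list(one_atom_pose("L1", c(0, 0, 4))))
  cp <- contact_frequency(ps, cutoff = 5)
  expect_equal(cp$frequency, c(1, 1, 0))  # 4.0 A, 2.0 A, 8.0 A
})

test_that("the 0.5 frequency boundary is low-contact and above it is high", {
  rec <- toy_receptor_3res()
  ps <- pose_set(rec, list(one_atom_pose("L1", c(0, 0, 0)),
                           one_atom_pose("L2", c(0, 0, 12))))
  cp <- contact_frequency(ps, cutoff = 5)
  expect_equal(cp$frequency, c(0.5, 0, 0.5))
  expect_true(all(cp$category == "low"))
  ps2 <- pose_set(rec, list(one_atom_pose("L1", c(0, 0, 1)),
                            one_atom_pose("L2", c(0, 0, 2))))
  cp2 <- contact_frequency(ps2, cutoff = 5)
  expect_identical(cp2$category[1], "high")
})

test_that("frequencies are invariant under a joint rigid motion", {
  set.seed(23)
  toy <- gen_toy_poseset(8, 5, seed = 3)
  cp0 <- contact_frequency(toy$pose_set)
  R <- random_rotation(); tr <- runif(3, -20, 20)
  moved <- toy$pose_set
  xyz <- as.matrix(moved$receptor[, c("x", "y", "z")]) %*% t(R)
  moved$receptor$x <- xyz[, 1] + tr[1]
  moved$receptor$y <- xyz[, 2] + tr[2]
  moved$receptor$z <- xyz[, 3] + tr[3]
  moved$poses <- lapply(moved$poses, function(p) {
    p$coords <- p$coords %*% t(R) + matrix(tr, nrow(p$coords), 3, TRUE); p
  })
  cp1 <- contact_frequency(moved)
  expect_equal(cp1$frequency, cp0$frequency, tolerance = 1e-12)
})

test_that("adding one pose moves each frequency by at most 1/(n+1)", {
  toy <- gen_toy_poseset(10, 6, seed = 5)
  cp0 <- contact_frequency(toy$pose_set)
  augmented <- toy$pose_set
  augmented$poses <- c(augmented$poses,
                       list(one_atom_pose("extra", c(15, 0, 3))))
  cp1 <- contact_frequency(augmented)
  n <- 6
  expect_true(all(abs(cp1$frequency - cp0$frequency) <= 1 / (n + 1) + 1e-12))
})

test_that("contact frequencies equal an all-pairs brute-force scan", {
  toy <- gen_toy_poseset(50, 8, seed = 11)
  cp <- contact_frequency(toy$pose_set)
  o <- oracle_contact_freq(toy$pose_set)
  expect_equal(setNames(cp$frequency, cp$residue), o, tolerance = 1e-12)
})

test_that("interaction typing applies the distance rules", {
  rec <- make_interaction_receptor()
  # ligand cation 2.82 A from ASP OD1; donor N 3.1 A from POPC phosphate O
  poses <- list(list(ligand_id = "lig",
                     coords = rbind(c(-2.82, 0, 0), c(20.5, 1.0, 3.1), c(22, 0, 6)),
                     elements = c("N", "N", "C"),
                     charges = c(1L, 0L, 0L)))
  ps <- pose_set(rec, poses)
  ints <- annotate_interactions(ps)
  sb <- ints[ints$type == "salt-bridge", ]
  expect_true(all(sb$residue == "A:ASP:569"))
  expect_equal(min(sb$distance), 2.82, tolerance = 1e-9)
  hb <- ints[ints$type == "H-bond" & ints$residue == "A:POPC:100", ]
  expect_true(any(abs(hb$distance - 3.1) < 1e-9))
  # the apolar carbon sits 6 A from POPC C1: no hydrophobic contact recorded
  expect_false(any(ints$type == "hydrophobic" & ints$ligand_atom == 3))
})

test_that("zone assignment follows the axial intervals", {
  zones <- list(bottom = c(-10, -3), middle = c(-3, 3), top = c(3, 10))
  expect_identical(assign_zone(c(0, 0, 0), zones), "middle")
  expect_identical(assign_zone(c(1, 1, 12), zones), "outside")
  expect_identical(assign_zone(c(0, 0, -5), zones), "bottom")
  expect_identical(assign_zone(c(0, 0, 5), zones), "top")
  expect_error(assign_zone(c(0, 0, 0),
                           list(middle = c(-3, 3), top = c(2, 8))), "overlap")
})

test_that("empty poses are rejected", {
  expect_error(pose_set(toy_receptor_3res(),
                        list(list(ligand_id = "x",
                                  coords = matrix(numeric(), 0, 3),
                                  elements = character()))),
               "heavy")
})
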