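#' Specification of a planted-pharmacophore synthetic ligand set
#'
#' Describes a ground-truth feature arrangement (type signature plus
#' pairwise distances), the per-feature coordinate noise applied to each
#' synthetic active, and the composition of the set: actives that contain
#' the planted arrangement plus distractor features, and decoys that carry
#' the same feature-type inventory in randomized geometry.
#'
#' The default geometry is a four-point acceptor / positive-charge /
#' two-aromatic-ring (APRR) arrangement with inter-feature distances in the
#' 3-7 Angstrom range typical of small-molecule pharmacophores.
#'
#' @param signature Feature type signature, e.g. `"APRR"`.
#' @param distances Optional pairwise distance matrix (Angstrom) between
#'   the planted features; embedded into 3D by classical multidimensional
#'   scaling. Defaults to a fixed realistic geometry for `"APRR"`.
#' @param sigma Gaussian coordinate noise per active, Angstrom
#'   (default 0.2).
#' @param n_actives Number of active molecules (default 6).
#' @param n_decoys_per_active Decoys per active (default 40).
#' @param n_distractors Extra non-planted features per molecule
#'   (default 2).
#' @param seed Integer seed.
#' @return Object of class `planted_spec`.
#' @export
planted_spec <- function(signature = "APRR", distances = NULL, sigma = 0.2,
                         n_actives = 6L, n_decoys_per_active = 40L,
                         n_distractors = 2L, seed = 1L) {
  types <- strsplit(signature, "")[[1]]
  if (!all(types %in% c("A", "D", "H", "N", "P", "R")))
    abort_input("signature may only contain A, D, H, N, P, R")
  if (length(types) < 3L || length(types) > 5L)
    abort_input("planted signatures follow the 3-5 feature hypothesis bounds")
  if (sigma < 0) abort_input("sigma must be nonnegative")
  pos <- if (is.null(distances)) {
    if (signature == "APRR") {
      rbind(A = c(0.0, 0.0, 0.0),
            P = c(5.2, 0.0, 0.0),
            R1 = c(2.6, 3.4, 0.8),
            R2 = c(2.4, -2.9, 1.2))
    } else default_signature_geometry(types, seed)
  } else embed_distances(as.matrix(distances))
  if (nrow(pos) != length(types))
    abort_input("distance matrix size must match the signature length")
  pos <- sweep(pos, 2, colMeans(pos))
  structure(list(signature = signature, types = types, positions = pos,
                 sigma = sigma, n_actives = as.integer(n_actives),
                 n_decoys_per_active = as.integer(n_decoys_per_active),
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "planted_spec")
}

# Random (seeded) but fixed geometry for non-default signatures.
default_signature_geometry <- function(types, seed) {
  with_seed(child_seed(seed, "geometry"), {
    repeat {
      pos <- matrix(stats::runif(3 * length(types), -3.5, 3.5), ncol = 3)
      if (min(stats::dist(pos)) > 2.5) break
    }
    rownames(pos) <- types
    pos
  })
}

# Classical MDS embedding of a planted distance matrix into 3D; rejects
# distance sets that are not realizable.
embed_distances <- function(D) {
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    abort_input("distances must form a symmetric matrix")
  em <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(3L, nrow(D) - 1L), eig = TRUE))
  pos <- cbind(em$points, matrix(0, nrow(D), 3 - ncol(em$points)))
  if (max(abs(as.matrix(stats::dist(pos)) - D)) > 1e-6)
    abort_input("infeasible distance set: not embeddable in 3D")
  pos
}

# Fixed unit directions for the planted directional features.
planted_directions <- function(types) {
  dirs <- vector("list", length(types))
  base <- list(A = c(0, 0, 1), D = c(0, 1, 0), R = c(0.2, 0.1, 1))
  for (i in seq_along(types))
    if (types[i] %in% names(base)) dirs[[i]] <- unitize(base[[types[i]]])
  dirs
}

#' Generate a planted-pharmacophore ligand set with ground truth
#'
#' Actives contain the planted feature arrangement with independent
#' Gaussian coordinate noise (`sigma`) plus random distractor features, in
#' a random rigid frame per molecule. Decoys carry the identical
#' feature-type inventory but randomized geometry, rejection-sampled so
#' that the best rigid-superposition RMSD of their planted-type features
#' onto the ground truth exceeds `decoy_min_rmsd`. The ground-truth
#' hypothesis is returned alongside the data.
#'
#' @param spec A [planted_spec()].
#' @param tolerance Tolerance of the returned ground-truth hypothesis
#'   (default 1.0).
#' @param decoy_min_rmsd Decoy rejection radius in Angstrom (default 2.0).
#' @return List `actives`, `decoys` (lists of [feature_set()]), `truth`
#'   (a [hypothesis()]), `spec`.
#' @export
gen_planted_set <- function(spec, tolerance = 1.0, decoy_min_rmsd = 2.0) {
  stopifnot(inherits(spec, "planted_spec"))
  types <- spec$types
  dirs <- planted_directions(types)
  truth <- hypothesis(
    paste0(spec$signature, "-true"),
    lapply(seq_along(types), function(i)
      pharm_feature(types[i], spec$positions[i, ], direction = dirs[[i]])),
    tolerance = tolerance)

  all_types <- c("A", "D", "H", "N", "P", "R")
  span <- max(3, max(abs(spec$positions))) + 3

  make_active <- function(i) {
    with_seed(child_seed(spec$seed, paste0("active", i)), {
      pos <- spec$positions + matrix(stats::rnorm(length(spec$positions), 0, spec$sigma),
                                     ncol = 3)
      feats <- lapply(seq_along(types), function(j)
        pharm_feature(types[j], pos[j, ], direction = dirs[[j]]))
      for (k in seq_len(spec$n_distractors)) {
        ft <- sample(all_types, 1)
        feats[[length(feats) + 1L]] <- pharm_feature(
          ft, stats::runif(3, -span, span),
          direction = if (ft %in% c("A", "D", "R")) unitize(stats::rnorm(3)) else NULL)
      }
      fs <- feature_set(sprintf("active-%02d", i), feats)
      random_rigid_motion(fs)
    })
  }

  make_decoy <- function(i) {
    with_seed(child_seed(spec$seed, paste0("decoy", i)), {
      for (try in 1:500) {
        pos <- matrix(stats::runif(length(types) * 3, -span / 2, span / 2), ncol = 3)
        feats <- lapply(seq_along(types), function(j)
          pharm_feature(types[j], pos[j, ],
                        direction = if (types[j] %in% c("A", "D", "R"))
                          unitize(stats::rnorm(3)) else NULL))
        for (k in seq_len(spec$n_distractors)) {
          ft <- sample(all_types, 1)
          feats[[length(feats) + 1L]] <- pharm_feature(
            ft, stats::runif(3, -span, span),
            direction = if (ft %in% c("A", "D", "R")) unitize(stats::rnorm(3)) else NULL)
        }
        fs <- feature_set(sprintf("decoy-%03d", i), feats)
        m <- match_to_hypothesis(fs, truth, rmsd_max = Inf)
        if (is.null(m) || m$rmsd > decoy_min_rmsd) return(random_rigid_motion(fs))
      }
      abort_input("could not sample a decoy beyond the rejection radius")
    })
  }

  actives <- lapply(seq_len(spec$n_actives), make_active)
  decoys <- lapply(seq_len(spec$n_actives * spec$n_decoys_per_active), make_decoy)
  list(actives = actives, decoys = decoys, truth = truth, spec = spec)
}

# Apply a random rotation + translation to a feature set (uses the current
# RNG stream).
random_rigid_motion <- function(fs, max_shift = 10) {
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- stats::runif(3, -max_shift, max_shift)
  fs$features <- lapply(fs$features, function(f) {
    f$position <- as.numeric(R %*% f$position) + tr
    if (!is.null(f$direction)) f$direction <- as.numeric(R %*% f$direction)
    f
  })
  fs
}

#' Generate a toy pore structure with an analytic radius profile
#'
#' Stacks rings of pseudo-atoms along the z axis; the true pore radius at a
#' ring is the ring radius minus the atom van der Waals radius, so the
#' profiler can be validated against analytic geometry.
#'
#' @param ring_radii Data frame with columns `z` and `R` (ring radius,
#'   Angstrom), at least 2 rings.
#' @param atom_vdw Van der Waals radius of the pseudo-atoms (default 1.5).
#' @param atoms_per_ring Angular discretization (default 24).
#' @param seed Seed for the per-ring angular phase (default 1).
#' @return List `structure` (data frame x, y, z, element, vdw),
#'   `analytic` (data frame z, radius), `atom_vdw`.
#' @export
gen_toy_pore <- function(ring_radii, atom_vdw = 1.5, atoms_per_ring = 24L, seed = 1L) {
  ring_radii <- as.data.frame(ring_radii)
  if (!all(c("z", "R") %in% names(ring_radii)) || nrow(ring_radii) < 2L)
    abort_input("ring_radii needs >= 2 rows with columns z and R")
  if (any(ring_radii$R <= atom_vdw))
    abort_input("ring radius must exceed the atom vdW radius")
  rows <- with_seed(child_seed(seed, "toypore"), {
    lapply(seq_len(nrow(ring_radii)), function(i) {
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * seq_len(atoms_per_ring) / atoms_per_ring
      data.frame(x = ring_radii$R[i] * cos(ang),
                 y = ring_radii$R[i] * sin(ang),
                 z = ring_radii$z[i], element = "X", vdw = atom_vdw)
    })
  })
  list(structure = do.call(rbind, rows),
       analytic = data.frame(z = ring_radii$z, radius = ring_radii$R - atom_vdw),
       atom_vdw = atom_vdw)
}

#' Generate a toy receptor and pose ensemble with known contact fractions
#'
#' Places single-atom residues far apart (15 Angstrom spacing, beyond twice
#' the 5 Angstrom contact radius) and builds poses whose atoms sit 3
#' Angstrom from exactly the residues each pose is planted to contact, so
#' the returned ground-truth contact profile is exact by construction.
#'
#' @param n_residues Number of receptor residues.
#' @param n_poses Number of ligand poses (>= 1).
#' @param planted_frequencies Optional numeric vector in \[0, 1\] (length
#'   `n_residues`); realized counts are `round(f * n_poses)`. Random when
#'   omitted.
#' @param seed Integer seed.
#' @return List `pose_set` ([pose_set()]) and `truth` (data frame residue,
#'   count, frequency, category).
#' @export
gen_toy_poseset <- function(n_residues, n_poses, planted_frequencies = NULL,
                            seed = 1L) {
  if (n_poses < 1L) abort_input("need at least one pose")
  if (n_residues < 1L) abort_input("need at least one residue")
  with_seed(child_seed(seed, "toyposes"), {
    if (is.null(planted_frequencies))
      planted_frequencies <- sample(0:n_poses, n_residues, replace = TRUE) / n_poses
    if (length(planted_frequencies) != n_residues ||
        any(planted_frequencies < 0 | planted_frequencies > 1))
      abort_input("planted frequencies must be in [0, 1], one per residue")
    counts <- round(planted_frequencies * n_poses)
    receptor <- data.frame(
      chain = "A", resno = seq_len(n_residues),
      resname = "GLY", atom = "CA", element = "C",
      x = 15 * seq_len(n_residues), y = 0, z = 0)
    contacted_by <- lapply(seq_len(n_residues), function(i)
      sort(sample(seq_len(n_poses), counts[i])))
    poses <- lapply(seq_len(n_poses), function(p) {
      res_here <- which(vapply(contacted_by, function(s) p %in% s, logical(1)))
      coords <- if (length(res_here)) {
        cbind(15 * res_here, 0, 3)
      } else matrix(c(0, 500, 500), 1)
      list(ligand_id = sprintf("pose-%02d", p), coords = coords,
           elements = rep("C", nrow(coords)),
           charges = integer(nrow(coords)))
    })
    truth <- data.frame(
      residue = paste("A", "GLY", seq_len(n_residues), sep = ":"),
      count = as.integer(counts),
      frequency = counts / n_poses,
      category = ifelse(counts / n_poses > 0.5, "high", "low"))
    list(pose_set = pose_set(receptor, poses), truth = truth)
  })
}

#' Built-in demonstration compound set for diversity clustering
#'
#' A small library of drug-like SMILES spanning a few obvious structural
#' families (arylpiperazines, phenethylamines, benzamides) plus singletons;
#' used by the pipeline driver to exercise fingerprint clustering and
#' representative selection on synthetic runs.
#'
#' @return Named character vector of SMILES.
#' @export
demo_molecule_set <- function() {
  c(arylpip1 = "c1ccccc1N2CCN(C)CC2",
    arylpip2 = "c1ccc(Cl)cc1N2CCN(C)CC2",
    arylpip3 = "c1ccc(O)cc1N2CCN(CC)CC2",
    arylpip4 = "c1ccc(F)cc1N2CCNCC2",
    phenethyl1 = "NCCc1ccccc1",
    phenethyl2 = "CNCCc1ccc(O)cc1",
    phenethyl3 = "CC(N)Cc1ccccc1",
    benzamide1 = "NC(=O)c1ccccc1",
    benzamide2 = "CNC(=O)c1ccc(Cl)cc1",
    benzamide3 = "CCNC(=O)c1ccc(OC)cc1",
    singleton1 = "OCC1OC(O)C(O)C(O)C1O",
    singleton2 = "C1CCCCC1CCCCC",
    singleton3 = "c1ccc2ccccc2c1")
}

#' Synthetic binding-energy table for a compound set
#'
#' Draws per-compound binding energies (kcal/mol) without phospholipids
#' from a Normal(-40, 8) and adds a lipid shift Normal(-15, 6) for the
#' with-phospholipid column, mimicking the typical pattern of more
#' favorable energies when pore-adjacent lipids are included.
#'
#' @param ids Compound identifiers.
#' @param seed Integer seed.
#' @return An [energy_table()].
#' @export
gen_energy_table <- function(ids, seed = 1L) {
  with_seed(child_seed(seed, "energies"), {
    dg0 <- stats::rnorm(length(ids), -40, 8)
    energy_table(ids, dg0, dg0 + stats::rnorm(length(ids), -15, 6))
  })
}
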