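#' Receptor plus docked-pose ensemble container
#'
#' Holds a macromolecular receptor (protein chains plus any non-protein
#' residues such as membrane phospholipids, each lipid treated as one
#' residue under its PDB residue id) and an ensemble of docked ligand
#' poses. All geometry downstream uses heavy atoms only; hydrogens in
#' either component are dropped, since pose files commonly omit or misplace
#' them.
#'
#' @param receptor Data frame with columns `chain`, `resno`, `resname`,
#'   `atom` (atom name), `element`, `x`, `y`, `z`. Use
#'   [read_receptor_pdb()] to build one from a PDB file.
#' @param poses List of poses; each a list with `ligand_id`, `coords`
#'   (heavy-atom n x 3 matrix), `elements`, and optional `charges`.
#' @param grid Optional metadata (e.g. the docking grid box) carried along.
#' @return Object of class `pose_set`.
#' @export
pose_set <- function(receptor, poses, grid = NULL) {
  receptor <- as.data.frame(receptor)
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(receptor)))
    abort_input(sprintf("receptor needs columns: %s", paste(need, collapse = ", ")))
  receptor <- receptor[receptor$element != "H", , drop = FALSE]
  if (!all(is.finite(as.matrix(receptor[, c("x", "y", "z")]))))
    abort_input("receptor coordinates must be finite")
  if (!length(poses)) abort_input("need at least one pose")
  poses <- lapply(poses, function(p) {
    p$coords <- as.matrix(p$coords)
    if (is.null(p$elements)) p$elements <- rep("C", nrow(p$coords))
    keep <- p$elements != "H"
    p$coords <- p$coords[keep, , drop = FALSE]
    p$elements <- p$elements[keep]
    if (!is.null(p$charges)) p$charges <- p$charges[keep]
    if (!nrow(p$coords)) abort_input(sprintf("pose '%s' has no heavy atoms", p$ligand_id))
    if (!all(is.finite(p$coords))) abort_input("pose coordinates must be finite")
    p
  })
  structure(list(receptor = receptor, poses = poses, grid = grid),
            class = "pose_set")
}

residue_keys <- function(receptor) {
  paste(receptor$chain, receptor$resname, receptor$resno, sep = ":")
}

#' Read a receptor structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]; keeps ATOM and HETATM records (so membrane
#' lipids come along as residues) and infers the element from the PDB
#' element column or the atom name.
#'
#' @param path PDB file path.
#' @return Receptor data frame for [pose_set()].
#' @export
read_receptor_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  guess <- sub("[0-9'].*$", "", trimws(at$elety))
  guess <- ifelse(nchar(guess) > 1 & !guess %in% c("CL", "BR", "NA", "MG", "ZN", "CA"),
                  substr(guess, 1, 1), guess)
  elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2)))
  data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
             atom = trimws(at$elety), element = trimws(elem),
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

#' Per-residue ligand contact frequencies over a pose ensemble
#'
#' A residue is contacted by a ligand pose when any ligand heavy atom lies
#' within `cutoff` of any residue heavy atom; its contact frequency is the
#' fraction of poses contacting it. Residues with frequency strictly above
#' `high_threshold` are categorized `high`, all others `low` (a frequency of
#' exactly 0.5 is low). Non-protein residues such as phospholipids are
#' ordinary residues here.
#'
#' @param ps A [pose_set()].
#' @param cutoff Contact radius in Angstrom (default 5.0).
#' @param high_threshold High-contact cutoff on the frequency (default 0.5,
#'   strict inequality).
#' @return Data frame of class `contact_profile`: residue key, chain,
#'   resno, resname, contact count, frequency, category.
#' @export
contact_frequency <- function(ps, cutoff = 5.0, high_threshold = 0.5) {
  stopifnot(inherits(ps, "pose_set"))
  keys <- residue_keys(ps$receptor)
  ukeys <- unique(keys)
  rec_xyz <- as.matrix(ps$receptor[, c("x", "y", "z")])
  counts <- stats::setNames(integer(length(ukeys)), ukeys)
  for (p in ps$poses) {
    # squared-distance scan pose atoms x receptor atoms, then fold to residues
    d2 <- outer(rowSums(p$coords^2), rowSums(rec_xyz^2), `+`) -
      2 * p$coords %*% t(rec_xyz)
    hit_atom <- colSums(d2 <= cutoff^2 + 1e-9) > 0
    hit_res <- unique(keys[hit_atom])
    counts[hit_res] <- counts[hit_res] + 1L
  }
  n <- length(ps$poses)
  freq <- counts / n
  first <- match(ukeys, keys)
  structure(data.frame(
    residue = ukeys,
    chain = ps$receptor$chain[first],
    resno = ps$receptor$resno[first],
    resname = ps$receptor$resname[first],
    count = as.integer(counts),
    frequency = as.numeric(freq),
    category = ifelse(freq > high_threshold, "high", "low"),
    stringsAsFactors = FALSE), class = c("contact_profile", "data.frame"))
}

# Standard aromatic side-chain ring atoms for cation-pi detection.
aromatic_ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Load the residue interaction templates
#'
#' Maps (residue name, atom name) to interaction roles (cation, anion,
#' donor, acceptor); backbone amide N/O are covered under the pseudo-residue
#' `BCK`, and phospholipid head-group atoms are included so lipids
#' participate in interaction typing. Editable CSV shipped with the package.
#'
#' @param path Optional alternative CSV.
#' @return Data frame resname/atom/role.
#' @export
default_residue_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_templates.csv", package = "metscreen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Type receptor-ligand interactions over a pose ensemble
#'
#' Applies distance criteria between heavy atoms: salt bridge at most
#' `salt_bridge` Angstrom between oppositely charged atoms, hydrogen bond
#' at most `hbond` between a donor and an acceptor (either direction),
#' cation-pi at most `cation_pi` from a ligand cation to an aromatic
#' side-chain ring centroid, and hydrophobic contact at most `hydrophobic`
#' between apolar carbons. Ligand atom roles come from formal charges and
#' elements (charged atoms are ions; neutral N/O count as donor and
#' acceptor; carbons as apolar). Residues without a template entry simply
#' contribute no typed polar interactions.
#'
#' @param ps A [pose_set()] whose poses carry `charges`.
#' @param templates Residue role table ([default_residue_templates()]).
#' @param salt_bridge,hbond,cation_pi,hydrophobic Distance cutoffs in
#'   Angstrom (defaults 4.0, 3.5, 4.5, 4.5).
#' @return Data frame: ligand_id, residue, type, distance (Angstrom),
#'   ligand_atom, residue_atom. Hydrophobic contacts report the closest
#'   apolar pair per (ligand, residue).
#' @export
annotate_interactions <- function(ps, templates = default_residue_templates(),
                                  salt_bridge = 4.0, hbond = 3.5,
                                  cation_pi = 4.5, hydrophobic = 4.5) {
  stopifnot(inherits(ps, "pose_set"))
  rec <- ps$receptor
  keys <- residue_keys(rec)
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  tpl_key <- paste(templates$resname, templates$atom)
  # backbone roles only applied to standard amino-acid residues
  std_aa <- unique(c(names(aromatic_ring_atoms), bio3d::aa.table$aa3))
  rec_roles <- lapply(seq_len(nrow(rec)), function(i) {
    r <- templates$role[tpl_key == paste(rec$resname[i], rec$atom[i])]
    if (rec$resname[i] %in% std_aa && rec$atom[i] %in% c("N", "O"))
      r <- c(r, templates$role[tpl_key == paste("BCK", rec$atom[i])])
    setdiff(unique(r), "aromatic_ring")
  })
  out <- list()
  add <- function(lig, res, type, d, latom, ratom)
    out[[length(out) + 1L]] <<- data.frame(ligand_id = lig, residue = res,
                                           type = type, distance = d,
                                           ligand_atom = latom, residue_atom = ratom,
                                           stringsAsFactors = FALSE)
  for (p in ps$poses) {
    charges <- if (is.null(p$charges)) integer(nrow(p$coords)) else p$charges
    lig_roles <- lapply(seq_len(nrow(p$coords)), function(j) {
      el <- p$elements[j]
      r <- character()
      if (charges[j] > 0) r <- c(r, "cation")
      if (charges[j] < 0) r <- c(r, "anion")
      if (el %in% c("N", "O") && charges[j] >= 0) r <- c(r, "acceptor")
      if (el %in% c("N", "O")) r <- c(r, "donor")
      if (el == "C" && charges[j] == 0) r <- c(r, "apolar")
      r
    })
    d2 <- outer(rowSums(p$coords^2), rowSums(rec_xyz^2), `+`) -
      2 * p$coords %*% t(rec_xyz)
    d <- sqrt(pmax(d2, 0))
    maxcut <- max(salt_bridge, hbond, hydrophobic)
    hydro_best <- list()
    for (j in seq_len(nrow(p$coords))) {
      for (i in which(d[j, ] <= maxcut)) {
        lr <- lig_roles[[j]]; rr <- rec_roles[[i]]
        dist_ji <- d[j, i]
        if (dist_ji <= salt_bridge &&
            (("cation" %in% lr && "anion" %in% rr) ||
             ("anion" %in% lr && "cation" %in% rr)))
          add(p$ligand_id, keys[i], "salt-bridge", dist_ji, j, rec$atom[i])
        else if (dist_ji <= hbond &&
                 (("donor" %in% lr && "acceptor" %in% rr) ||
                  ("acceptor" %in% lr && "donor" %in% rr)))
          add(p$ligand_id, keys[i], "H-bond", dist_ji, j, rec$atom[i])
        else if (dist_ji <= hydrophobic && "apolar" %in% lr &&
                 rec$element[i] == "C" && !length(rr)) {
          key <- keys[i]
          if (is.null(hydro_best[[key]]) || dist_ji < hydro_best[[key]]$d)
            hydro_best[[key]] <- list(d = dist_ji, j = j, atom = rec$atom[i])
        }
      }
    }
    for (key in names(hydro_best))
      add(p$ligand_id, key, "hydrophobic", hydro_best[[key]]$d,
          hydro_best[[key]]$j, hydro_best[[key]]$atom)
    # cation-pi: ligand cations versus aromatic side-chain ring centroids
    cations <- which(charges > 0)
    if (length(cations)) {
      for (key in unique(keys)) {
        rows <- which(keys == key)
        rn <- rec$resname[rows[1]]
        ring <- aromatic_ring_atoms[[rn]]
        if (is.null(ring)) next
        ring_rows <- rows[rec$atom[rows] %in% ring]
        if (length(ring_rows) < length(ring)) next
        ctr <- colMeans(rec_xyz[ring_rows, , drop = FALSE])
        for (j in cations) {
          dd <- sqrt(sum((p$coords[j, ] - ctr)^2))
          if (dd <= cation_pi)
            add(p$ligand_id, key, "cation-pi", dd, j, "ring")
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(ligand_id = character(), residue = character(),
                      type = character(), distance = numeric(),
                      ligand_atom = integer(), residue_atom = character()))
  do.call(rbind, out)
}

#' Assign a position to a pore zone by its axial coordinate
#'
#' Pore-facing ligand positions are labeled `top`, `middle` or `bottom` by
#' the axial (z) coordinate of the ligand centroid against disjoint axial
#' intervals; positions outside the covered span are `outside`.
#'
#' @param position Length-3 numeric (ligand centroid), or a single axial
#'   coordinate.
#' @param zones Named list of `c(lo, hi)` intervals for `top`, `middle`,
#'   `bottom` (as from [zone_boundaries_from_profile()]).
#' @return Zone label.
#' @export
assign_zone <- function(position, zones) {
  z <- if (length(position) == 3L) position[3] else position[1]
  nm <- names(zones)
  iv <- do.call(rbind, zones)
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]; nm <- nm[ord]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
    abort_config("zone intervals overlap")
  for (k in seq_along(nm)) if (z >= iv[k, 1] && z <= iv[k, 2]) return(nm[k])
  "outside"
}
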