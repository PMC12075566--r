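#' Pharmacophore feature and feature-set containers
#'
#' A pharmacophore feature is one of six chemical feature types placed in 3D:
#' hydrogen-bond acceptor (`A`), hydrogen-bond donor (`D`), hydrophobic group
#' (`H`), negatively charged group (`N`), positively charged group (`P`) and
#' aromatic ring (`R`). Acceptors, donors and rings carry a unit direction
#' vector (idealized lone pair, X-H vector, ring normal).
#'
#' @param ftype One of `"A"`, `"D"`, `"H"`, `"N"`, `"P"`, `"R"`.
#' @param position Length-3 numeric, Angstrom.
#' @param direction Optional length-3 numeric; normalized to unit length.
#' @param source_atoms Integer vector of contributing atom indices.
#' @return An object of class `pharm_feature`.
#' @export
pharm_feature <- function(ftype, position, direction = NULL, source_atoms = integer()) {
  if (!ftype %in% c("A", "D", "H", "N", "P", "R"))
    abort_input(sprintf("unknown feature type '%s'", ftype))
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    abort_input("feature position must be a finite 3-vector")
  if (!is.null(direction)) {
    direction <- unitize(as.numeric(direction))
  }
  structure(list(ftype = ftype, position = position, direction = direction,
                 source_atoms = as.integer(source_atoms)),
            class = "pharm_feature")
}

#' @param molecule_id Compound identifier the features belong to.
#' @param conformer_id Integer conformer tag.
#' @param features List of [pharm_feature()] objects.
#' @rdname pharm_feature
#' @export
feature_set <- function(molecule_id, features, conformer_id = 1L) {
  stopifnot(is.character(molecule_id), length(molecule_id) == 1L)
  if (!all(vapply(features, inherits, logical(1), "pharm_feature")))
    abort_input("features must be pharm_feature objects")
  structure(list(molecule_id = molecule_id, conformer_id = as.integer(conformer_id),
                 features = features),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s (conformer %d): %s\n", x$molecule_id,
              x$conformer_id, paste(feature_types(x), collapse = "")))
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$features)

feature_types <- function(fs) vapply(fs$features, `[[`, character(1), "ftype")

feature_positions <- function(fs) {
  if (!length(fs$features)) return(matrix(numeric(), 0, 3))
  do.call(rbind, lapply(fs$features, `[[`, "position"))
}

#' Load the pharmacophore feature rule table
#'
#' The perception rules are a versioned, editable table shipped with the
#' package: one row per (feature type, structural predicate, placement
#' mode). Each predicate is a named graph rule evaluated on the molecular
#' graph (elements, bonds, formal charges, aromaticity); users may disable
#' rows or point [perceive_features()] at an edited copy.
#'
#' @param path Optional path to an alternative rule table (CSV).
#' @return Data frame of rules.
#' @export
default_feature_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feature_rules.csv", package = "metscreen")
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ftype", "rule", "placement", "param", "enabled")
  if (!all(need %in% names(rules)))
    abort_config("rule table must have columns ftype, rule, placement, param, enabled")
  rules[as.logical(rules$enabled), , drop = FALSE]
}

#' Perceive 3D pharmacophore features of a molecule
#'
#' Assigns A/D/H/N/P/R features from the rule table: aromatic rings at ring
#' centroids with the ring normal as direction, positive/negative charge
#' centers, acceptor/donor heteroatoms with idealized lone-pair or X-H
#' directions, and centroids of apolar carbon clusters. Structures must
#' carry explicit hydrogens and formal charges. Overlapping features of the
#' same type within `merge_radius` are merged to their centroid, which
#' prevents double-counting in fused-ring systems.
#'
#' A molecule in which no rule fires yields an empty feature set (not an
#' error); an unparsable molecule is an input error upstream.
#'
#' @param mol A [molecule3d()].
#' @param rules Rule table from [default_feature_rules()].
#' @param merge_radius Same-type features closer than this (Angstrom) are
#'   merged (default 1.0).
#' @return A [feature_set()].
#' @export
perceive_features <- function(mol, rules = default_feature_rules(), merge_radius = 1.0) {
  stopifnot(inherits(mol, "molecule3d"))
  ctx <- perception_context(mol)
  feats <- list()
  claimed <- list(A = integer(), D = integer(), H = integer(),
                  N = integer(), P = integer(), R = integer())
  for (i in seq_len(nrow(rules))) {
    fn <- feature_rule_registry[[rules$rule[i]]]
    if (is.null(fn))
      abort_config(sprintf("unknown feature rule '%s'", rules$rule[i]))
    ft <- rules$ftype[i]
    got <- fn(mol, ctx, param = rules$param[i], claimed = claimed[[ft]])
    for (f in got) {
      f$ftype <- ft
      feats[[length(feats) + 1L]] <- do.call(pharm_feature, f)
      claimed[[ft]] <- union(claimed[[ft]], f$source_atoms)
    }
  }
  feats <- merge_close_features(feats, merge_radius)
  feature_set(mol$id, feats, conformer_id = mol$conformer_id)
}

# Precompute graph context shared by all rules.
perception_context <- function(mol) {
  adj <- mol_adjacency(mol)
  list(adj = adj,
       rings = aromatic_rings(mol, adj),
       h_neighbors = lapply(seq_len(n_atoms(mol)),
                            function(i) adj[[i]][mol$elements[adj[[i]]] == "H"]))
}

# Smallest rings of the molecular graph: for every bond, the shortest
# cycle through it (BFS in the graph with that bond removed). This
# recovers the rings chemists care about (SSSR-style) without enumerating
# all simple cycles.
smallest_rings <- function(mol, adj, max_size = 7L) {
  rings <- list()
  seen <- character()
  for (b in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$from[b]; z <- mol$bonds$to[b]
    # BFS from a to z avoiding the direct edge
    prev <- rep(NA_integer_, n_atoms(mol))
    prev[a] <- 0L
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (cur == a && nb == z) next
        if (!is.na(prev[nb])) next
        prev[nb] <- cur
        if (nb == z) { found <- TRUE; break }
        queue <- c(queue, nb)
      }
    }
    if (!found) next
    path <- z
    while (path[1] != a) path <- c(prev[path[1]], path)
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- path
  }
  rings
}

# Aromatic ring detection: smallest rings of size 5-7 whose atoms are
# C/N/O/S, approximately coplanar, with bond orders drawn from {1,2,4} and
# enough double/aromatic bonds for a conjugated ring.
aromatic_rings <- function(mol, adj = mol_adjacency(mol)) {
  if (!nrow(mol$bonds)) return(list())
  rings <- list()
  order_lookup <- function(a, b) {
    hit <- (mol$bonds$from == a & mol$bonds$to == b) |
      (mol$bonds$from == b & mol$bonds$to == a)
    mol$bonds$order[which(hit)[1]]
  }
  for (idx in smallest_rings(mol, adj)) {
    if (length(idx) < 5L || length(idx) > 7L) next
    if (!all(mol$elements[idx] %in% c("C", "N", "O", "S"))) next
    orders <- mapply(order_lookup, idx, c(idx[-1], idx[1]))
    if (!all(orders %in% c(1, 2, 4))) next
    if (sum(orders >= 2) < floor(length(idx) / 2)) next
    pts <- mol$coords[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    dec <- svd(sweep(pts, 2, ctr))
    normal <- dec$v[, 3]
    # coplanarity: residual along the normal
    if (max(abs(sweep(pts, 2, ctr) %*% normal)) > 0.15) next
    rings[[length(rings) + 1L]] <- list(atoms = idx, centroid = ctr, normal = normal)
  }
  rings
}

# --- rule implementations ------------------------------------------------
# Each returns a list of lists(position, direction, source_atoms); ftype is
# filled in by the dispatcher. `claimed` lists atoms already consumed by an
# earlier rule of the same feature type.

rule_aromatic_ring <- function(mol, ctx, param, claimed) {
  lapply(ctx$rings, function(r)
    list(position = r$centroid, direction = r$normal, source_atoms = r$atoms))
}

rule_positive_atom <- function(mol, ctx, param, claimed) {
  idx <- setdiff(which(mol$charges > 0 & mol$elements != "H"), claimed)
  lapply(idx, function(i)
    list(position = mol$coords[i, ], direction = NULL, source_atoms = i))
}

rule_carboxylate <- function(mol, ctx, param, claimed) {
  out <- list()
  for (c_idx in which(mol$elements == "C")) {
    ox <- ctx$adj[[c_idx]][mol$elements[ctx$adj[[c_idx]]] == "O"]
    if (length(ox) != 2L) next
    # one oxygen negatively charged (or either, in a delocalized record)
    if (!any(mol$charges[ox] < 0)) next
    if (any(ox %in% claimed)) next
    out[[length(out) + 1L]] <- list(position = colMeans(mol$coords[ox, , drop = FALSE]),
                                    direction = NULL, source_atoms = ox)
  }
  out
}

rule_negative_atom <- function(mol, ctx, param, claimed) {
  idx <- setdiff(which(mol$charges < 0 & mol$elements != "H"), claimed)
  lapply(idx, function(i)
    list(position = mol$coords[i, ], direction = NULL, source_atoms = i))
}

rule_acceptor_atom <- function(mol, ctx, param, claimed) {
  out <- list()
  for (i in setdiff(which(mol$elements %in% c("N", "O")), claimed)) {
    if (mol$charges[i] > 0) next
    nb <- ctx$adj[[i]]
    if (!length(nb)) next
    # a nitrogen with four connections has no lone pair to donate
    if (mol$elements[i] == "N" && length(nb) >= 4L) next
    vecs <- sweep(mol$coords[nb, , drop = FALSE], 2, mol$coords[i, ])
    vsum <- -colSums(vecs / sqrt(rowSums(vecs^2)))
    dir <- if (sqrt(sum(vsum^2)) > 1e-8) unitize(vsum) else NULL
    out[[length(out) + 1L]] <- list(position = mol$coords[i, ],
                                    direction = dir, source_atoms = i)
  }
  out
}

rule_donor_atom <- function(mol, ctx, param, claimed) {
  out <- list()
  for (i in setdiff(which(mol$elements %in% c("N", "O")), claimed)) {
    hs <- ctx$h_neighbors[[i]]
    if (!length(hs)) next
    vecs <- sweep(mol$coords[hs, , drop = FALSE], 2, mol$coords[i, ])
    dir <- unitize(colSums(vecs / sqrt(rowSums(vecs^2))))
    out[[length(out) + 1L]] <- list(position = mol$coords[i, ],
                                    direction = dir, source_atoms = i)
  }
  out
}

rule_apolar_cluster <- function(mol, ctx, param, claimed) {
  min_size <- if (is.na(param) || param == "") 2L else as.integer(param)
  ring_atoms <- unique(unlist(lapply(ctx$rings, `[[`, "atoms")))
  apolar <- vapply(seq_len(n_atoms(mol)), function(i) {
    if (mol$elements[i] != "C" || i %in% ring_atoms || mol$charges[i] != 0) return(FALSE)
    nb <- ctx$adj[[i]]
    all(mol$elements[nb] %in% c("C", "H", "F", "Cl", "Br", "I"))
  }, logical(1))
  idx <- setdiff(which(apolar), claimed)
  if (!length(idx)) return(list())
  # connected components among the apolar carbons
  comp <- rep(NA_integer_, n_atoms(mol))
  cid <- 0L
  for (start in idx) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[a])) next
      comp[a] <- cid
      queue <- c(queue, intersect(ctx$adj[[a]], idx))
    }
  }
  out <- list()
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    if (length(members) < min_size) next
    out[[length(out) + 1L]] <- list(
      position = colMeans(mol$coords[members, , drop = FALSE]),
      direction = NULL, source_atoms = members)
  }
  out
}

feature_rule_registry <- list(
  aromatic_ring = rule_aromatic_ring,
  positive_atom = rule_positive_atom,
  carboxylate = rule_carboxylate,
  negative_atom = rule_negative_atom,
  acceptor_atom = rule_acceptor_atom,
  donor_atom = rule_donor_atom,
  apolar_cluster = rule_apolar_cluster
)

# Connected components of a logical adjacency matrix (single linkage).
single_linkage_components <- function(adjmat) {
  n <- nrow(adjmat)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[a])) next
      comp[a] <- cid
      queue <- c(queue, which(adjmat[a, ] & is.na(comp)))
    }
  }
  comp
}

# Merge same-type features whose positions fall within `radius` of each
# other (single-linkage), replacing them by their centroid.
merge_close_features <- function(feats, radius) {
  if (length(feats) < 2L) return(feats)
  types <- vapply(feats, `[[`, character(1), "ftype")
  out <- list()
  for (ft in unique(types)) {
    idx <- which(types == ft)
    if (length(idx) == 1L) { out <- c(out, feats[idx]); next }
    pos <- do.call(rbind, lapply(feats[idx], `[[`, "position"))
    d <- as.matrix(stats::dist(pos))
    comp <- single_linkage_components(d <= radius)
    for (k in unique(comp)) {
      members <- idx[comp == k]
      if (length(members) == 1L) { out <- c(out, feats[members]); next }
      dirs <- Filter(Negate(is.null), lapply(feats[members], `[[`, "direction"))
      dir <- if (length(dirs) == length(members)) {
        s <- colSums(do.call(rbind, dirs))
        if (sqrt(sum(s^2)) > 1e-8) unitize(s) else NULL
      } else NULL
      out[[length(out) + 1L]] <- pharm_feature(
        ft, colMeans(do.call(rbind, lapply(feats[members], `[[`, "position"))),
        direction = dir,
        source_atoms = unique(unlist(lapply(feats[members], `[[`, "source_atoms"))))
    }
  }
  out
}

#' Serialize feature sets to JSON
#'
#' @param fsets A `feature_set` or list of them.
#' @param path Output path.
#' @export
write_feature_sets <- function(fsets, path) {
  if (inherits(fsets, "feature_set")) fsets <- list(fsets)
  payload <- lapply(fsets, function(fs) list(
    molecule_id = fs$molecule_id, conformer_id = fs$conformer_id,
    features = lapply(fs$features, function(f) list(
      ftype = f$ftype, position = f$position, direction = f$direction,
      source_atoms = f$source_atoms))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_sets
#' @export
read_feature_sets <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) feature_set(
    p$molecule_id,
    lapply(p$features, function(f) pharm_feature(
      f$ftype, unlist(f$position),
      direction = if (is.null(f$direction)) NULL else unlist(f$direction),
      source_atoms = unlist(f$source_atoms))),
    conformer_id = p$conformer_id))
}
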