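#' Morgan (circular, radius-2) fingerprints for a compound set
#'
#' Computes extended-connectivity fingerprints (ECFP4: circular environments
#' up to radius 2) through OpenBabel via [ChemmineR::fingerprintOB()], from
#' either an `SDFset` or a named character vector of SMILES. Returned as a
#' logical bit matrix, one row per compound.
#'
#' @param x Named character vector of SMILES, or a `ChemmineR::SDFset`.
#' @return Object of class `fingerprint_set`: list with `ids` and `bits`
#'   (logical matrix, rows = compounds).
#' @export
morgan_fingerprints <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("cmp%03d", seq_along(x))
    sdf <- ChemmineR::smiles2sdf(x)
  } else if (inherits(x, "SDFset")) {
    sdf <- x
  } else abort_input("x must be SMILES or an SDFset")
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  mat <- ChemmineR::as.matrix(fp) > 0
  rownames(mat) <- ChemmineR::sdfid(sdf)
  fingerprint_set(rownames(mat), mat)
}

#' @param ids Compound identifiers.
#' @param bits Logical matrix of fingerprint bits (rows = compounds).
#' @rdname morgan_fingerprints
#' @export
fingerprint_set <- function(ids, bits) {
  bits <- as.matrix(bits)
  mode(bits) <- "logical"
  if (!nrow(bits)) abort_input("fingerprint set is empty")
  if (length(ids) != nrow(bits)) abort_input("one id per fingerprint row required")
  rownames(bits) <- ids
  structure(list(ids = as.character(ids), bits = bits), class = "fingerprint_set")
}

#' Tanimoto similarity matrix of a fingerprint set
#'
#' Pairwise Tanimoto coefficients `|A & B| / |A | B|` between fingerprint
#' bit sets; 1 means identical circular environments, 0 none shared. The
#' matrix is symmetric with unit diagonal; the corresponding distance is
#' `1 - similarity`.
#'
#' @param fps A `fingerprint_set` with at least 2 compounds.
#' @return Numeric similarity matrix with compound ids as dimnames.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  if (nrow(fps$bits) < 2L) abort_input("need at least 2 fingerprints")
  B <- fps$bits * 1L
  inter <- tcrossprod(B)
  ones <- rowSums(B)
  uni <- outer(ones, ones, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / uni)   # two empty fingerprints: identical
  diag(sim) <- 1
  dimnames(sim) <- list(fps$ids, fps$ids)
  sim
}

#' Average-linkage clustering with a normalized dendrogram cut
#'
#' Builds an average-linkage (UPGMA) tree on a distance matrix and cuts it
#' at `normalized_threshold * max(merge height)`, assigning cluster labels
#' by the connected subtrees below the cut. The normalized (dendrogram-
#' relative) cut is the default reading of a "normalized distance
#' threshold": linkage heights vary per dataset even when distances live in
#' \[0, 1\], so a relative cut yields dataset-appropriate absolute cuts. Set
#' `normalized = FALSE` to cut at the absolute height instead.
#'
#' @param dist_mat Square symmetric distance matrix (e.g.
#'   `1 - tanimoto_matrix(fps)`).
#' @param normalized_threshold Cut height as a fraction of the maximum merge
#'   height, in (0, 1\] (or an absolute height when `normalized = FALSE`).
#' @param normalized Interpret the threshold as dendrogram-relative
#'   (default `TRUE`).
#' @return Object of class `cluster_assignment`: `labels` (named integer
#'   vector, contiguous), `tree` (`hclust`), `threshold`, `cut_height`,
#'   `n_clusters`.
#' @export
cluster_cut <- function(dist_mat, normalized_threshold, normalized = TRUE) {
  dist_mat <- as.matrix(dist_mat)
  if (nrow(dist_mat) != ncol(dist_mat) ||
      max(abs(dist_mat - t(dist_mat))) > 1e-8)
    abort_input("distance matrix must be square and symmetric")
  if (normalized_threshold <= 0 || (normalized && normalized_threshold > 1))
    abort_config("normalized threshold must lie in (0, 1]")
  tree <- stats::hclust(stats::as.dist(dist_mat), method = "average")
  hmax <- if (length(tree$height)) max(tree$height) else 0
  cut_height <- if (normalized) normalized_threshold * hmax else normalized_threshold
  labels <- if (hmax == 0) {
    # all points coincide: a single cluster at any threshold
    stats::setNames(rep(1L, nrow(dist_mat)), rownames(dist_mat))
  } else stats::cutree(tree, h = cut_height)
  # relabel contiguously in order of first appearance
  labels <- stats::setNames(match(labels, unique(labels)), names(labels))
  structure(list(labels = labels, tree = tree,
                 threshold = normalized_threshold, cut_height = cut_height,
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d items in %d clusters (cut %.3f)\n",
              length(x$labels), x$n_clusters, x$cut_height))
  invisible(x)
}

#' Binding-energy table for hit triage
#'
#' Per-compound binding free energies (kcal/mol), computed without and with
#' pore-adjacent phospholipids. These arrive as an input table from an
#' upstream rescoring step; more negative is more favorable.
#'
#' @param ids Compound identifiers.
#' @param dg_without,dg_with Numeric vectors of binding energies.
#' @return Data frame of class `energy_table`.
#' @export
energy_table <- function(ids, dg_without, dg_with) {
  if (!all(is.finite(dg_without)) || !all(is.finite(dg_with)))
    abort_input("binding energies must be finite")
  structure(data.frame(id = as.character(ids), dg_without = dg_without,
                       dg_with = dg_with, stringsAsFactors = FALSE),
            class = c("energy_table", "data.frame"))
}

#' Select representative hits from clusters by binding energy
#'
#' Within each cluster of at least `min_cluster_size` members, sorts members
#' by their binding energy without phospholipids (ascending: most favorable
#' first, ties broken by id) and takes the top `reps_per_cluster`.
#'
#' @param ca A [cluster_cut()] assignment.
#' @param e An [energy_table()] covering every clustered id.
#' @param min_cluster_size Minimum cluster size to contribute hits
#'   (default 3).
#' @param reps_per_cluster Either a single count, or a named list/vector
#'   mapping cluster labels to counts (unnamed default applies elsewhere).
#' @return Data frame of selected hits: id, cluster, dg_without, dg_with,
#'   rank within cluster.
#' @export
select_representatives <- function(ca, e, min_cluster_size = 3L, reps_per_cluster = 1L) {
  stopifnot(inherits(ca, "cluster_assignment"))
  e <- as.data.frame(e)
  missing_ids <- setdiff(names(ca$labels), e$id)
  if (length(missing_ids))
    abort_input(sprintf("missing binding energy for: %s",
                        paste(missing_ids, collapse = ", ")))
  reps_for <- function(cl) {
    if (length(reps_per_cluster) == 1L && is.null(names(reps_per_cluster)))
      return(as.integer(reps_per_cluster))
    v <- reps_per_cluster[[as.character(cl)]]
    if (is.null(v)) v <- reps_per_cluster[["default"]]
    if (is.null(v)) v <- 1L
    as.integer(v)
  }
  out <- list()
  for (cl in sort(unique(ca$labels))) {
    members <- names(ca$labels)[ca$labels == cl]
    if (length(members) < min_cluster_size) next
    sub <- e[match(members, e$id), , drop = FALSE]
    sub <- sub[order(sub$dg_without, sub$id), , drop = FALSE]
    take <- utils::head(seq_len(nrow(sub)), reps_for(cl))
    if (!length(take)) next
    out[[length(out) + 1L]] <- data.frame(
      id = sub$id[take], cluster = cl,
      dg_without = sub$dg_without[take], dg_with = sub$dg_with[take],
      rank_in_cluster = seq_along(take))
  }
  if (!length(out))
    return(data.frame(id = character(), cluster = integer(),
                      dg_without = numeric(), dg_with = numeric(),
                      rank_in_cluster = integer()))
  do.call(rbind, out)
}

#' Cross-check selected hits against phospholipid-aware energies
#'
#' Hits are triaged on binding energies computed without phospholipids;
#' this check verifies each selected hit also has a thermodynamically
#' favorable (negative) energy with phospholipids present, reports each
#' hit's rank percentile in both energy columns, and flags hits whose
#' binding weakens when phospholipids are included.
#'
#' @param hits Data frame from [select_representatives()] (needs `id`).
#' @param e Full [energy_table()].
#' @return Data frame: id, dg_without, dg_with, favorable_without,
#'   favorable_with, pct_rank_without, pct_rank_with, weaker_with_lipids.
#' @export
consistency_check <- function(hits, e) {
  e <- as.data.frame(e)
  idx <- match(hits$id, e$id)
  if (anyNA(idx)) abort_input("hit ids missing from the energy table")
  pct <- function(x, v) 100 * rank(x)[v] / length(x)
  data.frame(
    id = hits$id,
    dg_without = e$dg_without[idx],
    dg_with = e$dg_with[idx],
    favorable_without = e$dg_without[idx] < 0,
    favorable_with = e$dg_with[idx] < 0,
    pct_rank_without = pct(e$dg_without, idx),
    pct_rank_with = pct(e$dg_with, idx),
    weaker_with_lipids = e$dg_with[idx] > e$dg_without[idx])
}

#' Export an hclust tree as Newick text
#'
#' For inspection of the diversity dendrogram in standard tree viewers.
#'
#' @param tree An `hclust` object (e.g. `cluster_cut(...)$tree`).
#' @return Newick string (with branch lengths from merge heights).
#' @export
hclust_to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ph <- ape::as.phylo(tree)
  ape::write.tree(ph)
}
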