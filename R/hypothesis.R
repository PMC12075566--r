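#' Pharmacophore hypothesis container
#'
#' A hypothesis is an arrangement of 3-5 pharmacophore features in 3D with a
#' per-feature match radius (tolerance), a coverage fraction (share of
#' training molecules matched) and a quality score in \[0, 1\].
#'
#' @param id Hypothesis identifier; conventionally the type signature plus a
#'   counter, e.g. `"APRR-1"`.
#' @param features List of [pharm_feature()] (3 to 5 entries).
#' @param tolerance Match radius in Angstrom (default 1.0, the same value as
#'   the first-pass RMSD gate).
#' @param coverage Fraction of training molecules matched.
#' @param hypo_score Quality score, see [score_hypothesis()].
#' @return Object of class `hypothesis`.
#' @export
hypothesis <- function(id, features, tolerance = 1.0, coverage = NA_real_,
                       hypo_score = NA_real_) {
  if (length(features) < 3L || length(features) > 5L)
    abort_config("a hypothesis needs between 3 and 5 features")
  if (!all(vapply(features, inherits, logical(1), "pharm_feature")))
    abort_input("features must be pharm_feature objects")
  pos <- do.call(rbind, lapply(features, `[[`, "position"))
  h <- structure(list(id = as.character(id), features = features,
                      distance_matrix = as.matrix(stats::dist(pos)),
                      tolerance = tolerance, coverage = coverage,
                      hypo_score = hypo_score),
                 class = "hypothesis")
  h
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis> %s [%s] tol=%.2f A coverage=%.2f score=%.3f\n",
              x$id, hypothesis_signature(x), x$tolerance, x$coverage, x$hypo_score))
  invisible(x)
}

#' Type signature of a hypothesis (sorted feature letters, e.g. "APRR")
#' @param h A [hypothesis()].
#' @export
hypothesis_signature <- function(h) {
  paste(sort(vapply(h$features, `[[`, character(1), "ftype")), collapse = "")
}

hypothesis_positions <- function(h) do.call(rbind, lapply(h$features, `[[`, "position"))

#' Derive common pharmacophore hypotheses from a training set
#'
#' Enumerates candidate feature arrangements on each training molecule in
#' turn (all k-subsets of its perceived features, k between `min_features`
#' and `max_features`), verifies each candidate against every training
#' molecule by correspondence search with rigid superposition
#' ([match_to_hypothesis()]), keeps arrangements matched by at least
#' `min_coverage` of the molecules, deduplicates by type signature plus
#' distance-matrix agreement within tolerance, scores the survivors with
#' [score_hypothesis()] and returns them ranked.
#'
#' Training sets may contain several conformers per molecule (same
#' `molecule_id`); coverage counts molecules, using each molecule's best
#' conformer.
#'
#' @param training List of [feature_set()] objects.
#' @param min_features,max_features Hypothesis size bounds (3 and 5).
#' @param min_coverage Minimum fraction of training molecules a hypothesis
#'   must match (default 0.5).
#' @param tolerance Match radius / RMSD gate in Angstrom (default 1.0).
#' @param max_hypotheses Maximum number returned, best first (default 10).
#' @return List of [hypothesis()] objects ranked by `hypo_score`
#'   (descending; ties by id then feature count descending). Empty list if
#'   no arrangement reaches `min_coverage`.
#' @export
generate_hypotheses <- function(training, min_features = 3L, max_features = 5L,
                                min_coverage = 0.5, tolerance = 1.0,
                                max_hypotheses = 10L) {
  if (min_features > max_features)
    abort_config("min_features must not exceed max_features")
  if (min_features < 3L || max_features > 5L)
    abort_config("hypothesis sizes are restricted to 3-5 features")
  mol_ids <- unique(vapply(training, `[[`, character(1), "molecule_id"))
  if (length(mol_ids) < 2L)
    abort_config("need at least 2 training molecules")
  n_mol <- length(mol_ids)

  candidates <- list()
  sigs <- character()
  for (ref in training) {
    nf <- length(ref$features)
    if (nf < min_features) next
    for (k in seq(min_features, min(max_features, nf))) {
      combs <- utils::combn(nf, k, simplify = FALSE)
      for (cc in combs) {
        feats <- ref$features[cc]
        # center the arrangement at its centroid so hypotheses are
        # translation-free
        ctr <- colMeans(do.call(rbind, lapply(feats, `[[`, "position")))
        feats <- lapply(feats, function(f) { f$position <- f$position - ctr; f })
        cand <- hypothesis("tmp", feats, tolerance = tolerance)
        sig <- hypothesis_signature(cand)
        # dedupe: same signature and same sorted distance multiset within
        # tolerance
        dm <- sort(cand$distance_matrix[upper.tri(cand$distance_matrix)])
        dup <- FALSE
        for (j in seq_along(candidates)) {
          if (sigs[j] != sig) next
          dmj <- sort(candidates[[j]]$distance_matrix[upper.tri(candidates[[j]]$distance_matrix)])
          if (length(dm) == length(dmj) && all(abs(dm - dmj) <= tolerance)) {
            dup <- TRUE; break
          }
        }
        if (dup) next
        candidates[[length(candidates) + 1L]] <- cand
        sigs <- c(sigs, sig)
      }
    }
  }

  kept <- list()
  sig_counter <- integer()
  for (cand in candidates) {
    matched <- vapply(mol_ids, function(id) {
      confs <- Filter(function(fs) fs$molecule_id == id, training)
      any(vapply(confs, function(fs) {
        m <- match_to_hypothesis(fs, cand, rmsd_max = tolerance)
        !is.null(m)
      }, logical(1)))
    }, logical(1))
    cov <- mean(matched)
    if (cov < min_coverage) next
    cand$coverage <- cov
    cand$hypo_score <- score_hypothesis(cand, training)
    sig <- hypothesis_signature(cand)
    sig_counter[sig] <- if (is.na(sig_counter[sig])) 1L else sig_counter[sig] + 1L
    cand$id <- sprintf("%s-%d", sig, sig_counter[sig])
    kept[[length(kept) + 1L]] <- cand
  }
  if (!length(kept)) {
    message("no feature arrangement reached the coverage threshold; returning empty list")
    return(list())
  }
  scores <- vapply(kept, `[[`, numeric(1), "hypo_score")
  ids <- vapply(kept, `[[`, character(1), "id")
  nfeat <- vapply(kept, function(h) length(h$features), integer(1))
  ord <- order(-scores, ids, -nfeat)
  kept <- kept[ord]
  kept[seq_len(min(max_hypotheses, length(kept)))]
}

#' Score a hypothesis against a training set
#'
#' Quality score in \[0, 1\]: the mean, over matched training molecules, of
#' `(1 - RMSD / RMSD_max) * (mean direction-cosine of matched directional
#' features)`, multiplied by the coverage fraction, with
#' `RMSD_max = 2 * tolerance`. The score is 1 when every molecule matches
#' every feature exactly with perfectly aligned feature vectors, and 0 when
#' nothing matches. It is monotone in feature-vector alignment and match
#' geometry but is an analog quality score, not numerically comparable to
#' scores printed by proprietary pharmacophore software.
#'
#' @param h A [hypothesis()].
#' @param training List of [feature_set()] objects.
#' @return Numeric score in \[0, 1\].
#' @export
score_hypothesis <- function(h, training) {
  if (!length(training)) abort_config("empty training set")
  mol_ids <- unique(vapply(training, `[[`, character(1), "molecule_id"))
  rmsd_max <- 2 * h$tolerance
  per_mol <- vapply(mol_ids, function(id) {
    confs <- Filter(function(fs) fs$molecule_id == id, training)
    best <- NA_real_
    for (fs in confs) {
      m <- match_to_hypothesis(fs, h, rmsd_max = h$tolerance)
      if (is.null(m)) next
      q <- (1 - m$rmsd / rmsd_max) * m$vector_alignment
      if (is.na(best) || q > best) best <- q
    }
    best
  }, numeric(1))
  matched <- !is.na(per_mol)
  if (!any(matched)) return(0)
  coverage <- mean(matched)
  mean(per_mol[matched]) * coverage
}

#' Write / read hypotheses as JSON
#' @param hypos List of [hypothesis()] objects.
#' @param path File path.
#' @export
write_hypotheses <- function(hypos, path) {
  payload <- lapply(hypos, function(h) list(
    id = h$id, tolerance = h$tolerance, coverage = h$coverage,
    hypo_score = h$hypo_score,
    features = lapply(h$features, function(f) list(
      ftype = f$ftype, position = f$position, direction = f$direction))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hypotheses
#' @export
read_hypotheses <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) hypothesis(
    p$id,
    lapply(p$features, function(f) pharm_feature(
      f$ftype, unlist(f$position),
      direction = if (is.null(f$direction)) NULL else unlist(f$direction))),
    tolerance = p$tolerance,
    coverage = if (is.null(p$coverage)) NA_real_ else p$coverage,
    hypo_score = if (is.null(p$hypo_score)) NA_real_ else p$hypo_score))
}

#' Tabular report of a hypothesis list
#'
#' One row per hypothesis: id, type signature, number of features, coverage,
#' number of matching training molecules and quality score.
#'
#' @param hypos List of [hypothesis()] objects.
#' @param n_training Number of training molecules (to convert coverage into
#'   a matching-compound count); optional.
#' @return Data frame.
#' @export
hypothesis_report <- function(hypos, n_training = NULL) {
  df <- data.frame(
    id = vapply(hypos, `[[`, character(1), "id"),
    signature = vapply(hypos, hypothesis_signature, character(1)),
    n_features = vapply(hypos, function(h) length(h$features), integer(1)),
    coverage = vapply(hypos, `[[`, numeric(1), "coverage"),
    hypo_score = vapply(hypos, `[[`, numeric(1), "hypo_score"))
  if (!is.null(n_training)) df$n_matching <- round(df$coverage * n_training)
  df
}
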