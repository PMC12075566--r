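#' Match a molecule's features to a pharmacophore hypothesis
#'
#' First-pass geometric matching: over all same-type correspondences between
#' hypothesis features and molecule features (complete by default; when
#' `allow_partial = TRUE`, any subset covering at least 75% of the
#' hypothesis, rounded up), finds the correspondence minimizing the RMSD
#' after optimal rigid-body superposition (Kabsch). Molecules whose best
#' RMSD exceeds `rmsd_max` do not match and `NULL` is returned, mirroring a
#' 1 Angstrom geometric gate.
#'
#' @param fs A [feature_set()]; must be non-empty.
#' @param h A [hypothesis()].
#' @param rmsd_max RMSD gate in Angstrom (default 1.0).
#' @param allow_partial Allow partial matches covering >= 75% of the
#'   hypothesis features (default `FALSE`).
#' @return A `match_result` list (`molecule_id`, `hypothesis_id`,
#'   `correspondence` two-column matrix of hypothesis/molecule feature
#'   indices, `rmsd`, `matched_fraction`, `vector_alignment`) or `NULL` when
#'   nothing passes the gate.
#' @export
match_to_hypothesis <- function(fs, h, rmsd_max = 1.0, allow_partial = FALSE) {
  stopifnot(inherits(fs, "feature_set"), inherits(h, "hypothesis"))
  if (length(h$features) < 3L) abort_config("hypothesis has fewer than 3 features")
  if (!length(fs$features)) abort_input("feature set is empty")

  nh <- length(h$features)
  min_matched <- if (allow_partial) max(3L, ceiling(0.75 * nh)) else nh
  h_types <- vapply(h$features, `[[`, character(1), "ftype")
  m_types <- feature_types(fs)

  subsets <- if (allow_partial) {
    unlist(lapply(seq(min_matched, nh), function(k)
      utils::combn(nh, k, simplify = FALSE)), recursive = FALSE)
  } else list(seq_len(nh))

  best <- NULL
  for (sub in subsets) {
    for (asg in enumerate_assignments(h_types[sub], m_types)) {
      P <- feature_positions(fs)[asg, , drop = FALSE]
      Q <- hypothesis_positions(h)[sub, , drop = FALSE]
      fit <- kabsch_fit(P, Q)
      if (is.null(best) || fit$rmsd < best$rmsd - 1e-12) {
        best <- list(sub = sub, asg = asg, fit = fit, rmsd = fit$rmsd)
      }
    }
  }
  if (is.null(best) || best$rmsd > rmsd_max) return(NULL)

  # mean direction-cosine over matched pairs where both carry directions;
  # ring normals have arbitrary sign, so rings use |cos|; other directional
  # features use cos clamped at zero
  cosines <- numeric()
  for (j in seq_along(best$sub)) {
    fh <- h$features[[best$sub[j]]]
    fm <- fs$features[[best$asg[j]]]
    if (is.null(fh$direction) || is.null(fm$direction)) next
    cs <- sum(kabsch_rotate_dir(best$fit, fm$direction) * fh$direction)
    cosines <- c(cosines, if (fh$ftype == "R") abs(cs) else max(0, cs))
  }
  structure(list(
    molecule_id = fs$molecule_id,
    hypothesis_id = h$id,
    correspondence = cbind(hypothesis = best$sub, molecule = best$asg),
    rmsd = best$rmsd,
    matched_fraction = length(best$sub) / nh,
    vector_alignment = if (length(cosines)) mean(cosines) else 1.0),
    class = "match_result")
}

# All injective same-type assignments of hypothesis feature slots (types
# `h_types`, in order) to molecule feature indices (types `m_types`).
# Returns a list of integer vectors parallel to h_types.
enumerate_assignments <- function(h_types, m_types) {
  out <- list()
  recurse <- function(slot, used, acc) {
    if (slot > length(h_types)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (cand in which(m_types == h_types[slot])) {
      if (cand %in% used) next
      recurse(slot + 1L, c(used, cand), c(acc, cand))
    }
  }
  recurse(1L, integer(), integer())
  out
}

#' Screen score of a pharmacophore match
#'
#' Second-pass score combining site matching, geometric alignment, and
#' feature-vector alignment:
#' `scale * (w_site * matched_fraction + w_align * (1 - rmsd / rmsd_max) +
#' w_vec * vector_alignment) / (w_site + w_align + w_vec)`.
#' A perfect complete match with aligned vectors scores `scale`; a complete
#' match at the RMSD gate with perfect vectors scores `2/3 * scale` under
#' the default equal weights. Higher is better. This is an analog score
#' defined by this package; it is not numerically comparable to scores
#' printed by proprietary screening software.
#'
#' @param m A `match_result` from [match_to_hypothesis()].
#' @param h The matched [hypothesis()] (unused beyond validation; kept for
#'   interface symmetry).
#' @param rmsd_max RMSD gate used in matching (default 1.0).
#' @param weights Length-3 numeric `(site, align, vector)` (default equal).
#' @param scale Overall scale of the score (default 1).
#' @return Numeric score >= 0.
#' @export
screen_score <- function(m, h = NULL, rmsd_max = 1.0, weights = c(1, 1, 1), scale = 1) {
  stopifnot(inherits(m, "match_result"))
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    abort_config("weights must be 3 nonnegative numbers with positive sum")
  comp <- c(m$matched_fraction, 1 - m$rmsd / rmsd_max, m$vector_alignment)
  scale * sum(weights * comp) / sum(weights)
}

#' Aggregate per-hypothesis screen scores into a screen matrix
#'
#' Builds the molecules-by-hypotheses score table (zero where unmatched),
#' collapsing protomers/conformers of one compound to the compound id by the
#' per-hypothesis maximum, and derives the per-compound total screen score
#' `TPS_S` (row sum), its mean and sample standard deviation, the docking
#' threshold `D_T = mean + 2 * sd`, and the selected compounds
#' (`TPS_S >= D_T`).
#'
#' @param scores Data frame with columns `molecule_id`, `hypothesis_id`,
#'   `score`, and optionally `protomer` (tag distinguishing records of one
#'   compound). Duplicate (molecule, hypothesis) rows without a protomer
#'   column are an input error.
#' @return Object of class `screen_matrix`: `score_matrix`, `tpss`,
#'   `mean_tpss`, `sd_tpss`, `d_threshold`, `selected`.
#' @export
aggregate_tpss <- function(scores) {
  scores <- as.data.frame(scores)
  need <- c("molecule_id", "hypothesis_id", "score")
  if (!all(need %in% names(scores)))
    abort_input("scores need columns molecule_id, hypothesis_id, score")
  if (any(scores$score < 0)) abort_input("screen scores must be nonnegative")
  if (!"protomer" %in% names(scores)) {
    if (anyDuplicated(scores[, c("molecule_id", "hypothesis_id")]))
      abort_input("duplicated (molecule, hypothesis) entries")
  }
  # collapse protomers by per-hypothesis maximum
  agg <- stats::aggregate(score ~ molecule_id + hypothesis_id, data = scores, FUN = max)
  mols <- unique(as.character(scores$molecule_id))   # preserve input order
  hyps <- sort(unique(as.character(agg$hypothesis_id)))
  mat <- matrix(0, length(mols), length(hyps), dimnames = list(mols, hyps))
  mat[cbind(match(as.character(agg$molecule_id), mols),
            match(as.character(agg$hypothesis_id), hyps))] <- agg$score
  tpss <- rowSums(mat)
  thr <- docking_threshold(tpss)
  structure(list(score_matrix = mat, tpss = tpss,
                 mean_tpss = thr$mean_tpss, sd_tpss = thr$sd_tpss,
                 d_threshold = thr$d_threshold, selected = thr$selected),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d molecules x %d hypotheses; mean TPS_S %.3f, sd %.3f, D_T %.3f, %d selected\n",
              nrow(x$score_matrix), ncol(x$score_matrix), x$mean_tpss,
              x$sd_tpss, x$d_threshold, length(x$selected)))
  invisible(x)
}

#' Docking threshold from total screen scores
#'
#' `D_T = mean(TPS_S) + 2 * sd(TPS_S)` with the sample (n-1) standard
#' deviation; compounds with `TPS_S >= D_T` are selected (input order
#' preserved). With all-equal scores the threshold equals the common value
#' and every compound is selected.
#'
#' @param tpss Named numeric vector of per-compound total screen scores, or
#'   a `screen_matrix`.
#' @return List `mean_tpss`, `sd_tpss`, `d_threshold`, `selected` (ids).
#' @export
docking_threshold <- function(tpss) {
  if (inherits(tpss, "screen_matrix")) tpss <- tpss$tpss
  if (length(tpss) < 2L) abort_input("need at least 2 compounds with defined TPS_S")
  if (is.null(names(tpss))) names(tpss) <- as.character(seq_along(tpss))
  m <- mean(tpss); s <- sample_sd(tpss)
  dt <- m + 2 * s
  list(mean_tpss = m, sd_tpss = s, d_threshold = dt,
       selected = names(tpss)[tpss >= dt])
}

#' First-pass RMSD filter across hypotheses
#'
#' Per hypothesis, keeps the `top_n` molecules with the lowest match RMSD
#' (ties broken by molecule id), then retains only molecules appearing under
#' at least `min_hypotheses` hypotheses. This mirrors a first screening pass
#' that keeps the best geometric matches per model and then demands
#' agreement between two or more models.
#'
#' @param matches Data frame with columns `molecule_id`, `hypothesis_id`,
#'   `rmsd` (best match RMSD per molecule and hypothesis).
#' @param top_n Per-hypothesis retention count (default 5000).
#' @param min_hypotheses Minimum number of hypotheses a molecule must appear
#'   under (default 2).
#' @return Character vector of retained molecule ids (sorted).
#' @export
first_pass_filter <- function(matches, top_n = 5000L, min_hypotheses = 2L) {
  if (top_n <= 0L) abort_config("top_n must be positive")
  matches <- as.data.frame(matches)
  need <- c("molecule_id", "hypothesis_id", "rmsd")
  if (!all(need %in% names(matches)))
    abort_input("matches need columns molecule_id, hypothesis_id, rmsd")
  if (!all(is.finite(matches$rmsd))) abort_input("rmsd values must be finite")
  kept <- lapply(split(matches, matches$hypothesis_id), function(df) {
    df <- df[order(df$rmsd, df$molecule_id), , drop = FALSE]
    utils::head(df$molecule_id, top_n)
  })
  counts <- table(unlist(kept))
  sort(names(counts)[counts >= min_hypotheses])
}

#' Run the full two-pass screen of a library against hypotheses
#'
#' Convenience driver: matches every feature set against every hypothesis
#' (RMSD gate), computes screen scores for matches, and aggregates into a
#' [aggregate_tpss()] screen matrix. Feature sets sharing a `molecule_id`
#' are treated as protomers/conformers of one compound and collapsed by the
#' per-hypothesis maximum score.
#'
#' @param library_fsets List of [feature_set()] objects.
#' @param hypos List of [hypothesis()] objects.
#' @param rmsd_max RMSD gate (default 1.0).
#' @param allow_partial Passed to [match_to_hypothesis()].
#' @return List with `matches` (long data frame incl. rmsd and score) and
#'   `screen_matrix`.
#' @export
screen_library <- function(library_fsets, hypos, rmsd_max = 1.0, allow_partial = FALSE) {
  rows <- list()
  for (fi in seq_along(library_fsets)) {
    fs <- library_fsets[[fi]]
    for (h in hypos) {
      m <- match_to_hypothesis(fs, h, rmsd_max = rmsd_max, allow_partial = allow_partial)
      if (is.null(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = fs$molecule_id, protomer = fs$conformer_id,
        hypothesis_id = h$id, rmsd = m$rmsd,
        score = screen_score(m, h, rmsd_max = rmsd_max))
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows)
  else data.frame(molecule_id = character(), protomer = integer(),
                  hypothesis_id = character(), rmsd = numeric(), score = numeric())
  # unmatched molecules still belong in the matrix with all-zero rows
  all_ids <- unique(vapply(library_fsets, `[[`, character(1), "molecule_id"))
  pad <- setdiff(all_ids, unique(matches$molecule_id))
  if (length(pad) && length(hypos)) {
    matches_aug <- rbind(matches, data.frame(
      molecule_id = pad, protomer = 1L, hypothesis_id = hypos[[1]]$id,
      rmsd = NA_real_, score = 0))
  } else matches_aug <- matches
  sm <- if (nrow(matches_aug) && length(all_ids) >= 2L) aggregate_tpss(matches_aug) else NULL
  list(matches = matches, screen_matrix = sm)
}
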