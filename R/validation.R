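#' ROC AUC of active versus decoy scores
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly drawn
#' active outscores a randomly drawn decoy, with half credit for ties. This
#' equals the area under the trapezoidal ROC curve.
#'
#' @param active_scores,decoy_scores Nonempty numeric vectors; higher score
#'   means predicted more active.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(active_scores, decoy_scores) {
  if (!length(active_scores) || !length(decoy_scores))
    abort_input("both score lists must be nonempty")
  if (!all(is.finite(c(active_scores, decoy_scores))))
    abort_input("scores must be finite")
  r <- rank(c(active_scores, decoy_scores), ties.method = "average")
  na <- length(active_scores); nd <- length(decoy_scores)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nd)
}

#' Retrieval counts for decoy-based model validation
#'
#' @param D Total compounds screened (actives plus decoys).
#' @param A Total actives in the screened set.
#' @param Ht Total hits retrieved by the model.
#' @param Ha Active hits retrieved.
#' @return Object of class `validation_counts`.
#' @export
validation_counts <- function(D, A, Ht, Ha) {
  for (v in list(D, A, Ht, Ha)) if (!is_number(v) || v < 0 || v != round(v))
    abort_input("counts must be nonnegative integers")
  if (Ha > min(A, Ht) || Ht > D || A > D)
    abort_input("inconsistent counts: need Ha <= min(A, Ht), Ht <= D, A <= D")
  structure(list(D = D, A = A, Ht = Ht, Ha = Ha), class = "validation_counts")
}

#' Guener-Henry metric family for retrieval validation
#'
#' Computes the standard decoy-validation metrics from retrieval counts:
#' percentage yield of actives `%Yield = 100 * Ha / Ht`, yield of actives
#' `Ya = Ha / Ht`, sensitivity `Se = Ha / A`, specificity
#' `Sp = ((D - A) - (Ht - Ha)) / (D - A)`, enrichment factor
#' `EF = (Ha / Ht) / (A / D)`, and the Guener-Henry score
#' `GH = (Ha * (3A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))`,
#' which balances precision-like yield against a false-positive penalty and
#' lies in \[0, 1\].
#'
#' @param c A [validation_counts()] object (requires `Ht > 0`, `A > 0`,
#'   `D > A`).
#' @return Named list `yield_pct`, `Ya`, `Se`, `Sp`, `EF`, `GH`.
#' @export
gh_metrics <- function(c) {
  stopifnot(inherits(c, "validation_counts"))
  if (c$Ht == 0) abort_input("Ht = 0: retrieval metrics undefined")
  if (c$A == 0) abort_input("A = 0: retrieval metrics undefined")
  if (c$D == c$A) abort_input("D = A: specificity undefined (no decoys)")
  ya <- c$Ha / c$Ht
  list(
    yield_pct = 100 * ya,
    Ya = ya,
    Se = c$Ha / c$A,
    Sp = ((c$D - c$A) - (c$Ht - c$Ha)) / (c$D - c$A),
    EF = ya / (c$A / c$D),
    GH = (c$Ha * (3 * c$A + c$Ht) / (4 * c$Ht * c$A)) *
      (1 - (c$Ht - c$Ha) / (c$D - c$A)))
}

#' Classify pharmacophore-model reliability from its GH score
#'
#' A GH score strictly above 0.7 reads as a good, reliable model; strictly
#' above 0.5 as acceptable; otherwise poor.
#'
#' @param GH GH score in \[0, 1\].
#' @param thresholds Named list with `good` and `acceptable` cutoffs.
#' @return `"good"`, `"acceptable"` or `"poor"`.
#' @export
classify_model_quality <- function(GH, thresholds = list(good = 0.7, acceptable = 0.5)) {
  if (!is_number(GH) || GH < 0 || GH > 1) abort_input("GH must be in [0, 1]")
  if (GH > thresholds$good) "good"
  else if (GH > thresholds$acceptable) "acceptable"
  else "poor"
}

#' Validate hypotheses against labeled actives and decoys
#'
#' Screens actives and decoys against each hypothesis (RMSD gate plus
#' screen score), then reports per-hypothesis AUC and Guener-Henry metrics,
#' one row per hypothesis. A compound counts as a hit of a hypothesis when
#' it passes the RMSD gate.
#'
#' @param active_fsets,decoy_fsets Lists of [feature_set()] objects.
#' @param hypos List of [hypothesis()] objects.
#' @param rmsd_max RMSD gate (default 1.0).
#' @return Data frame: hypothesis id, D, A, Ht, Ha, AUC, yield_pct, Ya, Se,
#'   Sp, EF, GH, quality label.
#' @export
validate_hypotheses <- function(active_fsets, decoy_fsets, hypos, rmsd_max = 1.0) {
  rows <- lapply(hypos, function(h) {
    score_of <- function(fs) {
      m <- match_to_hypothesis(fs, h, rmsd_max = rmsd_max)
      if (is.null(m)) 0 else screen_score(m, h, rmsd_max = rmsd_max)
    }
    sa <- vapply(active_fsets, score_of, numeric(1))
    sd_ <- vapply(decoy_fsets, score_of, numeric(1))
    counts <- validation_counts(
      D = length(sa) + length(sd_), A = length(sa),
      Ht = sum(sa > 0) + sum(sd_ > 0), Ha = sum(sa > 0))
    gm <- if (counts$Ht > 0) gh_metrics(counts) else
      list(yield_pct = NA_real_, Ya = NA_real_, Se = 0, Sp = 1, EF = NA_real_, GH = 0)
    data.frame(hypothesis_id = h$id, D = counts$D, A = counts$A,
               Ht = counts$Ht, Ha = counts$Ha,
               AUC = roc_auc(sa, sd_),
               yield_pct = gm$yield_pct, Ya = gm$Ya, Se = gm$Se, Sp = gm$Sp,
               EF = gm$EF, GH = gm$GH,
               quality = classify_model_quality(max(0, min(1, gm$GH))))
  })
  do.call(rbind, rows)
}
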