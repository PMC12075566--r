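# Independent oracles, deliberately implemented with different algorithms
# than the package (Horn's quaternion method instead of SVD Kabsch; double
# loops instead of rank/vectorized formulations; naive agglomeration
# instead of hclust).

# Closed-form optimal superposition RMSD via Horn's quaternion method.
oracle_superpose_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P))
}

# Brute-force best same-type correspondence RMSD (complete matches).
oracle_match_rmsd <- function(fs, h) {
  ht <- vapply(h$features, `[[`, character(1), "ftype")
  mt <- vapply(fs$features, `[[`, character(1), "ftype")
  cand <- lapply(ht, function(t) which(mt == t))
  if (any(vapply(cand, length, integer(1)) == 0)) return(NULL)
  grid <- do.call(expand.grid, cand)
  Q <- do.call(rbind, lapply(h$features, `[[`, "position"))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (anyDuplicated(asg)) next
    P <- do.call(rbind, lapply(fs$features[asg], `[[`, "position"))
    best <- min(best, oracle_superpose_rmsd(P, Q))
  }
  if (is.infinite(best)) NULL else best
}

# Pairwise-counting AUC.
oracle_auc <- function(a, d) {
  wins <- 0
  for (x in a) for (y in d) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(d))
}

# Naive average-linkage agglomeration; returns merge heights and the
# partition obtained by refusing merges above `cut`.
oracle_average_linkage <- function(D, cut = Inf) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric()
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    if (bestd > cut) break
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(D))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  list(heights = heights, labels = labels)
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# All-pairs contact scan with explicit loops.
oracle_contact_freq <- function(ps, cutoff = 5) {
  keys <- paste(ps$receptor$chain, ps$receptor$resname, ps$receptor$resno, sep = ":")
  ukeys <- unique(keys)
  counts <- setNames(integer(length(ukeys)), ukeys)
  for (p in ps$poses) {
    touched <- character()
    for (j in seq_len(nrow(p$coords))) {
      for (i in seq_len(nrow(ps$receptor))) {
        d <- sqrt(sum((p$coords[j, ] - c(ps$receptor$x[i], ps$receptor$y[i],
                                         ps$receptor$z[i]))^2))
        if (d <= cutoff) touched <- c(touched, keys[i])
      }
    }
    for (k in unique(touched)) counts[k] <- counts[k] + 1L
  }
  counts / length(ps$poses)
}

# Random rotation matrix from the current RNG stream.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random feature set + hypothesis pair for oracle-equivalence sweeps.
random_match_case <- function(extra = 2L) {
  k <- sample(3:5, 1)
  types <- sample(c("A", "D", "H", "N", "P", "R"), k, replace = TRUE)
  hpos <- matrix(runif(3 * k, -4, 4), ncol = 3)
  h <- hypothesis("case", lapply(seq_len(k), function(i)
    pharm_feature(types[i], hpos[i, ])))
  mtypes <- c(types, sample(types, extra, replace = TRUE))
  mpos <- matrix(runif(3 * length(mtypes), -4, 4), ncol = 3)
  fs <- feature_set("case-mol", lapply(seq_along(mtypes), function(i)
    pharm_feature(mtypes[i], mpos[i, ])))
  list(fs = fs, h = h)
}
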