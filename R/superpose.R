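# Optimal rigid-body superposition (Kabsch algorithm).
#
# Returns the rotation R and translations such that X (moving) superposed
# onto Y (reference) minimizes RMSD: x' = (x - cx) %*% R + cy.
kabsch_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3L, ncol(Y) == 3L, nrow(X) >= 1L)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(crossprod(X0, Y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Xf <- X0 %*% R
  rmsd <- sqrt(mean(rowSums((Xf - Y0)^2)))
  list(rotation = R, center_x = cx, center_y = cy, rmsd = rmsd)
}

# Apply a kabsch_fit to arbitrary points / directions.
kabsch_apply <- function(fit, pts) {
  sweep(sweep(as.matrix(pts), 2, fit$center_x) %*% fit$rotation, 2, fit$center_y, `+`)
}

kabsch_rotate_dir <- function(fit, dir) as.numeric(dir %*% fit$rotation)
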