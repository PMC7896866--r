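# Independent oracles, coded from algorithm definitions rather than from the
# package's implementation.

# PLS-1 via its Krylov-subspace characterization: the k-factor PLS-1
# prediction equals least squares restricted to the Krylov space
# span{s, As, ..., A^(k-1) s} with s = X'y and A = X'X (centered data).
# Orthonormalizing the Krylov basis by QR keeps it numerically sane.
krylov_pls1_predict <- function(X, y, k, Xnew = X) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm, "-")
  yc <- y - ym
  A <- crossprod(Xc)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) {
    K[, j] <- v
    v <- A %*% v
  }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  beta <- solve(crossprod(Z), crossprod(Z, yc))
  b <- Q %*% beta
  as.numeric(ym + sweep(as.matrix(Xnew), 2L, xm, "-") %*% b)
}

# Apply a fitted pls1 core to raw preprocessed rows using its documented
# fields (y_mean + (x - x_mean) . coef).
predict_pls1_for_test <- function(fit, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  as.numeric(fit$y_mean + sweep(X, 2L, fit$x_mean, "-") %*% fit$coef)
}

# Closed-form simple linear regression (for the MSC oracle).
ols_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Random evenly spaced descending test grid.
random_grid <- function(n = 20L, step = NULL) {
  if (is.null(step)) step <- sample(c(1, 2, 4), 1L)
  start <- sample(1500:2000, 1L)
  seq(start, by = -step, length.out = n)
}
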