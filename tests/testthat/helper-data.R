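# small fixtures built in code, shared across test files

toy_gaussian <- function(n = 60, m = 4, seed = 1, layer = "M") {
  set.seed(seed)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
  y <- 0.2 * X[, 1] + stats::rnorm(n)
  D <- matrix(stats::rnorm(n * m), n, m)
  ids <- sprintf("S%03d", seq_len(n))
  names(y) <- ids
  rownames(X) <- rownames(D) <- ids
  list(y = y, X = X, block = omics_block(D, layer, subject_ids = ids),
       ids = ids)
}

toy_binary <- function(n = 80, m = 4, seed = 2, layer = "G") {
  set.seed(seed)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
  y <- stats::rbinom(n, 1, stats::plogis(0.3 * X[, 1]))
  D <- matrix(stats::rbinom(n * m, 2, 0.3), n, m)
  ids <- sprintf("S%03d", seq_len(n))
  names(y) <- ids
  rownames(X) <- rownames(D) <- ids
  list(y = y, X = X, block = omics_block(D, layer, subject_ids = ids),
       ids = ids)
}

# dense P0 computed straight from the textbook formulas, independent of the
# package's matrix-free code path
dense_p0 <- function(y, X, family) {
  X <- cbind(1, X)
  n <- length(y)
  if (family == "gaussian") {
    diag(n) - X %*% solve(crossprod(X), t(X))
  } else {
    g <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- g$fitted.values
    S <- diag(mu * (1 - mu))
    S - S %*% X %*% solve(t(X) %*% S %*% X, t(X) %*% S)
  }
}

small_pools <- function(seed = 11) {
  build_pools(n_haplotypes = 2000, n_methyl_samples = 200,
              n_expr_samples = 150, seed = seed)
}
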