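test_that("Q matches the dense triple-product oracle on a 6-subject toy", {
  y <- c(1.2, -0.3, 0.5, 2.1, -1.0, 0.4)
  G <- matrix(c(0, 1, 2, 0, 1, 0,
                1, 0, 0, 2, 1, 1,
                0, 0, 1, 1, 2, 0), 6, 3)
  fit <- fit_null(y, family = "gaussian")
  blk <- omics_block(G, "G")
  r <- y - mean(y)
  s2 <- sum(r^2) / (6 - 1)
  Q_oracle <- drop(t(r) %*% G %*% t(G) %*% r) / s2
  expect_equal(km_statistic(fit, blk), Q_oracle, tolerance = 1e-10)
})

test_that("Q is zero for zero residuals and zero feature matrices", {
  suppressWarnings(fit0 <- fit_null(2 + 3 * (1:8), X = cbind(x = 1:8),
                                    family = "gaussian"))
  blk <- omics_block(matrix(rnorm(16), 8, 2), "M")
  expect_equal(km_statistic(fit0, blk), 0)
  d <- toy_gaussian()
  fit <- fit_null(d$y, d$X, family = "gaussian")
  zero <- omics_block(matrix(0, 60, 3), "M", subject_ids = d$ids)
  expect_equal(km_statistic(fit, zero), 0)
  kt <- km_test(fit, zero)
  expect_equal(kt$p_value, 1)
  expect_equal(kt$method_used, "exact_zero")
})

test_that("a single feature yields the centered-sum-of-squares eigenvalue", {
  d <- toy_gaussian(n = 50, m = 1)
  fit <- fit_null(d$y, d$X, family = "gaussian")
  e <- km_eigens(fit, d$block)
  g <- d$block$matrix[, 1]
  P0 <- dense_p0(d$y, d$X, "gaussian")
  expect_length(e$lambda, 1)
  expect_equal(e$lambda, drop(t(g) %*% P0 %*% g), tolerance = 1e-8)
})

test_that("dual m x m eigenvalues equal the n x n eigenvalues and V is orthonormal", {
  for (fam in c("gaussian", "binomial")) {
    d <- if (fam == "gaussian") toy_gaussian(n = 40, m = 5)
         else toy_binary(n = 40, m = 5)
    fit <- fit_null(d$y, d$X, family = fam)
    e <- km_eigens(fit, d$block)
    P0 <- p0_matrix(fit)
    # nonzero spectrum of P0^(1/2) K P0^(1/2) equals that of the m x m dual
    A <- t(d$block$matrix) %*% P0 %*% d$block$matrix
    lam_dual <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam_dual <- lam_dual[lam_dual > 1e-10 * max(lam_dual)]
    expect_equal(e$lambda, lam_dual, tolerance = 1e-8)
    V <- km_eigenvectors(e)
    expect_equal(crossprod(V), diag(length(e$lambda)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # V diagonalizes P0^{1/2} K P0^{1/2}: check the quadratic form identity
    expect_equal(sum(e$lambda), sum(diag(P0 %*% tcrossprod(d$block$matrix))),
                 tolerance = 1e-6)
  }
})

test_that("feature weights act as column scalings of the feature matrix", {
  d <- toy_gaussian(n = 45, m = 3)
  fit <- fit_null(d$y, d$X, family = "gaussian")
  w <- c(0.5, 2, 1.3)
  bw <- omics_block(d$block$matrix, "M", subject_ids = d$ids, weights = w)
  bs <- omics_block(sweep(d$block$matrix, 2, sqrt(w), `*`), "M",
                    subject_ids = d$ids)
  expect_equal(km_statistic(fit, bw), km_statistic(fit, bs), tolerance = 1e-10)
  expect_equal(km_eigens(fit, bw)$lambda, km_eigens(fit, bs)$lambda,
               tolerance = 1e-8)
})

test_that("mixture tail probabilities match exact and Monte-Carlo oracles", {
  expect_equal(as.numeric(mixture_chisq_pvalue(0, c(1, 2))), 1)
  expect_equal(attr(mixture_chisq_pvalue(0, c(1, 2)), "method"), "exact_zero")
  # chi-square(1) survival oracle
  expect_equal(as.numeric(mixture_chisq_pvalue(3.841459, 1)), 0.05,
               tolerance = 1e-4)
  # two-weight Monte-Carlo oracle: 2 chisq1 + chisq1 at Q = 4
  p <- as.numeric(mixture_chisq_pvalue(4, c(2, 1)))
  set.seed(71)
  draws <- 2 * rchisq(2e6, 1) + rchisq(2e6, 1)
  mc <- mean(draws > 4)
  se <- sqrt(mc * (1 - mc) / 2e6)
  expect_lt(abs(p - mc), 3 * se)
  # many-weight case against a Monte-Carlo oracle
  set.seed(72)
  lam <- rexp(20) * 5
  q <- 1.4 * sum(lam)
  p20 <- as.numeric(mixture_chisq_pvalue(q, lam))
  mcq <- colSums(lam * matrix(rchisq(20 * 5e5, 1), 20))
  mc20 <- mean(mcq > q)
  expect_lt(abs(p20 - mc20), 3 * sqrt(mc20 * (1 - mc20) / 5e5))
  expect_error(mixture_chisq_pvalue(1, numeric(0)), "nonempty")
  expect_error(mixture_chisq_pvalue(-1, 1), "nonnegative")
  expect_error(mixture_chisq_pvalue(1, c(1, -1)), "positive")
})

test_that("the p-value is monotone decreasing in Q and bounded in (0, 1]", {
  set.seed(5)
  lam <- sort(rexp(8) * 3, decreasing = TRUE)
  qs <- seq(0.01, 6 * sum(lam), length.out = 40)
  ps <- as.numeric(mixture_chisq_pvalue(qs, lam))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  # deep tail handled by the saddlepoint, still monotone and positive
  deep <- as.numeric(mixture_chisq_pvalue(c(50, 80, 120) * sum(lam), lam))
  expect_true(all(diff(deep) < 0) && all(deep > 0))
})

test_that("single-feature KM p equals the regression score test", {
  d <- toy_gaussian(n = 80, m = 1, seed = 8)
  fit <- fit_null(d$y, d$X, family = "gaussian")
  kt <- km_test(fit, d$block)
  f0 <- glm(d$y ~ d$X)
  f1 <- glm(d$y ~ d$X + d$block$matrix)
  rao <- anova(f0, f1, test = "Rao", dispersion = fit$sigma2_hat)$`Pr(>Chi)`[2]
  expect_equal(kt$p_value, rao, tolerance = 1e-6)
})

test_that("duplicating a block doubles Q and leaves the p-value unchanged", {
  d <- toy_binary(n = 70, m = 4, seed = 12)
  fit <- fit_null(d$y, d$X, family = "binomial")
  b2 <- omics_block(cbind(d$block$matrix, d$block$matrix), "G",
                    subject_ids = d$ids)
  k1 <- km_test(fit, d$block)
  k2 <- km_test(fit, b2)
  expect_equal(k2$Q, 2 * k1$Q, tolerance = 1e-10)
  expect_equal(k2$lambda, 2 * k1$lambda, tolerance = 1e-8)
  expect_equal(k2$p_value, k1$p_value, tolerance = 1e-6)
})

test_that("null p-values are uniform for both trait families", {
  n <- 150
  set.seed(33)
  X <- cbind(x1 = rnorm(n))
  D <- matrix(rnorm(n * 5), n, 5)
  blk <- omics_block(D, "M")
  pg <- pb <- numeric(400)
  for (i in 1:400) {
    yg <- rnorm(n)
    pg[i] <- km_test(fit_null(yg, X, family = "gaussian"), blk)$p_value
    yb <- rbinom(n, 1, 0.4)
    pb[i] <- km_test(fit_null(yb, X, family = "binomial"), blk)$p_value
  }
  expect_gt(ks.test(pg, "punif")$p.value, 0.01)
  expect_gt(ks.test(pb, "punif")$p.value, 0.01)
})

test_that("subject mismatches and empty blocks are rejected", {
  d <- toy_gaussian(n = 30)
  fit <- fit_null(d$y, d$X, family = "gaussian")
  bad <- omics_block(matrix(rnorm(30), 30, 1), "M",
                     subject_ids = paste0("T", 1:30))
  expect_error(km_statistic(fit, bad), "unmatched")
  expect_error(omics_block(matrix(nrow = 30, ncol = 0), "M"), "empty feature")
  expect_error(omics_block(matrix(3, 5, 1), "G"), "dosages")
  # subject reordering is transparent
  ord <- sample(30)
  rb <- omics_block(d$block$matrix[ord, , drop = FALSE], "M",
                    subject_ids = d$ids[ord])
  expect_equal(km_statistic(fit, rb), km_statistic(fit, d$block),
               tolerance = 1e-12)
})
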