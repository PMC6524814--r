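make_kms <- function(n = 90, seed = 21, family = "binomial") {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- if (family == "binomial") rbinom(n, 1, 0.5) else rnorm(n)
  ids <- sprintf("S%03d", 1:n)
  names(y) <- ids
  rownames(X) <- ids
  fit <- fit_null(y, X, family = family, subject_ids = ids)
  G <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  M <- matrix(rnorm(n * 4), n, 4)
  E <- matrix(rnorm(n), n, 1)
  kms <- list(G = km_test(fit, omics_block(G, "G", ids)),
              M = km_test(fit, omics_block(M, "M", ids)),
              E = km_test(fit, omics_block(E, "E", ids)))
  list(fit = fit, kms = kms, ids = ids, y = y, X = X)
}

test_that("identical layers receive identical perturbed p-values", {
  n <- 60
  set.seed(31)
  D <- matrix(rnorm(n * 4), n, 4)
  ids <- sprintf("S%02d", 1:n)
  y <- rnorm(n); names(y) <- ids
  fit <- fit_null(y, family = "gaussian", subject_ids = ids)
  kms <- list(G = km_test(fit, omics_block(pmin(abs(D), 2), "G", ids)),
              M = km_test(fit, omics_block(pmin(abs(D), 2), "M", ids)))
  draws <- perturb_layer_pvalues(kms, B = 50, seed = 7)
  expect_equal(draws[, "G"], draws[, "M"], tolerance = 1e-6)
})

test_that("perturbed p-values are uniform under the null", {
  mk <- make_kms(n = 120, seed = 22, family = "gaussian")
  draws <- perturb_layer_pvalues(mk$kms["M"], B = 2000, seed = 3)
  expect_gt(ks.test(draws[, "M"], "punif")$p.value, 0.01)
  mkb <- make_kms(n = 120, seed = 23, family = "binomial")
  drawsb <- perturb_layer_pvalues(mkb$kms["G"], B = 2000, seed = 4)
  expect_gt(ks.test(drawsb[, "G"], "punif")$p.value, 0.01)
})

test_that("the joint rotation reproduces the explicit eigenvector Gram matrix", {
  mk <- make_kms(n = 70, seed = 24, family = "binomial")
  jr <- omnifisher:::joint_rotation(mk$kms)
  V <- do.call(cbind, lapply(mk$kms, function(k) km_eigenvectors(k$eigens)))
  expect_equal(jr$R %*% jr$R, crossprod(V), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("draws are deterministic given a seed and layer-order invariant", {
  mk <- make_kms()
  d1 <- perturb_layer_pvalues(mk$kms, B = 100, seed = 11)
  d2 <- perturb_layer_pvalues(mk$kms, B = 100, seed = 11)
  expect_identical(d1, d2)
  d3 <- perturb_layer_pvalues(mk$kms[c("E", "G", "M")], B = 100, seed = 11)
  expect_equal(d1, d3[, colnames(d1)])
  expect_error(perturb_layer_pvalues(mk$kms, B = -1), "B must be")
  expect_equal(nrow(perturb_layer_pvalues(mk$kms, B = 0)), 0)
})

test_that("estimated covariance recovers independence, duplication and the null variance", {
  # duplicated layer: correlation of -2 ln p equals 1
  n <- 60
  set.seed(41)
  D <- matrix(rnorm(n * 3), n, 3)
  ids <- sprintf("S%02d", 1:n)
  y <- rnorm(n); names(y) <- ids
  fit <- fit_null(y, family = "gaussian", subject_ids = ids)
  kms <- list(G = km_test(fit, omics_block(pmin(abs(D), 2), "G", ids)),
              M = km_test(fit, omics_block(pmin(abs(D), 2), "M", ids)))
  dr <- perturb_layer_pvalues(kms, B = 300, seed = 5)
  C <- estimate_cov(dr)
  expect_equal(C["G", "M"] / sqrt(C["G", "G"] * C["M", "M"]), 1,
               tolerance = 1e-6)

  # disjoint subject sets: layers are independent, off-diagonals near 0,
  # diagonals near var(-2 ln U) = 4
  set.seed(42)
  ids1 <- sprintf("A%03d", 1:80)
  ids2 <- sprintf("B%03d", 1:80)
  y1 <- rnorm(80); names(y1) <- ids1
  y2 <- rnorm(80); names(y2) <- ids2
  f1 <- fit_null(y1, family = "gaussian", subject_ids = ids1)
  f2 <- fit_null(y2, family = "gaussian", subject_ids = ids2)
  kd <- list(G = km_test(f1, omics_block(matrix(rbinom(80 * 4, 2, .3), 80, 4), "G", ids1)),
             M = km_test(f2, omics_block(matrix(rnorm(80 * 4), 80, 4), "M", ids2)))
  drd <- perturb_layer_pvalues(kd, B = 5000, seed = 6)
  Cd <- estimate_cov(drd)
  expect_lt(abs(Cd["G", "M"]), 0.5)
  expect_lt(abs(Cd["G", "G"] - 4), 0.4)
  expect_lt(abs(Cd["M", "M"] - 4), 0.4)
})

test_that("model combinations cover all subsets and match the direct combiner", {
  mk <- make_kms(seed = 26)
  obs <- vapply(mk$kms, function(k) k$p_value, 0)
  dr <- perturb_layer_pvalues(mk$kms, B = 40, seed = 9)
  C <- estimate_cov(dr, obs)
  mp <- combine_all_models(obs, dr, C)
  expect_identical(colnames(mp), c("G", "M", "E", "GM", "GE", "ME", "GME"))
  expect_equal(nrow(mp), 41)
  expect_equal(unname(mp[1, "G"]), unname(obs["G"]))
  cs <- C[c("G", "E"), c("G", "E")]
  expect_equal(unname(mp[1, "GE"]),
               omnibus_fisher_combine(obs[c("G", "E")], cs), tolerance = 1e-12)
  # zero covariance, p = (0.5, 0.5, 0.5): chi-square(6) oracle
  obs3 <- c(G = 0.5, M = 0.5, E = 0.5)
  m0 <- combine_all_models(obs3, NULL, diag(4, 3) |>
                             `dimnames<-`(list(c("G", "M", "E"),
                                               c("G", "M", "E"))))
  expect_equal(unname(m0[1, "GME"]),
               pchisq(-6 * log(0.5), 6, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("the optimal test is bounded, degenerate-safe and tracks a single layer", {
  mk <- make_kms(seed = 27)
  obs <- vapply(mk$kms, function(k) k$p_value, 0)
  dr <- perturb_layer_pvalues(mk$kms, B = 500, seed = 10)
  C <- estimate_cov(dr, obs)
  mp <- combine_all_models(obs, dr, C)
  ot <- optimal_test(mp)
  expect_gte(ot$p, 1 / 501)
  expect_lte(ot$p, 1)
  # all observed p = 1: every perturbed min is <= 1, so the final p is 1
  mp1 <- mp
  mp1[1, ] <- 1
  expect_equal(optimal_test(mp1)$p, 1)
  # a single layer: the optimal p is the rank of p_G among its own draws
  drG <- perturb_layer_pvalues(mk$kms["G"], B = 2000, seed = 12)
  mpG <- combine_all_models(obs["G"], drG, NULL)
  pg <- obs[["G"]]
  expect_lt(abs(optimal_test(mpG)$p - pg),
            4 * sqrt(pg * (1 - pg) / 2000) + 2 / 2000)
})

test_that("run_gene is internally consistent, deterministic and layer-flexible", {
  set.seed(55)
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  y <- rbinom(n, 1, 0.5)
  names(y) <- ids
  X <- cbind(x1 = rnorm(n)); rownames(X) <- ids
  blocks <- list(omics_block(matrix(rbinom(n * 5, 2, .25), n, 5), "G", ids),
                 omics_block(matrix(rnorm(n * 3), n, 3), "M", ids),
                 omics_block(matrix(rnorm(n), n, 1), "E", ids))
  r1 <- run_gene(y, blocks, covariates = X, B_cov = 100, optimal = TRUE,
                 B_stages = 500, seed = 3, gene_id = "g1")
  r2 <- run_gene(y, blocks, covariates = X, B_cov = 100, optimal = TRUE,
                 B_stages = 500, seed = 3, gene_id = "g1")
  expect_identical(r1[setdiff(names(r1), "km")], r2[setdiff(names(r2), "km")])
  # the regular combined p equals combining the observed p-values directly
  obs <- c(G = r1$p_G, M = r1$p_M, E = r1$p_E)
  expect_equal(r1$p_omnibus,
               omnibus_fisher_combine(obs, r1$cov_hat[names(obs), names(obs)]),
               tolerance = 1e-12)
  expect_true(r1$p_optimal >= 1 / 501 && r1$p_optimal <= 1)
  expect_equal(r1$B_used, 500)
  # two layers reduce the model set; absent combinations stay NA
  r3 <- run_gene(y, blocks[1:2], covariates = X, B_cov = 100,
                 optimal = FALSE, seed = 3)
  expect_true(is.na(r3$p_E) && is.na(r3$p_GE) && is.na(r3$p_GME))
  expect_false(is.na(r3$p_GM))
  expect_equal(r3$p_omnibus, r3$p_GM)
  # layers with disjoint subjects still combine
  ids2 <- sprintf("T%03d", 1:n)
  y2 <- c(y, setNames(rbinom(n, 1, 0.5), ids2))
  blocksd <- list(omics_block(matrix(rbinom(n * 5, 2, .25), n, 5), "G", ids),
                  omics_block(matrix(rnorm(n * 3), n, 3), "M", ids2))
  r4 <- run_gene(y2, blocksd, B_cov = 100, optimal = FALSE, seed = 4)
  expect_true(r4$p_GM > 0 && r4$p_GM <= 1)
  expect_equal(unname(r4$n), c(100L, 100L))
})
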