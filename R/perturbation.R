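LAYER_ORDER <- c("G", "M", "E")

# deterministic 31-bit substream seed from (seed, gene_id)
derive_seed <- function(seed, gene_id = NULL) {
  h <- as.double(seed %% 2147483647)
  if (!is.null(gene_id)) {
    for (ch in utf8ToInt(as.character(gene_id))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h %% 2147483647)
}

# Joint rotation structure for the shared-draw perturbation.  The
# textbook scheme draws one N(0,1) per subject in the union of layer subject sets and
# rotates it by each layer's eigenvectors: s_l = V_l' r.  The stacked vector
# s = (s_G, s_M, s_E) is exactly N(0, Gram) with Gram the cross-layer
# eigenvector Gram matrix, so we sample s directly through the symmetric
# square root of Gram.  When all layers share one null model the Gram only
# needs P0 products (V_l' V_l' = C_l' P0 C_l'), avoiding any n x n
# factorization; otherwise explicit eigenvectors are materialized.
joint_rotation <- function(kms) {
  kms <- kms[order(match(names(kms), LAYER_ORDER))]
  eigs <- lapply(kms, function(k) if (inherits(k, "of_km_test")) k$eigens else k)
  ms <- vapply(eigs, function(e) length(e$lambda), 0L)
  mtot <- sum(ms)
  idx <- split(seq_len(mtot), rep(seq_along(eigs), ms))
  names(idx) <- names(eigs)
  if (mtot == 0) {
    return(list(R = matrix(0, 0, 0), idx = idx,
                lambda = lapply(eigs, `[[`, "lambda")))
  }
  shared <- all(vapply(eigs, function(e) same_null_model(e$fit, eigs[[1]]$fit), TRUE))
  G <- matrix(0, mtot, mtot)
  if (shared) {
    fit <- eigs[[1]]$fit
    pre <- do.call(cbind, lapply(eigs, `[[`, "pre"))
    G <- crossprod(pre, p0_mult(fit, pre))
  } else {
    union_ids <- Reduce(union, lapply(eigs, `[[`, "subject_ids"))
    Vs <- lapply(eigs, function(e) {
      V <- km_eigenvectors(e)
      out <- matrix(0, length(union_ids), ncol(V))
      out[match(e$subject_ids, union_ids), ] <- V
      out
    })
    Vall <- do.call(cbind, Vs)
    G <- crossprod(Vall)
  }
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  R <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  list(R = R, idx = idx, lambda = lapply(eigs, `[[`, "lambda"))
}

#' Perturbed per-layer p-values with shared subject draws
#'
#' Implements the perturbation of the score statistics: for each iteration b
#' a standard-normal vector with one entry per subject (shared across
#' layers, so that cross-layer correlation under the null is preserved) is
#' rotated by each layer's eigenvectors, giving
#' \eqn{Q_l^{(b)} = r_l^{(b)\prime} \Lambda_l r_l^{(b)}} and a p-value
#' \eqn{p_l^{(b)}} from the same mixture-of-chi-square law as the observed
#' statistic.  Sampling is performed jointly through the eigenvector Gram
#' matrix, which is distribution-identical to drawing the per-subject vector
#' explicitly (see the methods vignette); layers are processed in the
#' canonical order G, M, E so results do not depend on input order.
#'
#' @param kms Named list of per-layer [km_test()] results (or [km_eigens()]
#'   objects); names must be among `"G"`, `"M"`, `"E"`.
#' @param B Number of perturbation iterations (>= 1; `B = 0` returns an
#'   empty draw matrix).
#' @param seed Optional integer seed (set before drawing).
#' @param acc Absolute accuracy of the mixture-tail inversion for the
#'   perturbed p-values (relaxed relative to observed p-values, since the
#'   draws feed a covariance estimate and rank comparisons).
#' @return B x L matrix of perturbed p-values, columns named by layer.
#' @export
perturb_layer_pvalues <- function(kms, B, seed = NULL, acc = 3e-7) {
  if (B < 0) stop("B must be >= 0")
  stopifnot(length(kms) >= 1)
  if (is.null(names(kms))) {
    names(kms) <- vapply(kms, function(k) k$layer, "")
  }
  if (!all(names(kms) %in% LAYER_ORDER)) {
    stop("layer names must be among G, M, E")
  }
  kms <- kms[order(match(names(kms), LAYER_ORDER))]
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, B, length(kms), dimnames = list(NULL, names(kms)))
  if (B == 0) return(out)
  jr <- joint_rotation(kms)
  mtot <- nrow(jr$R)
  if (mtot == 0) {
    out[] <- 1
    return(out)
  }
  S <- jr$R %*% matrix(stats::rnorm(mtot * B), mtot, B)
  for (l in names(kms)) {
    lam <- jr$lambda[[l]]
    if (length(lam) == 0) {
      out[, l] <- 1
    } else {
      Qb <- colSums(lam * S[jr$idx[[l]], , drop = FALSE]^2)
      out[, l] <- batch_mixture_pvalue(Qb, lam, acc = acc)
    }
  }
  out
}

#' Empirical covariance of -2 ln p across layers
#'
#' Estimates the covariance matrix of \eqn{-2\ln p_l} across layers from the
#' perturbation draws, including the observed p-values as iteration b = 0 by
#' default.  A degenerate (constant) column yields zero covariances with a
#' warning.  The diagonal is returned as estimated; downstream combination
#' replaces it by the theoretical value 4.
#'
#' @param draws B x L matrix from [perturb_layer_pvalues()].
#' @param observed Optional named vector of observed per-layer p-values
#'   (iteration b = 0).
#' @param include_observed Include the observed draw in the estimate
#'   (default TRUE).
#' @return L x L covariance matrix with layer dimnames.
#' @export
estimate_cov <- function(draws, observed = NULL, include_observed = TRUE) {
  M <- draws
  if (!is.null(observed) && include_observed) {
    observed <- observed[colnames(draws)]
    M <- rbind(matrix(observed, 1, dimnames = list(NULL, colnames(draws))), M)
  }
  if (nrow(M) < 3) stop("need at least 3 draws to estimate a covariance")
  L <- -2 * log(pmax(M, 1e-300))
  C <- stats::cov(L)
  v <- diag(C)
  bad <- v < 1e-12
  if (any(bad)) {
    warning("degenerate (constant) p-value column(s): ",
            paste(colnames(M)[bad], collapse = ", "),
            "; covariance rows set to 0")
    C[bad, ] <- 0
    C[, bad] <- 0
  }
  C
}

# all nonempty layer subsets in canonical order: G, M, E, GM, GE, ME, GME
model_subsets <- function(layers) {
  layers <- layers[order(match(layers, LAYER_ORDER))]
  subs <- list()
  for (k in seq_along(layers)) {
    cmb <- utils::combn(layers, k, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  names(subs) <- vapply(subs, paste, "", collapse = "")
  subs
}

#' Combined p-values of all layer-subset disease models
#'
#' For each of the nonempty layer subsets (7 models with three layers:
#' G, M, E, GM, GE, ME, GME; fewer with fewer layers) computes the
#' covariance-adjusted Fisher combination of the corresponding p-values,
#' identically for the observed iteration (row 1, b = 0) and every
#' perturbed iteration.  Pairwise models use the corresponding sub-block of
#' the covariance matrix.
#'
#' @param observed Named vector of observed per-layer p-values.
#' @param draws B x L matrix of perturbed p-values (or `NULL` for observed
#'   only).
#' @param cov L x L covariance matrix of -2 ln p (layer dimnames matching).
#' @return (B + 1) x n_models matrix of combined p-values; row 1 is the
#'   observed iteration.
#' @export
combine_all_models <- function(observed, draws = NULL, cov = NULL) {
  layers <- names(observed)
  if (is.null(layers)) stop("observed p-values must be named by layer")
  P <- matrix(observed, 1, dimnames = list(NULL, layers))
  if (!is.null(draws) && nrow(draws) > 0) {
    P <- rbind(P, draws[, layers, drop = FALSE])
  }
  subs <- model_subsets(layers)
  out <- matrix(NA_real_, nrow(P), length(subs),
                dimnames = list(NULL, names(subs)))
  for (nm in names(subs)) {
    S <- subs[[nm]]
    if (length(S) == 1) {
      out[, nm] <- P[, S]
    } else {
      cs <- if (is.null(cov)) diag(4, length(S)) else cov[S, S]
      out[, nm] <- omnibus_fisher_combine(P[, S, drop = FALSE], cs)
    }
  }
  out
}

#' Optimal (minimum-p) test over all disease models
#'
#' Takes the minimum combined p-value across the layer-subset models as the
#' test statistic and calibrates it against the perturbed iterations:
#' \deqn{\hat p = \frac{1 + \sum_{b=1}^{B} I(p^{(b)} \le p^{(0)})}{1 + B}}
#' (the +1 correction keeps the estimate strictly positive; its resolution
#' is 1/(B + 1)).
#'
#' @param model_p (B + 1) x n_models matrix from [combine_all_models()];
#'   row 1 is the observed iteration.
#' @return List with `p` (final p-value), `min_observed` (observed min-p
#'   statistic), `B` (perturbation count used).
#' @export
optimal_test <- function(model_p) {
  if (nrow(model_p) < 2) stop("optimal test requires at least one perturbed iteration")
  p0 <- min(model_p[1, ])
  pb <- do.call(pmin, as.data.frame(model_p[-1, , drop = FALSE]))
  B <- length(pb)
  list(p = (1 + sum(pb <= p0)) / (1 + B), min_observed = p0, B = B)
}

#' Full gene-level analysis: per-layer tests, Omnibus-Fisher, optimal test
#'
#' Orchestrates the whole procedure for one gene: per-layer null models
#' (refitted on each layer's subjects, with optional layer-specific
#' covariates), kernel-machine score tests, perturbation-based covariance of
#' the p-values, the covariance-adjusted Fisher combination of the available
#' layers (`p_omnibus`), all pairwise/triple combinations, and optionally
#' the perturbation-calibrated minimum-p test (`p_optimal`) with a stepwise
#' escalation of the perturbation count so that small p-values receive more
#' iterations.
#'
#' @param phenotype Named numeric vector (names = subject ids), or a list
#'   with elements `values` and `subject_ids`.
#' @param blocks List of [omics_block()] objects (at most one per layer).
#' @param covariates Covariate matrix with rownames = subject ids, or
#'   `NULL` for intercept only.
#' @param family `"gaussian"`, `"binomial"`, or `NULL` to infer.
#' @param covariates_by_layer Optional named list of per-layer covariate
#'   matrices overriding `covariates`.
#' @param B_cov Perturbation count for covariance estimation (default 200).
#' @param optimal Run the optimal minimum-p test (default TRUE).
#' @param B_stages Stepwise perturbation schedule for the optimal test;
#'   escalates to the next stage while the current p-value is below
#'   `escalation_threshold / B`.
#' @param escalation_threshold Escalation rule constant (default 10).
#' @param seed Integer seed; combined with `gene_id` into a substream so
#'   genes are reproducible in any execution order.
#' @param gene_id Optional gene identifier (used in the seed substream and
#'   carried into the result).
#' @param include_observed_in_cov Include the observed p-values as
#'   iteration b = 0 in covariance estimation (default TRUE).
#' @return An object of class `of_gene_result`: per-layer `p_G/p_M/p_E`,
#'   pairwise/triple `p_GM/p_GE/p_ME/p_GME`, `p_omnibus`, `p_optimal`,
#'   `cov_hat`, `B_used`, per-layer sample sizes and test objects.
#' @export
run_gene <- function(phenotype, blocks, covariates = NULL, family = NULL,
                     covariates_by_layer = NULL, B_cov = 200, optimal = TRUE,
                     B_stages = c(1000, 10000, 100000),
                     escalation_threshold = 10, seed = NULL, gene_id = NULL,
                     include_observed_in_cov = TRUE) {
  if (is.list(phenotype) && !is.null(phenotype$values)) {
    y <- as.numeric(phenotype$values)
    ids <- as.character(phenotype$subject_ids)
    if (is.null(family) && !is.null(phenotype$family)) family <- phenotype$family
  } else {
    y <- as.numeric(phenotype)
    ids <- names(phenotype)
    if (is.null(ids)) stop("phenotype must carry subject ids (names or $subject_ids)")
  }
  names(y) <- ids

  if (length(blocks) < 1) stop("at least one omics block is required")
  layer_of <- vapply(blocks, function(b) b$layer, "")
  if (anyDuplicated(layer_of)) stop("at most one block per layer")
  names(blocks) <- layer_of
  blocks <- blocks[order(match(layer_of, LAYER_ORDER))]
  layers <- names(blocks)

  if (!is.null(seed)) set.seed(derive_seed(seed, gene_id))

  fits <- list()
  kms <- list()
  for (l in layers) {
    blk <- blocks[[l]]
    common <- ids[ids %in% blk$subject_ids]
    if (length(common) < 3) {
      stop("layer ", l, ": fewer than 3 subjects shared with the phenotype")
    }
    Xl <- if (!is.null(covariates_by_layer[[l]])) covariates_by_layer[[l]] else covariates
    if (!is.null(Xl)) {
      Xl <- as.matrix(Xl)
      if (is.null(rownames(Xl))) {
        if (nrow(Xl) != length(ids)) stop("covariates need rownames or phenotype-aligned rows")
        rownames(Xl) <- ids
      }
      missing_cov <- setdiff(common, rownames(Xl))
      if (length(missing_cov)) {
        stop("layer ", l, ": subjects missing covariates: ",
             paste(utils::head(missing_cov, 5), collapse = ", "))
      }
      Xl <- Xl[common, , drop = FALSE]
    }
    key <- paste(l, paste(common, collapse = ","),
                 if (is.null(Xl)) "" else paste(dim(Xl), collapse = "x"))
    # reuse the fit when subjects and covariates coincide across layers
    fit <- NULL
    for (f in fits) {
      if (identical(f$subject_ids, common) &&
          isTRUE(all.equal(f$X_input, Xl, check.attributes = FALSE))) {
        fit <- f
        break
      }
    }
    if (is.null(fit)) {
      fit <- fit_null(y[common], Xl, family = family, subject_ids = common)
      fit$X_input <- Xl
      fits[[length(fits) + 1]] <- fit
    }
    kms[[l]] <- km_test(fit, blk)
  }

  observed <- vapply(kms, function(k) k$p_value, 0)
  names(observed) <- layers

  draws_cov <- perturb_layer_pvalues(kms, B_cov)
  cov_hat <- estimate_cov(draws_cov, observed,
                          include_observed = include_observed_in_cov)
  obs_models <- combine_all_models(observed, NULL, cov_hat)
  full_model <- paste(layers, collapse = "")
  p_omnibus <- obs_models[1, full_model]

  p_optimal <- NA_real_
  B_used <- 0L
  if (optimal) {
    for (B in B_stages) {
      draws <- perturb_layer_pvalues(kms, B)
      cov_stage <- estimate_cov(draws, observed,
                                include_observed = include_observed_in_cov)
      mp <- combine_all_models(observed, draws, cov_stage)
      ot <- optimal_test(mp)
      p_optimal <- ot$p
      B_used <- B
      if (p_optimal >= escalation_threshold / B) break
    }
  }

  res <- list(gene_id = gene_id,
              p_G = NA_real_, p_M = NA_real_, p_E = NA_real_,
              p_GM = NA_real_, p_GE = NA_real_, p_ME = NA_real_,
              p_GME = NA_real_,
              p_omnibus = unname(p_omnibus), p_optimal = p_optimal,
              cov_hat = cov_hat, B_used = B_used,
              n = vapply(kms, function(k) k$n, 0L),
              Q = vapply(kms, function(k) k$Q, 0),
              method_used = vapply(kms, function(k) k$method_used, ""),
              layers = layers, km = kms)
  for (nm in colnames(obs_models)) {
    res[[paste0("p_", nm)]] <- unname(obs_models[1, nm])
  }
  class(res) <- "of_gene_result"
  res
}

#' @export
print.of_gene_result <- function(x, ...) {
  cat("Gene-level omnibus test", if (!is.null(x$gene_id)) paste0(" (", x$gene_id, ")"),
      "\n  layers: ", paste(x$layers, collapse = ", "), "\n", sep = "")
  for (l in x$layers) {
    cat(sprintf("  p_%s = %.4g (n = %d)\n", l, x[[paste0("p_", l)]], x$n[[l]]))
  }
  cat(sprintf("  p_omnibus = %.4g\n", x$p_omnibus))
  if (!is.na(x$p_optimal)) {
    cat(sprintf("  p_optimal = %.4g (B = %d)\n", x$p_optimal, x$B_used))
  }
  invisible(x)
}
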