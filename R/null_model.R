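#' Fit the covariates-only null model for a continuous or binary trait
#'
#' Fits the regression of the trait on covariates alone (no omics features),
#' which is the null model of the variance-component score test.  For a
#' continuous trait this is ordinary least squares, \eqn{y = X\beta + \epsilon};
#' for a binary trait it is logistic regression,
#' \eqn{logit P(y = 1) = X\beta}, fitted by iteratively reweighted least
#' squares.  The returned object carries everything the score test needs:
#' the estimated coefficients, the residual-type vector, the error-variance
#' or Bernoulli-variance estimate, and (implicitly, via matrix-free products)
#' the projection-like matrix
#' \deqn{P_0 = I - X(X'X)^{-1}X' \quad (gaussian)}
#' \deqn{P_0 = \hat\Sigma - \hat\Sigma X(X'\hat\Sigma X)^{-1}X'\hat\Sigma
#'   \quad (binomial, \hat\Sigma = diag(\hat\mu(1-\hat\mu))).}
#'
#' An intercept column is always enforced (prepended when no constant column
#' is present).  The gaussian error variance uses the unbiased denominator
#' \eqn{n - p}.
#'
#' @param y Numeric phenotype vector; binary traits must be coded 0/1.
#' @param X Covariate matrix (n x p) or `NULL` for intercept only.
#' @param family `"gaussian"` or `"binomial"`; when `NULL`, inferred as
#'   binomial iff all values of `y` are in \{0, 1\}.
#' @param subject_ids Optional subject identifiers (default
#'   `rownames(X)` or `seq_along(y)` as character).
#' @param p0_cap Largest n for which [p0_matrix()] will materialize the dense
#'   n x n matrix (matrix-free products via [p0_mult()] are always available).
#'
#' @return An object of class `of_null_model` with elements `beta_hat`,
#'   `residual`, `sigma2_hat` (gaussian), `mu_hat` and `sigma_diag`
#'   (binomial), `family`, `X`, `y`, `subject_ids`, `n`, `p`, `degenerate`.
#'
#' @examples
#' fit <- fit_null(c(1, 2, 3), family = "gaussian")
#' fit$beta_hat     # 2
#' fit$residual     # -1 0 1
#' @export
fit_null <- function(y, X = NULL, family = NULL, subject_ids = NULL,
                     p0_cap = 5000) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("phenotype contains missing values")
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- match.arg(family, c("gaussian", "binomial"))

  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
    if (nrow(X) != n) stop("covariate rows (", nrow(X),
                           ") do not match phenotype length (", n, ")")
    if (anyNA(X)) stop("covariates contain missing values")
    has_const <- apply(X, 2, function(cc) all(cc == cc[1]) && cc[1] != 0)
    if (!any(has_const)) {
      X <- cbind("(Intercept)" = 1, X)
    }
  }
  p <- ncol(X)
  if (n < p + 2) stop("need n >= p + 2 subjects (n = ", n, ", p = ", p, ")")

  if (is.null(subject_ids)) {
    subject_ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids in phenotype")

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  fit <- list(family = family, X = X, y = y, n = n, p = p,
              subject_ids = subject_ids, p0_cap = p0_cap,
              cache = new.env(parent = emptyenv()))

  if (family == "gaussian") {
    beta <- qr.coef(qx, y)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    rss <- sum(res^2)
    sigma2 <- rss / (n - p)
    fit$beta_hat <- beta
    fit$residual <- res
    fit$sigma2_hat <- sigma2
    fit$qr <- qx
    fit$degenerate <- sigma2 < 1e-12 * max(1, mean(y^2))
    if (fit$degenerate) {
      warning("null model fits the trait exactly (sigma2_hat ~ 0); ",
              "score statistics are degenerate")
    }
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial family requires a 0/1 phenotype")
    if (length(unique(y)) < 2) {
      stop("binary phenotype has a single class; cannot fit the null model")
    }
    g <- stats::glm.fit(x = X, y = y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 50))
    if (!g$converged) {
      stop("logistic null model did not converge in 50 IRLS iterations")
    }
    mu <- g$fitted.values
    if (g$boundary || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop("fitted probabilities numerically at 0/1; ",
           "possible separation in the logistic null model")
    }
    fit$beta_hat <- g$coefficients
    fit$mu_hat <- mu
    fit$residual <- y - mu
    fit$sigma_diag <- mu * (1 - mu)
    # factors for P0 = S - SX (X'SX)^-1 X'S products
    sX <- X * fit$sigma_diag
    fit$sX <- sX
    fit$XtSX_inv <- solve(crossprod(X, sX))
    fit$degenerate <- FALSE
  }
  class(fit) <- "of_null_model"
  fit
}

#' @export
print.of_null_model <- function(x, ...) {
  cat("Null model (", x$family, "), n = ", x$n, ", p = ", x$p, "\n", sep = "")
  cat("beta_hat:", format(x$beta_hat, digits = 4), "\n")
  if (x$family == "gaussian") cat("sigma2_hat:", format(x$sigma2_hat, digits = 6), "\n")
  invisible(x)
}

#' Multiply the null-model projection matrix P0 into a matrix, matrix-free
#'
#' Computes `P0 %*% M` without forming the n x n matrix:
#' gaussian `P0 = I - X(X'X)^-1 X'`, binomial
#' `P0 = S - SX(X'SX)^-1 X'S` with `S = diag(mu(1-mu))`.
#'
#' @param fit An [fit_null()] object.
#' @param M Numeric vector or n x k matrix.
#' @return Matrix of the same shape as `M`.
#' @export
p0_mult <- function(fit, M) {
  M <- as.matrix(M)
  if (nrow(M) != fit$n) stop("M has ", nrow(M), " rows; expected ", fit$n)
  if (fit$family == "gaussian") {
    M - qr.fitted(fit$qr, M)
  } else {
    sM <- M * fit$sigma_diag
    sM - fit$sX %*% (fit$XtSX_inv %*% crossprod(fit$sX, M))
  }
}

#' Materialize the dense P0 matrix
#'
#' Forms the n x n matrix explicitly; refused above `p0_cap` (set in
#' [fit_null()]) unless `force = TRUE`, since all internal computation uses
#' matrix-free products.
#'
#' @param fit An [fit_null()] object.
#' @param force Materialize even when n exceeds the cap.
#' @return n x n symmetric positive semi-definite matrix.
#' @export
p0_matrix <- function(fit, force = FALSE) {
  if (fit$n > fit$p0_cap && !force) {
    stop("n = ", fit$n, " exceeds p0_cap = ", fit$p0_cap,
         "; use p0_mult() or force = TRUE")
  }
  P <- p0_mult(fit, diag(fit$n))
  (P + t(P)) / 2
}

# P0^{1/2} %*% M.  Gaussian P0 is an orthogonal projection, so the square
# root is P0 itself; binomial needs the symmetric eigendecomposition of P0
# (cached on the fit), with tiny negative eigenvalues clamped to zero.
p0_sqrt_mult <- function(fit, M) {
  M <- as.matrix(M)
  if (fit$family == "gaussian") return(p0_mult(fit, M))
  if (is.null(fit$cache$p0_eig)) {
    P <- p0_matrix(fit, force = TRUE)
    e <- eigen(P, symmetric = TRUE)
    e$values <- pmax(e$values, 0)
    fit$cache$p0_eig <- e
  }
  e <- fit$cache$p0_eig
  e$vectors %*% (sqrt(e$values) * crossprod(e$vectors, M))
}

# internal: compare two null fits for "same null model on same subjects"
same_null_model <- function(a, b) {
  identical(a$family, b$family) &&
    identical(a$subject_ids, b$subject_ids) &&
    isTRUE(all.equal(a$X, b$X, tolerance = 1e-12, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$y, b$y, tolerance = 1e-12))
}
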