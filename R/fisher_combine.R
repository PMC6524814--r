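#' Classical Fisher combination of p-values
#'
#' Combines p-values assuming independence:
#' \eqn{T = -2\sum_i \ln p_i \sim \chi^2_{2w}}.  Used as the uncorrected
#' comparison arm; with correlated inputs its Type I error is inflated.
#'
#' @param p Vector of p-values in (0, 1\], or a matrix whose rows are
#'   replicate p-value sets (combined row-wise).
#' @return Combined p-value(s) in (0, 1\].
#' @export
usual_fisher_combine <- function(p) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  check_pvalues(P)
  w <- ncol(P)
  T <- -2 * rowSums(log(pmax(P, 1e-300)))
  out <- stats::pchisq(T, df = 2 * w, lower.tail = FALSE)
  out <- pmin(pmax(out, 1e-300), 1)
  if (is.matrix(p)) out else out[1]
}

#' Covariance-adjusted Fisher combination (Omnibus-Fisher)
#'
#' Combines w correlated p-values via Fisher's statistic
#' \eqn{T = -2\sum_i \ln p_i} with a Satterthwaite adjustment: with
#' \eqn{E(T) = 2w} and
#' \eqn{Var(T) = 4w + 2\sum_{i<j} cov(-2\ln p_i, -2\ln p_j)},
#' the scaled statistic \eqn{cT \approx \chi^2_v} where
#' \eqn{v = 2[E(T)]^2/Var(T)} and \eqn{c = v/E(T)}.  The (generally
#' fractional) degrees of freedom are evaluated through the
#' gamma(v/2, scale 2) survival function.  Diagonal entries of `cov` are
#' fixed at 4 (the variance of \eqn{-2\ln U}, U uniform) regardless of what
#' was estimated; Var(T) is floored at `0.1 * 4w` (with a warning) when the
#' plugged-in covariances would drive it that low or negative.
#'
#' @param p Vector of p-values in (0, 1\] (length w), or a matrix whose rows
#'   are replicate p-value sets sharing one covariance matrix.
#' @param cov w x w symmetric covariance matrix of \eqn{-2\ln p_i}; only the
#'   off-diagonal entries are used.  `NULL` (default) means independence.
#' @return Combined p-value(s) in (0, 1\].
#' @examples
#' omnibus_fisher_combine(c(0.5, 0.5, 0.5))            # ~0.6547
#' omnibus_fisher_combine(c(0.01, 0.02),
#'                        cov = matrix(c(4, 2, 2, 4), 2))
#' @export
omnibus_fisher_combine <- function(p, cov = NULL) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  check_pvalues(P)
  w <- ncol(P)
  if (is.null(cov)) cov <- diag(4, w)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("covariance matrix of -2 ln p must be symmetric")
  }
  if (nrow(cov) != w) stop("cov must be ", w, " x ", w)
  diag(cov) <- 4
  ET <- 2 * w
  VT <- 4 * w + 2 * sum(cov[upper.tri(cov)])
  floor_VT <- 0.1 * 4 * w
  if (VT < floor_VT) {
    warning("Var(T) = ", format(VT, digits = 4),
            " after covariance plug-in; floored at ", floor_VT)
    VT <- floor_VT
  }
  v <- 2 * ET^2 / VT
  cc <- v / ET
  T <- -2 * rowSums(log(pmax(P, 1e-300)))
  out <- stats::pgamma(cc * T, shape = v / 2, scale = 2, lower.tail = FALSE)
  out <- pmin(pmax(out, 1e-300), 1)
  if (is.matrix(p)) out else out[1]
}

check_pvalues <- function(P) {
  if (anyNA(P)) stop("p-values contain NA")
  if (any(P <= 0) || any(P > 1)) {
    stop("p-values must lie in (0, 1]; floor tiny values at 1e-300 before combining")
  }
  invisible(P)
}
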