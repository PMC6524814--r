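#' Construct an omics block
#'
#' Wraps one omics layer's feature matrix for a gene: SNP genotype dosages
#' (`layer = "G"`, values in \[0, 2\]), methylation M-values (`"M"`), or
#' expression values (`"E"`), together with subject identifiers and an
#' optional diagonal feature-weight matrix (given as a vector; default all
#' ones, i.e. W = I).
#'
#' @param matrix Numeric n x m feature matrix (subjects x features).
#' @param layer One of `"G"`, `"M"`, `"E"`.
#' @param subject_ids Subject identifiers (default rownames or 1..n).
#' @param weights Nonnegative weight per feature (length m), the diagonal of
#'   W; default identity.
#' @return An object of class `of_omics_block`.
#' @export
omics_block <- function(matrix, layer = c("G", "M", "E"), subject_ids = NULL,
                        weights = NULL) {
  layer <- match.arg(layer)
  D <- as.matrix(matrix)
  storage.mode(D) <- "double"
  if (ncol(D) < 1) stop("omics block has an empty feature set")
  if (anyNA(D)) stop("omics block contains missing values")
  if (layer == "G" && (min(D) < 0 || max(D) > 2)) {
    stop("genotype layer must contain dosages in [0, 2]")
  }
  if (is.null(subject_ids)) {
    subject_ids <- if (!is.null(rownames(D))) rownames(D) else as.character(seq_len(nrow(D)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(D)) stop("subject_ids length does not match rows")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids in omics block")
  if (is.null(weights)) weights <- rep(1, ncol(D))
  if (length(weights) != ncol(D) || any(weights < 0)) {
    stop("weights must be a nonnegative vector of length ncol(matrix)")
  }
  structure(list(matrix = D, layer = layer, subject_ids = subject_ids,
                 weights = as.numeric(weights)),
            class = "of_omics_block")
}

# reorder block rows into the null fit's subject order; error on mismatch
align_block <- function(fit, block) {
  if (identical(fit$subject_ids, block$subject_ids)) return(block)
  idx <- match(fit$subject_ids, block$subject_ids)
  if (anyNA(idx) || length(fit$subject_ids) != length(block$subject_ids)) {
    miss_fit <- setdiff(fit$subject_ids, block$subject_ids)
    miss_blk <- setdiff(block$subject_ids, fit$subject_ids)
    stop("subject ids of the ", block$layer, " block do not match the null ",
         "model; unmatched: ",
         paste(utils::head(c(miss_fit, miss_blk), 10), collapse = ", "))
  }
  block$matrix <- block$matrix[idx, , drop = FALSE]
  block$subject_ids <- fit$subject_ids
  block
}

#' Kernel-machine variance-component score statistic Q
#'
#' Computes the quadratic-form score statistic for one omics block:
#' \deqn{Q = (y - X\hat\beta)' D W D' (y - X\hat\beta)/\hat\sigma_E^2}
#' for a continuous trait and
#' \deqn{Q = (y - \hat\mu)' D W D' (y - \hat\mu)}
#' for a binary trait, where D is the block's feature matrix.
#'
#' @param fit Null model from [fit_null()], fitted on exactly the block's
#'   subjects.
#' @param block An [omics_block()].
#' @return Nonnegative scalar Q.
#' @export
km_statistic <- function(fit, block) {
  block <- align_block(fit, block)
  s <- crossprod(km_dw(block), fit$residual)
  q <- sum(s^2)
  if (q == 0) return(0)
  if (fit$family == "gaussian") {
    # a degenerate (perfect) null fit leaves only rounding noise in the
    # residual; the 0/0 ratio is defined as 0
    if (isTRUE(fit$degenerate)) return(0)
    q <- q / fit$sigma2_hat
  }
  q
}

# column-weighted feature matrix D W^{1/2}
km_dw <- function(block) {
  sweep(block$matrix, 2, sqrt(block$weights), `*`)
}

#' Eigen-structure of the projected weighted feature matrix
#'
#' Returns the positive eigenvalues (descending) of
#' \eqn{P_0^{1/2} D W D' P_0^{1/2}}, which define the null law
#' \eqn{Q \sim \sum_i \lambda_i \chi^2_{1,i}}.  They are computed from the
#' m x m dual matrix \eqn{W^{1/2} D' P_0 D W^{1/2}}, whose nonzero spectrum
#' is identical, so no n x n factorization is needed.  The eigenvalues are
#' used as-is for both trait families: for a continuous trait the
#' \eqn{1/\hat\sigma_E^2} factor inside Q already cancels the residual
#' variance \eqn{\sigma^2} carried by \eqn{y - X\hat\beta}, so
#' \eqn{Q \sim \sum_i \lambda_i \chi^2_{1,i}} holds with the unscaled
#' eigenvalues.  Eigenvalues below `tol * max(lambda)` are
#' dropped.  Eigenvectors of the n x n matrix are not formed here; they are
#' available on demand from [km_eigenvectors()].
#'
#' @param fit Null model from [fit_null()].
#' @param block An [omics_block()].
#' @param tol Relative positivity threshold for retained eigenvalues.
#' @return An object of class `of_km_eigens`: `lambda` (scaled, descending),
#'   `lambda_raw` (unscaled), `pre` (n x m matrix C with V = P0^{1/2} C),
#'   `fit`, `layer`, `subject_ids`.
#' @export
km_eigens <- function(fit, block, tol = 1e-10) {
  block <- align_block(fit, block)
  Dw <- km_dw(block)
  PD <- p0_mult(fit, Dw)
  A <- crossprod(Dw, PD)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  lmax <- if (length(e$values)) max(e$values, 0) else 0
  if (lmax < 0) stop("projected feature matrix is not PSD; broken null fit")
  keep <- e$values > tol * lmax & e$values > 0
  lam_raw <- e$values[keep]
  U <- e$vectors[, keep, drop = FALSE]
  pre <- if (length(lam_raw)) {
    Dw %*% sweep(U, 2, sqrt(lam_raw), `/`)
  } else {
    matrix(0, fit$n, 0)
  }
  structure(list(lambda = lam_raw, lambda_raw = lam_raw, pre = pre, fit = fit,
                 layer = block$layer, subject_ids = fit$subject_ids),
            class = "of_km_eigens")
}

#' Explicit eigenvectors of P0^(1/2) D W D' P0^(1/2)
#'
#' Materializes the orthonormal eigenvectors `V = P0^{1/2} C` belonging to
#' the positive eigenvalues of [km_eigens()].  For gaussian null models the
#' square root is P0 itself (idempotent); for binomial models it requires an
#' n x n symmetric eigendecomposition of P0 (cached on the fit).
#'
#' @param eig An `of_km_eigens` object.
#' @return n x m matrix with orthonormal columns.
#' @export
km_eigenvectors <- function(eig) {
  p0_sqrt_mult(eig$fit, eig$pre)
}

#' Tail probability of a positively weighted sum of chi-square(1) variables
#'
#' Computes \eqn{p = P(\sum_i \lambda_i \chi^2_{1,i} > Q)} for positive
#' weights.  The primary algorithm inverts the characteristic function
#' numerically (Davies/Imhof-type oscillatory integral with an analytic
#' truncation bound and a total integration-term limit); when the required
#' number of terms exceeds the limit, the result falls outside \[0, 1\], or
#' the tail is too extreme for absolute-accuracy inversion (p < 1e-6), the
#' Kuonen saddlepoint approximation is used instead.  A single eigenvalue,
#' or all eigenvalues equal, is a scaled chi-square and is evaluated
#' exactly.  Results are clipped to (1e-300, 1\].
#'
#' @param Q Nonnegative statistic (scalar, or vector sharing `lambda`).
#' @param lambda Positive eigenvalue weights.
#' @param acc Target absolute accuracy of the inversion.
#' @param lim Integration-term limit before the saddlepoint takes over.
#' @return For scalar `Q`, a scalar p-value with attribute `method` (one of
#'   `"davies"`, `"saddlepoint"`, `"exact"`, `"exact_zero"`); for vector
#'   `Q`, a vector of p-values with a `method` attribute vector.
#' @examples
#' mixture_chisq_pvalue(3.841459, 1)   # ~0.05, chi-square(1)
#' @export
mixture_chisq_pvalue <- function(Q, lambda, acc = 1e-9, lim = 1e6) {
  lambda <- as.numeric(lambda)
  if (length(lambda) < 1) stop("lambda must be nonempty")
  if (any(lambda <= 0)) stop("lambda must be strictly positive")
  Q <- as.numeric(Q)
  if (anyNA(Q) || any(Q < 0)) stop("Q must be nonnegative")

  m <- length(lambda)
  p <- rep(NA_real_, length(Q))
  method <- rep(NA_character_, length(Q))

  zero <- Q == 0
  p[zero] <- 1
  method[zero] <- "exact_zero"
  todo <- which(!zero)
  if (length(todo)) {
    if (m == 1 || max(lambda) - min(lambda) <= 1e-12 * max(lambda)) {
      p[todo] <- stats::pchisq(Q[todo] / lambda[1], df = m, lower.tail = FALSE)
      method[todo] <- "exact"
    } else {
      # Statistics far below the null mean make the oscillatory truncation
      # bound of the inversion unattainable within the term limit; their
      # p-values (all close to 1) go straight to the saddlepoint.
      low <- Q[todo] < 0.05 * sum(lambda)
      dav <- todo[!low]
      if (length(dav)) {
        dv <- davies_batch(Q[dav], lambda, acc = acc, lim = lim)
        ok <- is.finite(dv) & dv >= 1e-6 & dv <= 1
        p[dav[ok]] <- dv[ok]
        method[dav[ok]] <- "davies"
        low <- Q[todo] < 0.05 * sum(lambda)
        sp_idx <- c(todo[low], dav[!ok])
      } else {
        sp_idx <- todo[low]
      }
      if (length(sp_idx)) {
        sp <- vapply(Q[sp_idx], saddlepoint_pvalue, 0, lambda = lambda)
        p[sp_idx] <- sp
        method[sp_idx] <- "saddlepoint"
      }
    }
  }
  p <- pmin(pmax(p, 1e-300), 1)
  attr(p, "method") <- method
  p
}

# Characteristic-function inversion for P(sum lambda_i chisq_1 > q), batched
# over q sharing one lambda.  Integrand (Imhof form):
#   p = 1/2 + (1/pi) * int_0^inf sin(theta(u)) / (u * rho(u)) du,
#   theta(u) = 0.5 * sum(atan(lambda u)) - 0.5 q u,
#   rho(u)   = prod (1 + lambda^2 u^2)^{1/4}.
# Truncation point U from the envelope |integrand| <= g(u) =
# u^{-1-m/2} prod(lambda)^{-1/2}: either the crude absolute bound
#   tail(U) <= (2/(pi m)) prod(lambda)^{-1/2} U^{-m/2} <= acc/2,
# or, for small m where that is hopeless, the integration-by-parts bound
# for the oscillatory tail (phase speed ~ q/2):
#   tail(U) <= (4/(pi q)) g(U) <= acc/2.
# The grid is doubled until the trapezoid estimate stabilizes; NA is
# returned for points that fail within the term limit.
davies_batch <- function(q, lambda, acc = 1e-9, lim = 1e6) {
  m <- length(lambda)
  slam <- sum(lambda)
  logprod <- sum(log(lambda))
  logU_crude <- (2 / m) * (log(4 / (pi * m * acc)) - 0.5 * logprod)
  qmin <- min(q)
  logU_osc <- (log(8 / (pi * qmin * acc)) - 0.5 * logprod) / (1 + m / 2)
  U <- exp(min(logU_crude, logU_osc))
  # oscillation count over [0, U]; phase speed <= (slam + max q)/2
  K <- U * (slam + max(q)) / (4 * pi)
  N <- max(512, 2^ceiling(log2(8 * max(1, K))))
  if (N * m > 64 * lim) return(rep(NA_real_, length(q)))  # hopeless range
  repeat {
    u <- seq(0, U, length.out = N + 1)
    uu <- u[-1]
    lamu <- outer(lambda, uu)
    theta0 <- 0.5 * colSums(atan(lamu))
    base <- exp(-0.25 * colSums(log1p(lamu^2))) / uu
    # value at u = 0: integrand -> 0.5 * (slam - q)
    f <- sin(theta0 - outer(uu, q / 2)) * base      # (N) x (nq)
    f0 <- 0.5 * (slam - q)
    h <- U / N
    # composite Simpson on the full grid, with the half-grid (every other
    # point) Simpson estimate from the same evaluations as error control
    odd <- seq(1, N, by = 2)                        # u = h, 3h, ...
    even <- seq(2, N - 1, by = 2)                   # interior even points
    s_full <- (h / 3) * (f0 + 4 * colSums(f[odd, , drop = FALSE]) +
                           2 * colSums(f[even, , drop = FALSE]) + f[N, ])
    est <- 0.5 + s_full / pi
    half <- seq(2, N, by = 2)                       # step 2h grid
    fh <- f[half, , drop = FALSE]
    nh <- length(half)
    oddh <- seq(1, nh, by = 2)
    evenh <- seq(2, nh - 1, by = 2)
    s_half <- (2 * h / 3) * (f0 + 4 * colSums(fh[oddh, , drop = FALSE]) +
                               2 * colSums(fh[evenh, , drop = FALSE]) +
                               fh[nh, ])
    err <- abs(s_full - s_half) / pi
    if (all(err < pmax(acc, 1e-10))) return(est)
    if (2 * N * m > 32 * lim) {
      est[err >= 1e-7] <- NA_real_
      return(est)
    }
    N <- 2 * N
  }
}

# Large-batch mixture p-values sharing one lambda: for many statistics the
# smooth monotone map q -> log p is evaluated by the full inversion on 257
# nodes spanning the batch range and interpolated by a monotone (Hyman)
# spline; small batches, near-zero statistics and degenerate spectra use
# the direct path.
batch_mixture_pvalue <- function(Q, lambda, acc = 3e-7) {
  m <- length(lambda)
  n_nodes <- if (length(Q) >= 600) 257 else 129
  if (length(Q) < 150 || m < 2 ||
      max(lambda) - min(lambda) <= 1e-12 * max(lambda)) {
    return(as.numeric(mixture_chisq_pvalue(Q, lambda, acc = acc)))
  }
  slam <- sum(lambda)
  hi <- Q >= 0.05 * slam
  p <- numeric(length(Q))
  if (any(!hi)) {
    p[!hi] <- as.numeric(mixture_chisq_pvalue(Q[!hi], lambda, acc = acc))
  }
  qhi <- Q[hi]
  if (max(qhi) - min(qhi) < 1e-8 * slam) {
    p[hi] <- as.numeric(mixture_chisq_pvalue(qhi, lambda, acc = acc))
    return(pmin(pmax(p, 1e-300), 1))
  }
  nodes <- seq(min(qhi), max(qhi), length.out = n_nodes)
  lp <- log(as.numeric(mixture_chisq_pvalue(nodes, lambda, acc = acc)))
  if (all(diff(lp) < 0)) {
    sf <- stats::splinefun(nodes, lp, method = "hyman")
    p[hi] <- exp(sf(qhi))
  } else {
    p[hi] <- as.numeric(mixture_chisq_pvalue(qhi, lambda, acc = acc))
  }
  pmin(pmax(p, 1e-300), 1)
}

# Kuonen's saddlepoint approximation for P(sum lambda_i chisq_1 > q).
# K(z) = -0.5 sum log(1 - 2 z lambda); solve K'(zhat) = q on
# (-inf, 1/(2 max lambda)); Lugannani-Rice tail formula.
saddlepoint_pvalue <- function(q, lambda) {
  slam <- sum(lambda)
  if (abs(q - slam) < 1e-10 * slam) return(0.5)
  zmax <- 1 / (2 * max(lambda))
  kp <- function(z) sum(lambda / (1 - 2 * z * lambda)) - q
  if (q > slam) {
    lo <- 0
    hi <- zmax * (1 - 1e-12)
    # K' -> +inf at zmax, so a root exists in (0, zmax)
  } else {
    hi <- 0
    lo <- -1
    while (kp(lo) > 0) lo <- lo * 2
  }
  zhat <- stats::uniroot(kp, c(lo, hi), tol = .Machine$double.eps^0.5,
                         maxiter = 1000)$root
  if (abs(zhat) < 1e-12) return(0.5)
  Kz <- -0.5 * sum(log1p(-2 * zhat * lambda))
  K2 <- sum(2 * lambda^2 / (1 - 2 * zhat * lambda)^2)
  w <- sign(zhat) * sqrt(max(0, 2 * (zhat * q - Kz)))
  v <- zhat * sqrt(K2)
  if (w == 0) return(0.5)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

#' Kernel-machine score test for one omics block
#'
#' Composes [km_statistic()], [km_eigens()] and [mixture_chisq_pvalue()]
#' into the full gene-level test of one layer, caching the eigen-structure
#' for the perturbation machinery.
#'
#' @inheritParams km_statistic
#' @param tol Eigenvalue positivity threshold passed to [km_eigens()].
#' @return An object of class `of_km_test`: `Q`, `lambda`, `p_value`,
#'   `method_used`, `layer`, `eigens` (the [km_eigens()] object), `n`.
#' @export
km_test <- function(fit, block, tol = 1e-10) {
  Q <- km_statistic(fit, block)
  eig <- km_eigens(fit, block, tol = tol)
  if (length(eig$lambda) == 0) {
    p <- 1
    meth <- "exact_zero"
  } else {
    p <- mixture_chisq_pvalue(Q, eig$lambda)
    meth <- attr(p, "method")
  }
  structure(list(Q = Q, lambda = eig$lambda, p_value = as.numeric(p),
                 method_used = meth, layer = block$layer, eigens = eig,
                 n = fit$n),
            class = "of_km_test")
}

#' @export
print.of_km_test <- function(x, ...) {
  cat("KM score test, layer ", x$layer, ": Q = ", format(x$Q, digits = 6),
      ", ", length(x$lambda), " eigenvalues, p = ",
      format(x$p_value, digits = 4), " (", x$method_used, ")\n", sep = "")
  invisible(x)
}
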