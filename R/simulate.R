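#' Build synthetic pools of haplotypes, methylation and expression
#'
#' Generates the three sampling pools that the per-dataset simulators draw
#' from, emulating the structure of real multi-omics panels:
#'
#' * **Haplotypes**: binary haplotypes over a SNP region with linkage
#'   disequilibrium generated by thresholding a stationary AR(1) latent
#'   Gaussian process along the chromosome: adjacent sites have liability
#'   correlation `ld_rho`, so allelic r-squared decays geometrically with
#'   distance (LD blocks over a 200-kb-like region).  Site allele
#'   frequencies are drawn log-uniform over `maf_range` (a rare-skewed,
#'   coalescent-like spectrum) and coded so the pool frequency of allele 1
#'   is in (0, 0.5].
#' * **Methylation**: M-values \eqn{\log_2(\beta/(1-\beta))} where each
#'   CpG's beta values follow a Beta distribution centered at a CpG-specific
#'   level drawn from a two-component (hypo-/hyper-methylated) mixture, with
#'   concentration `methyl_kappa` controlling the within-CpG spread
#'   (per-CpG M-value sd about 0.1, typical of array methylation in
#'   blood); CpGs come in blocks of `cpg_block_size` coupled through a
#'   Gaussian copula with within-block correlation `methyl_block_cor`.
#' * **Expression**: log-scale expression with per-gene means drawn around
#'   the global mean `expr_mean` (7.45 by default) and recentered so the
#'   pool grand mean equals it exactly.
#'
#' @param n_haplotypes,n_snps Haplotype pool dimensions (default 10000 x
#'   250; each simulated gene draws a contiguous 50-SNP window, so the
#'   pool spans several gene-widths and replicate datasets average over
#'   local LD/frequency realizations).
#' @param ld_rho Adjacent-site latent (liability) correlation.
#' @param maf_range Range of site allele frequencies (log-uniform draw).
#' @param n_methyl_samples,n_cpgs,cpg_block_size Methylation pool shape.
#' @param methyl_block_cor Within-block latent correlation of CpGs.
#' @param methyl_kappa Beta concentration of within-CpG variation.
#' @param methyl_levels Ranges of the CpG-level methylation fractions for
#'   the hypo and hyper components, as `list(hypo =, hyper =)`.
#' @param n_expr_samples,n_expr_genes Expression pool shape.
#' @param expr_mean Global expression mean (paper-scale log units).
#' @param expr_gene_sd,expr_within_sd Between-gene and within-gene spread.
#' @param seed Optional integer seed.
#' @return An object of class `of_pool_set` with elements `haplotypes`
#'   (H x S 0/1 matrix), `maf`, `methyl` (samples x CpGs M-values),
#'   `cpg_block_size`, `expr` (samples x genes), `expr_mean`.
#' @export
build_pools <- function(n_haplotypes = 10000, n_snps = 250, ld_rho = 0.95,
                        maf_range = c(0.002, 0.5),
                        n_methyl_samples = 600, n_cpgs = 100,
                        cpg_block_size = 5, methyl_block_cor = 0.6,
                        methyl_kappa = 1500,
                        methyl_levels = list(hypo = c(0.05, 0.3),
                                             hyper = c(0.7, 0.95)),
                        n_expr_samples = 400, n_expr_genes = 50,
                        expr_mean = 7.45, expr_gene_sd = 0.4,
                        expr_within_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_snps < 2 || n_haplotypes < 2) stop("invalid haplotype pool config")
  if (cpg_block_size < 1 || n_cpgs %% cpg_block_size != 0) {
    stop("n_cpgs must be a multiple of cpg_block_size")
  }
  if (methyl_block_cor < 0 || methyl_block_cor >= 1) {
    stop("methyl_block_cor must be in [0, 1)")
  }

  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  freq <- exp(stats::runif(n_snps, log(maf_range[1]), log(maf_range[2])))
  z <- matrix(0, n_haplotypes, n_snps)
  z[, 1] <- stats::rnorm(n_haplotypes)
  sd_innov <- sqrt(1 - ld_rho^2)
  for (s in 2:n_snps) {
    z[, s] <- ld_rho * z[, s - 1] + sd_innov * stats::rnorm(n_haplotypes)
  }
  hap <- matrix(0L, n_haplotypes, n_snps)
  hap[sweep(z, 2, stats::qnorm(freq), `<`)] <- 1L
  pf <- colMeans(hap)
  flip <- pf > 0.5
  hap[, flip] <- 1L - hap[, flip]
  mono <- colSums(hap) == 0
  if (any(mono)) {  # keep every site polymorphic in the pool
    for (s in which(mono)) hap[sample.int(n_haplotypes, 1), s] <- 1L
  }
  maf <- colMeans(hap)

  nblocks <- n_cpgs %/% cpg_block_size
  rho <- methyl_block_cor
  comp_hyper <- stats::runif(n_cpgs) < 0.5
  lev <- ifelse(comp_hyper,
                stats::runif(n_cpgs, methyl_levels$hyper[1], methyl_levels$hyper[2]),
                stats::runif(n_cpgs, methyl_levels$hypo[1], methyl_levels$hypo[2]))
  methyl <- matrix(0, n_methyl_samples, n_cpgs)
  for (bl in seq_len(nblocks)) {
    cols <- ((bl - 1) * cpg_block_size + 1):(bl * cpg_block_size)
    f <- stats::rnorm(n_methyl_samples)
    z <- sqrt(rho) * f + sqrt(1 - rho) *
      matrix(stats::rnorm(n_methyl_samples * cpg_block_size),
             n_methyl_samples, cpg_block_size)
    u <- stats::pnorm(z)
    for (j in seq_along(cols)) {
      cj <- cols[j]
      beta <- stats::qbeta(u[, j], lev[cj] * methyl_kappa,
                           (1 - lev[cj]) * methyl_kappa)
      beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
      methyl[, cj] <- log2(beta / (1 - beta))
    }
  }
  methyl_means <- colMeans(methyl)

  mu_g <- stats::rnorm(n_expr_genes, expr_mean, expr_gene_sd)
  expr <- matrix(stats::rnorm(n_expr_samples * n_expr_genes, 0, expr_within_sd),
                 n_expr_samples, n_expr_genes)
  expr <- sweep(expr, 2, mu_g, `+`)
  expr <- expr - mean(expr) + expr_mean

  structure(list(haplotypes = hap, maf = maf, methyl = methyl,
                 methyl_means = methyl_means,
                 cpg_block_size = cpg_block_size, expr = expr,
                 expr_mean = expr_mean),
            class = "of_pool_set")
}

#' Simulation scenario specification
#'
#' Describes one simulated study condition: trait type, which layers are
#' causal, whether genotype and expression are coupled (one causal SNP's
#' genotype added to the expression value), sample sizes and effect sizes.
#' Defaults follow the study design the package reproduces: 50 SNPs, 5
#' CpGs and 1 expression value per gene; 5 causal SNPs and 2 causal CpGs;
#' logistic intercept -2.94 (prevalence 0.05); genotype effect 0.3 when G
#' is the only causal layer and 0.2 otherwise; methylation effect 0.9;
#' expression effect 1 on the expression value centered at the pool mean;
#' 500 cases + 500 controls for binary traits and n = 1000 for continuous.
#'
#' @param trait `"binary"` or `"continuous"`.
#' @param causal Which layers carry signal: `"none"`, `"G"`, `"GM"`,
#'   `"GME"`.
#' @param coupling `"independent"` or `"GE"` (expression = pool value +
#'   first causal SNP's genotype).
#' @param n_cases,n_controls Binary-trait quotas.
#' @param n Continuous-trait sample size.
#' @param beta_G,beta_M,beta_E Effect sizes (beta_G defaults by `causal`).
#' @param intercept Logistic intercept.
#' @param n_snps,n_cpgs,n_expr,n_causal_snps,n_causal_cpgs Gene layout.
#' @return An object of class `of_scenario`.
#' @export
scenario_spec <- function(trait = c("binary", "continuous"),
                          causal = c("G", "GM", "GME", "none"),
                          coupling = c("independent", "GE"),
                          n_cases = 500, n_controls = 500, n = 1000,
                          beta_G = NULL, beta_M = 0.9, beta_E = 1,
                          intercept = -2.94, n_snps = 50, n_cpgs = 5,
                          n_expr = 1, n_causal_snps = 5, n_causal_cpgs = 2) {
  trait <- match.arg(trait)
  causal <- match.arg(causal)
  coupling <- match.arg(coupling)
  if (is.null(beta_G)) beta_G <- if (causal == "G") 0.3 else 0.2
  structure(list(trait = trait, causal = causal, coupling = coupling,
                 n_cases = n_cases, n_controls = n_controls, n = n,
                 beta_G = beta_G, beta_M = beta_M, beta_E = beta_E,
                 intercept = intercept, n_snps = n_snps, n_cpgs = n_cpgs,
                 n_expr = n_expr, n_causal_snps = n_causal_snps,
                 n_causal_cpgs = n_causal_cpgs),
            class = "of_scenario")
}

# draw nc subjects' worth of raw data from the pools for one simulated gene
draw_subjects <- function(nc, pools, gene, spec) {
  H <- nrow(pools$haplotypes)
  i1 <- sample.int(H, nc, replace = TRUE)
  i2 <- sample.int(H, nc, replace = TRUE)
  G <- pools$haplotypes[i1, gene$snp_cols, drop = FALSE] +
    pools$haplotypes[i2, gene$snp_cols, drop = FALSE]
  M <- pools$methyl[sample.int(nrow(pools$methyl), nc, replace = TRUE),
                    gene$cpg_cols, drop = FALSE]
  E <- pools$expr[sample.int(nrow(pools$expr), nc, replace = TRUE),
                  gene$expr_col, drop = FALSE]
  if (spec$coupling == "GE") {
    E <- E + G[, gene$causal_snps[1]]
  }
  X1 <- stats::rnorm(nc, 20, 1)
  X2 <- stats::rbinom(nc, 1, 0.5)
  list(G = G, M = M, E = E, X1 = X1, X2 = X2)
}

# Linear predictor excluding the intercept.  Causal methylation enters
# centered at its pool mean (the analogue of the expression term's
# centering at the pool's global mean): the CpG-level offsets of M-values
# are bimodal and uncentered contributions would drive the disease
# prevalence outside any samplable range.
linear_signal <- function(d, gene, spec, pools) {
  eta <- 0.001 * d$X1 + 0.001 * d$X2
  if (grepl("G", spec$causal)) {
    eta <- eta + spec$beta_G * rowSums(d$G[, gene$causal_snps, drop = FALSE])
  }
  if (grepl("M", spec$causal)) {
    mu <- pools$methyl_means[gene$cpg_cols[gene$causal_cpgs]]
    Mc <- sweep(d$M[, gene$causal_cpgs, drop = FALSE], 2, mu)
    eta <- eta + spec$beta_M * rowSums(Mc)
  }
  if (grepl("E", spec$causal)) {
    eta <- eta + spec$beta_E * (rowSums(d$E) - pools$expr_mean)
  }
  eta
}

#' Simulate one gene-level dataset from the pools
#'
#' Draws one dataset under a [scenario_spec()]: subjects' genotypes are sums
#' of two haplotypes sampled from the pool, methylation rows and expression
#' values are resampled (with replacement) from their pools, covariates are
#' X1 ~ Normal(20, 1) and X2 ~ Bernoulli(0.5), and the trait follows the
#' scenario's generating model.  Binary traits are produced by sampling
#' subjects until the case and control quotas fill, keeping the first
#' `n_cases` cases and `n_controls` controls in draw order; continuous
#' traits use standard-normal errors.  Causal SNPs are redrawn per dataset
#' among pool sites with minor-allele frequency at least 0.05.
#'
#' @param spec A [scenario_spec()].
#' @param pools A [build_pools()] object.
#' @param seed Optional integer seed.
#' @return List with named phenotype `y`, `covariates` (X1, X2),
#'   `blocks` (list of [omics_block()]: G, M, E), `causal_snps`,
#'   `causal_cpgs`, `family`, `spec`.
#' @export
simulate_gene_dataset <- function(spec, pools, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$n_snps > ncol(pools$haplotypes)) stop("pool has too few SNPs")
  start <- sample.int(ncol(pools$haplotypes) - spec$n_snps + 1L, 1)
  snp_cols <- start:(start + spec$n_snps - 1L)
  nblocks <- ncol(pools$methyl) %/% pools$cpg_block_size
  if (spec$n_cpgs > pools$cpg_block_size) stop("n_cpgs exceeds pool block size")
  bl <- sample.int(nblocks, 1)
  cpg_cols <- ((bl - 1) * pools$cpg_block_size + 1):((bl - 1) * pools$cpg_block_size + spec$n_cpgs)
  expr_col <- sample.int(ncol(pools$expr), spec$n_expr)

  # The first (anchor) causal SNP is a common variant — in the coupled
  # setting it doubles as the gene's eQTL, and eQTLs are typically common —
  # while the remaining causal variants come from the low-frequency band
  # (MAF 2-10%), which keeps gene-level power interior at the fixed
  # per-allele effects under LD.
  maf <- pools$maf[snp_cols]
  common <- which(maf >= 0.2)
  if (length(common) == 0) common <- which.max(maf)
  lowfreq <- setdiff(which(maf >= 0.02 & maf <= 0.10), common)
  if (length(lowfreq) < spec$n_causal_snps - 1) {
    lowfreq <- setdiff(order(abs(maf - 0.06))[seq_len(spec$n_causal_snps)],
                       common)
  }
  causal_snps <- c(common[sample.int(length(common), 1)],
                   lowfreq[sample.int(length(lowfreq),
                                      spec$n_causal_snps - 1)])
  causal_cpgs <- sort(sample.int(spec$n_cpgs, spec$n_causal_cpgs))
  gene <- list(snp_cols = snp_cols, cpg_cols = cpg_cols, expr_col = expr_col,
               causal_snps = causal_snps, causal_cpgs = causal_cpgs)

  if (spec$trait == "binary") {
    keep <- list()
    n_case <- 0L
    n_ctrl <- 0L
    tries <- 0L
    while ((n_case < spec$n_cases || n_ctrl < spec$n_controls) && tries < 200L) {
      tries <- tries + 1L
      d <- draw_subjects(4000L, pools, gene, spec)
      eta <- spec$intercept + linear_signal(d, gene, spec, pools)
      y <- stats::rbinom(length(eta), 1, stats::plogis(eta))
      # keep the first cases/controls in draw order until the quotas fill
      sel <- (y == 1 & n_case + cumsum(y == 1) <= spec$n_cases) |
        (y == 0 & n_ctrl + cumsum(y == 0) <= spec$n_controls)
      n_case <- n_case + sum(y[sel] == 1)
      n_ctrl <- n_ctrl + sum(y[sel] == 0)
      keep[[tries]] <- list(G = d$G[sel, , drop = FALSE], M = d$M[sel, , drop = FALSE],
                            E = d$E[sel, , drop = FALSE], X1 = d$X1[sel],
                            X2 = d$X2[sel], y = y[sel])
    }
    if (n_case < spec$n_cases || n_ctrl < spec$n_controls) {
      stop("case/control quotas infeasible under this configuration ",
           "(prevalence too extreme)")
    }
    G <- do.call(rbind, lapply(keep, `[[`, "G"))
    M <- do.call(rbind, lapply(keep, `[[`, "M"))
    E <- do.call(rbind, lapply(keep, `[[`, "E"))
    X1 <- unlist(lapply(keep, `[[`, "X1"))
    X2 <- unlist(lapply(keep, `[[`, "X2"))
    y <- unlist(lapply(keep, `[[`, "y"))
    family <- "binomial"
  } else {
    d <- draw_subjects(spec$n, pools, gene, spec)
    G <- d$G; M <- d$M; E <- d$E; X1 <- d$X1; X2 <- d$X2
    y <- linear_signal(d, gene, spec, pools) + stats::rnorm(spec$n)
    family <- "gaussian"
  }

  ids <- paste0("S", seq_along(y))
  names(y) <- ids
  rownames(G) <- rownames(M) <- rownames(E) <- ids
  covariates <- cbind(X1 = X1, X2 = X2)
  rownames(covariates) <- ids
  blocks <- list(G = omics_block(G, "G"), M = omics_block(M, "M"),
                 E = omics_block(E, "E"))
  list(y = y, covariates = covariates, blocks = blocks,
       causal_snps = causal_snps, causal_cpgs = causal_cpgs,
       family = family, spec = spec)
}

# One-dataset analysis used by the harnesses: per-layer KM tests plus the
# requested combinations.  All layers share the subjects and the null
# model, so the fast shared-null perturbation path applies.  When both the
# omnibus and the optimal test are requested, one draw set of size
# B_optimal is generated and the covariance for the regular test uses its
# first B_cov iterations.
analyze_dataset <- function(dat, methods = c("omnibus", "fisher"),
                            B_cov = 200, B_optimal = 1000, y = NULL) {
  yy <- if (is.null(y)) dat$y else y
  fit <- fit_null(yy, dat$covariates, family = dat$family,
                  subject_ids = names(dat$y))
  kms <- lapply(dat$blocks, function(b) km_test(fit, b))
  observed <- vapply(kms, function(k) k$p_value, 0)
  out <- c(omnibus = NA_real_, fisher = NA_real_, optimal = NA_real_)
  if ("fisher" %in% methods) {
    out["fisher"] <- usual_fisher_combine(observed)
  }
  draws <- NULL
  if ("optimal" %in% methods) {
    draws <- perturb_layer_pvalues(kms, B_optimal)
    ch <- estimate_cov(draws, observed)
    mp <- combine_all_models(observed, draws, ch)
    out["optimal"] <- optimal_test(mp)$p
  }
  if ("omnibus" %in% methods) {
    dc <- if (!is.null(draws)) draws[seq_len(min(B_cov, nrow(draws))), , drop = FALSE]
          else perturb_layer_pvalues(kms, B_cov)
    ch <- estimate_cov(dc, observed)
    out["omnibus"] <- omnibus_fisher_combine(observed, ch[names(observed), names(observed)])
  }
  out[methods]
}

check_harness_resolution <- function(n_datasets, alpha) {
  if (n_datasets < 100) warning("fewer than 100 datasets; rates are unstable")
  low <- alpha[alpha < 10 / n_datasets]
  if (length(low)) {
    warning("alpha level(s) ", paste(low, collapse = ", "),
            " need more datasets for resolution (have ", n_datasets, ")")
  }
}

#' Empirical Type I error of the combination tests
#'
#' Simulates null datasets by the permutation design: causal datasets are
#' generated under the scenario's generating model, then the traits are
#' permuted `n_perm` times per dataset (breaking all trait-omics
#' association while preserving the omics structure, including any G-E
#' coupling).  Each permuted dataset is analyzed with the requested
#' methods and the empirical rejection rate at each significance level is
#' returned with its binomial standard error.
#'
#' @param scenario A [scenario_spec()]; its `causal` field defines the
#'   generating model whose traits get permuted (`"none"` is promoted to
#'   `"G"`, the permutation base used throughout).
#' @param n_datasets Total null datasets (causal datasets x `n_perm`).
#' @param alpha Significance levels.
#' @param methods Subset of `c("optimal", "omnibus", "fisher")`.
#' @param pools A [build_pools()] object (built from `seed` when `NULL`).
#' @param seed Integer seed; each dataset gets a derived substream.
#' @param B_cov Perturbation count for the covariance estimate.
#' @param B_optimal Perturbation count for the optimal test.
#' @param n_perm Trait permutations per causal dataset (default 10).
#' @return `data.frame` with columns `alpha`, `method`, `rate`, `se`,
#'   `n_datasets`.
#' @export
type1_harness <- function(scenario, n_datasets = 2000,
                          alpha = c(0.05, 0.01, 0.001),
                          methods = c("optimal", "omnibus", "fisher"),
                          pools = NULL, seed = 1, B_cov = 200,
                          B_optimal = 1000, n_perm = 10) {
  methods <- match.arg(methods, c("optimal", "omnibus", "fisher"),
                       several.ok = TRUE)
  check_harness_resolution(n_datasets, alpha)
  if (scenario$causal == "none") {
    scenario <- scenario_spec(scenario$trait, "G", scenario$coupling,
                              n_cases = scenario$n_cases,
                              n_controls = scenario$n_controls, n = scenario$n)
  }
  if (is.null(pools)) pools <- build_pools(seed = derive_seed(seed, "pools"))
  n_causal <- ceiling(n_datasets / n_perm)
  P <- matrix(NA_real_, n_datasets, length(methods),
              dimnames = list(NULL, methods))
  row <- 0L
  for (d in seq_len(n_causal)) {
    set.seed(derive_seed(seed, paste0("dataset", d)))
    dat <- simulate_gene_dataset(scenario, pools)
    for (k in seq_len(n_perm)) {
      if (row >= n_datasets) break
      row <- row + 1L
      yp <- stats::setNames(sample(unname(dat$y)), names(dat$y))
      P[row, ] <- analyze_dataset(dat, methods, B_cov = B_cov,
                                  B_optimal = B_optimal, y = yp)
    }
  }
  rate_table(P, alpha)
}

#' Empirical power of the combination tests
#'
#' As [type1_harness()] but on the causal datasets themselves (no trait
#' permutation): each dataset is generated under the scenario's causal
#' model and analyzed directly.
#'
#' @inheritParams type1_harness
#' @return `data.frame` with columns `alpha`, `method`, `rate`, `se`,
#'   `n_datasets`.
#' @export
power_harness <- function(scenario, n_datasets = 500,
                          alpha = c(0.05, 0.01),
                          methods = c("optimal", "omnibus"),
                          pools = NULL, seed = 1, B_cov = 200,
                          B_optimal = 1000) {
  methods <- match.arg(methods, c("optimal", "omnibus", "fisher"),
                       several.ok = TRUE)
  if (scenario$causal == "none") stop("power harness needs a causal scenario")
  check_harness_resolution(n_datasets, alpha)
  if (is.null(pools)) pools <- build_pools(seed = derive_seed(seed, "pools"))
  P <- matrix(NA_real_, n_datasets, length(methods),
              dimnames = list(NULL, methods))
  for (d in seq_len(n_datasets)) {
    set.seed(derive_seed(seed, paste0("dataset", d)))
    dat <- simulate_gene_dataset(scenario, pools)
    P[d, ] <- analyze_dataset(dat, methods, B_cov = B_cov,
                              B_optimal = B_optimal)
  }
  rate_table(P, alpha)
}

rate_table <- function(P, alpha) {
  n <- nrow(P)
  out <- expand.grid(alpha = alpha, method = colnames(P),
                     stringsAsFactors = FALSE)
  out$rate <- mapply(function(a, m) mean(P[, m] <= a), out$alpha, out$method)
  out$se <- sqrt(out$rate * (1 - out$rate) / n)
  out$n_datasets <- n
  attr(out, "pvalues") <- P
  out
}
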