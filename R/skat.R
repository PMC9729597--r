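#' Genomic relationship (kinship) matrix from common variants
#'
#' Estimates pairwise relatedness as the standardized genomic relationship
#' matrix `K = Z %*% t(Z) / m`, where `Z` holds per-variant standardized
#' dosages `(g - 2p) / sqrt(2 p (1 - p))` and `p` is the within-sample
#' allele frequency. Missing genotypes are mean-imputed per variant before
#' standardization; variants below the frequency cutoff or monomorphic in
#' the sample are excluded.
#'
#' @param geno integer matrix, variants x samples, of allele counts.
#' @param maf_min minimum within-sample minor-allele frequency for a
#'   variant to inform relatedness (default 0.05).
#' @return symmetric samples x samples matrix with the number of variants
#'   used in attribute `"m"`.
#' @export
compute_kinship <- function(geno, maf_min = 0.05) {
  G <- t(geno)                                   # samples x variants
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= maf_min)
  if (!length(keep))
    stop("no polymorphic variant at or above the frequency cutoff")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- 2 * p[j]
  }
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(G), rownames(G))
  attr(K, "m") <- ncol(Z)
  K
}

#' Principal components and broad clusters from common variants
#'
#' Computes the top principal components of the standardized common-variant
#' dosage matrix (monomorphic, "uninformative", sites are excluded) and
#' partitions the samples into broad ancestry clusters by k-means on the PC
#' scores. Both the PC scores and the cluster labels feed the association
#' null model as fixed covariates.
#'
#' @param geno integer matrix, variants x samples.
#' @param k number of components to return (default 3).
#' @param n_clusters number of k-means clusters (default 3).
#' @param seed seed for the k-means initialization.
#' @param maf_min minimum within-sample minor-allele frequency (default
#'   0.05).
#' @return list with `scores` (samples x k), `clusters` (integer labels),
#'   `var_explained`.
#' @export
run_pca <- function(geno, k = 3, n_clusters = 3, seed = 1, maf_min = 0.05) {
  G <- t(geno)
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf > 0 & maf >= maf_min)
  if (!length(keep)) stop("no informative variants for PCA")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- 2 * p[j]
  }
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(scale(Z, center = TRUE, scale = FALSE), nu = min(k, nrow(Z)),
            nv = 0)
  rank <- sum(sv$d > 1e-8 * max(sv$d, 1e-300))
  if (rank < k)
    stop("requested ", k, " components but genotype matrix has rank ", rank)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  km <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    kmeans(scores, centers = n_clusters, nstart = 20)
  })
  list(scores = scores, clusters = km$cluster,
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Fit the mixed-model null for kinship-adjusted score tests
#'
#' Fits the linear mixed model `y = X beta + u + e`, `u ~ (0, sg2 K)`,
#' `e ~ (0, se2 I)`, by restricted maximum likelihood, profiling the
#' variance ratio `lambda = sg2 / se2` on the eigenbasis of `K` (one
#' one-dimensional optimization; the EMMA/EMMAX device). The binary
#' case/control phenotype is handled on the linear scale, which is what an
#' EMMAX-style approximation does. After the fit, phenotype, covariates
#' and later genotypes are decorrelated by `V^(-1/2)` with
#' `V = sg2 K + se2 I`, so downstream score statistics reduce to the
#' ordinary fixed-effects form on transformed data and residuals are
#' exchangeable for permutation.
#'
#' @param y numeric phenotype vector (0/1 for case/control).
#' @param X covariate matrix including the intercept (e.g. intercept,
#'   three PCs, two cluster indicator columns); full column rank required.
#' @param K kinship matrix; made positive semi-definite by adding
#'   `reg_eps * I` when its smallest eigenvalue is below zero.
#' @param reg_eps regularization floor (default `1e-6`).
#' @return object of class `pedseg_null`: list with `lambda`, `sigma_g2`,
#'   `sigma_e2`, `beta`, `residuals` (decorrelated), `s2` (residual
#'   variance of the decorrelated fit), `Vinv_half` (the decorrelating
#'   matrix), `Xstar` (decorrelated covariates), `H` hat matrix pieces,
#'   `degenerate` flag, `n`, `p`.
#' @export
fit_null_emmax <- function(y, X, K, reg_eps = 1e-6) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  if (sd(y) == 0) {
    return(structure(list(lambda = 0, sigma_g2 = 0, sigma_e2 = 0,
                          beta = rep(0, ncol(X)), residuals = rep(0, n),
                          s2 = 0, Vinv_half = diag(n), Xstar = X,
                          degenerate = TRUE, n = n, p = ncol(X)),
                     class = "pedseg_null"))
  }
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  if (min(d) < 0) d <- d + (reg_eps - min(d))
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  p <- ncol(X)

  reml_nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xr, w * Xr)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xr, w * yr)))
    r <- yr - Xr %*% beta
    rss <- sum(w * r^2)
    0.5 * ((n - p) * log(rss) + sum(log(lam * d + 1)) +
             2 * sum(log(diag(ch))))
  }
  opt <- optimize(reml_nll, interval = log(c(1e-6, 1e6)), tol = 1e-8)
  if (!is.finite(opt$objective) || opt$objective >= 1e10)
    stop("REML variance-ratio search failed to converge; bracket [1e-6, 1e6], ",
         "objective at optimum = ", opt$objective)
  lambda <- exp(opt$minimum)
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xr, w * Xr)
  beta <- solve(XtWX, crossprod(Xr, w * yr))
  rr <- yr - Xr %*% beta
  sigma_e2 <- sum(w * rr^2) / (n - p)
  sigma_g2 <- lambda * sigma_e2

  # decorrelate by V^(-1/2), V = sigma_e2 (lambda K + I)
  scale_d <- 1 / sqrt(sigma_e2 * (lambda * d + 1))
  Vinv_half <- U %*% (scale_d * t(U))
  ystar <- drop(Vinv_half %*% y)
  Xstar <- Vinv_half %*% X
  qx <- qr(Xstar)
  resid <- qr.resid(qx, ystar)
  s2 <- sum(resid^2) / (n - p)

  structure(list(lambda = lambda, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 beta = drop(beta), residuals = resid, s2 = s2,
                 Vinv_half = Vinv_half, Xstar = Xstar, qx = qx,
                 degenerate = FALSE, n = n, p = ncol(X)),
            class = "pedseg_null")
}

#' @export
print.pedseg_null <- function(x, ...) {
  cat(sprintf(
    "pedseg mixed-model null: n = %d, lambda = %.4g (sg2 = %.4g, se2 = %.4g)%s\n",
    x$n, x$lambda, x$sigma_g2, x$sigma_e2,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Default SKAT variant weights
#'
#' The Beta(1, 25) density evaluated at the within-sample allele frequency,
#' which up-weights the rarest variants; `"flat"` gives every variant unit
#' weight.
#'
#' @param maf within-sample allele frequencies of the tested variants.
#' @param type `"beta"` (default) or `"flat"`.
#' @return numeric weight vector.
#' @export
skat_weights <- function(maf, type = c("beta", "flat")) {
  type <- match.arg(type)
  if (type == "flat") return(rep(1, length(maf)))
  dbeta(pmin(pmax(maf, 1e-8), 1 - 1e-8), 1, 25)
}

#' Variance-component score (SKAT) test for one variant unit
#'
#' Computes the kernel statistic `Q = r' G W^2 G' r` on decorrelated data,
#' where `r` are the null-model residuals, `G` the decorrelated dosages of
#' the unit's variants and `W = diag(weights)`. The asymptotic null of `Q`
#' is the weighted chi-square sum with weights equal to the eigenvalues of
#' `s2 * W G' P G W` (`P` the residual projection), evaluated with
#' [davies_pvalue()]. The resampling p-value permutes the decorrelated
#' residuals, which are exchangeable under the null, with an adaptive early
#' stop once `min_exceed` exceedances accumulate; the reported p-value uses
#' the resampling estimate in the permutation-accurate range and switches
#' to the asymptotic value below `switch_p`.
#'
#' @param null a `pedseg_null` from [fit_null_emmax()].
#' @param G raw dosage matrix, samples x variants, aligned to the null
#'   model's samples; missing dosages are treated as 0.
#' @param weights per-variant weights (default Beta(1, 25) at the
#'   within-sample frequency; see [skat_weights()]).
#' @param B permutation ceiling (default `1e4`; the resampling estimate is
#'   already stable far earlier for moderate p).
#' @param min_exceed adaptive stop: quit permuting after this many
#'   exceedances (default 200).
#' @param switch_p below this asymptotic p the Davies value is reported
#'   instead of the permutation estimate (default `1e-5`).
#' @param resample compute the permutation p-value (default `TRUE`).
#' @return one-row data.frame: `Q`, `p_asymptotic`, `p_resampling`,
#'   `p_reported`, `n_perm_used`, `davies_method`.
#' @export
skat_test <- function(null, G, weights = NULL, B = 1e4, min_exceed = 200,
                      switch_p = 1e-5, resample = TRUE) {
  G <- as.matrix(G)
  stopifnot(nrow(G) == null$n)
  if (ncol(G) == 0) stop("no variants in unit")
  G[is.na(G)] <- 0
  if (is.null(weights)) weights <- skat_weights(colMeans(G) / 2)
  if (all(G == 0)) {
    return(data.frame(Q = 0, p_asymptotic = 1, p_resampling = 1,
                      p_reported = 1, n_perm_used = 0L,
                      davies_method = "degenerate",
                      stringsAsFactors = FALSE))
  }
  Gs <- null$Vinv_half %*% G
  GW <- sweep(Gs, 2, weights, "*")
  r <- null$residuals
  Q <- sum(drop(crossprod(GW, r))^2)

  # eigenvalues of s2 * W G' P G W, P = I - H (projection off Xstar)
  PGW <- qr.resid(null$qx, GW)
  Kmat <- null$s2 * crossprod(GW, PGW)
  ev <- eigen((Kmat + t(Kmat)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p_asym <- davies_pvalue(Q, ev)

  p_res <- NA_real_
  used <- 0L
  if (resample) {
    exceed <- 0L
    block <- 500L
    n <- length(r)
    while (used < B && exceed < min_exceed) {
      nb <- min(block, B - used)
      Rmat <- vapply(seq_len(nb), function(b) r[sample.int(n)],
                     numeric(n))
      Qb <- colSums(crossprod(GW, Rmat)^2)
      exceed <- exceed + sum(Qb >= Q)
      used <- used + nb
    }
    p_res <- (1 + exceed) / (1 + used)
  }
  p_rep <- if (!is.na(p_res) && p_asym > switch_p) p_res else as.numeric(p_asym)
  data.frame(Q = Q, p_asymptotic = as.numeric(p_asym), p_resampling = p_res,
             p_reported = p_rep, n_perm_used = used,
             davies_method = attr(p_asym, "method"),
             stringsAsFactors = FALSE)
}

#' Gene- and gene-set-level kinship-adjusted association analysis
#'
#' Runs the full cross-pedigree association arm: the phenotype contrasts
#' sequenced cases against unrelated controls (family controls do not enter
#' the phenotype vector); kinship and population structure are absorbed by
#' the EMMAX-style null of [fit_null_emmax()] with covariates intercept,
#' the first three principal components and the broad ancestry clusters
#' (encoded as `n_clusters - 1` indicator columns); each unit (gene, or a
#' gene set pooled into one variant set) is then tested with [skat_test()].
#'
#' @param cohort a `pedseg_cohort`.
#' @param rpd a `pedseg_rpd` object (the tested rare variants).
#' @param common_geno variants x samples dosage matrix of common variants
#'   used for kinship and PCA (e.g. the pre-filter genotypes); column
#'   names must cover the cases and unrelated controls.
#' @param units `"genes"` for per-gene tests, or a named list of
#'   `pedseg_gene_set` objects to test as pooled sets.
#' @param B permutation ceiling per unit (default `1e4`).
#' @param seed seed governing permutations.
#' @param weights_type `"beta"` or `"flat"` (see [skat_weights()]).
#' @param adjust apply the kinship/structure adjustment (default `TRUE`);
#'   with `FALSE` the null model is an unadjusted intercept-only linear
#'   model (useful to demonstrate inflation under family structure).
#' @param n_pcs number of principal components (default 3).
#' @param n_clusters number of ancestry clusters (default 3).
#' @param gene_alpha genome-wide gene-level significance threshold
#'   (default `2.4e-6`, Bonferroni for 20203 protein-coding genes).
#' @param resample compute permutation p-values (default `TRUE`).
#' @return data.frame with one row per unit: `unit`, `variant_count`,
#'   `case_variant_count`, `control_variant_count` (carrier observations
#'   among cases / unrelated controls), `Q`, `p_asymptotic`,
#'   `p_resampling`, `p_reported`, `p_bonferroni`, `significant`; the
#'   fitted null model is attached as attribute `"null_model"`.
#' @export
run_association <- function(cohort, rpd, common_geno, units = "genes",
                            B = 1e4, seed = 1,
                            weights_type = c("beta", "flat"),
                            adjust = TRUE, n_pcs = 3, n_clusters = 3,
                            gene_alpha = 2.4e-6, resample = TRUE) {
  weights_type <- match.arg(weights_type)
  s <- cohort$samples
  ids <- s$sample_id[s$role %in% c("case", "unrelated_control")]
  ids <- intersect(ids, rpd$samples)
  y <- as.numeric(s$affected[match(ids, s$sample_id)])
  n <- length(ids)
  if (n < 4) stop("too few case/unrelated-control samples")

  if (adjust) {
    cg <- common_geno[, ids, drop = FALSE]
    K <- compute_kinship(cg)
    pca <- run_pca(cg, k = n_pcs, n_clusters = n_clusters, seed = seed)
    cl <- factor(pca$clusters)
    Xcl <- if (nlevels(cl) > 1)
      model.matrix(~cl)[, -1, drop = FALSE] else NULL
    X <- cbind(Intercept = 1, pca$scores, Xcl)
  } else {
    K <- diag(n)
    X <- matrix(1, n, 1, dimnames = list(NULL, "Intercept"))
  }
  null <- fit_null_emmax(y, X, K)

  calls <- rpd$calls
  geno <- rpd$geno[, ids, drop = FALSE]
  case_ids <- ids[y == 1]
  ctrl_ids <- ids[y == 0]

  unit_rows <- if (identical(units, "genes")) {
    split(seq_len(nrow(calls)), calls$gene)
  } else {
    lapply(units, function(set) {
      which(toupper(calls$gene) %in% toupper(set$genes))
    })
  }
  if (!identical(units, "genes") && is.null(names(unit_rows)))
    names(unit_rows) <- vapply(units, `[[`, character(1), "name")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  res <- lapply(names(unit_rows), function(u) {
    rows <- unit_rows[[u]]
    # one dosage column per distinct variant site (multi-gene rows collapse)
    vidx <- unique(calls$var_idx[rows])
    if (!length(vidx)) {
      warning("unit ", u, " has no variants; skipped")
      return(NULL)
    }
    G <- t(geno[vidx, , drop = FALSE])
    carr <- !is.na(geno[vidx, , drop = FALSE]) & geno[vidx, , drop = FALSE] >= 1
    st <- skat_test(null, G,
                    weights = skat_weights(colMeans(G, na.rm = TRUE) / 2,
                                           weights_type),
                    B = B, resample = resample)
    cbind(data.frame(unit = u,
                     variant_count = length(vidx),
                     case_variant_count = sum(carr[, case_ids, drop = FALSE]),
                     control_variant_count = sum(carr[, ctrl_ids, drop = FALSE]),
                     stringsAsFactors = FALSE),
          st)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable units")
  n_units <- nrow(out)
  if (identical(units, "genes")) {
    out$p_bonferroni <- pmin(1, 20203 * out$p_reported)
    out$significant <- out$p_reported < gene_alpha
  } else {
    out$p_bonferroni <- pmin(1, n_units * out$p_reported)
    out$significant <- out$p_bonferroni < 0.05
  }
  out <- out[order(out$p_reported, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null_model") <- null
  out
}
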