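# ---- kinship -----------------------------------------------------------

test_that("the genomic relationship matrix recovers expected relatedness", {
  set.seed(81)
  m <- 2000
  f <- runif(m, 0.1, 0.5)
  # 30 unrelated pairs + 20 parent-offspring pairs via direct transmission
  n_unrel <- 60
  G_unrel <- matrix(rbinom(m * n_unrel, 2, f), m)
  parents <- matrix(rbinom(m * 20, 2, f), m)
  mates <- matrix(rbinom(m * 20, 2, f), m)
  kids <- matrix(rbinom(m * 20, 1, parents / 2) + rbinom(m * 20, 1, mates / 2), m)
  geno <- cbind(G_unrel, parents, kids)
  colnames(geno) <- c(sprintf("U%02d", 1:n_unrel), sprintf("P%02d", 1:20),
                      sprintf("K%02d", 1:20))
  K <- compute_kinship(geno)
  expect_true(isSymmetric(K))
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  po <- vapply(1:20, function(i) K[sprintf("P%02d", i), sprintf("K%02d", i)],
               numeric(1))
  expect_equal(mean(po), 0.5, tolerance = 0.08)
  off <- K[1:n_unrel, 1:n_unrel][upper.tri(diag(n_unrel))]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)) + 0.01)

  # duplicated sample: relatedness ~ its own diagonal
  dup <- cbind(geno, DUP = geno[, 1])
  Kd <- compute_kinship(dup)
  expect_equal(Kd["U01", "DUP"], Kd["U01", "U01"], tolerance = 1e-8)

  mono <- matrix(0L, 10, 4)
  expect_error(compute_kinship(mono), "polymorphic")
})

# ---- PCA / clustering ---------------------------------------------------

test_that("principal components separate divergent populations and recover clusters", {
  set.seed(99)
  m <- 800; n_per <- 30
  f_base <- runif(m, 0.1, 0.9)
  geno <- do.call(cbind, lapply(1:3, function(pop) {
    fp <- rbeta(m, f_base * 19, (1 - f_base) * 19)   # Fst = 0.05 drift
    matrix(rbinom(m * n_per, 2, fp), m)
  }))
  colnames(geno) <- sprintf("S%03d", seq_len(3 * n_per))
  pca <- run_pca(geno, k = 3, n_clusters = 3, seed = 5)
  truth <- rep(1:3, each = n_per)
  # cluster labels match planted membership up to relabeling
  tab <- table(pca$clusters, truth)
  expect_equal(sum(apply(tab, 2, max)), 3 * n_per)
  # PC1-2 distances: within-population spread < between-population spread
  centroid <- apply(pca$scores[, 1:2], 2, function(x) tapply(x, truth, mean))
  within <- mean(sqrt(rowSums((pca$scores[, 1:2] - centroid[truth, ])^2)))
  between <- mean(dist(centroid))
  expect_gt(between / within, 2)

  flat <- matrix(1L, 50, 10)
  expect_error(run_pca(flat, k = 3), "informative|rank")
})

# ---- mixed-model null ---------------------------------------------------

test_that("with identity kinship the null model reduces to ordinary least squares", {
  set.seed(3)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.4)
  null <- fit_null_emmax(y, X, diag(n))
  ols <- residuals(lm(y ~ X - 1))
  # decorrelated residuals are the OLS residuals up to a scalar
  ratio <- null$residuals / ols
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-6)

  const <- fit_null_emmax(rep(1, n), X, diag(n))
  expect_true(const$degenerate)
  expect_equal(const$residuals, rep(0, n))
})

test_that("REML recovers a planted variance ratio on block-family kinship", {
  set.seed(17)
  n_fam <- 60; fam_size <- 5; n <- n_fam * fam_size
  block <- matrix(0.5, fam_size, fam_size); diag(block) <- 1
  K <- as.matrix(Matrix::bdiag(replicate(n_fam, block, simplify = FALSE)))
  ch <- chol(K)
  est <- replicate(10, {
    u <- drop(crossprod(ch, rnorm(n)))       # var 1 * K
    y <- u + rnorm(n)                        # sigma_g2 = sigma_e2 = 1
    fit_null_emmax(y, matrix(1, n, 1), K)$lambda
  })
  expect_lt(abs(median(est) - 1), 0.3)
})

# ---- SKAT statistic -----------------------------------------------------

test_that("single-variant units reduce to the chi-square score test", {
  set.seed(21)
  n <- 100
  y <- rbinom(n, 1, 0.3)
  X <- matrix(1, n, 1)
  null <- fit_null_emmax(y, X, diag(n))
  g <- rbinom(n, 2, 0.05)
  res <- skat_test(null, matrix(g, ncol = 1), weights = 1, resample = FALSE)
  # independent score-test computation
  gs <- drop(null$Vinv_half %*% g)
  r <- null$residuals
  U <- sum(gs * r)
  Pg <- qr.resid(null$qx, gs)
  p_score <- pchisq(U^2 / (null$s2 * sum(gs * Pg)), 1, lower.tail = FALSE)
  expect_equal(res$Q, U^2, tolerance = 1e-10)
  expect_equal(res$p_asymptotic, p_score, tolerance = 1e-6)
})

test_that("the kernel statistic matches an independent dense-matrix computation", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(30:50, 1); m <- sample(2:5, 1)
    y <- rbinom(n, 1, 0.4)
    if (sd(y) == 0) y[1] <- 1 - y[1]
    X <- matrix(1, n, 1)
    G <- matrix(rbinom(n * m, 2, runif(m, 0.02, 0.2)), n, byrow = TRUE)
    w <- runif(m, 0.5, 2)
    null <- fit_null_emmax(y, X, diag(n))
    res <- skat_test(null, G, weights = w, resample = FALSE)

    # oracle: raw-scale weighted kernel on OLS residuals, dense projection
    fit <- lm(y ~ 1)
    r0 <- residuals(fit)
    s2 <- sum(r0^2) / (n - 1)
    A <- G %*% diag(w^2, m) %*% t(G)
    Q0 <- drop(r0 %*% A %*% r0)
    P <- diag(n) - matrix(1 / n, n, n)
    ev <- eigen(s2 * P %*% A %*% P, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-10 * max(ev)]
    p0 <- as.numeric(davies_pvalue(Q0, ev))
    # identity kinship: decorrelation is the scalar 1 / sqrt(sg2 + se2),
    # so Q scales by the squared total variance; p is scale-invariant
    s_tot <- null$sigma_g2 + null$sigma_e2
    expect_equal(res$Q * s_tot^2, Q0, tolerance = 1e-6)
    expect_equal(res$p_asymptotic, p0, tolerance = 1e-4)
  }
})

test_that("degenerate units and determinism behave as promised", {
  set.seed(8)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  null <- fit_null_emmax(y, matrix(1, n, 1), diag(n))
  zero <- skat_test(null, matrix(0L, n, 3))
  expect_equal(zero$Q, 0)
  expect_equal(zero$p_reported, 1)

  G <- matrix(rbinom(n * 4, 1, 0.1), n)
  run1 <- local({ set.seed(42); skat_test(null, G, B = 2000) })
  run2 <- local({ set.seed(42); skat_test(null, G, B = 2000) })
  expect_equal(run1$p_resampling, run2$p_resampling)
  # column order cannot matter
  run3 <- local({ set.seed(42); skat_test(null, G[, 4:1], B = 2000) })
  expect_equal(run1$Q, run3$Q, tolerance = 1e-10)
  expect_equal(run1$p_resampling, run3$p_resampling)
})

# ---- end-to-end association --------------------------------------------

make_assoc_cohort <- function(n_case = 50, n_ctrl = 50) {
  cases <- data.frame(
    sample_id = sprintf("CA%03d", seq_len(n_case)),
    family_id = sprintf("F%03d", seq_len(n_case)),
    father_id = NA_character_, mother_id = NA_character_, sex = 1L,
    affected = TRUE, role = "case", stringsAsFactors = FALSE)
  ctrls <- data.frame(
    sample_id = sprintf("UC%03d", seq_len(n_ctrl)), family_id = "",
    father_id = NA_character_, mother_id = NA_character_, sex = 1L,
    affected = FALSE, role = "unrelated_control", stringsAsFactors = FALSE)
  new_cohort(rbind(cases, ctrls))
}

test_that("a planted high-burden gene attains the smallest association p-value", {
  set.seed(55)
  co <- make_assoc_cohort()
  samples <- co$samples$sample_id
  n <- length(samples)
  n_gene <- 25; per_gene <- 3
  rows <- list(); geno <- NULL
  pos <- 0L
  for (g in seq_len(n_gene)) {
    for (v in seq_len(per_gene)) {
      pos <- pos + 50L
      rows[[length(rows) + 1]] <- make_variant_row(
        pos = pos, gene = sprintf("G%02d", g), consequence = "stopgain")
      carrier_p <- if (g == 1) c(rep(0.35, 50), rep(0.02, 50))
                   else rep(0.04, n)
      geno <- rbind(geno, rbinom(n, 1, carrier_p))
    }
  }
  colnames(geno) <- samples
  # common variants for kinship/PCA
  common <- matrix(rbinom(500 * n, 2, 0.3), 500, dimnames = list(NULL, samples))
  vs <- make_variant_set(rows, geno, samples)
  rpd <- filter_rpd(vs)
  res <- run_association(co, rpd, common_geno = common, units = "genes",
                         B = 500, seed = 9)
  expect_equal(res$unit[1], "G01")
  expect_lt(res$p_reported[1], 0.01)
  expect_gt(res$case_variant_count[1], res$control_variant_count[1])
  # switching rule: resampling p reported in the permutation-accurate range
  mid <- res[res$p_asymptotic > 1e-5 & !is.na(res$p_resampling), ]
  expect_equal(mid$p_reported, mid$p_resampling)
})

test_that("gene-set association pools variants and applies the two-set correction", {
  set.seed(77)
  co <- make_assoc_cohort(30, 30)
  samples <- co$samples$sample_id
  rows <- lapply(1:12, function(i) make_variant_row(
    pos = i * 100L, gene = sprintf("G%02d", i), consequence = "stopgain"))
  geno <- matrix(rbinom(12 * 60, 1, 0.08), 12, dimnames = list(NULL, samples))
  common <- matrix(rbinom(400 * 60, 2, 0.3), 400,
                   dimnames = list(NULL, samples))
  vs <- make_variant_set(rows, geno, samples)
  rpd <- filter_rpd(vs)
  sets <- list(gene_set(sprintf("G%02d", 1:6), "setA", 12),
               gene_set(sprintf("G%02d", 7:12), "setB", 12))
  res <- run_association(co, rpd, common_geno = common, units = sets,
                         B = 2000, seed = 4)
  expect_setequal(res$unit, c("setA", "setB"))
  expect_equal(res$variant_count, c(6L, 6L))
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p_reported))
  # determinism under the seed
  res2 <- run_association(co, rpd, common_geno = common, units = sets,
                          B = 2000, seed = 4)
  expect_equal(res$p_resampling, res2$p_resampling)
})
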