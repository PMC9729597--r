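#' Two-sided Fisher exact p by hypergeometric summation
#'
#' Conditions on both margins of the 2x2 table and sums the hypergeometric
#' probabilities of every table as or less probable than the observed one
#' (the minimum-likelihood rule used by standard exact-test software). A
#' small relative slack guards against ties lost to floating point.
#'
#' @param a,b,c,d the 2x2 cell counts.
#' @return two-sided p-value.
#' @keywords internal
.fisher_p_twosided <- function(a, b, c, d) {
  m1 <- a + b          # size of the first row (e.g. prioritized list)
  k <- a + c           # size of the first column (e.g. gene set)
  n <- a + b + c + d
  lo <- max(0L, k - (n - m1))
  hi <- min(k, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, n - m1, k)
  p_obs <- dhyper(a, m1, n - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Gene-set overrepresentation by Fisher's exact test
#'
#' Tests whether a prioritized gene list is enriched for members of a gene
#' set within a universe of protein-coding genes. The 2x2 table is
#' `a` = prioritized genes in the set, `b` = prioritized genes outside it,
#' `c` = remaining set members, `d` = the rest of the universe. The
#' reported odds ratio is the unconditional sample odds ratio
#' `(a*d)/(b*c)` with a Wald 95% confidence interval on the log scale; the
#' conditional maximum-likelihood odds ratio and exact interval (as
#' computed by [stats::fisher.test()]) are available with
#' `or_method = "cmle"`. The p-value is always the exact two-sided
#' hypergeometric probability.
#'
#' @param hits number of prioritized genes belonging to the set (`a`).
#' @param list_size number of prioritized genes.
#' @param set_size number of genes in the set.
#' @param universe_size number of genes in the universe (default 20203).
#' @param gene_set_name label carried into the result.
#' @param or_method `"sample"` (default) or `"cmle"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `pedseg_enrichment`: a one-row data.frame with
#'   `gene_set_name`, the counts `a, b, c, d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_two_sided`, and `ci_defined` (FALSE when a zero cell
#'   makes the Wald interval undefined).
#' @export
fisher_overrepresentation <- function(hits, list_size, set_size,
                                      universe_size = 20203L,
                                      gene_set_name = "gene_set",
                                      or_method = c("sample", "cmle"),
                                      conf_level = 0.95) {
  or_method <- match.arg(or_method)
  a <- as.integer(hits)
  b <- as.integer(list_size) - a
  cc <- as.integer(set_size) - a
  d <- as.integer(universe_size) - as.integer(list_size) - cc
  if (any(c(a, b, cc, d) < 0))
    stop("inconsistent counts: require hits <= list_size, hits <= set_size, ",
         "list_size + set_size - hits <= universe_size")
  p <- .fisher_p_twosided(a, b, cc, d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (or_method == "sample") {
    if (b * cc == 0) {
      or <- if (a * d == 0) NaN else Inf
      ci <- c(NA_real_, NA_real_)
      ci_defined <- FALSE
    } else {
      or <- (a * d) / (b * cc)
      ci_defined <- all(c(a, b, cc, d) > 0)
      se <- if (ci_defined) sqrt(1 / a + 1 / b + 1 / cc + 1 / d) else NA_real_
      ci <- exp(log(or) + c(-1, 1) * z * se)
    }
  } else {
    ft <- fisher.test(matrix(c(a, cc, b, d), 2), conf.level = conf_level)
    or <- unname(ft$estimate)
    ci <- ft$conf.int
    ci_defined <- TRUE
  }
  out <- data.frame(gene_set_name = gene_set_name,
                    a = a, b = b, c = cc, d = d,
                    odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                    p_two_sided = p, ci_defined = ci_defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("pedseg_enrichment", "data.frame")
  out
}

#' Overrepresentation of a prioritized gene list in a named gene set
#'
#' Convenience wrapper computing the overlap (case-insensitive, trimmed
#' symbols) before calling [fisher_overrepresentation()].
#'
#' @param prioritized_genes character vector of prioritized gene symbols.
#' @param set a `pedseg_gene_set` from [gene_set()] / [read_gene_list()].
#' @param universe_size overrides the set's universe size when given.
#' @inheritParams fisher_overrepresentation
#' @return see [fisher_overrepresentation()].
#' @export
enrich_gene_list <- function(prioritized_genes, set, universe_size = NULL,
                             or_method = c("sample", "cmle")) {
  norm <- function(x) toupper(trimws(x))
  pg <- unique(norm(prioritized_genes))
  sg <- unique(norm(set$genes))
  fisher_overrepresentation(
    hits = sum(pg %in% sg),
    list_size = length(pg),
    set_size = length(sg),
    universe_size = universe_size %||% set$universe_size,
    gene_set_name = set$name,
    or_method = match.arg(or_method))
}

#' Specificity scan over several gene sets with Bonferroni correction
#'
#' Runs [enrich_gene_list()] against each provided gene set and corrects
#' the exact p-values for the number of sets tested
#' (`p_corrected = min(1, m * p)`). A set is flagged significant when its
#' corrected p is below `alpha`, i.e. the raw p is below `alpha / m`. When
#' a universe gene list is supplied, set members outside it are dropped
#' with a warning before testing.
#'
#' @param prioritized_genes character vector of prioritized gene symbols.
#' @param gene_sets list of `pedseg_gene_set` objects.
#' @param universe_size universe size shared across sets (defaults to each
#'   set's own).
#' @param universe_genes optional character vector enumerating the
#'   universe, used only to validate set membership.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per set: the
#'   [fisher_overrepresentation()] columns plus `p_corrected` and
#'   `significant`.
#' @export
specificity_scan <- function(prioritized_genes, gene_sets,
                             universe_size = NULL, universe_genes = NULL,
                             alpha = 0.05) {
  if (!length(gene_sets)) stop("at least one gene set is required")
  m <- length(gene_sets)
  rows <- lapply(gene_sets, function(set) {
    if (!is.null(universe_genes)) {
      outside <- setdiff(toupper(trimws(set$genes)),
                         toupper(trimws(universe_genes)))
      if (length(outside)) {
        warning(sprintf("%d gene(s) of set '%s' outside the universe; dropped",
                        length(outside), set$name))
        set$genes <- set$genes[!(toupper(trimws(set$genes)) %in% outside)]
      }
    }
    enrich_gene_list(prioritized_genes, set, universe_size = universe_size)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, m * out$p_two_sided)
  out$significant <- out$p_corrected < alpha
  rownames(out) <- NULL
  out
}

#' Compare two odds ratios on the log scale
#'
#' Recovers the standard error of each log odds ratio from its Wald
#' confidence interval, `se = (log(ci_high) - log(ci_low)) / (2 * z)`, and
#' tests the difference with a one-tailed normal test of
#' `log(OR1) > log(OR2)`.
#'
#' @param result_1,result_2 one-row results from
#'   [fisher_overrepresentation()] (or any list with `odds_ratio`,
#'   `ci_low`, `ci_high`).
#' @param conf_level level at which the intervals were built (default
#'   0.95).
#' @return data.frame with `log_or_1`, `log_or_2`, `se_1`, `se_2`, `z`,
#'   `p_one_tailed`.
#' @export
compare_log_or <- function(result_1, result_2, conf_level = 0.95) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  get <- function(r) {
    vals <- c(r$odds_ratio, r$ci_low, r$ci_high)
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("odds ratio and confidence bounds must be finite and positive")
    list(log_or = log(r$odds_ratio),
         se = (log(r$ci_high) - log(r$ci_low)) / (2 * zq))
  }
  r1 <- get(result_1); r2 <- get(result_2)
  z <- (r1$log_or - r2$log_or) / sqrt(r1$se^2 + r2$se^2)
  data.frame(log_or_1 = r1$log_or, log_or_2 = r2$log_or,
             se_1 = r1$se, se_2 = r2$se, z = z,
             p_one_tailed = pnorm(-z))
}

#' Welch's unequal-variance t-test
#'
#' Compares gene-level scores (constraint, conservation, expression)
#' between a prioritized list and a background list without assuming equal
#' variances (Satterthwaite degrees of freedom).
#'
#' @param group_1_values,group_2_values numeric vectors; non-finite values
#'   are dropped, at least two finite values per group are required.
#' @return data.frame with `t`, `df`, `p_two_sided`, `mean_1`, `mean_2`.
#' @export
welch_t <- function(group_1_values, group_2_values) {
  g1 <- group_1_values[is.finite(group_1_values)]
  g2 <- group_2_values[is.finite(group_2_values)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least two finite values")
  if (var(g1) == 0 && var(g2) == 0)
    stop("both groups have zero variance")
  tt <- t.test(g1, g2, var.equal = FALSE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p_two_sided = tt$p.value,
             mean_1 = mean(g1), mean_2 = mean(g2))
}

#' Welch's t statistic from summary statistics
#'
#' Computes the Welch statistic from group means, standard deviations and
#' sizes — useful when only published summaries are available.
#'
#' @param mean_1,sd_1,n_1 summary of group 1.
#' @param mean_2,sd_2,n_2 summary of group 2.
#' @return data.frame with `t`, `df`, `p_two_sided`.
#' @export
welch_t_summary <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2) {
  v1 <- sd_1^2 / n_1
  v2 <- sd_2^2 / n_2
  t <- (mean_1 - mean_2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n_1 - 1) + v2^2 / (n_2 - 1))
  data.frame(t = t, df = df, p_two_sided = 2 * pt(-abs(t), df))
}
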