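.ptv_classes <- c("stopgain", "stoploss", "startloss", "canonical_splice",
                  "frameshift_indel")

#' Protein-truncating variant classification
#'
#' A variant is protein-truncating when its consequence is stop-gain,
#' stop-loss, start-loss, canonical splice site (the two intronic bases
#' flanking each exon, taken from the consequence annotation) or an
#' out-of-frame indel. In-frame indels, missense and synonymous changes are
#' not truncating.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
classify_ptv <- function(consequence) {
  consequence %in% .ptv_classes
}

#' Deleteriousness consensus over the five predictors
#'
#' Counts deleterious (`"D"`) calls among the five predictor slots (SIFT,
#' LRT, MutationTaster, MutationAssessor, MetaSVM). Under the default
#' `"strict"` rule a missing call can never contribute, so a variant with
#' two or more missing predictions cannot reach the 4-of-5 consensus; under
#' `"lenient"` the threshold applies to the predictors with available calls
#' (>= 4 deleterious of those available; with fewer than four calls, every
#' available call must be deleterious).
#'
#' @param calls character matrix (rows = variants, 5 columns) or length-5
#'   vector of `"D"`, `"T"`, `NA`.
#' @param min_votes consensus threshold (default 4).
#' @param rule `"strict"` (missing counts against) or `"lenient"`.
#' @return data.frame with `votes`, `available`, `passes`.
#' @export
deleterious_consensus <- function(calls, min_votes = 4, rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != 5) stop("exactly 5 predictor slots are required")
  votes <- rowSums(calls == "D", na.rm = TRUE)
  available <- rowSums(!is.na(calls))
  passes <- if (rule == "strict") votes >= min_votes
            else available > 0 & votes >= pmin(min_votes, available)
  data.frame(votes = as.integer(votes), available = as.integer(available),
             passes = passes)
}

#' Rarity filter against two reference panels
#'
#' A variant passes when its allele frequency is at or below `threshold` in
#' both the South Asian and the global gnomAD panels. A missing frequency
#' means the variant was not observed in that panel and is treated as zero
#' (rare); set `missing_is_rare = FALSE` to require observed frequencies.
#'
#' @param maf_sas,maf_global numeric vectors of panel allele frequencies
#'   (`NA` = absent from panel).
#' @param threshold frequency cutoff, e.g. `1e-3` (broad) or `1e-4`
#'   (stringent).
#' @param missing_is_rare treat `NA` as 0 (default `TRUE`).
#' @return logical vector.
#' @export
passes_rarity <- function(maf_sas, maf_global, threshold,
                          missing_is_rare = TRUE) {
  if (threshold < 0) stop("threshold must be non-negative")
  ok <- function(x) if (missing_is_rare) is.na(x) | x <= threshold
                    else !is.na(x) & x <= threshold
  ok(maf_sas) & ok(maf_global)
}

#' Classify rare predicted-deleterious (RPD) variants
#'
#' Applies the two-part RPD definition: rarity (allele frequency <= 1e-3 in
#' both gnomAD panels, absence counting as rare) and predicted
#' deleteriousness (protein-truncating, or missense with a >= 4-of-5
#' deleterious predictor consensus). Variants annotated to several genes
#' (symbols separated by `;` or `,`) are expanded to one call per gene so
#' that gene-level analyses see per-gene rows.
#'
#' @param vs a `pedseg_variants` object.
#' @param maf_broad broad rarity threshold (default `1e-3`).
#' @param maf_stringent stringent rarity threshold (default `1e-4`),
#'   recorded per call for the downstream shared-stringent tier.
#' @param consensus_rule `"strict"` or `"lenient"`, see
#'   [deleterious_consensus()].
#' @param keep_all keep non-RPD rows too (default `FALSE`: only
#'   `is_rpd == TRUE` rows are returned).
#' @return object of class `pedseg_rpd`: list with `calls` (one row per
#'   variant x gene, columns `var_idx`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `is_ptv`, `deleterious_votes`,
#'   `votes_available`, `passes_rarity_broad`, `passes_rarity_stringent`,
#'   `is_rpd`), plus the genotype matrix and sample ids carried over from
#'   `vs` (`geno` rows follow `calls$var_idx`).
#' @export
filter_rpd <- function(vs, maf_broad = 1e-3, maf_stringent = 1e-4,
                       consensus_rule = c("strict", "lenient"),
                       keep_all = FALSE) {
  consensus_rule <- match.arg(consensus_rule)
  v <- vs$variants
  cons <- deleterious_consensus(as.matrix(v[, .predictor_cols]),
                                rule = consensus_rule)
  broad <- passes_rarity(v$maf_sas, v$maf_global, maf_broad)
  stringent <- passes_rarity(v$maf_sas, v$maf_global, maf_stringent)
  ptv <- classify_ptv(v$consequence)
  is_rpd <- broad & (ptv | (v$consequence == "missense" & cons$passes))

  calls <- data.frame(
    var_idx = seq_len(nrow(v)),
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = v$gene, consequence = v$consequence,
    is_ptv = ptv,
    deleterious_votes = cons$votes,
    votes_available = cons$available,
    maf_sas = v$maf_sas, maf_global = v$maf_global,
    passes_rarity_broad = broad,
    passes_rarity_stringent = stringent,
    is_rpd = is_rpd,
    stringsAsFactors = FALSE
  )
  # expand multi-gene annotations to one row per gene
  gene_lists <- strsplit(calls$gene, "[;,]")
  gene_lists[lengths(gene_lists) == 0] <- list(NA_character_)
  rep_idx <- rep(seq_len(nrow(calls)), lengths(gene_lists))
  calls <- calls[rep_idx, , drop = FALSE]
  calls$gene <- trimws(unlist(gene_lists))
  rownames(calls) <- NULL
  if (!keep_all) calls <- calls[calls$is_rpd, , drop = FALSE]
  # deterministic order irrespective of input ordering
  ord <- order(calls$chrom, calls$pos, calls$alt, calls$gene)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, geno = vs$geno, samples = vs$samples),
            class = "pedseg_rpd")
}

#' @export
print.pedseg_rpd <- function(x, ...) {
  cat(sprintf("pedseg RPD calls: %d variant-gene rows (%d RPD) across %d samples\n",
              nrow(x$calls), sum(x$calls$is_rpd), length(x$samples)))
  invisible(x)
}
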