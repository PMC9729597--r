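# Shared fixture builders and independent oracles.

# A two-family cohort plus unrelated controls, built directly.
make_test_cohort <- function(n_uc = 3) {
  fam <- function(f, n_cases, n_ctrl) {
    ids <- sprintf("%s_S%d", f, seq_len(n_cases + n_ctrl))
    data.frame(sample_id = ids, family_id = f,
               father_id = NA_character_, mother_id = NA_character_,
               sex = 1L,
               affected = c(rep(TRUE, n_cases), rep(FALSE, n_ctrl)),
               role = c(rep("case", n_cases), rep("family_control", n_ctrl)),
               stringsAsFactors = FALSE)
  }
  uc <- data.frame(sample_id = sprintf("UC%d", seq_len(n_uc)),
                   family_id = "", father_id = NA_character_,
                   mother_id = NA_character_, sex = 2L, affected = FALSE,
                   role = "unrelated_control", stringsAsFactors = FALSE)
  new_cohort(rbind(fam("FA", 3, 1), fam("FB", 3, 2), uc))
}

# A variant table row with sensible defaults, overridable per field.
make_variant_row <- function(chrom = "1", pos = 1000L, ref = "A", alt = "T",
                             gene = "GENE1", consequence = "missense",
                             maf_sas = NA_real_, maf_global = NA_real_,
                             preds = rep("D", 5)) {
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = gene, consequence = consequence,
                    maf_sas = maf_sas, maf_global = maf_global,
                    stringsAsFactors = FALSE)
  pc <- c("pred_sift", "pred_lrt", "pred_mutationtaster",
          "pred_mutationassessor", "pred_metasvm")
  for (i in 1:5) out[[pc[i]]] <- preds[i]
  out
}

make_variant_set <- function(rows, geno, samples) {
  new_variant_set(do.call(rbind, rows), geno, samples)
}

# Exhaustive two-sided Fisher p by direct enumeration with choose();
# independent of the package's dhyper-based summation.
fisher_p_bruteforce <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; n <- a + b + c + d
  lo <- max(0, k - (n - m1)); hi <- min(k, m1)
  tab_prob <- function(x)
    exp(lchoose(m1, x) + lchoose(n - m1, k - x) - lchoose(n, k))
  p_obs <- tab_prob(a)
  total <- 0
  for (x in lo:hi) {
    px <- tab_prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  total
}

# Expected count of variants with >= k carriers among n samples at
# per-sample carrier probability p (binomial tail), for the segregation
# specificity oracle.
binom_tail_expected <- function(n_variants, n_samples, p, k) {
  n_variants * pbinom(k - 1, n_samples, p, lower.tail = FALSE)
}

minimal_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
           '##INFO=<ID=CSQ,Number=1,Type=String,Description="c">',
           '##INFO=<ID=MAF_SAS,Number=1,Type=Float,Description="f">',
           '##INFO=<ID=MAF_GLOBAL,Number=1,Type=Float,Description="f">',
           '##INFO=<ID=SIFT,Number=1,Type=String,Description="p">',
           '##INFO=<ID=LRT,Number=1,Type=String,Description="p">',
           '##INFO=<ID=MUTTASTER,Number=1,Type=String,Description="p">',
           '##INFO=<ID=MUTASSESSOR,Number=1,Type=String,Description="p">',
           '##INFO=<ID=METASVM,Number=1,Type=String,Description="p">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
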