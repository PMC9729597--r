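# Build an RPD object directly: one genotype row per variant, all rows RPD.
make_rpd <- function(rows, geno, samples) {
  vs <- make_variant_set(rows, geno, samples)
  filter_rpd(vs)
}

test_that("carrier counting ignores zygosity and missing genotypes", {
  g <- c(A = 1L, B = 2L, C = 0L, D = NA)
  expect_equal(count_carriers(g, c("A", "B", "C")), 2)
  expect_equal(count_carriers(g, c("C", "D")), 0)
  expect_equal(count_carriers(setNames(rep(NA_integer_, 3), c("A", "B", "C")),
                              c("A", "B", "C")), 0)
  expect_error(count_carriers(g, "ZZZ"), "unknown sample")
})

test_that("multiplex family selection respects the case threshold", {
  co <- make_test_cohort()        # FA: 3 cases, FB: 3 cases
  expect_setequal(select_multisample_families(co), c("FA", "FB"))
  expect_setequal(select_multisample_families(co, min_cases = 1), c("FA", "FB"))
  expect_length(select_multisample_families(co, min_cases = 4), 0)
  empty <- new_cohort(data.frame(
    sample_id = "U", family_id = "", father_id = NA, mother_id = NA,
    sex = 1L, affected = FALSE, role = "unrelated_control",
    stringsAsFactors = FALSE))
  expect_length(select_multisample_families(empty), 0)
})

test_that("shared-broad detection requires >=3 affected carriers and control absence", {
  co <- make_test_cohort()
  samples <- co$samples$sample_id
  g <- function(carriers) {
    out <- setNames(rep(0L, length(samples)), samples)
    out[carriers] <- 1L
    matrix(out, nrow = 1, dimnames = list(NULL, samples))
  }
  rows <- list(
    make_variant_row(pos = 100L, gene = "SHARED", consequence = "stopgain"),
    make_variant_row(pos = 200L, gene = "TWOONLY", consequence = "stopgain"),
    make_variant_row(pos = 300L, gene = "INCTRL", consequence = "stopgain"),
    make_variant_row(pos = 400L, gene = "BOTHFAM", consequence = "stopgain"))
  geno <- rbind(g(c("FA_S1", "FA_S2", "FA_S3")),
                g(c("FA_S1", "FA_S2")),
                g(c("FA_S1", "FA_S2", "FA_S3", "UC1")),
                g(c("FA_S1", "FA_S2", "FA_S3", "FB_S1", "FB_S2", "FB_S3")))
  rpd <- make_rpd(rows, geno, samples)
  res <- find_shared_broad(rpd, co)
  expect_setequal(res$gene[res$family_id == "FA"], c("SHARED", "BOTHFAM"))
  expect_false("TWOONLY" %in% res$gene)           # only 2 carriers
  expect_false("INCTRL" %in% res$gene)            # present in an unrelated control
  # a variant segregating in two families yields one row per family
  expect_equal(sort(res$family_id[res$gene == "BOTHFAM"]), c("FA", "FB"))
  expect_equal(res$affected_carriers[res$gene == "SHARED"], 3L)
  expect_true(all(res$tier == "shared_broad"))
})

test_that("stringent upgrade needs stringent rarity and at most one family-control carrier", {
  co <- make_test_cohort()
  samples <- co$samples$sample_id
  mk_geno <- function(extra) {
    out <- setNames(rep(0L, length(samples)), samples)
    out[c("FA_S1", "FA_S2", "FA_S3", extra)] <- 1L
    matrix(out, nrow = 1, dimnames = list(NULL, samples))
  }
  rows <- list(
    make_variant_row(pos = 100L, gene = "TOOCOMMON", consequence = "stopgain",
                     maf_sas = 5e-4, maf_global = 5e-4),
    make_variant_row(pos = 200L, gene = "ONEFC", consequence = "stopgain"),
    make_variant_row(pos = 300L, gene = "TWOFC", consequence = "stopgain"))
  geno <- rbind(mk_geno(character(0)),
                mk_geno("FA_S4"),                     # one family control
                mk_geno(c("FA_S4", "FB_S4")))         # two family controls
  rpd <- make_rpd(rows, geno, samples)
  broad <- find_shared_broad(rpd, co)
  expect_setequal(broad$gene, c("TOOCOMMON", "ONEFC", "TWOFC"))
  strict <- find_shared_stringent(broad, rpd, co)
  expect_setequal(strict$gene, "ONEFC")
  expect_true(all(strict$tier == "shared_stringent"))
  # per-family counting matches here (controls in different families)
  strict_pf <- find_shared_stringent(broad, rpd, co, per_family = TRUE)
  expect_true(all(c("ONEFC", "TWOFC") %in% strict_pf$gene))
})

test_that("cross-family overlap reports gene- and variant-level recurrences", {
  fam <- function(f, n_cases) data.frame(
    sample_id = sprintf("%s_S%d", f, seq_len(n_cases)), family_id = f,
    father_id = NA_character_, mother_id = NA_character_, sex = 1L,
    affected = TRUE, role = "case", stringsAsFactors = FALSE)
  co <- new_cohort(rbind(fam("BIG", 3), fam("SMALL", 2)))
  samples <- co$samples$sample_id
  rows <- list(
    make_variant_row(pos = 100L, gene = "GSHARED", consequence = "stopgain"),
    make_variant_row(pos = 150L, gene = "GSHARED", consequence = "stopgain"),
    make_variant_row(pos = 500L, gene = "GVAR", consequence = "stopgain"))
  geno <- rbind(
    matrix(c(1L, 1L, 1L, 0L, 0L), 1),    # sb-RPD in BIG only
    matrix(c(0L, 0L, 0L, 1L, 0L), 1),    # different variant, same gene, SMALL
    matrix(c(1L, 1L, 1L, 1L, 0L), 1))    # identical variant in both groups
  colnames(geno) <- samples
  rpd <- make_rpd(rows, geno, samples)
  shared <- find_shared_broad(rpd, co)
  expect_setequal(shared$gene, c("GSHARED", "GVAR"))
  ov <- cross_family_overlap(shared, rpd, co)
  expect_setequal(ov$gene_overlap, c("GSHARED", "GVAR"))
  expect_equal(ov$n_variant_overlap, 1)
  expect_equal(ov$variant_overlap$gene, "GVAR")
})

test_that("gene summary collapses families and reports the maximum burden", {
  seg <- data.frame(
    chrom = "1", pos = c(100L, 100L, 900L), ref = "A", alt = "T",
    gene = c("GEM", "GEM", "PCN"), family_id = c("D002", "D012", "D003"),
    affected_carriers = c(3L, 3L, 6L), affected_sequenced = c(6L, 3L, 6L),
    family_control_carriers = 0L, unrelated_control_carriers = 0L,
    passes_rarity_stringent = TRUE, tier = "shared_broad",
    stringsAsFactors = FALSE)
  gs <- gene_summary(seg)
  expect_equal(gs$n_families[gs$gene == "GEM"], 2)
  expect_equal(gs$families[gs$gene == "GEM"], "D002,D012")
  expect_equal(gs$max_burden[gs$gene == "PCN"], 6)
  expect_equal(nrow(gene_summary(seg[0, ])), 0)
})

test_that("planted segregating variants are always recovered and tiers nest", {
  for (seed in c(11, 23, 35)) {
    sim <- simulate_cohort(sim_config("mini", seed = seed))
    rpd <- filter_rpd(sim$vs)
    broad <- find_shared_broad(rpd, sim$cohort)
    strict <- find_shared_stringent(broad, rpd, sim$cohort)
    truth <- sim$truth$variants[sim$truth$variants$planted, ]
    key <- function(d) paste(d$chrom, d$pos, d$alt)
    expect_true(all(key(truth) %in% key(broad)),
                label = sprintf("planted recovery, seed %d", seed))
    expect_true(all(key(strict) %in% key(broad)))
    # removing an unrelated control can only grow the sb-RPD set
    co2 <- sim$cohort
    drop_id <- samples_by_role(co2, "unrelated_control")[1]
    co2 <- new_cohort(co2$samples[co2$samples$sample_id != drop_id, ])
    broad2 <- find_shared_broad(rpd, co2)
    expect_true(all(key(broad) %in% key(broad2)))
  }
})

test_that("null sb-RPD counts match the binomial-tail oracle", {
  # carriers drawn independently per sample: expected number of variants with
  # >=3 case carriers and 0 unrelated-control carriers follows a product of
  # binomial tails
  set.seed(99)
  fam <- function(f, n) data.frame(
    sample_id = sprintf("%s_S%d", f, seq_len(n)), family_id = f,
    father_id = NA_character_, mother_id = NA_character_, sex = 1L,
    affected = TRUE, role = "case", stringsAsFactors = FALSE)
  uc <- data.frame(sample_id = sprintf("UC%d", 1:10), family_id = "",
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = 1L, affected = FALSE, role = "unrelated_control",
                   stringsAsFactors = FALSE)
  co <- new_cohort(rbind(fam("FX", 4), uc))
  samples <- co$samples$sample_id
  p <- 0.2
  n_var <- 4000
  rows <- lapply(seq_len(n_var), function(i)
    make_variant_row(pos = i * 10L, gene = sprintf("G%04d", i),
                     consequence = "stopgain"))
  geno <- matrix(rbinom(n_var * length(samples), 1, p), n_var,
                 dimnames = list(NULL, samples))
  rpd <- make_rpd(rows, geno, samples)
  res <- find_shared_broad(rpd, co)
  p_hit <- pbinom(2, 4, p, lower.tail = FALSE) * (1 - p)^10
  expected <- n_var * p_hit
  se <- sqrt(n_var * p_hit * (1 - p_hit))
  expect_lt(abs(nrow(res) - expected), 4 * se)
})
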