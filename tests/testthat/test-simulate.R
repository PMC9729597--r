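.predictor_cols_for_test <- function() {
  c("pred_sift", "pred_lrt", "pred_mutationtaster",
    "pred_mutationassessor", "pred_metasvm")
}

test_that("gene dropping is Mendelian-consistent and frequency-preserving", {
  ped <- data.frame(
    id = c("F", "M", "C1", "C2"), family_id = "F1",
    father = c(NA, NA, "F", "F"), mother = c(NA, NA, "M", "M"),
    stringsAsFactors = FALSE)
  founder <- matrix(c(0L, 0L, 2L, 0L, 2L, 2L), nrow = 3,
                    dimnames = list(NULL, c("F", "M")))
  set.seed(1)
  g <- gene_drop(ped, founder)
  expect_equal(unname(g[1, c("C1", "C2")]), c(0L, 0L))   # 0/0 x 0/0
  expect_equal(unname(g[2, c("C1", "C2")]), c(1L, 1L))   # 1/1 x 0/0 -> het
  expect_equal(unname(g[3, c("C1", "C2")]), c(2L, 2L))   # 1/1 x 1/1

  # founder frequency is preserved through random founders
  set.seed(2)
  n_f <- 10000
  ids <- sprintf("X%05d", seq_len(n_f))
  ped_f <- data.frame(id = ids, family_id = ids,
                      father = NA_character_, mother = NA_character_,
                      stringsAsFactors = FALSE)
  fg <- matrix(rbinom(n_f, 2, 0.3), 1, dimnames = list(NULL, ids))
  g2 <- gene_drop(ped_f, fg)
  se <- sqrt(0.3 * 0.7 / (2 * n_f))
  expect_lt(abs(mean(g2) / 2 - 0.3), 3 * se)

  cyc <- data.frame(id = c("A", "B"), family_id = "F1",
                    father = c("B", "A"), mother = c("B", "A"),
                    stringsAsFactors = FALSE)
  expect_error(gene_drop(cyc, matrix(0L, 1, 0)), "cycle")
})

test_that("liability phenotypes hit the configured prevalence and penetrance", {
  cfg <- sim_config("mini", baseline_prevalence = 0.1)
  n <- 10000
  ped <- data.frame(id = sprintf("P%05d", 1:n), family_id = "",
                    stringsAsFactors = FALSE)
  set.seed(4)
  ph <- assign_phenotypes(ped, cfg)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(ph$affected) - 0.1), 3 * se)

  # penetrance 1 carriers are always affected, penetrance 0.5 about half
  carriers <- ped$id[1:4000]
  ph1 <- assign_phenotypes(ped, cfg,
    planted_carriers = list(list(carriers = carriers, penetrance = 1)))
  expect_true(all(ph1$affected[1:4000]))
  set.seed(5)
  ph5 <- assign_phenotypes(ped, cfg,
    planted_carriers = list(list(carriers = carriers, penetrance = 0.5)))
  se5 <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(ph5$affected[1:4000]) - 0.5), 3 * se5)
  expect_error(sim_config("mini", baseline_prevalence = 1.5), "prevalence")
})

test_that("simulated cohorts have the configured structure", {
  sim <- simulate_cohort(sim_config("default", seed = 12))
  co <- sim$cohort
  expect_length(co$families, 75)
  expect_equal(sum(co$samples$role == "unrelated_control"), 60)
  multi <- select_multisample_families(co)
  expect_gte(length(multi), 16)     # every planned multiplex family qualifies
  expect_length(sim$cns_genes, 600)
  # per-sample rare-variant content of realistic order
  rare <- sim$truth$variants$true_f < 0.01
  carriers_per_sample <- colSums(sim$vs$geno[rare, ] >= 1, na.rm = TRUE)
  expect_gt(median(carriers_per_sample), 100)
  expect_lt(median(carriers_per_sample), 5000)
  # case counts per family span the designed 1-6 range
  cases_per_fam <- table(co$samples$family_id[co$samples$role == "case"])
  expect_gte(min(cases_per_fam), 1)
  expect_lte(max(cases_per_fam), 6)
})

test_that("generation is fully deterministic under the seed", {
  s1 <- simulate_cohort(sim_config("mini", seed = 42))
  s2 <- simulate_cohort(sim_config("mini", seed = 42))
  expect_identical(s1$vs$variants, s2$vs$variants)
  expect_identical(s1$vs$geno, s2$vs$geno)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  emit_simulation(s1, d1); emit_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("emitted file", f))
  }
})

test_that("emitted files parse back to the identical in-memory model", {
  sim <- simulate_cohort(sim_config("mini", seed = 9))
  dir <- tempfile()
  paths <- emit_simulation(sim, dir)
  co <- read_pedigree(paths["ped"])
  expect_equal(co$samples$sample_id, sim$cohort$samples$sample_id)
  expect_equal(co$samples$role, sim$cohort$samples$role)
  expect_equal(co$families, sim$cohort$families)
  vs <- read_annotated_vcf(paths["vcf"], co)
  expect_equal(vs$variants$gene, sim$vs$variants$gene)
  expect_equal(vs$variants$maf_sas, sim$vs$variants$maf_sas)
  expect_equal(vs$variants[.predictor_cols_for_test()],
               sim$vs$variants[.predictor_cols_for_test()])
  expect_identical(vs$geno, sim$vs$geno)
  gs <- read_gene_list(paths["cns"], universe_size = nrow(sim$truth$genes))
  expect_setequal(gs$genes, sim$cns_genes)
  expect_length(gs$genes, sim$config$n_cns_genes)
  # truth-table carrier lists match the emitted genotypes
  tv <- sim$truth$variants[sim$truth$variants$planted, ]
  for (i in seq_len(nrow(tv))) {
    carriers <- strsplit(tv$carriers[i], ",")[[1]]
    carriers <- intersect(carriers, colnames(vs$geno))
    row <- which(vs$variants$pos == tv$pos[i] & vs$variants$chrom == tv$chrom[i])
    expect_setequal(colnames(vs$geno)[which(vs$geno[row, ] >= 1)], carriers)
  }
})

test_that("annotation rules hold: synonymous never RPD, planted always RPD", {
  sim <- simulate_cohort(sim_config("test", seed = 77))
  rpd_all <- filter_rpd(sim$vs, keep_all = TRUE)
  syn <- rpd_all$calls$consequence == "synonymous"
  expect_false(any(rpd_all$calls$is_rpd[syn]))
  truth <- sim$truth$variants
  key_truth <- paste(truth$chrom, truth$pos, truth$alt)[truth$planted]
  key_rpd <- paste(rpd_all$calls$chrom, rpd_all$calls$pos, rpd_all$calls$alt)
  expect_true(all(key_truth %in% key_rpd[rpd_all$calls$is_rpd]))

  # full missingness leaves every predictor slot empty
  cfg <- sim_config("mini", annotation_missingness_rate = 1)
  set.seed(3)
  ann <- generate_annotations(rep(1e-4, 50), cfg)
  expect_true(all(is.na(ann$pred_sift)))
})
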