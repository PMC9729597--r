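#' Simulation configuration
#'
#' Builds the parameter set for [simulate_cohort()]. The `"default"`
#' profile emulates the structure of a familial serious-mental-illness
#' exome study: 75 families contributing 1-6 sequenced cases each (median
#' 2), 16 of them multiplex (>= 3 sequenced cases), 60 unrelated
#' population controls, a synthetic gene universe with a designated
#' "CNS" subset (~12% of genes, mirroring the 2450/20203 proportion of
#' the OMIM clinical-synopsis CNS list), per-sample rare-variant content of
#' order 10^2-10^3, three founder sub-populations with Balding-Nichols
#' drift at common sites, and six planted fully penetrant causal variants
#' in distinct CNS genes, each private to one multiplex family. The
#' `"test"` profile keeps the same planting density and effect
#' configuration on a smaller cohort; `"mini"` backs fast unit tests.
#'
#' @param profile `"default"`, `"test"` or `"mini"`.
#' @param ... named overrides of any configuration field (e.g. `seed`,
#'   `n_families`, `planted`, `baseline_prevalence`).
#' @return list of class `pedseg_sim_config`. Key fields: `n_families`,
#'   `n_multisample_families`, `n_unrelated_controls`, `n_genes`,
#'   `n_cns_genes`, `variants_per_gene`, `prop_common`, `fst`,
#'   `n_subpops`, `planted` (data.frame with `penetrance`, `maf_sas`,
#'   `maf_global` per planted variant; `NA` frequency means absent from
#'   the reference panels), `baseline_prevalence`, `family_effect_sd`,
#'   `predictor_deleterious_prob` (named by consequence class),
#'   `annotation_missingness_rate`, `panel_n_sas`, `panel_n_global`,
#'   `seed`.
#' @export
sim_config <- function(profile = c("default", "test", "mini"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    default = list(n_families = 75, n_multisample_families = 16,
                   n_unrelated_controls = 60, n_genes = 5000,
                   n_cns_genes = 600, variants_per_gene = 12,
                   n_planted = 6),
    test = list(n_families = 20, n_multisample_families = 8,
                n_unrelated_controls = 30, n_genes = 500,
                n_cns_genes = 60, variants_per_gene = 4,
                n_planted = 6),
    mini = list(n_families = 6, n_multisample_families = 3,
                n_unrelated_controls = 12, n_genes = 40,
                n_cns_genes = 8, variants_per_gene = 5,
                n_planted = 2))
  cfg <- c(base, list(
    profile = profile,
    prop_common = 0.25,
    fst = 0.02,
    n_subpops = 3,
    planted = data.frame(penetrance = rep(1, base$n_planted),
                         maf_sas = NA_real_, maf_global = NA_real_),
    baseline_prevalence = 0.01,
    family_effect_sd = 0.8,
    predictor_deleterious_prob = c(
      stopgain = 0.8, stoploss = 0.8, startloss = 0.8,
      canonical_splice = 0.7, frameshift_indel = 0.8, inframe_indel = 0.3,
      missense = 0.25, synonymous = 0.02, other = 0.05),
    annotation_missingness_rate = 0.05,
    panel_n_sas = 15308, panel_n_global = 100000,
    seed = 1L))
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "n_planted"))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$n_multisample_families > cfg$n_families)
    stop("n_multisample_families cannot exceed n_families")
  if (nrow(cfg$planted) > cfg$n_multisample_families)
    stop("cannot plant more variants than multiplex families")
  if (any(cfg$planted$penetrance < 0 | cfg$planted$penetrance > 1))
    stop("penetrance must lie in [0, 1]")
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)")
  structure(cfg, class = "pedseg_sim_config")
}

#' Simulate pedigree structures and the sequencing plan
#'
#' Builds multi-generation families (a founder couple, their children, and
#' — for large sequencing plans — a married-in spouse with grandchildren),
#' designates which members are sequenced, and attaches unrelated
#' controls. Multiplex families receive 3-6 planned sequenced cases, the
#' remaining families 1-2, and each family 0-2 sequenced unaffected
#' relatives; every founder (and each family as a unit) is assigned to one
#' of the ancestry sub-populations.
#'
#' @param config a [sim_config()] object.
#' @return list with `pedigree` (data.frame over all simulated
#'   individuals: `id`, `family_id`, `father`, `mother`, `sex`, `founder`,
#'   `subpop`, `sequenced`, `planned_role`) and `family_ids`.
#' @export
simulate_pedigrees <- function(config) {
  fam_ids <- sprintf("F%03d", seq_len(config$n_families))
  multi <- fam_ids[seq_len(config$n_multisample_families)]
  rows <- list()
  for (f in fam_ids) {
    n_cases <- if (f %in% multi)
      sample(3:6, 1, prob = c(0.5, 0.3, 0.15, 0.05))
    else sample(1:2, 1, prob = c(0.6, 0.4))
    n_fctrl <- sample(0:2, 1, prob = c(0.35, 0.45, 0.2))
    n_seq <- n_cases + n_fctrl
    subpop <- sample.int(config$n_subpops, 1)
    mk <- function(i, fa, mo, founder) data.frame(
      id = sprintf("%s_I%02d", f, i), family_id = f,
      father = fa, mother = mo,
      sex = sample(1:2, 1), founder = founder, subpop = subpop,
      sequenced = FALSE, planned_role = NA_character_,
      stringsAsFactors = FALSE)
    fa_id <- sprintf("%s_I01", f); mo_id <- sprintf("%s_I02", f)
    ped <- rbind(mk(1, NA, NA, TRUE), mk(2, NA, NA, TRUE))
    n_child <- min(max(2, n_seq), 5)
    child_ids <- character(n_child)
    for (k in seq_len(n_child)) {
      ped <- rbind(ped, mk(2 + k, fa_id, mo_id, FALSE))
      child_ids[k] <- ped$id[nrow(ped)]
    }
    members <- child_ids
    if (n_seq > n_child) {            # third generation via a married-in spouse
      sp <- mk(2 + n_child + 1, NA, NA, TRUE)
      ped <- rbind(ped, sp)
      for (g in seq_len(n_seq - n_child)) {
        ped <- rbind(ped, mk(2 + n_child + 1 + g, child_ids[1], sp$id, FALSE))
        members <- c(members, ped$id[nrow(ped)])
      }
    }
    seq_ids <- sample(members, n_seq)
    roles <- sample(c(rep("case", n_cases), rep("family_control", n_fctrl)))
    ped$sequenced[ped$id %in% seq_ids] <- TRUE
    ped$planned_role[match(seq_ids, ped$id)] <- roles
    rows[[f]] <- ped
  }
  uc <- data.frame(
    id = sprintf("UC%03d", seq_len(config$n_unrelated_controls)),
    family_id = "", father = NA_character_, mother = NA_character_,
    sex = sample(1:2, config$n_unrelated_controls, replace = TRUE),
    founder = TRUE,
    subpop = sample.int(config$n_subpops, config$n_unrelated_controls,
                        replace = TRUE),
    sequenced = TRUE, planned_role = "unrelated_control",
    stringsAsFactors = FALSE)
  list(pedigree = rbind(do.call(rbind, rows), uc), family_ids = fam_ids)
}

#' Mendelian gene dropping down a pedigree
#'
#' Founders receive the supplied genotypes; every non-founder draws one
#' allele from each parent, the transmission probability of the alternate
#' allele being half the parental dosage. Variants are treated as unlinked.
#'
#' @param pedigree pedigree table from [simulate_pedigrees()] (columns
#'   `id`, `father`, `mother`).
#' @param founder_geno integer matrix, variants x founders, with columns
#'   named by founder id.
#' @return integer matrix, variants x individuals (all pedigree members).
#' @export
gene_drop <- function(pedigree, founder_geno) {
  m <- nrow(founder_geno)
  n <- nrow(pedigree)
  geno <- matrix(NA_integer_, m, n, dimnames = list(NULL, pedigree$id))
  done <- setNames(rep(FALSE, n), pedigree$id)
  pending <- seq_len(n)
  guard <- 0L
  while (length(pending)) {
    progressed <- FALSE
    still <- integer(0)
    for (i in pending) {
      fa <- pedigree$father[i]; mo <- pedigree$mother[i]
      if (is.na(fa) && is.na(mo)) {
        geno[, i] <- founder_geno[, pedigree$id[i]]
        done[i] <- TRUE; progressed <- TRUE
      } else if (done[fa] && done[mo]) {
        geno[, i] <- rbinom(m, 1, geno[, fa] / 2) + rbinom(m, 1, geno[, mo] / 2)
        done[i] <- TRUE; progressed <- TRUE
      } else still <- c(still, i)
    }
    pending <- still
    if (!progressed)
      stop("pedigree contains a cycle or unresolvable parent links")
    guard <- guard + 1L
    if (guard > n + 1L) stop("pedigree ordering did not converge")
  }
  geno
}

#' Liability-threshold phenotype assignment
#'
#' Liability is the sum of a family-level random effect (shared by all
#' members of a pedigree) and unit-variance individual noise; an
#' individual is affected when liability exceeds the threshold implied by
#' the baseline prevalence. Carriers of a planted variant are governed by
#' that variant's penetrance instead: a fully penetrant carrier is always
#' affected, a penetrance-q carrier with probability q. Affected
#' individuals draw a diagnosis from a trans-diagnostic distribution
#' (SCZ 0.40, BD 0.35, OCD 0.15, SUD 0.10), so most simulated multiplex
#' families end up with mixed diagnoses.
#'
#' @param pedigree pedigree table (`id`, `family_id`).
#' @param config a [sim_config()] object (`baseline_prevalence`,
#'   `family_effect_sd`).
#' @param planted_carriers optional list: for each planted variant, a list
#'   with `carriers` (ids) and `penetrance`.
#' @return data.frame with `id`, `liability`, `affected`, `diagnosis`.
#' @export
assign_phenotypes <- function(pedigree, config, planted_carriers = list()) {
  n <- nrow(pedigree)
  fam <- pedigree$family_id
  fam_key <- ifelse(fam == "", pedigree$id, fam)   # unrelateds: own effect
  u_fam <- unique(fam_key)
  b <- setNames(rnorm(length(u_fam), 0, config$family_effect_sd), u_fam)
  liability <- b[fam_key] + rnorm(n)
  thr <- qnorm(1 - config$baseline_prevalence,
               sd = sqrt(1 + config$family_effect_sd^2))
  affected <- liability > thr
  for (pv in planted_carriers) {
    idx <- match(pv$carriers, pedigree$id)
    idx <- idx[!is.na(idx)]
    affected[idx] <- runif(length(idx)) < pv$penetrance
  }
  diagnosis <- rep(NA_character_, n)
  n_aff <- sum(affected)
  if (n_aff)
    diagnosis[affected] <- sample(c("SCZ", "BD", "OCD", "SUD"), n_aff,
                                  replace = TRUE,
                                  prob = c(0.40, 0.35, 0.15, 0.10))
  data.frame(id = pedigree$id, liability = unname(liability),
             affected = unname(affected), diagnosis = diagnosis,
             stringsAsFactors = FALSE)
}

#' gnomAD-style annotation fields for simulated variants
#'
#' Panel allele frequencies are drawn as binomial sampling from the true
#' simulated frequency at the panel's chromosome count, so rare variants
#' naturally come out as exact small fractions or as panel-absent
#' (missing). Consequence classes follow fixed per-class proportions, and
#' each of the five predictor slots is deleterious with a per-class
#' probability, tolerated otherwise, and missing at the configured rate.
#'
#' @param true_f numeric vector of true alternate-allele frequencies.
#' @param config a [sim_config()] object.
#' @return data.frame with `consequence`, `maf_sas`, `maf_global` and the
#'   five predictor columns.
#' @export
generate_annotations <- function(true_f, config) {
  m <- length(true_f)
  classes <- sample(names(config$predictor_deleterious_prob), m,
                    replace = TRUE,
                    prob = c(0.03, 0.01, 0.01, 0.03, 0.04, 0.02,
                             0.45, 0.29, 0.12))
  draw_panel <- function(n_chrom) {
    count <- rbinom(m, n_chrom, true_f)
    ifelse(count == 0, NA_real_, count / n_chrom)
  }
  out <- data.frame(consequence = classes,
                    maf_sas = draw_panel(2 * config$panel_n_sas),
                    maf_global = draw_panel(2 * config$panel_n_global),
                    stringsAsFactors = FALSE)
  p_del <- config$predictor_deleterious_prob[classes]
  for (col in .predictor_cols) {
    call <- ifelse(runif(m) < p_del, "D", "T")
    call[runif(m) < config$annotation_missingness_rate] <- NA
    out[[col]] <- call
  }
  out
}

#' Simulate a complete annotated family cohort with known truth
#'
#' Runs the whole generator: pedigrees and a sequencing plan
#' ([simulate_pedigrees()]), founder genotypes under three-sub-population
#' Balding-Nichols structure, Mendelian transmission ([gene_drop()]),
#' planted causal variants (each private to one multiplex family, carried
#' by that family's planned cases, guaranteed to satisfy the
#' rare-predicted-deleterious definition), liability-threshold phenotypes
#' ([assign_phenotypes()]), and gnomAD-style annotations
#' ([generate_annotations()]). Because families are recruited for
#' multiplex affection, the generator conditions on the sequencing plan:
#' if liability leaves a multiplex family short of three affected
#' sequenced members, the highest-liability sequenced members are promoted
#' until the plan is met (and at least one case per non-multiplex family).
#' Unrelated controls are screened, i.e. never affected.
#'
#' @param config a [sim_config()] object.
#' @return list of class `pedseg_simulation`: `cohort` (a
#'   `pedseg_cohort` over sequenced samples), `vs` (a `pedseg_variants`
#'   set aligned to the cohort), `truth` (list of data.frames:
#'   `variants` with true frequency, planted status and carrier lists;
#'   `genes` with CNS membership; `samples` with liability and
#'   diagnosis), `cns_genes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  cns_genes <- sort(sample(genes, config$n_cns_genes))
  m_bg <- config$n_genes * config$variants_per_gene
  gene_of <- rep(genes, each = config$variants_per_gene)

  # allele-frequency spectrum: a common component for kinship/PCA plus a
  # rare tail mixing an ultra-rare log-uniform mass with a low-frequency
  # band, sized so sequenced samples carry rare variants at the realistic
  # order of 10^2 per exome
  is_common <- runif(m_bg) < config$prop_common
  ultra <- runif(m_bg) < 0.5
  true_f <- ifelse(is_common, runif(m_bg, 0.05, 0.5),
                   ifelse(ultra, 10^runif(m_bg, -6, -3),
                          runif(m_bg, 2e-4, 5e-3)))

  # Balding-Nichols divergence across sub-populations at common sites
  subpop_f <- matrix(rep(true_f, config$n_subpops), ncol = config$n_subpops)
  fst <- config$fst
  common_idx <- which(is_common)
  for (s in seq_len(config$n_subpops)) {
    f <- true_f[common_idx]
    subpop_f[common_idx, s] <- rbeta(length(common_idx),
                                     f * (1 - fst) / fst,
                                     (1 - f) * (1 - fst) / fst)
  }

  sim <- simulate_pedigrees(config)
  ped <- sim$pedigree
  founders <- ped$id[ped$founder]
  founder_geno <- matrix(0L, m_bg, length(founders),
                         dimnames = list(NULL, founders))
  for (j in seq_along(founders)) {
    sp <- ped$subpop[match(founders[j], ped$id)]
    founder_geno[, j] <- rbinom(m_bg, 2, subpop_f[, sp])
  }
  geno <- gene_drop(ped, founder_geno)

  # planted causal variants: one extra variant per row of config$planted,
  # in a distinct CNS gene, private to one multiplex family's planned cases
  planted <- config$planted
  n_pl <- nrow(planted)
  multi_fams <- sim$family_ids[seq_len(config$n_multisample_families)]
  target_fams <- sample(multi_fams, n_pl)
  target_genes <- sample(cns_genes, n_pl)
  planted_geno <- matrix(0L, n_pl, ncol(geno),
                         dimnames = list(NULL, colnames(geno)))
  planted_carriers <- vector("list", n_pl)
  for (i in seq_len(n_pl)) {
    carriers <- ped$id[ped$family_id == target_fams[i] &
                       !is.na(ped$planned_role) & ped$planned_role == "case"]
    planted_geno[i, carriers] <- 1L
    planted_carriers[[i]] <- list(carriers = carriers,
                                  penetrance = planted$penetrance[i])
  }
  geno <- rbind(geno, planted_geno)
  gene_of <- c(gene_of, target_genes)
  true_f <- c(true_f, rep(0, n_pl))
  m <- m_bg + n_pl

  phen <- assign_phenotypes(ped, config, planted_carriers)

  # ascertainment: hold the sequencing plan's case counts
  aff <- setNames(phen$affected, phen$id)
  for (f in sim$family_ids) {
    seq_ids <- ped$id[ped$family_id == f & ped$sequenced]
    need <- max(1L, sum(ped$planned_role[match(seq_ids, ped$id)] == "case",
                        na.rm = TRUE))
    short <- need - sum(aff[seq_ids])
    if (short > 0) {
      cand <- seq_ids[!aff[seq_ids]]
      cand <- cand[order(-phen$liability[match(cand, phen$id)])]
      promote <- cand[seq_len(min(short, length(cand)))]
      aff[promote] <- TRUE
      phen$diagnosis[match(promote, phen$id)] <-
        sample(c("SCZ", "BD", "OCD", "SUD"), length(promote), replace = TRUE,
               prob = c(0.40, 0.35, 0.15, 0.10))
    }
  }
  uc_ids <- ped$id[ped$planned_role %in% "unrelated_control"]
  aff[uc_ids] <- FALSE                     # screened population controls
  phen$affected <- unname(aff[phen$id])
  phen$diagnosis[!phen$affected] <- NA_character_

  # cohort over sequenced samples; parents recorded only when sequenced
  sq <- ped[ped$sequenced, , drop = FALSE]
  role <- ifelse(sq$planned_role == "unrelated_control", "unrelated_control",
                 ifelse(aff[sq$id], "case", "family_control"))
  parent_if_seq <- function(p) ifelse(!is.na(p) & p %in% sq$id, p, NA)
  cohort <- new_cohort(data.frame(
    sample_id = sq$id, family_id = sq$family_id,
    father_id = parent_if_seq(sq$father), mother_id = parent_if_seq(sq$mother),
    sex = sq$sex, affected = unname(aff[sq$id]), role = role,
    diagnosis = phen$diagnosis[match(sq$id, phen$id)],
    stringsAsFactors = FALSE))

  anno <- generate_annotations(true_f, config)
  # planted variants must satisfy the RPD definition by construction
  pl_rows <- m_bg + seq_len(n_pl)
  anno$consequence[pl_rows] <- sample(c("stopgain", "missense"), n_pl,
                                      replace = TRUE)
  for (col in .predictor_cols) anno[[col]][pl_rows] <- "D"
  anno$maf_sas[pl_rows] <- planted$maf_sas
  anno$maf_global[pl_rows] <- planted$maf_global

  chrom_of_gene <- setNames(as.character(rep_len(1:22, config$n_genes)), genes)
  ord <- order(as.integer(chrom_of_gene[gene_of]), gene_of)
  base <- c("A", "C", "G", "T")
  ref <- sample(base, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(base, r), 1), character(1))
  variants <- data.frame(
    chrom = chrom_of_gene[gene_of], pos = NA_integer_,
    ref = ref, alt = alt, gene = gene_of,
    anno, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  true_f <- true_f[ord]
  planted_flag <- seq_len(m) %in% pl_rows
  planted_flag <- planted_flag[ord]
  penetrance_of <- rep(NA_real_, m)
  penetrance_of[pl_rows] <- planted$penetrance
  penetrance_of <- penetrance_of[ord]
  carriers_str <- rep(NA_character_, m)
  carriers_str[pl_rows] <- vapply(planted_carriers, function(x)
    paste(x$carriers, collapse = ","), character(1))
  carriers_str <- carriers_str[ord]
  variants$pos <- as.integer(ave(seq_len(m), variants$chrom,
                                 FUN = function(i) seq_along(i) * 997L + 10000L))
  rownames(variants) <- NULL

  vs <- new_variant_set(variants,
                        geno[, cohort$samples$sample_id, drop = FALSE],
                        cohort$samples$sample_id)
  truth <- list(
    variants = data.frame(
      chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
      alt = variants$alt, gene = variants$gene, true_f = true_f,
      planted = planted_flag, penetrance = penetrance_of,
      carriers = carriers_str, stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, cns = genes %in% cns_genes,
                       stringsAsFactors = FALSE),
    samples = data.frame(phen[match(cohort$samples$sample_id, phen$id), ],
                         role = cohort$samples$role,
                         stringsAsFactors = FALSE))
  rownames(truth$samples) <- NULL
  structure(list(cohort = cohort, vs = vs, truth = truth,
                 cns_genes = cns_genes, config = config),
            class = "pedseg_simulation")
}

#' @export
print.pedseg_simulation <- function(x, ...) {
  cat(sprintf("pedseg simulation ('%s' profile, seed %d): ",
              x$config$profile, x$config$seed))
  print(x$cohort)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the annotated VCF, the 7-column PED, the synthetic CNS gene list
#' and the truth tables as plain-text files that parse back through
#' [read_annotated_vcf()] / [read_pedigree()] / [read_gene_list()] to the
#' identical in-memory model.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param config VCF field mapping, see [vcf_field_config()].
#' @return named character vector of the written paths.
#' @export
emit_simulation <- function(sim, dir, config = vcf_field_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    cns = file.path(dir, "cns_genes.txt"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"))
  write_annotated_vcf(sim$vs, paths["vcf"], config)
  write_pedigree(sim$cohort, paths["ped"])
  writeLines(sim$cns_genes, paths["cns"])
  for (nm in c("variants", "genes", "samples"))
    write.table(sim$truth[[nm]], paths[paste0("truth_", nm)], sep = "\t",
                quote = FALSE, row.names = FALSE)
  paths
}
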