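#' Pipeline run configuration
#'
#' Collects every tunable of the full workflow with the analysis defaults:
#' broad rarity 1e-3, stringent rarity 1e-4, sharing threshold 3,
#' strict 4-of-5 deleteriousness consensus, a 20203-gene universe, and the
#' SKAT settings (permutation ceiling, Beta(1, 25) weights, seed). With no
#' input paths the pipeline runs on a simulated cohort of the requested
#' profile.
#'
#' @param vcf,ped optional input paths (both required to run on real
#'   data); when `NULL` the cohort is simulated.
#' @param gene_set_paths optional character vector of gene-list files; for
#'   simulated runs the synthetic CNS list plus a size-matched random
#'   control set are used instead.
#' @param vcf_fields field mapping, see [vcf_field_config()].
#' @param maf_broad,maf_stringent rarity thresholds.
#' @param min_shared sharing threshold within a family.
#' @param consensus_rule `"strict"` or `"lenient"`.
#' @param universe_size gene universe for enrichment (ignored for
#'   simulated runs, which use the synthetic universe size).
#' @param skat_B permutation ceiling per unit.
#' @param skat_weights `"beta"` or `"flat"`.
#' @param sim_profile simulation profile for input-free runs.
#' @param seed seed for simulation, k-means and permutations.
#' @param out_dir output directory.
#' @return list of class `pedseg_run_config`.
#' @export
run_config <- function(vcf = NULL, ped = NULL, gene_set_paths = NULL,
                       vcf_fields = vcf_field_config(),
                       maf_broad = 1e-3, maf_stringent = 1e-4,
                       min_shared = 3, consensus_rule = "strict",
                       universe_size = 20203L, skat_B = 1e4,
                       skat_weights = "beta", sim_profile = "default",
                       seed = 1L, out_dir = tempfile("pedseg_run_")) {
  structure(list(vcf = vcf, ped = ped, gene_set_paths = gene_set_paths,
                 vcf_fields = vcf_fields, maf_broad = maf_broad,
                 maf_stringent = maf_stringent, min_shared = min_shared,
                 consensus_rule = consensus_rule,
                 universe_size = universe_size, skat_B = skat_B,
                 skat_weights = skat_weights, sim_profile = sim_profile,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pedseg_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a `pedseg_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Validate a pipeline configuration
#'
#' Reports problems without running anything: error-level entries make
#' the configuration unrunnable, warning-level entries flag suspicious but
#' legal settings (for example a broad rarity threshold outside the
#' rare-variant regime).
#'
#' @param cfg a `pedseg_run_config`.
#' @return data.frame with columns `level` (`"error"`/`"warning"`),
#'   `key`, `message`; zero rows when nothing is wrong.
#' @export
validate_config <- function(cfg) {
  probs <- list()
  add <- function(level, key, message)
    probs[[length(probs) + 1]] <<- data.frame(level = level, key = key,
                                              message = message,
                                              stringsAsFactors = FALSE)
  if (cfg$maf_broad < 0 || cfg$maf_broad > 1)
    add("error", "maf_broad", "must lie in [0, 1]")
  else if (cfg$maf_broad > 0.01)
    add("warning", "maf_broad", "outside the rare-variant regime (> 0.01)")
  if (cfg$maf_stringent < 0 || cfg$maf_stringent > cfg$maf_broad)
    add("error", "maf_stringent", "must lie in [0, maf_broad]")
  if (cfg$min_shared < 1)
    add("error", "min_shared", "must be >= 1")
  if (!cfg$consensus_rule %in% c("strict", "lenient"))
    add("error", "consensus_rule", "must be 'strict' or 'lenient'")
  if (cfg$universe_size < 1)
    add("error", "universe_size", "must be positive")
  if (cfg$skat_B < 1e3)
    add("warning", "skat_B", "fewer than 1000 permutations gives unstable resampling p-values")
  if (is.null(cfg$vcf) != is.null(cfg$ped))
    add("error", "vcf/ped", "provide both a VCF and a PED, or neither")
  for (key in c("vcf", "ped")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      add("error", key, paste0("file not found: ", cfg[[key]]))
  }
  for (p in cfg$gene_set_paths %||% character(0)) {
    if (!file.exists(p))
      add("error", "gene_set_paths", paste0("file not found: ", p))
  }
  if (!length(probs))
    return(data.frame(level = character(0), key = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, probs)
}

# small stable content hash (polynomial rolling hash over the deparsed
# configuration; output directory excluded so reruns elsewhere match)
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg[setdiff(names(cfg), "out_dir")]),
                           collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

.write_report <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pedseg run config=%s seed=%d", hash, seed), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  path
}

#' Run the full analysis workflow
#'
#' Executes both analytical arms end to end —
#' simulate/load, RPD prioritization, within-pedigree segregation
#' (broad and stringent tiers plus the cross-family overlap report),
#' gene-set overrepresentation, and the kinship-adjusted gene-set SKAT —
#' and writes one TSV per stage plus a reproducibility manifest to the
#' configured output directory. Each output file carries the
#' configuration hash and seed in its first comment line.
#'
#' @param cfg a [run_config()] object.
#' @param quiet suppress per-stage count messages (default `FALSE`).
#' @return invisible list with all in-memory stage results: `cohort`,
#'   `vs`, `rpd`, `broad`, `stringent`, `overlap`, `genes` (gene
#'   summary), `enrichment`, `skat`, `manifest`, `paths`.
#' @export
run_full_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  probs <- validate_config(cfg)
  if (any(probs$level == "error"))
    stop("configuration invalid:\n",
         paste(sprintf("  [%s] %s: %s", probs$level, probs$key, probs$message),
               collapse = "\n"))
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- .config_hash(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  t0 <- Sys.time()
  stage <- "load"
  res <- tryCatch({
    if (is.null(cfg$vcf)) {
      sim <- simulate_cohort(sim_config(cfg$sim_profile, seed = cfg$seed))
      cohort <- sim$cohort; vs <- sim$vs
      universe_genes <- sim$truth$genes$gene
      sets <- list(gene_set(sim$cns_genes, "synthetic_CNS",
                            nrow(sim$truth$genes)))
      non_cns <- setdiff(universe_genes, sim$cns_genes)
      sets[[2]] <- gene_set(sample(non_cns, min(length(sim$cns_genes),
                                                length(non_cns))),
                            "synthetic_control_set", nrow(sim$truth$genes))
      universe_size <- nrow(sim$truth$genes)
    } else {
      sim <- NULL
      cohort <- read_pedigree(cfg$ped)
      vs <- read_annotated_vcf(cfg$vcf, cohort, cfg$vcf_fields)
      sets <- lapply(cfg$gene_set_paths, read_gene_list,
                     universe_size = cfg$universe_size)
      universe_size <- cfg$universe_size
    }
    say("loaded %d variants x %d samples", nrow(vs$variants),
        length(vs$samples))

    stage <- "prioritize"
    rpd <- filter_rpd(vs, maf_broad = cfg$maf_broad,
                      maf_stringent = cfg$maf_stringent,
                      consensus_rule = cfg$consensus_rule)
    say("retained %d RPD variant-gene rows", nrow(rpd$calls))

    stage <- "segregate"
    broad <- find_shared_broad(rpd, cohort, min_shared = cfg$min_shared)
    stringent <- find_shared_stringent(broad, rpd, cohort)
    overlap <- cross_family_overlap(broad, rpd, cohort,
                                    min_shared = cfg$min_shared)
    genes_tab <- gene_summary(broad)
    say("sb-RPD: %d rows (%d genes); ss-RPD: %d rows; overlap: %d genes, %d variants",
        nrow(broad), nrow(genes_tab), nrow(stringent),
        overlap$n_gene_overlap, overlap$n_variant_overlap)

    stage <- "enrich"
    enr <- if (nrow(genes_tab) && length(sets)) {
      specificity_scan(genes_tab$gene, sets, universe_size = universe_size)
    } else data.frame()
    if (nrow(enr))
      say("enrichment: top set %s OR=%.2f p=%.3g", enr$gene_set_name[1],
          enr$odds_ratio[1], enr$p_two_sided[1])

    stage <- "skat"
    skat <- run_association(cohort, rpd, common_geno = vs$geno,
                            units = sets, B = cfg$skat_B, seed = cfg$seed,
                            weights_type = cfg$skat_weights)
    say("SKAT: %d gene sets tested, min p_reported=%.3g", nrow(skat),
        min(skat$p_reported))

    stage <- "report"
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      prioritized = .write_report(rpd$calls,
        file.path(cfg$out_dir, "prioritized_variants.tsv"), hash, cfg$seed),
      segregation = .write_report(
        rbind(broad[!paste(broad$chrom, broad$pos, broad$alt, broad$family_id)
                    %in% paste(stringent$chrom, stringent$pos, stringent$alt,
                               stringent$family_id), , drop = FALSE],
              stringent),
        file.path(cfg$out_dir, "segregation.tsv"), hash, cfg$seed),
      gene_summary = .write_report(genes_tab,
        file.path(cfg$out_dir, "gene_summary.tsv"), hash, cfg$seed),
      enrichment = .write_report(enr,
        file.path(cfg$out_dir, "enrichment.tsv"), hash, cfg$seed),
      skat = .write_report(skat,
        file.path(cfg$out_dir, "skat.tsv"), hash, cfg$seed))
    manifest <- list(
      tool = "pedseg", version = as.character(packageVersion("pedseg")),
      config_hash = hash, seed = cfg$seed,
      started = format(t0, "%Y-%m-%dT%H:%M:%S"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      counts = list(variants = nrow(vs$variants), samples = length(vs$samples),
                    rpd = nrow(rpd$calls), sb_rpd = nrow(broad),
                    ss_rpd = nrow(stringent), genes = nrow(genes_tab)))
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
    paths <- c(paths, manifest = file.path(cfg$out_dir, "manifest.yaml"))
    list(cohort = cohort, vs = vs, rpd = rpd, broad = broad,
         stringent = stringent, overlap = overlap, genes = genes_tab,
         enrichment = enr, skat = skat, manifest = manifest, paths = paths,
         sim = sim)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
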