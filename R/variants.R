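.consequences <- c("stopgain", "stoploss", "startloss", "canonical_splice",
                   "frameshift_indel", "inframe_indel", "missense",
                   "synonymous", "other")

.predictor_cols <- c("pred_sift", "pred_lrt", "pred_mutationtaster",
                     "pred_mutationassessor", "pred_metasvm")

#' Default VCF annotation field mapping
#'
#' Annotation key names in annotated VCFs vary with the annotation tool and
#' version, so the logical fields the analysis needs (gene symbol,
#' consequence class, the two gnomAD allele-frequency fields, and the five
#' deleteriousness predictors SIFT, LRT, MutationTaster, MutationAssessor,
#' MetaSVM) are mapped to concrete INFO keys through a configuration list.
#' Override entries to match your annotation.
#'
#' @param ... named overrides of the default keys (`gene`, `consequence`,
#'   `maf_sas`, `maf_global`, `predictors` — a length-5 named character
#'   vector).
#' @return list of INFO key names.
#' @export
vcf_field_config <- function(...) {
  cfg <- list(
    gene = "GENE",
    consequence = "CSQ",
    maf_sas = "MAF_SAS",
    maf_global = "MAF_GLOBAL",
    predictors = c(pred_sift = "SIFT", pred_lrt = "LRT",
                   pred_mutationtaster = "MUTTASTER",
                   pred_mutationassessor = "MUTASSESSOR",
                   pred_metasvm = "METASVM")
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (length(cfg$predictors) != 5)
    stop("exactly five predictor keys are required")
  cfg
}

#' Construct a variant set
#'
#' @param variants data.frame with one row per biallelic variant: `chrom`,
#'   `pos` (1-based, VCF convention), `ref`, `alt`, `gene`, `consequence`
#'   (one of the recognized classes), `maf_sas`, `maf_global` (in `[0, 1]`
#'   or `NA` when the variant is absent from the reference panel), and the
#'   five predictor-call columns (`"D"` deleterious, `"T"` tolerated, `NA`
#'   missing).
#' @param geno integer matrix, variants x samples, of alternate-allele
#'   counts in `{0, 1, 2, NA}`; hemizygous calls carry dosage 1.
#' @param samples character vector of sample ids naming `geno` columns.
#' @return object of class `pedseg_variants`.
#' @export
new_variant_set <- function(variants, geno, samples) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
              "maf_sas", "maf_global", .predictor_cols)
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols))
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  for (col in c("maf_sas", "maf_global")) {
    v <- variants[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " outside [0, 1]")
  }
  bad <- setdiff(unique(variants$consequence), .consequences)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stop("genotype matrix rows must match variant rows")
  if (ncol(geno) != length(samples))
    stop("genotype matrix columns must match sample ids")
  colnames(geno) <- samples
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno, samples = samples),
            class = "pedseg_variants")
}

#' @export
print.pedseg_variants <- function(x, ...) {
  cat(sprintf("pedseg variant set: %d biallelic variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

.parse_freq <- function(x, key, id) {
  x[x %in% c(".", "", "NA")] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("unparsable ", key, " frequency '", x[bad[1]], "' at record ",
         id[bad[1]])
  out
}

.pick_allele_value <- function(values, k, n_alt) {
  # per-record INFO values may be scalar or comma-separated per ALT allele
  vapply(seq_along(values), function(i) {
    v <- values[i]
    if (is.na(v)) return(NA_character_)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (length(parts) == n_alt[i]) parts[k[i]] else parts[1]
  }, character(1))
}

#' Read an annotated multi-sample VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) carrying per-variant
#' annotations in INFO fields, splits multi-allelic records into biallelic
#' variants, decodes genotypes into unphased alternate-allele counts, and
#' aligns the sample columns to the cohort. Missing annotation values stay
#' missing; the rare-by-absence rule is applied later, during variant
#' prioritization, where it is a documented filtering decision.
#'
#' @param path VCF path.
#' @param cohort a [new_cohort()] object; every VCF sample must be present
#'   in it, and genotype columns are reordered to the cohort's sample order.
#' @param config field mapping from [vcf_field_config()].
#' @return a [new_variant_set()] object.
#' @export
read_annotated_vcf <- function(path, cohort, config = vcf_field_config()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  vcf_samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(vcf_samples, cohort$samples$sample_id)
  if (length(unknown))
    stop("VCF sample(s) absent from cohort: ", paste(unknown, collapse = ", "))

  info_of <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else {
      v[v %in% c(".", "")] <- NA
      v
    }
  }
  gene_raw <- info_of(config$gene)
  csq_raw <- info_of(config$consequence)
  maf_sas_raw <- info_of(config$maf_sas)
  maf_glob_raw <- info_of(config$maf_global)
  pred_raw <- lapply(config$predictors, info_of)

  # expand multi-allelic records: one row per (record, alt allele)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  k <- unlist(lapply(n_alt, seq_len))
  id <- paste0(fix[rec, "CHROM"], ":", fix[rec, "POS"])

  norm_pred <- function(x) {
    x <- toupper(x)
    out <- rep(NA_character_, length(x))
    out[x %in% c("D", "DELETERIOUS")] <- "D"
    out[x %in% c("T", "TOLERATED", "N", "B")] <- "T"
    out
  }
  csq <- .pick_allele_value(csq_raw[rec], k, n_alt[rec])
  csq[is.na(csq) | !(csq %in% .consequences)] <- "other"

  variants <- data.frame(
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alt_list),
    gene = .pick_allele_value(gene_raw[rec], k, n_alt[rec]),
    consequence = csq,
    maf_sas = .parse_freq(.pick_allele_value(maf_sas_raw[rec], k, n_alt[rec]),
                          config$maf_sas, id),
    maf_global = .parse_freq(.pick_allele_value(maf_glob_raw[rec], k, n_alt[rec]),
                             config$maf_global, id),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(.predictor_cols))
    variants[[.predictor_cols[i]]] <-
      norm_pred(.pick_allele_value(pred_raw[[i]][rec], k, n_alt[rec]))

  # allele-count dosage for allele k of each expanded row; "." -> NA;
  # hemizygous single-allele calls count as carriers with dosage 1
  geno <- matrix(NA_integer_, nrow = length(rec), ncol = length(vcf_samples))
  allele_lists <- apply(gt_raw, 2, function(col) strsplit(col, "[/|]"))
  for (j in seq_along(vcf_samples)) {
    al <- allele_lists[[j]]
    geno[, j] <- vapply(seq_along(rec), function(r) {
      a <- al[[rec[r]]]
      if (is.null(a) || all(is.na(a)) || any(a == "."))
        return(NA_integer_)
      sum(a == as.character(k[r]))
    }, integer(1))
  }
  colnames(geno) <- vcf_samples

  # align to cohort sample order, restricted to samples present in the VCF
  keep <- cohort$samples$sample_id[cohort$samples$sample_id %in% vcf_samples]
  new_variant_set(variants, geno[, keep, drop = FALSE], keep)
}

#' Write a variant set as an annotated VCF
#'
#' Emits a minimal VCF 4.2 file whose INFO keys follow `config`; used by the
#' simulator so generated cohorts flow through the same reader as real data.
#'
#' @param vs a `pedseg_variants` object.
#' @param path output path.
#' @param config field mapping from [vcf_field_config()].
#' @export
write_annotated_vcf <- function(vs, path, config = vcf_field_config()) {
  v <- vs$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedseg",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">',
            config$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Consequence class">',
            config$consequence),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="gnomAD South Asian allele frequency">',
            config$maf_sas),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="gnomAD global allele frequency">',
            config$maf_global),
    vapply(config$predictors, function(key) sprintf(
      '##INFO=<ID=%s,Number=1,Type=String,Description="Deleteriousness call (D/T)">',
      key), character(1)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 15))
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- c(
      paste0(config$gene, "=", v$gene[i]),
      paste0(config$consequence, "=", v$consequence[i])
    )
    if (!is.na(v$maf_sas[i]))
      parts <- c(parts, paste0(config$maf_sas, "=", fmt_num(v$maf_sas[i])))
    if (!is.na(v$maf_global[i]))
      parts <- c(parts, paste0(config$maf_global, "=", fmt_num(v$maf_global[i])))
    for (p in seq_along(.predictor_cols)) {
      call <- v[[.predictor_cols[p]]][i]
      if (!is.na(call))
        parts <- c(parts, paste0(config$predictors[p], "=", call))
    }
    paste(parts, collapse = ";")
  }, character(1))
  gt_str <- matrix("./.", nrow = nrow(v), ncol = length(vs$samples))
  gt_str[vs$geno == 0L] <- "0/0"
  gt_str[vs$geno == 1L] <- "0/1"
  gt_str[vs$geno == 2L] <- "1/1"
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene list file
#'
#' One gene symbol per line; blank lines ignored, surrounding whitespace
#' trimmed, duplicates removed. Symbols are matched case-insensitively
#' downstream.
#'
#' @param path path to the list file.
#' @param name label for the gene set (defaults to the file name).
#' @param universe_size number of protein-coding genes the set is drawn
#'   from; the default 20203 is the protein-coding gene count used for the
#'   overrepresentation universe.
#' @return object of class `pedseg_gene_set` with elements `name`, `genes`,
#'   `universe_size`.
#' @export
read_gene_list <- function(path, name = basename(path), universe_size = 20203L) {
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (!length(genes)) stop("gene list is empty: ", path)
  gene_set(genes, name, universe_size)
}

#' Construct a gene set
#'
#' @param genes character vector of gene symbols (deduplicated).
#' @param name label.
#' @param universe_size size of the gene universe.
#' @return `pedseg_gene_set` object.
#' @export
gene_set <- function(genes, name, universe_size = 20203L) {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set must be non-empty")
  if (length(genes) > universe_size)
    stop("gene set larger than its universe")
  structure(list(name = name, genes = genes,
                 universe_size = as.integer(universe_size)),
            class = "pedseg_gene_set")
}

#' Write / read the flat variant table
#'
#' The TSV holds one row per biallelic variant: annotation columns followed
#' by one genotype column per sample (`NA` for missing calls). Reading the
#' file back reproduces the variant set exactly.
#'
#' @param vs a `pedseg_variants` object.
#' @param path file path.
#' @return `write_variant_table` returns `path` invisibly;
#'   `read_variant_table` returns a `pedseg_variants` object.
#' @export
write_variant_table <- function(vs, path) {
  out <- cbind(vs$variants,
               as.data.frame(vs$geno, optional = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  tab$pos <- as.integer(tab$pos)
  anno_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                 "maf_sas", "maf_global", .predictor_cols)
  samples <- setdiff(names(tab), anno_cols)
  geno <- as.matrix(tab[, samples, drop = FALSE])
  storage.mode(geno) <- "integer"
  variants <- tab[, anno_cols, drop = FALSE]
  variants$chrom <- as.character(variants$chrom)
  for (col in c("ref", "alt", "gene", "consequence", .predictor_cols))
    variants[[col]] <- as.character(variants[[col]])
  for (col in c("maf_sas", "maf_global"))
    variants[[col]] <- as.numeric(variants[[col]])
  new_variant_set(variants, geno, samples)
}
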