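#' Carrier count within a sample subset
#'
#' A sample carries a variant when its alternate-allele count is at least
#' one; zygosity is ignored (het and hom-alt both count) and missing
#' genotypes count as non-carriers.
#'
#' @param geno_row integer vector of allele counts, named by sample id.
#' @param sample_subset character vector of sample ids to count within.
#' @return integer carrier count.
#' @export
count_carriers <- function(geno_row, sample_subset) {
  unknown <- setdiff(sample_subset, names(geno_row))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  g <- geno_row[sample_subset]
  sum(!is.na(g) & g >= 1)
}

.carrier_matrix <- function(rpd) {
  g <- rpd$geno[rpd$calls$var_idx, , drop = FALSE]
  m <- !is.na(g) & g >= 1
  colnames(m) <- rpd$samples
  m
}

#' Shared-broad RPD variants (sb-RPD)
#'
#' Within each multiplex family (>= `min_shared` sequenced cases), flags RPD
#' variants carried by at least `min_shared` affected members of that family
#' and by no unrelated control. Families without a sequenced unaffected
#' relative remain eligible: the unrelated-control absence condition carries
#' the specificity burden. A variant segregating in two families yields two
#' rows.
#'
#' @param rpd a `pedseg_rpd` object (RPD rows only).
#' @param cohort a `pedseg_cohort`.
#' @param min_shared minimum number of affected carriers per family
#'   (default 3).
#' @return data.frame of class `pedseg_segregation`, one row per
#'   (variant-gene, family): `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `family_id`, `affected_carriers`, `affected_sequenced`,
#'   `family_control_carriers` (cohort-wide), `unrelated_control_carriers`,
#'   `passes_rarity_stringent`, `tier` (`"shared_broad"` here). Rows are
#'   sorted by (family, chrom, pos, alt) for reproducible output.
#' @export
find_shared_broad <- function(rpd, cohort, min_shared = 3) {
  calls <- rpd$calls
  stopifnot(all(calls$is_rpd))
  empty <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), family_id = character(0),
    affected_carriers = integer(0), affected_sequenced = integer(0),
    family_control_carriers = integer(0),
    unrelated_control_carriers = integer(0),
    passes_rarity_stringent = logical(0), tier = character(0),
    stringsAsFactors = FALSE)
  class(empty) <- c("pedseg_segregation", "data.frame")
  if (!nrow(calls)) return(empty)

  carrier <- .carrier_matrix(rpd)
  s <- cohort$samples
  fams <- select_multisample_families(cohort, min_cases = min_shared)
  if (!length(fams)) return(empty)

  uc <- intersect(s$sample_id[s$role == "unrelated_control"], rpd$samples)
  fc_all <- intersect(s$sample_id[s$role == "family_control"], rpd$samples)
  uc_carriers <- if (length(uc)) rowSums(carrier[, uc, drop = FALSE]) else
    rep(0L, nrow(calls))
  fc_carriers <- if (length(fc_all)) rowSums(carrier[, fc_all, drop = FALSE]) else
    rep(0L, nrow(calls))

  pieces <- lapply(fams, function(f) {
    fam_cases <- intersect(s$sample_id[s$family_id == f & s$role == "case"],
                           rpd$samples)
    n_carr <- rowSums(carrier[, fam_cases, drop = FALSE])
    hit <- which(n_carr >= min_shared & uc_carriers == 0)
    if (!length(hit)) return(NULL)
    data.frame(
      chrom = calls$chrom[hit], pos = calls$pos[hit],
      ref = calls$ref[hit], alt = calls$alt[hit], gene = calls$gene[hit],
      family_id = f,
      affected_carriers = as.integer(n_carr[hit]),
      affected_sequenced = length(fam_cases),
      family_control_carriers = as.integer(fc_carriers[hit]),
      unrelated_control_carriers = as.integer(uc_carriers[hit]),
      passes_rarity_stringent = calls$passes_rarity_stringent[hit],
      tier = "shared_broad",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out <- out[order(out$family_id, out$chrom, out$pos, out$alt, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedseg_segregation", "data.frame")
  out
}

#' Shared-stringent RPD variants (ss-RPD)
#'
#' Upgrades sb-RPD rows that survive the stringent rarity cutoff (allele
#' frequency <= 1e-4 in both panels, applied in [filter_rpd()]) and are
#' carried by at most `max_family_control_carriers` unaffected family
#' controls — the tolerance of one carrier allows for incomplete
#' penetrance. By default the family-control count is cohort-wide; set
#' `per_family = TRUE` to count only the segregating family's own controls.
#'
#' @param broad result of [find_shared_broad()].
#' @param rpd the `pedseg_rpd` object the broad results came from.
#' @param cohort the cohort.
#' @param max_family_control_carriers maximum tolerated unaffected
#'   family-control carriers (default 1).
#' @param per_family count family-control carriers within the segregating
#'   family only (default `FALSE`).
#' @return the subset of `broad` rows meeting the stringent criteria, with
#'   `tier` set to `"shared_stringent"`.
#' @export
find_shared_stringent <- function(broad, rpd, cohort,
                                  max_family_control_carriers = 1,
                                  per_family = FALSE) {
  if (!nrow(broad)) {
    broad$tier <- character(0)
    return(broad)
  }
  fc_count <- broad$family_control_carriers
  if (per_family) {
    s <- cohort$samples
    carrier <- .carrier_matrix(rpd)
    key_rpd <- paste(rpd$calls$chrom, rpd$calls$pos, rpd$calls$alt,
                     rpd$calls$gene)
    key_seg <- paste(broad$chrom, broad$pos, broad$alt, broad$gene)
    fc_count <- vapply(seq_len(nrow(broad)), function(i) {
      fc <- intersect(
        s$sample_id[s$family_id == broad$family_id[i] &
                    s$role == "family_control"], rpd$samples)
      if (!length(fc)) return(0L)
      row <- match(key_seg[i], key_rpd)
      as.integer(sum(carrier[row, fc]))
    }, integer(1))
  }
  keep <- broad$passes_rarity_stringent &
    fc_count <= max_family_control_carriers
  out <- broad[keep, , drop = FALSE]
  out$tier <- rep("shared_stringent", nrow(out))
  rownames(out) <- NULL
  out
}

#' Overlap of segregating genes/variants with the held-out families
#'
#' Families with fewer than three sequenced cases do not enter the sharing
#' analysis, but their RPD variants can corroborate it: this reports which
#' sb-RPD genes also harbor RPD variants in the held-out families (gene
#' level) and which exact sb-RPD variants recur there (variant level).
#'
#' @param shared a `pedseg_segregation` table from the multiplex families.
#' @param rpd_other `pedseg_rpd` calls restricted to carriers in the
#'   held-out (< 3-case) families — pass the full call set plus `cohort`
#'   and the function restricts to samples of non-multiplex families.
#' @param cohort the cohort.
#' @param min_shared threshold used to define the multiplex families
#'   (default 3).
#' @return list with `gene_overlap` (character vector of genes),
#'   `variant_overlap` (data.frame of chrom/pos/ref/alt/gene) and the counts
#'   `n_gene_overlap`, `n_variant_overlap`.
#' @export
cross_family_overlap <- function(shared, rpd_other, cohort, min_shared = 3) {
  s <- cohort$samples
  multi <- select_multisample_families(cohort, min_cases = min_shared)
  held_out <- setdiff(unique(s$family_id[s$family_id != ""]), multi)
  held_samples <- intersect(
    s$sample_id[s$family_id %in% held_out & s$role == "case"],
    rpd_other$samples)
  calls <- rpd_other$calls
  if (length(held_samples) && nrow(calls)) {
    carrier <- .carrier_matrix(rpd_other)
    in_held <- rowSums(carrier[, held_samples, drop = FALSE]) > 0
  } else in_held <- rep(FALSE, nrow(calls))
  held_calls <- calls[in_held, , drop = FALSE]

  gene_overlap <- sort(intersect(unique(shared$gene),
                                 unique(held_calls$gene)))
  key_shared <- unique(paste(shared$chrom, shared$pos, shared$ref, shared$alt))
  key_held <- paste(held_calls$chrom, held_calls$pos, held_calls$ref,
                    held_calls$alt)
  hit <- held_calls[key_held %in% key_shared, c("chrom", "pos", "ref", "alt",
                                                "gene"), drop = FALSE]
  hit <- unique(hit)
  rownames(hit) <- NULL
  list(gene_overlap = gene_overlap,
       variant_overlap = hit,
       n_gene_overlap = length(gene_overlap),
       n_variant_overlap = nrow(hit))
}

#' Per-gene summary of segregating variants
#'
#' Collapses a segregation table to one row per gene, listing the families
#' in which the gene segregates, the best tier reached, and the maximum
#' affected-carrier burden (the count of affected carriers in the family,
#' mirroring a per-family "burden" column).
#'
#' @param shared a `pedseg_segregation` table (broad results, optionally
#'   with stringent rows substituted).
#' @return data.frame with `gene`, `n_families`, `families`
#'   (comma-separated), `tier`, `max_burden`.
#' @export
gene_summary <- function(shared) {
  if (!nrow(shared))
    return(data.frame(gene = character(0), n_families = integer(0),
                      families = character(0), tier = character(0),
                      max_burden = integer(0), stringsAsFactors = FALSE))
  sp <- split(shared, shared$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    fams <- sort(unique(d$family_id))
    data.frame(
      gene = d$gene[1],
      n_families = length(fams),
      families = paste(fams, collapse = ","),
      tier = if (any(d$tier == "shared_stringent")) "shared_stringent"
             else "shared_broad",
      max_burden = max(d$affected_carriers),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
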