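#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

.valid_roles <- c("case", "family_control", "unrelated_control")
.valid_diagnoses <- c("SCZ", "BD", "OCD", "SUD", "mixed")

#' Construct a cohort from a sample table
#'
#' A cohort holds the sequenced samples of a family study: cases and
#' unaffected family controls grouped into pedigrees, plus unrelated
#' population controls (empty `family_id`).
#'
#' @param samples data.frame with columns `sample_id`, `family_id` (empty
#'   string for unrelated controls), `father_id`, `mother_id` (`NA` or "0"
#'   when unknown), `sex` (1 = male, 2 = female, 0 = unknown), `affected`
#'   (logical), `role` (one of `"case"`, `"family_control"`,
#'   `"unrelated_control"`) and optionally `diagnosis`.
#' @return An object of class `pedseg_cohort`: a list with the normalized
#'   `samples` table and `families`, a named list mapping family id to
#'   member sample ids.
#' @export
new_cohort <- function(samples) {
  stopifnot(is.data.frame(samples))
  needed <- c("sample_id", "family_id", "father_id", "mother_id",
              "sex", "affected", "role")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$family_id <- as.character(samples$family_id)
  samples$family_id[is.na(samples$family_id) | samples$family_id == "0"] <- ""
  for (col in c("father_id", "mother_id")) {
    samples[[col]] <- as.character(samples[[col]])
    samples[[col]][samples[[col]] %in% c("0", "")] <- NA_character_
  }
  samples$affected <- as.logical(samples$affected)
  if (!"diagnosis" %in% names(samples)) samples$diagnosis <- NA_character_

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad_role <- setdiff(unique(samples$role), .valid_roles)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (any(samples$role == "case" & !samples$affected))
    stop("role 'case' requires affected status")
  if (any(samples$role == "unrelated_control" & samples$family_id != ""))
    stop("unrelated controls must have empty family_id")
  if (any(samples$role != "unrelated_control" & samples$family_id == ""))
    stop("family members must carry a family_id")

  # parent links must resolve within the same family
  idx <- seq_len(nrow(samples))
  for (col in c("father_id", "mother_id")) {
    has <- which(!is.na(samples[[col]]))
    for (i in has) {
      j <- match(samples[[col]][i], samples$sample_id)
      if (is.na(j))
        stop("sample ", samples$sample_id[i], " references unknown parent ",
             samples[[col]][i])
      if (samples$family_id[j] != samples$family_id[i])
        stop("parent ", samples[[col]][i], " of ", samples$sample_id[i],
             " belongs to a different family")
    }
  }

  fam_ids <- unique(samples$family_id[samples$family_id != ""])
  families <- lapply(fam_ids,
                     function(f) samples$sample_id[samples$family_id == f])
  names(families) <- fam_ids
  structure(list(samples = samples, families = families),
            class = "pedseg_cohort")
}

#' Read a pedigree file into a cohort
#'
#' Reads a tab-separated PED file extended with a seventh `role` column.
#' The first six columns follow the PLINK convention: family id, sample id,
#' father id, mother id, sex, affection status (2 = affected, 1 =
#' unaffected, 0/-9 = unknown treated as unaffected). The role column takes
#' `case`, `family_control` or `unrelated_control`; the standard PED format
#' cannot express the three-way split between affected family members,
#' unaffected relatives and unrelated population controls, hence the
#' required extension. A family id of `0` denotes no family (unrelated
#' controls).
#'
#' @param path path to the 7-column PED file; lines starting with `#` are
#'   skipped.
#' @return A [new_cohort()] object.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character", comment.char = "#",
                    blank.lines.skip = TRUE)
  if (ncol(ped) != 7)
    stop("expected 7 tab-separated columns (6-column PED + role), got ",
         ncol(ped), " in ", path)
  names(ped) <- c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype", "role")
  new_cohort(data.frame(
    sample_id = ped$sample_id,
    family_id = ped$family_id,
    father_id = ped$father_id,
    mother_id = ped$mother_id,
    sex = as.integer(ped$sex),
    affected = ped$phenotype == "2",
    role = ped$role,
    stringsAsFactors = FALSE
  ))
}

#' Write a cohort as a 7-column PED file
#'
#' Inverse of [read_pedigree()]; see that function for the column layout.
#'
#' @param cohort a `pedseg_cohort`.
#' @param path output path.
#' @export
write_pedigree <- function(cohort, path) {
  s <- cohort$samples
  out <- data.frame(
    family_id = ifelse(s$family_id == "", "0", s$family_id),
    sample_id = s$sample_id,
    father_id = ifelse(is.na(s$father_id), "0", s$father_id),
    mother_id = ifelse(is.na(s$mother_id), "0", s$mother_id),
    sex = s$sex,
    phenotype = ifelse(s$affected, 2L, 1L),
    role = s$role,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pedseg_cohort <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "pedseg cohort: %d samples (%d cases, %d family controls, %d unrelated controls) in %d families\n",
    nrow(s), sum(s$role == "case"), sum(s$role == "family_control"),
    sum(s$role == "unrelated_control"), length(x$families)))
  invisible(x)
}

#' Sample ids by role
#'
#' @param cohort a `pedseg_cohort`.
#' @param role one or more of `"case"`, `"family_control"`,
#'   `"unrelated_control"`.
#' @return character vector of sample ids.
#' @export
samples_by_role <- function(cohort, role) {
  role <- match.arg(role, .valid_roles, several.ok = TRUE)
  cohort$samples$sample_id[cohort$samples$role %in% role]
}

#' Families with at least a given number of sequenced cases
#'
#' Multiplex families with three or more sequenced affected members are the
#' substrate of the within-pedigree sharing analysis; families below the
#' threshold are held out and only revisited in the cross-family overlap
#' report.
#'
#' @param cohort a `pedseg_cohort`.
#' @param min_cases minimum number of sequenced cases (default 3).
#' @return character vector of family ids.
#' @export
select_multisample_families <- function(cohort, min_cases = 3) {
  s <- cohort$samples
  cases <- s[s$role == "case", , drop = FALSE]
  if (!nrow(cases)) return(character(0))
  tab <- table(cases$family_id)
  names(tab)[tab >= min_cases]
}
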