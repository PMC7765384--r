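#' Family designs
#'
#' A `family_design` records which VCF samples are affected and which serve
#' as unaffected controls. The cascade's segregation stages are driven
#' entirely by this partition: sharing is required across all affected
#' members, and any number (including zero) of unaffected members can be
#' used for carrier exclusion — the design is not restricted to a trio.
#'
#' @param sample_id Character vector of sample names (non-empty, unique).
#' @param affected Logical vector, one per sample.
#' @param role Optional free-text role per sample (e.g. "sibling",
#'   "father"); defaults to "affected"/"unaffected".
#' @return An object of class `family_design` (a data.frame with columns
#'   `sample_id`, `affected`, `role`).
#' @export
family_design <- function(sample_id, affected, role = NULL) {
  sample_id <- as.character(sample_id)
  affected <- as.logical(affected)
  if (length(sample_id) != length(affected)) {
    stop("sample_id and affected must have equal length")
  }
  if (any(!nzchar(sample_id)) || anyNA(sample_id)) {
    stop("sample ids must be non-empty")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1])
  }
  if (anyNA(affected)) stop("affected status must be TRUE or FALSE")
  if (is.null(role)) role <- ifelse(affected, "affected", "unaffected")
  d <- data.frame(sample_id = sample_id, affected = affected,
                  role = as.character(role), stringsAsFactors = FALSE)
  class(d) <- c("family_design", "data.frame")
  d
}

#' @export
print.family_design <- function(x, ...) {
  cat("<family_design> ", sum(x$affected), " affected, ",
      sum(!x$affected), " unaffected\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Affected / unaffected sample ids of a design
#' @param design A [family_design()].
#' @return Character vector of sample ids.
#' @export
affected_samples <- function(design) design$sample_id[design$affected]

#' @rdname affected_samples
#' @export
unaffected_samples <- function(design) design$sample_id[!design$affected]

#' Read a 6-column PED file into a family design
#'
#' Standard whitespace-delimited PED (FID IID PAT MAT SEX PHENO). Phenotype
#' 2 marks a sample affected, 1 unaffected; 0 and -9 (unknown) exclude the
#' sample with a warning rather than guessing a status. Roles are inferred
#' from the pedigree columns where possible (an id appearing in the PAT/MAT
#' column of another line becomes "father"/"mother").
#'
#' @param path Path to the PED file.
#' @return A [family_design()].
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("PED file '", path, "' has no data lines")
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- vapply(fields, length, integer(1)) < 6
  if (any(short)) {
    stop("PED line ", which(short)[1], " has fewer than 6 columns")
  }
  iid <- vapply(fields, `[`, character(1), 2)
  pat <- vapply(fields, `[`, character(1), 3)
  mat <- vapply(fields, `[`, character(1), 4)
  pheno <- vapply(fields, `[`, character(1), 6)
  if (anyDuplicated(iid)) {
    stop("duplicate sample id in PED: ", iid[duplicated(iid)][1])
  }
  known <- pheno %in% c("1", "2")
  unknown <- pheno %in% c("0", "-9")
  if (any(!known & !unknown)) {
    stop("unrecognized phenotype code '", pheno[!known & !unknown][1],
         "' (expected 1, 2, 0 or -9)")
  }
  if (any(unknown)) {
    warning("excluding sample(s) with unknown phenotype: ",
            paste(iid[unknown], collapse = ", "))
  }
  role <- ifelse(iid %in% pat, "father",
          ifelse(iid %in% mat, "mother",
          ifelse(pheno == "2", "affected", "unaffected")))
  keep <- known
  family_design(iid[keep], pheno[keep] == "2", role[keep])
}

#' Validate a family design against a variant set
#'
#' Passes iff every design sample is present in the variant set and the
#' design has at least one affected member; otherwise fails fatally listing
#' every defect.
#'
#' @param design A [family_design()].
#' @param vset A [variant_set()].
#' @return The design, invisibly, unchanged.
#' @export
validate_design <- function(design, vset) {
  problems <- character()
  absent <- setdiff(design$sample_id, vset$sample_ids)
  if (length(absent)) {
    problems <- c(problems, paste0("design sample(s) not in variant set: ",
                                   paste(absent, collapse = ", ")))
  }
  if (sum(design$affected) < 1) {
    problems <- c(problems, "design has no affected sample")
  }
  if (length(problems)) {
    stop("invalid family design: ", paste(problems, collapse = "; "))
  }
  invisible(design)
}
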