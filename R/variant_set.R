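#' Variant sets
#'
#' A `variant_set` holds normalized biallelic variants with per-sample
#' genotype calls and an annotation bundle per record. It is the container
#' every stage of the filter cascade and every screen operates on.
#'
#' Internally it is a list of three aligned pieces:
#' \describe{
#'   \item{`variants`}{data.frame with identity columns `chrom`, `pos` (1-based,
#'     GRCh37/hg19), `ref`, `alt`, the flag `is_snv`, and the annotation bundle:
#'     `gene`, `full_name`, `transcript`, `rsid`, `consequence`,
#'     `protein_change`, `pop_af`, `classification` (NA encodes missing).}
#'   \item{`gt`}{integer matrix (records x samples) of alternate-allele dosage:
#'     0 hom-ref, 1 het, 2 hom-alt, NA missing call.}
#'   \item{`dp`}{integer matrix (records x samples) of read depth, NA missing.}
#' }
#' Records are kept sorted by (chromosome, position, ref, alt) with numeric
#' chromosome ordering; the key (chrom, pos, ref, alt) is unique and is the
#' only identity used for cross-sample comparison (rsid is annotation only).
#'
#' @param variants data.frame as described above; missing annotation columns
#'   are added as NA.
#' @param gt,dp integer matrices, one row per variant row, one column per
#'   sample in `sample_ids` order.
#' @param sample_ids character vector of sample names.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, gt, dp = NULL, sample_ids = colnames(gt)) {
  stopifnot(is.data.frame(variants))
  for (col in c("chrom", "pos", "ref", "alt")) {
    if (is.null(variants[[col]])) stop("variants lacks column '", col, "'")
  }
  n <- nrow(variants)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  for (col in annotation_columns()) {
    if (is.null(variants[[col]])) {
      variants[[col]] <- if (col == "pop_af") rep(NA_real_, n) else rep(NA_character_, n)
    }
  }
  variants$pop_af <- as.numeric(variants$pop_af)
  if (is.null(variants$is_snv)) {
    variants$is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
      variants$ref %in% c("A", "C", "G", "T") & variants$alt %in% c("A", "C", "G", "T")
  }
  gt <- as_dosage_matrix(gt, n, sample_ids, "gt")
  if (is.null(dp)) dp <- matrix(NA_integer_, n, length(sample_ids),
                                dimnames = list(NULL, sample_ids))
  dp <- as_dosage_matrix(dp, n, sample_ids, "dp")

  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ")
  }
  bad_af <- !is.na(variants$pop_af) & (variants$pop_af < 0 | variants$pop_af > 1)
  if (any(bad_af)) stop("pop_af outside [0, 1]")
  bad_cls <- !is.na(variants$classification) &
    !variants$classification %in% classification_levels()
  if (any(bad_cls)) {
    stop("unknown classification tier: ",
         paste(unique(variants$classification[bad_cls]), collapse = ", "))
  }
  bad_csq <- !is.na(variants$consequence) &
    !variants$consequence %in% consequence_levels()
  if (any(bad_csq)) {
    stop("unknown consequence: ",
         paste(unique(variants$consequence[bad_csq]), collapse = ", "))
  }
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant key: ", key[duplicated(key)][1])
  }

  ord <- variant_order(variants)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  gt <- gt[ord, , drop = FALSE]
  dp <- dp[ord, , drop = FALSE]

  structure(list(variants = variants, gt = gt, dp = dp,
                 sample_ids = as.character(sample_ids)),
            class = "variant_set")
}

annotation_columns <- function() {
  c("gene", "full_name", "transcript", "rsid", "consequence",
    "protein_change", "pop_af", "classification")
}

as_dosage_matrix <- function(m, n, sample_ids, what) {
  if (is.null(m)) stop("'", what, "' matrix is required")
  m <- as.matrix(m)
  if (n == 0 && nrow(m) == 0) {
    m <- matrix(NA_integer_, 0, length(sample_ids))
  }
  if (nrow(m) != n || ncol(m) != length(sample_ids)) {
    stop("'", what, "' must be ", n, " x ", length(sample_ids))
  }
  storage.mode(m) <- "integer"
  colnames(m) <- sample_ids
  m
}

#' Number of variant records in a set
#' @param vset A `variant_set`.
#' @return Integer record count.
#' @export
n_variants <- function(vset) nrow(vset$variants)

#' Subset a variant set by row index or logical mask
#' @param vset A `variant_set`.
#' @param i Logical or integer index over records.
#' @return A `variant_set` with the selected records (order preserved).
#' @export
vset_subset <- function(vset, i) {
  v <- vset$variants[i, , drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v,
                 gt = vset$gt[i, , drop = FALSE],
                 dp = vset$dp[i, , drop = FALSE],
                 sample_ids = vset$sample_ids),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", n_variants(x), " records, ",
      length(x$sample_ids), " samples (",
      paste(x$sample_ids, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

variant_keys <- function(vset) {
  variant_key(vset$variants$chrom, vset$variants$pos,
              vset$variants$ref, vset$variants$alt)
}

# Genotype dosage as zygosity labels used in reports.
zygosity_labels <- function(dosage) {
  out <- rep(NA_character_, length(dosage))
  out[!is.na(dosage) & dosage == 0] <- "Ref"
  out[!is.na(dosage) & dosage == 1] <- "Het"
  out[!is.na(dosage) & dosage >= 2] <- "Hom"
  out
}
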