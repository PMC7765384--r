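#' Default INFO key names used to populate annotations from a VCF
#'
#' When annotations travel inside the VCF rather than in a sidecar table,
#' these INFO keys are read. Every name is overridable; `pop_af` expects a
#' gnomAD-style cohort allele frequency, `classification` a 5-tier
#' ACMG-style label (pathogenic, likely_pathogenic, uncertain,
#' likely_benign, benign).
#'
#' @return Named list of INFO key names.
#' @export
default_info_keys <- function() {
  list(pop_af = "GNOMAD_AF", gene = "GENE", consequence = "CSQ_CLASS",
       classification = "ACMG", transcript = "TRANSCRIPT",
       protein_change = "PCHANGE", full_name = "FULL_NAME")
}

#' Read a multi-sample VCF into a variant set
#'
#' Reads a VCF v4.x file (GT required, DP optional in FORMAT), restricts it
#' to `wanted_samples`, splits multi-allelic sites into one biallelic record
#' per alternate allele (genotype indices remapped to alt-allele dosage),
#' and sorts records by (chrom, pos, ref, alt). Annotation fields are
#' populated from INFO keys when present and left missing otherwise;
#' Number=A INFO values are split per alternate allele. Non-SNV records are
#' retained and flagged via the `is_snv` column (the consequence filter
#' governs them downstream). The ID column supplies the rsid.
#'
#' @param path Path to a VCF file.
#' @param wanted_samples Character vector of sample names to keep, in the
#'   order the returned set should use; `NULL` keeps all header samples.
#' @param info_keys Named list mapping annotation fields to INFO keys, see
#'   [default_info_keys()].
#' @return A [variant_set()].
#' @export
read_multisample_vcf <- function(path, wanted_samples = NULL,
                                 info_keys = default_info_keys()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_cols <- colnames(v@gt)
  if (is.null(gt_cols) || length(gt_cols) < 2) {
    stop("VCF '", path, "' has no sample columns")
  }
  header_samples <- gt_cols[-1]
  if (is.null(wanted_samples)) wanted_samples <- header_samples
  absent <- setdiff(wanted_samples, header_samples)
  if (length(absent)) {
    stop("sample(s) not in VCF header: ", paste(absent, collapse = ", "))
  }

  fix <- v@fix
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    return(variant_set(empty,
                       gt = matrix(NA_integer_, 0, length(wanted_samples)),
                       dp = matrix(NA_integer_, 0, length(wanted_samples)),
                       sample_ids = wanted_samples))
  }

  gtm <- vcfR::extract.gt(v, element = "GT")
  dpm <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) matrix(NA_real_, n_rec, length(header_samples),
                               dimnames = list(NULL, header_samples)))
  gtm <- gtm[, wanted_samples, drop = FALSE]
  dpm <- dpm[, wanted_samples, drop = FALSE]

  # data lines start after the meta header plus the #CHROM line
  first_data_line <- length(v@meta) + 2L

  rows <- vector("list", n_rec)
  gt_rows <- vector("list", n_rec)
  dp_rows <- vector("list", n_rec)
  gt_re <- "^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$"
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    calls <- gtm[i, ]
    calls[is.na(calls)] <- "."
    bad <- !grepl(gt_re, calls)
    if (any(bad)) {
      stop("malformed GT '", calls[which(bad)[1]], "' for sample ",
           wanted_samples[which(bad)[1]], " at line ",
           first_data_line + i - 1L)
    }
    allele_lists <- strsplit(calls, "[/|]")
    max_idx <- suppressWarnings(
      vapply(allele_lists,
             function(a) max(c(-1, as.integer(a[a != "."])), na.rm = TRUE),
             numeric(1)))
    if (any(max_idx > n_alt)) {
      stop("GT allele index exceeds ALT count at line ",
           first_data_line + i - 1L)
    }

    info <- parse_info_field(fix[i, "INFO"])
    id <- fix[i, "ID"]
    rsid <- if (is.na(id) || id == ".") NA_character_ else
      strsplit(id, ";", fixed = TRUE)[[1]][1]

    sub_rows <- vector("list", n_alt)
    sub_gt <- matrix(NA_integer_, n_alt, length(wanted_samples))
    sub_dp <- matrix(as.integer(round(dpm[i, ])), n_alt,
                     length(wanted_samples), byrow = TRUE)
    for (a in seq_len(n_alt)) {
      dosage <- vapply(allele_lists, function(al) {
        if (any(al == ".")) return(NA_integer_)
        sum(as.integer(al) == a)
      }, integer(1))
      sub_gt[a, ] <- dosage
      sub_rows[[a]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        gene = info_value(info, info_keys$gene, a, n_alt),
        full_name = info_value(info, info_keys$full_name, a, n_alt),
        transcript = info_value(info, info_keys$transcript, a, n_alt),
        rsid = rsid,
        consequence = info_value(info, info_keys$consequence, a, n_alt),
        protein_change = info_value(info, info_keys$protein_change, a, n_alt),
        pop_af = suppressWarnings(
          as.numeric(info_value(info, info_keys$pop_af, a, n_alt))),
        classification = info_value(info, info_keys$classification, a, n_alt),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
    gt_rows[[i]] <- sub_gt
    dp_rows[[i]] <- sub_dp
  }

  variants <- do.call(rbind, rows)
  variant_set(variants,
              gt = do.call(rbind, gt_rows),
              dp = do.call(rbind, dp_rows),
              sample_ids = wanted_samples)
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else TRUE)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

# Pull one annotation value for alt allele `a`; Number=A lists are split.
info_value <- function(info, key, a, n_alt) {
  if (is.null(key) || is.null(info[[key]])) return(NA_character_)
  val <- info[[key]]
  if (isTRUE(val)) return(NA_character_)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  out <- if (length(parts) == n_alt) parts[a] else parts[1]
  if (out == "." || out == "") NA_character_ else out
}

#' Read a sidecar annotation table
#'
#' The sidecar dialect is a TSV keyed by (chrom, pos, ref, alt) with any of
#' the annotation columns `gene`, `full_name`, `transcript`, `rsid`,
#' `consequence`, `protein_change`, `pop_af`, `classification`. `.` and `NA`
#' encode missing.
#'
#' @param path Path to the TSV.
#' @return data.frame of annotation rows.
#' @export
read_annotation_tsv <- function(path) {
  tab <- read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  if (!is.null(tab$pop_af)) tab$pop_af <- as.numeric(tab$pop_af)
  tab
}

#' Attach sidecar annotations to a variant set
#'
#' Joins annotation rows onto records by exact (chrom, pos, ref, alt) match
#' (never by rsid). Non-missing sidecar values replace record values; when a
#' record already carries a different non-missing value, the sidecar wins
#' with a warning. Sidecar rows matching no record leave the set unchanged
#' and are reported in a warning. The operation is idempotent.
#'
#' @param vset A [variant_set()].
#' @param table data.frame from [read_annotation_tsv()] (or equivalent).
#' @return The annotated `variant_set`.
#' @export
attach_annotations <- function(vset, table) {
  tkey <- variant_key(table$chrom, table$pos, table$ref, table$alt)
  if (anyDuplicated(tkey)) {
    stop("duplicate annotation key: ", tkey[duplicated(tkey)][1])
  }
  vkey <- variant_keys(vset)
  hit <- match(tkey, vkey)
  n_unmatched <- sum(is.na(hit))
  if (n_unmatched > 0) {
    warning(n_unmatched, " annotation row(s) matched no variant record")
  }
  src <- which(!is.na(hit))
  dst <- hit[src]

  n_conflict <- 0L
  for (col in intersect(annotation_columns(), names(table))) {
    new_vals <- table[[col]][src]
    old_vals <- vset$variants[[col]][dst]
    use <- !is.na(new_vals)
    conflict <- use & !is.na(old_vals) & old_vals != new_vals
    n_conflict <- n_conflict + sum(conflict)
    vset$variants[[col]][dst[use]] <- new_vals[use]
  }
  if (n_conflict > 0) {
    warning(n_conflict, " annotation value(s) conflicted; sidecar value kept")
  }
  # revalidate vocabulary/range constraints on the merged bundle
  variant_set(vset$variants, vset$gt, vset$dp, vset$sample_ids)
}

#' Write a candidate variant table
#'
#' Emits the reporting TSV used for the final candidate list: gene, full
#' name, rsid, chromosome, coordinate, transcript, protein-level effect, and
#' one zygosity column (Ref/Het/Hom) per affected sample (all samples when
#' no design is supplied). Rows follow variant-set order.
#'
#' @param vset A [variant_set()].
#' @param path Output TSV path.
#' @param design Optional [family_design()]; restricts zygosity columns to
#'   the affected samples.
#' @return Invisibly, the number of data rows written.
#' @export
write_candidate_table <- function(vset, path, design = NULL) {
  samples <- if (is.null(design)) vset$sample_ids else affected_samples(design)
  v <- vset$variants
  out <- data.frame(gene = v$gene, full_name = v$full_name, rsid = v$rsid,
                    chrom = v$chrom, pos = v$pos, transcript = v$transcript,
                    effect = v$protein_change, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0("zygosity_", s)]] <- zygosity_labels(vset$gt[, s])
  }
  write_tsv(out, path)
  invisible(nrow(out))
}

#' Read back a candidate variant table
#' @param path Path written by [write_candidate_table()].
#' @return data.frame with the table's columns.
#' @export
read_candidate_table <- function(path) read_tsv(path)
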