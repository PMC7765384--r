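# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
consequence_levels <- function() {
  c("missense", "synonymous", "nonsense", "frameshift", "splice_region",
    "inframe_indel", "utr", "intronic", "other")
}

#' @keywords internal
classification_levels <- function() {
  c("pathogenic", "likely_pathogenic", "uncertain", "likely_benign", "benign")
}

# Numeric-aware chromosome ordering: 1..22, X, Y, MT, then anything else
# lexicographically. "chr" prefixes are ignored for ranking only.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(n), n,
          ifelse(core == "X", 23L,
          ifelse(core == "Y", 24L,
          ifelse(core %in% c("M", "MT"), 25L, 26L))))
  rank
}

# Canonical identity key; coordinates + alleles, never rsid.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Row order used everywhere a VariantSet is materialized.
variant_order <- function(df) {
  order(chrom_rank(df$chrom), df$chrom, df$pos, df$ref, df$alt)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write to '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", "."),
                    stringsAsFactors = FALSE, colClasses = NA, ...)
}
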