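# In-code fixtures shared across test files. Everything is generated at test
# time; nothing binary is stored.

# Write a small VCF from explicit body lines (header built for `samples`).
write_mini_vcf <- function(body, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"AF\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=ACMG,Number=1,Type=String,Description=\"Classification\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# Construct a variant_set directly, with per-record annotation vectors
# recycled as needed. gt/dp given as matrices (records x samples).
make_vset <- function(gt, dp = NULL, samples = colnames(gt),
                      af = NA_real_, csq = "missense", cls = "uncertain",
                      gene = NULL, rsid = NA_character_, chrom = NULL,
                      pos = NULL, ref = "A", alt = "G") {
  n <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- samples
  variants <- data.frame(
    chrom = if (is.null(chrom)) rep("1", n) else chrom,
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    ref = ref, alt = alt,
    gene = if (is.null(gene)) sprintf("G%03d", seq_len(n)) else gene,
    rsid = rsid, consequence = csq, classification = cls, pop_af = af,
    stringsAsFactors = FALSE)
  variant_set(variants, gt, dp, samples)
}

trio_design <- function() {
  family_design(c("A1", "A2", "U1"), c(TRUE, TRUE, FALSE),
                role = c("sibling", "sibling", "father"))
}

# Random variant set exercising missing data and every annotation level;
# independent of the package's synthetic generator.
make_random_vset <- function(n, seed, n_unaffected = 1) {
  set.seed(seed)
  samples <- c("A1", "A2", if (n_unaffected > 0)
    paste0("U", seq_len(n_unaffected)))
  gt <- matrix(sample(c(NA, 0L, 0L, 1L, 1L, 2L), n * length(samples),
                      replace = TRUE),
               n, length(samples), dimnames = list(NULL, samples))
  dp <- matrix(sample(c(NA, 5L, 19L, 20L, 21L, 100L), n * length(samples),
                      replace = TRUE),
               n, length(samples), dimnames = list(NULL, samples))
  vset <- make_vset(
    gt, dp, samples,
    af = ifelse(stats::runif(n) < 0.2, NA,
                round(stats::runif(n, 0, 0.2), 5)),
    csq = sample(c("missense", "synonymous", "nonsense", "intronic", "utr",
                   NA), n, replace = TRUE),
    cls = sample(c("pathogenic", "likely_pathogenic", "uncertain",
                   "likely_benign", "benign", NA), n, replace = TRUE),
    chrom = sample(c("1", "2", "10", "X"), n, replace = TRUE),
    pos = sample.int(1000000L, n))
  design <- family_design(samples, startsWith(samples, "A"))
  list(vset = vset, design = design)
}

vkeys <- function(vset) {
  with(vset$variants, paste(chrom, pos, ref, alt, sep = ":"))
}

# All permutations of a small vector (5! = 120 for the stage order).
all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
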