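#' Configuration of the five-stage filter cascade
#'
#' Thresholds and policies for the family-based screening cascade:
#' population allele frequency, sharing among affected members, exclusion of
#' unaffected carriers, pathogenicity class / coding consequence, and
#' sequencing depth.
#'
#' @param af_threshold Population allele-frequency cut-off as a fraction;
#'   records pass when `pop_af < af_threshold` (strict, so an AF of exactly
#'   1% is removed at the default 0.01).
#' @param missing_af_passes Should records absent from the frequency
#'   resource pass the frequency filter? Default `TRUE`: novel variants are
#'   presumed rare.
#' @param excluded_classes 5-tier classification labels removed at the
#'   class/consequence stage. Default removes `benign` and `likely_benign`,
#'   keeping VUS and above; set to `"benign"` alone for the narrower
#'   reading.
#' @param allowed_consequences Consequence labels that count as potentially
#'   protein-affecting; anything else (synonymous, UTR, intronic, ...) is
#'   removed. A missing consequence is removed (an unannotated record
#'   cannot be confirmed protein-affecting).
#' @param report_consequences Consequences retained in the final reported
#'   candidate set (default missense only); must be a subset of
#'   `allowed_consequences`.
#' @param min_depth Minimum read depth (reads) required in each design
#'   sample with a non-missing depth; `depth >= min_depth` passes.
#' @param affected_missing_gt_policy,unaffected_missing_gt_policy
#'   `"strict_drop"` (default) treats a missing genotype as failing the
#'   segregation stage that consults it — an unverifiable variant is never
#'   promoted; `"lenient_keep"` gives it the benefit of the doubt.
#' @param snv_only If `TRUE`, non-SNV records are removed in a preliminary
#'   stage before the cascade proper (mirrors an SNV-first analysis).
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(af_threshold = 0.01,
                           missing_af_passes = TRUE,
                           excluded_classes = c("benign", "likely_benign"),
                           allowed_consequences = c("missense", "nonsense",
                                                    "frameshift",
                                                    "splice_region",
                                                    "inframe_indel"),
                           report_consequences = "missense",
                           min_depth = 20L,
                           affected_missing_gt_policy = c("strict_drop",
                                                          "lenient_keep"),
                           unaffected_missing_gt_policy = c("strict_drop",
                                                            "lenient_keep"),
                           snv_only = FALSE) {
  affected_missing_gt_policy <- match.arg(affected_missing_gt_policy)
  unaffected_missing_gt_policy <- match.arg(unaffected_missing_gt_policy)
  if (!is.numeric(af_threshold) || length(af_threshold) != 1 ||
      af_threshold <= 0 || af_threshold > 1) {
    stop("af_threshold must be in (0, 1]")
  }
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 0) stop("min_depth must be >= 0")
  bad <- setdiff(excluded_classes, classification_levels())
  if (length(bad)) stop("unknown classification tier: ", paste(bad, collapse = ", "))
  bad <- setdiff(allowed_consequences, consequence_levels())
  if (length(bad)) stop("unknown consequence: ", paste(bad, collapse = ", "))
  extra <- setdiff(report_consequences, allowed_consequences)
  if (length(extra)) {
    stop("report_consequences must be a subset of allowed_consequences (",
         paste(extra, collapse = ", "), ")")
  }
  structure(list(af_threshold = af_threshold,
                 missing_af_passes = isTRUE(missing_af_passes),
                 excluded_classes = excluded_classes,
                 allowed_consequences = allowed_consequences,
                 report_consequences = report_consequences,
                 min_depth = min_depth,
                 affected_missing_gt_policy = affected_missing_gt_policy,
                 unaffected_missing_gt_policy = unaffected_missing_gt_policy,
                 snv_only = isTRUE(snv_only)),
            class = "cascade_config")
}

#' Read a cascade configuration from a key=value file
#'
#' Lines of the form `key = value`; `#` starts a comment. Set-valued fields
#' (`excluded_classes`, `allowed_consequences`, `report_consequences`) are
#' comma-separated; booleans are `true`/`false`. Unknown keys are fatal.
#'
#' @param path Path to the config file.
#' @return A [cascade_config()].
#' @export
read_cascade_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    args[[key]] <- switch(key,
      af_threshold = as.numeric(val),
      min_depth = as.integer(val),
      missing_af_passes = , snv_only = tolower(val) %in% c("true", "1", "yes"),
      excluded_classes = , allowed_consequences = , report_consequences =
        trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
      affected_missing_gt_policy = , unaffected_missing_gt_policy = val,
      stop("unknown config key: '", key, "'"))
  }
  do.call(cascade_config, args)
}

# ---- stage predicates (pure, per record) -----------------------------------

pass_frequency <- function(vset, cfg) {
  af <- vset$variants$pop_af
  ifelse(is.na(af), cfg$missing_af_passes, af < cfg$af_threshold)
}

pass_affected_sharing <- function(vset, design, cfg) {
  aff <- affected_samples(design)
  g <- vset$gt[, aff, drop = FALSE]
  carries <- g >= 1
  if (cfg$affected_missing_gt_policy == "strict_drop") {
    carries[is.na(carries)] <- FALSE
  } else {
    carries[is.na(carries)] <- TRUE
  }
  if (length(aff) == 0) return(rep(TRUE, n_variants(vset)))
  rowSums(carries) == length(aff)
}

pass_unaffected_exclusion <- function(vset, design, cfg) {
  una <- unaffected_samples(design)
  if (length(una) == 0) return(rep(TRUE, n_variants(vset)))
  g <- vset$gt[, una, drop = FALSE]
  carries <- g >= 1
  if (cfg$unaffected_missing_gt_policy == "strict_drop") {
    # absence of the allele cannot be confirmed -> treat as carrying
    carries[is.na(carries)] <- TRUE
  } else {
    carries[is.na(carries)] <- FALSE
  }
  rowSums(carries) == 0
}

pass_class_consequence <- function(vset, cfg) {
  cls <- vset$variants$classification
  csq <- vset$variants$consequence
  # missing classification is treated as uncertain (kept)
  class_ok <- is.na(cls) | !(cls %in% cfg$excluded_classes)
  csq_ok <- !is.na(csq) & csq %in% cfg$allowed_consequences
  class_ok & csq_ok
}

pass_depth <- function(vset, design, cfg, warn = TRUE) {
  d <- vset$dp[, design$sample_id, drop = FALSE]
  if (ncol(d) == 0) return(rep(TRUE, n_variants(vset)))
  all_missing <- rowSums(!is.na(d)) == 0
  ok <- d >= cfg$min_depth
  ok[is.na(ok)] <- TRUE                 # only non-missing depths are asserted
  keep <- rowSums(ok) == ncol(d)
  keep[all_missing] <- TRUE
  if (warn && any(all_missing)) {
    warning(sum(all_missing),
            " record(s) kept with no depth data in any design sample")
  }
  keep
}

# ---- exported single-stage operations --------------------------------------

#' Individual cascade stages
#'
#' Each stage is a pure per-record filter returning the surviving
#' [variant_set()]. [run_cascade()] composes them, in order, with
#' provenance; because the predicates are independent per record the final
#' candidate set does not depend on stage order.
#'
#' * `filter_by_population_frequency()` keeps records with
#'   `pop_af < af_threshold` (missing AF passes by default).
#' * `keep_shared_by_affected()` keeps records where every affected sample
#'   carries at least one alternate allele (het or hom-alt).
#' * `drop_unaffected_carriers()` removes records where any unaffected
#'   sample carries the alternate allele; with zero unaffected samples it is
#'   the identity.
#' * `drop_benign_and_silent()` removes records whose classification is in
#'   `excluded_classes` or whose consequence is outside
#'   `allowed_consequences`.
#' * `enforce_min_depth()` keeps records covered by at least `min_depth`
#'   reads in every design sample that reports a depth.
#'
#' @param vset A [variant_set()] with annotations attached.
#' @param design A [family_design()], validated against `vset`.
#' @param cfg A [cascade_config()].
#' @return The filtered `variant_set`.
#' @name cascade_stages
NULL

#' @rdname cascade_stages
#' @export
filter_by_population_frequency <- function(vset, cfg = cascade_config()) {
  vset_subset(vset, pass_frequency(vset, cfg))
}

#' @rdname cascade_stages
#' @export
keep_shared_by_affected <- function(vset, design, cfg = cascade_config()) {
  vset_subset(vset, pass_affected_sharing(vset, design, cfg))
}

#' @rdname cascade_stages
#' @export
drop_unaffected_carriers <- function(vset, design, cfg = cascade_config()) {
  vset_subset(vset, pass_unaffected_exclusion(vset, design, cfg))
}

#' @rdname cascade_stages
#' @export
drop_benign_and_silent <- function(vset, cfg = cascade_config()) {
  vset_subset(vset, pass_class_consequence(vset, cfg))
}

#' @rdname cascade_stages
#' @export
enforce_min_depth <- function(vset, design, cfg = cascade_config()) {
  vset_subset(vset, pass_depth(vset, design, cfg))
}

cascade_stage_names <- function() {
  c("frequency", "affected_sharing", "unaffected_carrier",
    "class_consequence", "depth")
}

stage_keep <- function(stage, vset, design, cfg, warn_depth = TRUE) {
  switch(stage,
         snv_only = vset$variants$is_snv,
         frequency = pass_frequency(vset, cfg),
         affected_sharing = pass_affected_sharing(vset, design, cfg),
         unaffected_carrier = pass_unaffected_exclusion(vset, design, cfg),
         class_consequence = pass_class_consequence(vset, cfg),
         depth = pass_depth(vset, design, cfg, warn = warn_depth),
         report = !is.na(vset$variants$consequence) &
           vset$variants$consequence %in% cfg$report_consequences,
         stop("unknown stage: ", stage))
}

#' Run the five-stage family filter cascade
#'
#' Applies, in order: population-frequency filter, sharing among affected
#' samples, exclusion of unaffected carriers, pathogenicity-class /
#' consequence filter, and minimum-depth filter; then restricts the
#' reported candidate set to `report_consequences` (missense by default).
#' Every removal is attributed to exactly one stage in the returned
#' [filter trace][write_trace].
#'
#' @param vset A [variant_set()] with annotations attached.
#' @param design A [family_design()]; validated internally.
#' @param cfg A [cascade_config()].
#' @param stage_order Order in which the five stages are applied. The final
#'   candidate set is invariant to this order (the trace is not).
#' @return A list with elements `candidates` (a `variant_set`) and `trace`
#'   (class `filter_trace`: `$stages` telescoping per-stage input/output
#'   counts, `$removal` one row per input record with the stage that removed
#'   it, `"none"` for candidates).
#' @export
run_cascade <- function(vset, design, cfg = cascade_config(),
                        stage_order = cascade_stage_names()) {
  validate_design(design, vset)
  if (!setequal(stage_order, cascade_stage_names()) ||
      length(stage_order) != 5) {
    stop("stage_order must be a permutation of: ",
         paste(cascade_stage_names(), collapse = ", "))
  }
  stages <- c(if (cfg$snv_only) "snv_only", stage_order, "report")

  removal <- data.frame(chrom = vset$variants$chrom, pos = vset$variants$pos,
                        ref = vset$variants$ref, alt = vset$variants$alt,
                        stage = rep("none", n_variants(vset)),
                        stringsAsFactors = FALSE)
  all_keys <- variant_keys(vset)

  counts <- data.frame(stage = stages, n_in = NA_integer_,
                       n_out = NA_integer_, stringsAsFactors = FALSE)
  current <- vset
  for (k in seq_along(stages)) {
    st <- stages[k]
    keep <- stage_keep(st, current, design, cfg)
    counts$n_in[k] <- n_variants(current)
    counts$n_out[k] <- sum(keep)
    dropped <- variant_keys(current)[!keep]
    removal$stage[match(dropped, all_keys)] <- st
    current <- vset_subset(current, keep)
  }

  trace <- structure(list(stages = counts, removal = removal),
                     class = "filter_trace")
  list(candidates = current, trace = trace)
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace>\n")
  print.data.frame(x$stages, row.names = FALSE)
  n_cand <- sum(x$removal$stage == "none")
  cat("candidates retained:", n_cand, "\n")
  invisible(x)
}

#' Write a filter trace as TSV
#'
#' One row per input record with columns chrom, pos, ref, alt, stage (the
#' stage that removed the record, or `none` for surviving candidates).
#'
#' @param trace A `filter_trace` from [run_cascade()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, path) {
  write_tsv(trace$removal, path)
}
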