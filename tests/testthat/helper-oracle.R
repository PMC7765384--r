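# Independent brute-force reference for the cascade: evaluates the
# conjunction of the filter predicates record by record with scalar logic,
# sharing no code with run_cascade.

oracle_keep <- function(vset, design, cfg) {
  aff <- design$sample_id[design$affected]
  una <- design$sample_id[!design$affected]
  n <- nrow(vset$variants)
  keep <- logical(n)
  for (i in seq_len(n)) {
    v <- vset$variants[i, ]

    p_freq <- if (is.na(v$pop_af)) cfg$missing_af_passes else
      v$pop_af < cfg$af_threshold

    p_share <- TRUE
    for (s in aff) {
      g <- vset$gt[i, s]
      ok <- if (is.na(g)) cfg$affected_missing_gt_policy == "lenient_keep" else
        g >= 1
      if (!ok) p_share <- FALSE
    }

    p_excl <- TRUE
    for (s in una) {
      g <- vset$gt[i, s]
      carrier <- if (is.na(g))
        cfg$unaffected_missing_gt_policy == "strict_drop" else g >= 1
      if (carrier) p_excl <- FALSE
    }

    cls_ok <- is.na(v$classification) ||
      !(v$classification %in% cfg$excluded_classes)
    csq_ok <- !is.na(v$consequence) &&
      v$consequence %in% cfg$allowed_consequences
    p_class <- cls_ok && csq_ok

    depths <- vset$dp[i, design$sample_id]
    seen <- depths[!is.na(depths)]
    p_depth <- length(seen) == 0 || all(seen >= cfg$min_depth)

    p_report <- !is.na(v$consequence) &&
      v$consequence %in% cfg$report_consequences

    p_snv <- !cfg$snv_only || isTRUE(v$is_snv)

    keep[i] <- p_freq && p_share && p_excl && p_class && p_depth &&
      p_report && p_snv
  }
  keep
}

oracle_candidate_keys <- function(vset, design, cfg) {
  vkeys(vset)[oracle_keep(vset, design, cfg)]
}
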