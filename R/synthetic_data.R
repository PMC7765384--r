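#' Configuration for the synthetic family VCF generator
#'
#' The generator emulates the statistical structure the cascade assumes: an
#' exome-scale set of biallelic SNVs over a family of affected siblings and
#' unaffected relatives, with planted true candidates (records that pass
#' all five filters) and distractor records each designed to fail exactly
#' one filter and pass all others.
#'
#' @param n_affected,n_unaffected Family shape (defaults: two affected
#'   siblings, one unaffected parent).
#' @param n_planted Number of planted true candidates.
#' @param n_distractors_per_class Distractors per failure class.
#' @param distractor_classes Subset of `common_af` (allele frequency above
#'   the 1% cut-off), `not_shared` (absent from one affected sibling),
#'   `unaffected_carrier` (carried by an unaffected control), `benign_class`
#'   (classified benign/likely benign), `silent_consequence` (synonymous or
#'   non-coding), `low_depth` (read depth below the 20x minimum).
#' @param rare_af,common_af Allele-frequency ranges (fractions) for
#'   rare/planted and common records; the rare range must lie entirely
#'   below, and the common range entirely above, the conventional 0.01
#'   cut-off.
#' @param depth_mean,depth_floor Poisson mean and lower floor for per-sample
#'   read depth at non-low-depth records (defaults 100x, floor 30 — safely
#'   above the 20x minimum).
#' @param low_depth_range Integer range the forced low depths are drawn
#'   from; must lie below the conventional 20-read minimum.
#' @param seed Integer seed; outputs are byte-identical given the seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_affected = 2L, n_unaffected = 1L,
                              n_planted = 5L, n_distractors_per_class = 5L,
                              distractor_classes = c("common_af", "not_shared",
                                                     "unaffected_carrier",
                                                     "benign_class",
                                                     "silent_consequence",
                                                     "low_depth"),
                              rare_af = c(1e-5, 5e-3),
                              common_af = c(0.05, 0.5),
                              depth_mean = 100, depth_floor = 30L,
                              low_depth_range = c(5L, 19L),
                              seed = 1L) {
  counts <- c(n_affected = n_affected, n_unaffected = n_unaffected,
              n_planted = n_planted,
              n_distractors_per_class = n_distractors_per_class)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (n_affected < 1) stop("need at least one affected sample")
  bad <- setdiff(distractor_classes, distractor_class_stages()$class)
  if (length(bad)) stop("unknown distractor class: ", paste(bad, collapse = ", "))
  if ("unaffected_carrier" %in% distractor_classes &&
      n_distractors_per_class > 0 && n_unaffected == 0) {
    stop("unaffected_carrier distractors require at least one unaffected sample")
  }
  if (!(rare_af[1] > 0 && rare_af[2] < 0.01)) {
    stop("rare_af range must lie strictly inside (0, 0.01)")
  }
  if (!(common_af[1] >= 0.01 && common_af[2] <= 1)) {
    stop("common_af range must lie within [0.01, 1]")
  }
  if (depth_floor > depth_mean) stop("depth_floor must not exceed depth_mean")
  if (low_depth_range[2] >= 20) stop("low_depth_range must lie below 20 reads")
  structure(list(n_affected = as.integer(n_affected),
                 n_unaffected = as.integer(n_unaffected),
                 n_planted = as.integer(n_planted),
                 n_distractors_per_class = as.integer(n_distractors_per_class),
                 distractor_classes = distractor_classes,
                 rare_af = rare_af, common_af = common_af,
                 depth_mean = depth_mean,
                 depth_floor = as.integer(depth_floor),
                 low_depth_range = as.integer(low_depth_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# stage of the default cascade each distractor class is designed to fail
distractor_class_stages <- function() {
  data.frame(
    class = c("common_af", "not_shared", "unaffected_carrier", "benign_class",
              "silent_consequence", "low_depth"),
    stage = c("frequency", "affected_sharing", "unaffected_carrier",
              "class_consequence", "class_consequence", "depth"),
    stringsAsFactors = FALSE)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic family VCF with planted ground truth
#'
#' Emits a multi-sample VCF, a sidecar annotation TSV, a PED file and a
#' truth table into `dir`. Planted records satisfy every cascade predicate
#' (rare AF, alternate allele in all affected samples, absent from
#' unaffected samples, missense with an uncertain-or-worse classification,
#' depth at or above the floor); each distractor violates exactly the
#' predicate of its class. Positions are drawn without collision; emitted
#' records are sorted by coordinate, so output bytes depend only on the
#' configuration (same seed, same bytes).
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (must exist).
#' @param prefix Basename prefix for the four output files.
#' @return List with paths `vcf`, `annotations`, `ped`, `truth_file`, the
#'   truth table `truth` (data.frame: chrom, pos, ref, alt, role,
#'   failure_stage — NA for planted records), and the `design`.
#' @export
generate_family_vcf <- function(cfg, dir, prefix = "family") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)

  classes <- if (cfg$n_distractors_per_class > 0) cfg$distractor_classes else
    character()
  roles <- c(rep("planted", cfg$n_planted),
             rep(classes, each = cfg$n_distractors_per_class))
  n <- length(roles)
  aff_ids <- sprintf("AFFECTED%d", seq_len(cfg$n_affected))
  una_ids <- if (cfg$n_unaffected > 0)
    sprintf("UNAFFECTED%d", seq_len(cfg$n_unaffected)) else character()
  samples <- c(aff_ids, una_ids)
  n_s <- length(samples)

  sim <- with_seed(cfg$seed, {
    chrom <- sample(as.character(1:22), n, replace = TRUE)
    pos <- sample.int(50000000L, n)            # globally unique => no collisions
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

    af <- stats::runif(n, cfg$rare_af[1], cfg$rare_af[2])
    af[roles == "common_af"] <- stats::runif(sum(roles == "common_af"),
                                             cfg$common_af[1], cfg$common_af[2])

    classification <- rep("uncertain", n)
    classification[roles == "planted"] <-
      sample(c("uncertain", "likely_pathogenic", "pathogenic"),
             sum(roles == "planted"), replace = TRUE)
    classification[roles == "benign_class"] <-
      sample(c("benign", "likely_benign"),
             sum(roles == "benign_class"), replace = TRUE)

    consequence <- rep("missense", n)
    consequence[roles == "silent_consequence"] <-
      sample(c("synonymous", "utr", "intronic"),
             sum(roles == "silent_consequence"), replace = TRUE)

    gt <- matrix(0L, n, n_s, dimnames = list(NULL, samples))
    gt[, aff_ids] <- 1L
    if (any(roles == "not_shared")) {
      gt[roles == "not_shared", aff_ids[1]] <- 0L
    }
    if (any(roles == "unaffected_carrier")) {
      gt[roles == "unaffected_carrier", una_ids[1]] <- 1L
    }

    dp <- matrix(pmax(cfg$depth_floor,
                      stats::rpois(n * n_s, cfg$depth_mean)),
                 n, n_s, dimnames = list(NULL, samples))
    if (any(roles == "low_depth")) {
      k <- sum(roles == "low_depth")
      dp[roles == "low_depth", ] <-
        matrix(sample(seq(cfg$low_depth_range[1], cfg$low_depth_range[2]),
                      k * n_s, replace = TRUE), k, n_s)
    }
    list(chrom = chrom, pos = pos, ref = ref, alt = alt, af = af,
         classification = classification, consequence = consequence,
         gt = gt, dp = dp)
  })

  variants <- data.frame(
    chrom = sim$chrom, pos = sim$pos, ref = sim$ref, alt = sim$alt,
    gene = sprintf("SYNG%04d", seq_len(n)),
    full_name = NA_character_,
    transcript = sprintf("NM_9%05d.1", seq_len(n)),
    rsid = NA_character_,
    consequence = sim$consequence,
    protein_change = sprintf("p.Ala%dVal", 100L + seq_len(n)),
    pop_af = sim$af,
    classification = sim$classification,
    stringsAsFactors = FALSE)

  vset <- variant_set(variants, sim$gt, sim$dp, samples)

  stage_of <- stats::setNames(distractor_class_stages()$stage,
                              distractor_class_stages()$class)
  truth <- data.frame(chrom = sim$chrom, pos = sim$pos, ref = sim$ref,
                      alt = sim$alt, role = roles,
                      failure_stage = ifelse(roles == "planted",
                                             NA_character_,
                                             unname(stage_of[roles])),
                      stringsAsFactors = FALSE)
  truth <- truth[variant_order(truth), , drop = FALSE]
  rownames(truth) <- NULL

  design <- family_design(samples, samples %in% aff_ids,
                          role = c(rep("sibling", cfg$n_affected),
                                   if (cfg$n_unaffected > 0) "father",
                                   rep("relative",
                                       max(0, cfg$n_unaffected - 1L))))

  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                annotations = file.path(dir, paste0(prefix, "_annotations.tsv")),
                ped = file.path(dir, paste0(prefix, ".ped")),
                truth_file = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_family_vcf(vset, paths$vcf)
  write_annotation_sidecar(vset, paths$annotations)
  write_ped(design, paths$ped)
  write_tsv(truth, paths$truth_file)
  c(paths, list(truth = truth, design = design))
}

#' Ground-truth helpers for generated data
#'
#' @param truth Truth table from [generate_family_vcf()].
#' @return `planted_keys()`: character keys (chrom:pos:ref:alt) of planted
#'   records; `distractor_stages()`: named character vector mapping each
#'   distractor key to its designed failure stage.
#' @export
planted_keys <- function(truth) {
  with(truth[truth$role == "planted", ], variant_key(chrom, pos, ref, alt))
}

#' @rdname planted_keys
#' @export
distractor_stages <- function(truth) {
  d <- truth[truth$role != "planted", ]
  stats::setNames(d$failure_stage, variant_key(d$chrom, d$pos, d$ref, d$alt))
}

# ---- plain-text emitters (the dialects the readers consume) ----------------

write_family_vcf <- function(vset, path) {
  v <- vset$variants
  chroms <- unique(v$chrom)
  chroms <- chroms[order(chrom_rank(chroms), chroms)]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trioscreen",
    sprintf("##contig=<ID=%s>", chroms),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vset$sample_ids), collapse = "\t"))
  gt_str <- matrix("./.", n_variants(vset), length(vset$sample_ids))
  gt_str[!is.na(vset$gt) & vset$gt == 0] <- "0/0"
  gt_str[!is.na(vset$gt) & vset$gt == 1] <- "0/1"
  gt_str[!is.na(vset$gt) & vset$gt >= 2] <- "1/1"
  dp_str <- ifelse(is.na(vset$dp), ".", as.character(vset$dp))
  calls <- matrix(paste(gt_str, dp_str, sep = ":"),
                  nrow = n_variants(vset))
  body <- vapply(seq_len(n_variants(vset)), function(i) {
    paste(c(v$chrom[i], v$pos[i],
            if (is.na(v$rsid[i])) "." else v$rsid[i],
            v$ref[i], v$alt[i], ".", "PASS", ".", "GT:DP",
            calls[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

write_annotation_sidecar <- function(vset, path) {
  v <- vset$variants
  out <- v[, c("chrom", "pos", "ref", "alt", "gene", "full_name",
               "transcript", "rsid", "consequence", "protein_change",
               "pop_af", "classification")]
  write_tsv(out, path)
}

write_ped <- function(design, path, family_id = "FAM1") {
  father <- design$sample_id[design$role == "father"]
  father <- if (length(father)) father[1] else "0"
  lines <- vapply(seq_len(nrow(design)), function(i) {
    s <- design[i, ]
    pat <- if (s$role %in% c("father", "mother")) "0" else father
    sex <- if (i == 1) "2" else "1"
    paste(family_id, s$sample_id, pat, "0", sex,
          if (s$affected) "2" else "1", sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
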