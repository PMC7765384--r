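# One shared 3-sample layout: rows are records, columns A1, A2 (affected),
# U1 (unaffected father).
gt3 <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  colnames(m) <- c("A1", "A2", "U1")
  m
}

test_that("frequency filter: strict cut-off, missing AF policy", {
  vset <- make_vset(gt3(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
                    af = c(0.5, NA, 1e-4, 0.01))
  cfg <- cascade_config()
  kept <- filter_by_population_frequency(vset, cfg)
  expect_equal(kept$variants$pop_af, c(NA, 1e-4))  # 0.5 out; exactly 1% out
  cfg2 <- cascade_config(missing_af_passes = FALSE)
  kept2 <- filter_by_population_frequency(vset, cfg2)
  expect_equal(kept2$variants$pop_af, 1e-4)
})

test_that("affected sharing requires allele presence in every affected sample", {
  vset <- make_vset(gt3(1, 1, 0,    # het/het -> shared
                        1, 2, 0,    # het/hom-alt -> shared
                        1, 0, 0,    # one sibling ref -> not shared
                        1, NA, 0))  # one sibling missing
  d <- trio_design()
  kept <- keep_shared_by_affected(vset, d, cascade_config())
  expect_equal(vkeys(kept), vkeys(vset)[1:2])
  lenient <- cascade_config(affected_missing_gt_policy = "lenient_keep")
  kept2 <- keep_shared_by_affected(vset, d, lenient)
  expect_equal(vkeys(kept2), vkeys(vset)[c(1, 2, 4)])
})

test_that("unaffected carriers are excluded; zero unaffected is the identity", {
  vset <- make_vset(gt3(1, 1, 0,    # father ref -> kept
                        1, 1, 1,    # father het -> removed
                        1, 1, 2,    # father hom-alt -> removed
                        1, 1, NA))  # father missing
  d <- trio_design()
  kept <- drop_unaffected_carriers(vset, d, cascade_config())
  expect_equal(vkeys(kept), vkeys(vset)[1])      # strict: missing drops too
  lenient <- cascade_config(unaffected_missing_gt_policy = "lenient_keep")
  kept2 <- drop_unaffected_carriers(vset, d, lenient)
  expect_equal(vkeys(kept2), vkeys(vset)[c(1, 4)])

  no_controls <- family_design(c("A1", "A2"), c(TRUE, TRUE))
  kept3 <- drop_unaffected_carriers(vset, no_controls, cascade_config())
  expect_equal(vkeys(kept3), vkeys(vset))
})

test_that("class/consequence filter drops benign tiers and silent variants", {
  vset <- make_vset(gt3(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
                    cls = c("benign", "likely_benign", "uncertain",
                            "uncertain", NA),
                    csq = c("missense", "missense", "synonymous",
                            "missense", "missense"))
  kept <- drop_benign_and_silent(vset, cascade_config())
  expect_equal(kept$variants$classification, c("uncertain", NA))
  # literal reading: only 'benign' excluded, one flag away
  narrow <- cascade_config(excluded_classes = "benign")
  kept2 <- drop_benign_and_silent(vset, narrow)
  expect_equal(kept2$variants$classification,
               c("likely_benign", "uncertain", NA))
  # missing consequence cannot be confirmed protein-affecting
  vset3 <- make_vset(gt3(1, 1, 0), csq = NA)
  expect_equal(n_variants(drop_benign_and_silent(vset3, cascade_config())), 0L)
})

test_that("depth filter: >= 20 passes, any covered sample below fails,
           all-missing depth kept with a warning", {
  dp <- gt3(100, 100, 100,
            19, 100, 100,
            20, 20, 20,
            NA, NA, NA,
            NA, 100, 100)
  vset <- make_vset(gt3(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0), dp = dp)
  d <- trio_design()
  expect_warning(kept <- enforce_min_depth(vset, d, cascade_config()),
                 "no depth data")
  expect_equal(vkeys(kept), vkeys(vset)[c(1, 3, 4, 5)])
})

test_that("run_cascade composes the stages with a telescoping trace", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_planted = 4, n_distractors_per_class = 3,
                           seed = 7)
  sim <- generate_family_vcf(cfg, dir)
  vset <- attach_annotations(
    read_multisample_vcf(sim$vcf, wanted_samples = sim$design$sample_id),
    read_annotation_tsv(sim$annotations))
  res <- run_cascade(vset, sim$design)

  st <- res$trace$stages
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])         # telescoping
  expect_equal(st$n_in[1], n_variants(vset))
  expect_equal(st$n_out[nrow(st)], n_variants(res$candidates))
  # every record is attributed to exactly one stage; 'none' = candidates
  expect_equal(sum(res$trace$removal$stage == "none"),
               n_variants(res$candidates))
  expect_equal(nrow(res$trace$removal), n_variants(vset))
  for (k in seq_len(nrow(st))) {
    expect_equal(st$n_in[k] - st$n_out[k],
                 sum(res$trace$removal$stage == st$stage[k]),
                 info = st$stage[k])
  }

  # trace TSV round-trip
  out <- tempfile(fileext = ".tsv")
  write_trace(res$trace, out)
  back <- read.delim(out, stringsAsFactors = FALSE)
  expect_equal(nrow(back), n_variants(vset))

  # empty input
  empty <- vset_subset(vset, integer())
  res0 <- run_cascade(empty, sim$design)
  expect_equal(n_variants(res0$candidates), 0L)
  expect_true(all(res0$trace$stages$n_in == 0L))
})

test_that("candidate set is invariant to stage order", {
  base <- c("frequency", "affected_sharing", "unaffected_carrier",
            "class_consequence", "depth")
  for (seed in 1:5) {
    rnd <- make_random_vset(40, seed)
    ref <- suppressWarnings(run_cascade(rnd$vset, rnd$design))
    for (k in 1:10) {
      perm <- sample(base)
      res <- suppressWarnings(
        run_cascade(rnd$vset, rnd$design, stage_order = perm))
      expect_setequal(vkeys(res$candidates), vkeys(ref$candidates))
    }
  }
})

test_that("cascade equals the brute-force conjunction oracle", {
  for (seed in 1:10) {
    rnd <- make_random_vset(80, seed, n_unaffected = seed %% 3)
    cfg <- if (seed %% 2 == 0) cascade_config() else
      cascade_config(affected_missing_gt_policy = "lenient_keep",
                     unaffected_missing_gt_policy = "lenient_keep",
                     excluded_classes = "benign", min_depth = 21L)
    res <- suppressWarnings(run_cascade(rnd$vset, rnd$design, cfg))
    expect_setequal(vkeys(res$candidates),
                    oracle_candidate_keys(rnd$vset, rnd$design, cfg))
  }
})

test_that("snv_only removes indels ahead of the cascade", {
  variants <- data.frame(chrom = "1", pos = c(100L, 200L), ref = c("A", "AT"),
                         alt = c("G", "A"), consequence = "missense",
                         classification = "uncertain", pop_af = 1e-4,
                         stringsAsFactors = FALSE)
  gt <- gt3(1, 1, 0, 1, 1, 0)
  vset <- variant_set(variants, gt, sample_ids = c("A1", "A2", "U1"))
  d <- trio_design()
  res <- suppressWarnings(
    run_cascade(vset, d, cascade_config(snv_only = TRUE)))
  expect_equal(res$candidates$variants$ref, "A")
  expect_equal(res$trace$removal$stage[res$trace$removal$ref == "AT"],
               "snv_only")
})

test_that("cascade_config validates its invariants", {
  expect_error(cascade_config(af_threshold = 0), "af_threshold")
  expect_error(cascade_config(af_threshold = 1.5), "af_threshold")
  expect_error(cascade_config(min_depth = -1), "min_depth")
  expect_error(cascade_config(report_consequences = "synonymous"), "subset")
  expect_error(cascade_config(excluded_classes = "awful"), "classification")
  expect_error(cascade_config(affected_missing_gt_policy = "maybe"))
})

test_that("key=value config files reproduce a configuration", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("af_threshold = 0.005",
               "min_depth = 30",
               "missing_af_passes = false",
               "excluded_classes = benign  # literal reading",
               "report_consequences = missense,nonsense",
               "allowed_consequences = missense,nonsense,frameshift",
               "snv_only = true"), path)
  cfg <- read_cascade_config(path)
  expect_equal(cfg$af_threshold, 0.005)
  expect_equal(cfg$min_depth, 30L)
  expect_false(cfg$missing_af_passes)
  expect_equal(cfg$excluded_classes, "benign")
  expect_equal(cfg$report_consequences, c("missense", "nonsense"))
  expect_true(cfg$snv_only)
  writeLines("frobnicate = 1", path)
  expect_error(read_cascade_config(path), "unknown config key")
})
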