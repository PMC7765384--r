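test_that("multi-allelic sites split into biallelic records conserving alleles", {
  path <- write_mini_vcf(
    "1\t100\trs1\tA\tG,C\t.\t.\tGNOMAD_AF=0.001,0.2\tGT:DP\t0/1:30\t1/2:25\t2/2:40")
  vset <- read_multisample_vcf(path)

  expect_equal(n_variants(vset), 2L)
  expect_equal(vset$variants$alt, c("C", "G"))  # sorted by (chrom,pos,ref,alt)
  g_row <- which(vset$variants$alt == "G")
  c_row <- which(vset$variants$alt == "C")
  expect_equal(unname(vset$gt[g_row, ]), c(1L, 1L, 0L))
  expect_equal(unname(vset$gt[c_row, ]), c(0L, 1L, 2L))
  # allele observations conserved: alt-allele count per sample sums to the
  # original multi-allelic genotype's non-ref allele count
  expect_equal(unname(colSums(vset$gt)), c(1L, 2L, 2L))
  # Number=A INFO split per alt
  expect_equal(vset$variants$pop_af[g_row], 0.001)
  expect_equal(vset$variants$pop_af[c_row], 0.2)
  expect_equal(vset$variants$rsid, c("rs1", "rs1"))
  expect_equal(unname(vset$dp[g_row, ]), c(30L, 25L, 40L))
})

test_that("header-only VCF gives an empty set that keeps its samples", {
  path <- write_mini_vcf(character())
  vset <- read_multisample_vcf(path)
  expect_equal(n_variants(vset), 0L)
  expect_equal(vset$sample_ids, c("S1", "S2", "S3"))
})

test_that("sample selection restricts and reorders; absences are fatal by name", {
  path <- write_mini_vcf(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0/1:30\t0/0:25\t1/1:40")
  vset <- read_multisample_vcf(path, wanted_samples = c("S3", "S1"))
  expect_equal(vset$sample_ids, c("S3", "S1"))
  expect_equal(unname(vset$gt[1, ]), c(2L, 1L))
  expect_error(read_multisample_vcf(path, wanted_samples = c("S1", "S9")),
               "S9")
})

test_that("malformed genotypes are fatal with the offending line number", {
  path <- write_mini_vcf(c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0/1:30\t0/0:25\t1/1:40",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT:DP\t0/x:30\t0/0:25\t0/0:40"))
  expect_error(read_multisample_vcf(path), "line 10")
  path2 <- write_mini_vcf(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0/2:30\t0/0:25\t0/0:40")
  expect_error(read_multisample_vcf(path2), "exceeds ALT count")
})

test_that("non-SNV records are retained but flagged", {
  path <- write_mini_vcf(c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/1\t0/0",
    "1\t200\t.\tCT\tC\t.\t.\t.\tGT\t0/1\t0/1\t0/0"))
  vset <- read_multisample_vcf(path)
  expect_equal(n_variants(vset), 2L)
  expect_equal(vset$variants$is_snv, c(TRUE, FALSE))
})

test_that("annotation join is exact on coordinates, sidecar wins, idempotent", {
  path <- write_mini_vcf(
    "1\t100\t.\tA\tG\t.\t.\tGENE=OLD;CSQ_CLASS=missense\tGT\t0/1\t0/1\t0/0")
  vset <- read_multisample_vcf(path)
  expect_true(is.na(vset$variants$pop_af))

  tab <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene = "NEW", pop_af = 1e-4, stringsAsFactors = FALSE)
  expect_warning(v2 <- attach_annotations(vset, tab), "conflicted")
  expect_equal(v2$variants$pop_af, 1e-4)
  expect_equal(v2$variants$gene, "NEW")              # sidecar wins
  expect_equal(v2$variants$consequence, "missense")  # untouched field kept

  # second attachment is a no-op and raises no conflict warning
  expect_silent(v3 <- attach_annotations(v2, tab))
  expect_identical(v2, v3)

  # unmatched sidecar row: set unchanged, one warning
  orphan <- data.frame(chrom = "9", pos = 1L, ref = "A", alt = "T",
                       pop_af = 0.5, stringsAsFactors = FALSE)
  expect_warning(v4 <- attach_annotations(v2, orphan), "matched no variant")
  expect_identical(v4$variants, v2$variants)

  dup <- rbind(tab, tab)
  expect_error(attach_annotations(vset, dup), "duplicate annotation key")
})

test_that("candidate table writes, counts rows, and round-trips key fields", {
  fx <- build_family_fixture(withr::local_tempdir())
  design <- read_ped(fx$ped)
  vset <- read_multisample_vcf(fx$vcf, wanted_samples = design$sample_id)
  vset <- attach_annotations(vset, read_annotation_tsv(fx$annotations))
  res <- run_cascade(vset, design)

  out <- tempfile(fileext = ".tsv")
  n <- write_candidate_table(res$candidates, out, design = design)
  expect_equal(n, 27L)

  back <- read_candidate_table(out)
  v <- res$candidates$variants
  expect_equal(back$gene, v$gene)
  expect_equal(as.character(back$rsid), v$rsid)
  expect_equal(as.character(back$chrom), v$chrom)
  expect_equal(back$pos, v$pos)
  expect_equal(back$effect, v$protein_change)
  expect_true(all(back$zygosity_PATIENT1 == "Het"))
  expect_true(all(back$zygosity_PATIENT2 == "Het"))
  expect_false("zygosity_FATHER" %in% names(back))

  # empty set: header-only file, zero rows
  empty <- vset_subset(res$candidates, integer())
  out2 <- tempfile(fileext = ".tsv")
  expect_equal(write_candidate_table(empty, out2), 0L)
  expect_equal(length(readLines(out2)), 1L)
})

test_that("fixture carries the printed gene/coordinate/transcript fields", {
  fx <- build_family_fixture(withr::local_tempdir())
  vset <- read_multisample_vcf(fx$vcf)
  vset <- attach_annotations(vset, read_annotation_tsv(fx$annotations))
  v <- vset$variants

  pla2g6 <- v[!is.na(v$gene) & v$gene == "PLA2G6", ]
  expect_equal(pla2g6$chrom, "22")
  expect_equal(pla2g6$pos, 38528920L)
  expect_equal(pla2g6$rsid, "rs780423461")

  zfat <- v[!is.na(v$gene) & v$gene == "ZFAT", ]
  expect_equal(zfat$transcript, "NM_020863.3")
  expect_equal(zfat$protein_change, "p.Arg930Cys")

  adcy3 <- v[!is.na(v$gene) & v$gene == "ADCY3", ]
  expect_equal(adcy3$pos, 25050928L)
  expect_equal(adcy3$protein_change, "p.Val759Met")

  bcl3 <- v[!is.na(v$gene) & v$gene == "BCL3", ]
  expect_equal(bcl3$pos, 45262063L)
  expect_equal(bcl3$rsid, "rs747655476")

  # the transcription itself: 27 variants over 25 genes, three on OXNAD1
  cand <- candidate_variant_table()
  expect_equal(nrow(cand), 27L)
  expect_equal(length(unique(cand$gene)), 25L)
  expect_equal(sum(cand$gene == "OXNAD1"), 3L)
  expect_equal(sort(cand$pos[cand$gene == "OXNAD1"]),
               c(16343175L, 16343176L, 16343177L))

  # father is hom-ref at every transcribed candidate site
  ck <- with(cand, paste(chrom, pos, ref, alt, sep = ":"))
  idx <- match(ck, vkeys(vset))
  expect_true(all(vset$gt[idx, "FATHER"] == 0L))
  expect_true(all(vset$gt[idx, c("PATIENT1", "PATIENT2")] == 1L))
})

test_that("variant_set enforces its invariants", {
  gt <- matrix(0L, 2, 2, dimnames = list(NULL, c("A", "B")))
  df <- data.frame(chrom = "1", pos = c(1L, 1L), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  expect_error(variant_set(df, gt), "duplicate variant key")
  df2 <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "A",
                    stringsAsFactors = FALSE)
  expect_error(variant_set(df2, gt), "must differ")
  df3 <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                    pop_af = c(0.5, 1.5), stringsAsFactors = FALSE)
  expect_error(variant_set(df3, gt), "pop_af")
  df4 <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                    classification = "bad_tier", stringsAsFactors = FALSE)
  expect_error(variant_set(df4, gt), "classification")
})
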