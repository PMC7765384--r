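#' Load the packaged sibling-pair candidate variant transcription
#'
#' The package ships a transcription of the 27 candidate missense variants
#' reported in a familial antiphospholipid-syndrome exome study (two
#' affected siblings, unaffected father): gene, full name, rsid where one
#' was printed, GRCh37 chromosome/coordinate, RefSeq transcript, protein
#' change, and ref/alt alleles. One gene (OXNAD1) contributes three adjacent
#' variants. The `allele_source` column records whether ref/alt come from a
#' printed allele pair or were derived from the printed c. notation —
#' either way they are transcription-level stand-ins, not validated genomic
#' alleles.
#'
#' @return data.frame with 27 rows.
#' @export
candidate_variant_table <- function() {
  path <- system.file("extdata", "aps_candidate_variants.tsv",
                      package = "trioscreen", mustWork = TRUE)
  tab <- read_tsv(path)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Build the packaged family case-study fixture
#'
#' Writes a trio VCF (two affected siblings PATIENT1/PATIENT2, unaffected
#' FATHER), a sidecar annotation TSV and a PED file reconstructing the
#' case-study inputs so that the published candidate count is reproducible
#' without any download. It contains:
#'
#' * the 27 transcribed candidate missense variants, heterozygous in both
#'   siblings and hom-ref in the father, with synthetic population AF
#'   (1e-4), classification `uncertain` and depth 100x (the study printed
#'   neither AF nor depth per variant; these values sit safely inside the
#'   passing region and are fixture metadata, not study data);
#' * six common (AF >= 5%) benign missense variants on APOH
#'   (beta-2-glycoprotein I) shared by the two siblings — synthetic
#'   stand-ins for the study's six shared common APOH polymorphisms, whose
#'   identities were not published;
#' * three common benign variants in thrombophilia-panel genes carried by
#'   all three family members;
#' * three rare missense variants also carried by the father.
#'
#' The cascade therefore genuinely filters: 39 records in, 27 candidates
#' out.
#'
#' @param dir Output directory (must exist).
#' @param prefix Basename prefix for the emitted files.
#' @return List with paths `vcf`, `annotations`, `ped`, the `candidates`
#'   transcription table, and the trio `design`.
#' @export
build_family_fixture <- function(dir, prefix = "aps_family") {
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  cand <- candidate_variant_table()
  n_c <- nrow(cand)
  samples <- c("PATIENT1", "PATIENT2", "FATHER")

  cand_v <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
    gene = cand$gene, full_name = cand$full_name,
    transcript = cand$transcript, rsid = cand$rsid,
    consequence = "missense", protein_change = cand$protein_change,
    pop_af = 1e-4, classification = "uncertain", stringsAsFactors = FALSE)
  cand_gt <- matrix(c(1L, 1L, 0L), n_c, 3, byrow = TRUE)

  apoh <- data.frame(
    chrom = "17", pos = 64210101L + 100L * (0:5), ref = "A", alt = "G",
    gene = "APOH", full_name = "Beta-2-glycoprotein I (apolipoprotein H)",
    transcript = "NM_000042.3", rsid = NA_character_,
    consequence = "missense", protein_change = NA_character_,
    pop_af = c(0.12, 0.18, 0.25, 0.31, 0.38, 0.45),
    classification = "benign", stringsAsFactors = FALSE)
  apoh_gt <- cbind(rep(1L, 6), rep(1L, 6), c(1L, 0L, 1L, 0L, 1L, 0L))

  thromb <- data.frame(
    chrom = c("1", "11", "1"), pos = c(169480000L, 46740000L, 11850000L),
    ref = c("G", "C", "A"), alt = c("A", "T", "G"),
    gene = c("F5", "F2", "MTHFR"), full_name = NA_character_,
    transcript = NA_character_, rsid = NA_character_,
    consequence = "missense", protein_change = NA_character_,
    pop_af = c(0.35, 0.22, 0.40), classification = "benign",
    stringsAsFactors = FALSE)
  thromb_gt <- matrix(1L, 3, 3)

  father_carried <- data.frame(
    chrom = c("2", "4", "11"), pos = c(179400000L, 74270000L, 76850000L),
    ref = c("C", "G", "T"), alt = c("T", "A", "C"),
    gene = c("TTN", "ALB", "MYO7A"), full_name = NA_character_,
    transcript = NA_character_, rsid = NA_character_,
    consequence = "missense", protein_change = NA_character_,
    pop_af = 2e-4, classification = "uncertain", stringsAsFactors = FALSE)
  father_gt <- matrix(1L, 3, 3)

  variants <- rbind(cand_v, apoh, thromb, father_carried)
  gt <- rbind(cand_gt, apoh_gt, thromb_gt, father_gt)
  dp <- matrix(100L, nrow(variants), 3)
  vset <- variant_set(variants, gt, dp, samples)

  design <- family_design(samples, c(TRUE, TRUE, FALSE),
                          role = c("sibling", "sibling", "father"))

  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                annotations = file.path(dir, paste0(prefix, "_annotations.tsv")),
                ped = file.path(dir, paste0(prefix, ".ped")))
  write_family_vcf(vset, paths$vcf)
  write_annotation_sidecar(vset, paths$annotations)
  write_ped(design, paths$ped)
  c(paths, list(candidates = cand, design = design))
}
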