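# trioscreen

Family-based rare-variant prioritization from multi-sample whole-exome
VCFs, built for the small-family setting in which a complex phenotype —
here, antiphospholipid syndrome (APS), an autoimmune thrombosis disorder —
clusters in siblings and an unaffected relative is available as a control.
It is aimed at clinical-genetics and immunogenetics analysts who have a
jointly called family VCF plus annotations and want a reproducible,
auditable filter cascade rather than ad-hoc spreadsheet triage.

## The method

Given genotyped family members partitioned into affected set *A* and
unaffected set *U*, a variant *v* (biallelic, GRCh37 coordinates) is a
candidate iff it passes the conjunction of five per-record predicates:

1. **Frequency**: population allele frequency AF(*v*) < 0.01 (gnomAD-style;
   missing AF passes — novel implies rare);
2. **Affected sharing**: every *s* ∈ *A* carries ≥ 1 alternate allele
   (het or hom-alt);
3. **Unaffected exclusion**: no *s* ∈ *U* carries an alternate allele;
4. **Class/consequence**: consequence ∈ {missense, nonsense, frameshift,
   splice region, in-frame indel} and ACMG-style 5-tier classification ∉
   {benign, likely benign};
5. **Depth**: DP ≥ 20 reads in every family member reporting a depth.

The reported candidate table is then restricted to missense variants.
Every threshold and policy (including how missing genotypes are treated)
is a `cascade_config()` field, and every removal is attributed to exactly
one stage in a telescoping per-variant filter trace. Because the
predicates are pure per-record tests, the candidate set is provably
order-invariant — the test suite checks this against all 120 stage
permutations and an independent brute-force oracle.

Around the cascade the package provides: VCF/PED/sidecar-annotation
readers (multi-allelic sites decomposed to biallelic records), curated
gene-panel screens (thrombophilia, thrombotic-PAPS, case-study genes of
interest) with legacy-symbol alias resolution, an rsID-anchored
known-variant catalogue matcher, a per-gene shared-variant report, a
byte-deterministic synthetic family generator with planted ground truth,
and a `simulate`/`filter`/`screen` command-line interface
(`inst/cli/trioscreen`).

## Worked example

The package ships a fixture reconstructing a published APS sibling-pair
case study: the transcribed 27-variant candidate table plus twelve
designed distractors (six common benign APOH variants shared by the
siblings, three common thrombophilia-gene variants carried by the whole
trio, three rare missense variants also carried by the father).

```r
library(trioscreen)

dir <- tempfile(); dir.create(dir)
fx     <- build_family_fixture(dir)
design <- read_ped(fx$ped)
vset   <- attach_annotations(
  read_multisample_vcf(fx$vcf, wanted_samples = design$sample_id),
  read_annotation_tsv(fx$annotations))

res <- run_cascade(vset, design)
print(res$trace)
#> <filter_trace>
#>               stage n_in n_out
#>           frequency   39    30
#>    affected_sharing   30    30
#>  unaffected_carrier   30    27
#>   class_consequence   27    27
#>               depth   27    27
#>              report   27    27
#> candidates retained: 27
```

Reading the trace: the frequency stage removes the nine common distractors
(the six APOH polymorphisms and three thrombophilia-gene variants), the
unaffected-exclusion stage removes the three father-carried rare variants,
and the 27 transcribed candidates — all rare, shared, missense, uncertain,
well covered — survive every stage.

```r
head(res$candidates$variants[, c("gene", "rsid", "chrom", "pos", "protein_change")], 4)
#>    gene         rsid chrom       pos protein_change
#> 1 CROCC rs1444279934     1  17270657    p.Gln624Leu
#> 2 HSPG2  rs766963773     1  22207015    p.Arg679His
#> 3 KIF14  rs373895990     1 200573037    p.Arg598Gln
#> 4 ADCY3  rs754839662     2  25050928    p.Val759Met

panels <- read_gene_panels()
screen_panel_genes(res$candidates, panels$thrombophilia)$n_hits   # 0
match_known_variants(vset, read_known_variants())$n_hits          # 0
nrow(gene_level_report(vset, design, "APOH"))                     # 6 (all common, benign)
```

The same pipeline runs from a shell:

```sh
Rscript inst/cli/trioscreen simulate --out fx --fixture
Rscript inst/cli/trioscreen filter --vcf fx/aps_family.vcf \
    --ped fx/aps_family.ped --annotations fx/aps_family_annotations.tsv \
    --out run
Rscript inst/cli/trioscreen screen --vcf fx/aps_family.vcf \
    --ped fx/aps_family.ped --annotations fx/aps_family_annotations.tsv \
    --out run --panel thrombophilia --known --gene APOH
```

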