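---
title: "Family-based variant filtering: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant filtering: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscreen)
```

## The screening model

`trioscreen` implements segregation-based rare-variant prioritization for a
small family in which a complex phenotype clusters: several affected
siblings and any number of unaffected relatives used as controls, genotyped
jointly by whole-exome sequencing. The implicit genetic model is a shared,
rare, dominant-acting coding allele: a variant is a candidate only if it is

1. **rare** in the general population — gnomAD-style cohort allele
   frequency strictly below a cut-off (default 1%);
2. **shared by every affected sample** — at least one alternate allele,
   heterozygous or homozygous;
3. **absent from every unaffected sample** — no unaffected carrier;
4. **plausibly protein-affecting** — a coding consequence in the allowed
   set and a 5-tier ACMG-style classification no better than uncertain
   (benign and likely-benign tiers are removed);
5. **well covered** — read depth of at least 20 reads in each family member
   at the site.

The reported candidate list is finally restricted to missense variants (the
`report_consequences` knob), which mirrors how such case studies present
their tables: the protein-affecting filter is broad, the table is missense.

Each of the five predicates is a pure per-record test, so the surviving
*set* is the conjunction of the predicates and does not depend on the order
in which the stages run; the per-variant *provenance* (which stage removed
a record) does depend on order, and the package fixes the canonical order:
frequency → affected sharing → unaffected exclusion → class/consequence →
depth. The trace telescopes exactly: the output count of each stage is the
input count of the next, every input record is attributed to exactly one
removal stage (or `none`), and the test suite verifies order-invariance of
the candidate set by brute-force permutation of all 120 stage orders as
well as equality with an independent record-by-record conjunction oracle.

## Assumptions and what the model cannot see

* **Dominant sharing.** Requiring an alternate allele in every affected
  sample and none in any unaffected sample encodes a shared dominant
  model. Recessive compound-heterozygous mechanisms, de novo events in a
  single sibling, and incomplete penetrance in a control all fall outside
  it by design.
* **Allele presence, not genotype equality.** Two siblings sharing a site
  het/hom-alt still "share" the variant. Published candidate tables in
  this setting are effectively all heterozygous, but the weaker predicate
  is the biologically meaningful one.
* **Coordinates are identity.** Cross-sample comparison joins on
  (chromosome, position, ref, alt) on GRCh37/hg19; rsIDs are annotation
  only, since real candidate tables contain variants with no rsID at all.
* **Biallelic records.** Multi-allelic VCF sites are split naively into one
  record per alternate allele with dosages recomputed per allele; no
  left-realignment or normalization is attempted. All variants in the
  motivating study are SNVs, so this is a documented limitation rather
  than a practical one; indels survive reading and are governed by the
  consequence filter (or removed wholesale by the `snv_only` flag).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `af_threshold` | 0.01 | allele fraction | the conventional 1% rare-variant cut-off; comparison is strict (`<`), so AF = 1% exactly is removed |
| `missing_af_passes` | `TRUE` | — | a variant absent from the frequency resource is novel, and novel implies rare |
| `excluded_classes` | benign, likely_benign | 5-tier labels | candidate triage conventionally keeps VUS and above; the literal "benign only" reading is one flag away |
| `allowed_consequences` | missense, nonsense, frameshift, splice_region, inframe_indel | — | the "affects protein function" set; missing consequence is removed because the property cannot be confirmed |
| `report_consequences` | missense | — | the final table restriction, layered separately so the broader filter stays intact |
| `min_depth` | 20 | reads | the conventional minimum coverage for a confident germline call; `>=` passes at the boundary |
| `*_missing_gt_policy` | strict_drop | — | a missing genotype defeats the stage that consults it: an unverifiable variant is never promoted. `lenient_keep` implements the opposite reading |

Two policy subtleties deserve spelling out. At the *sharing* stage a missing
genotype in an affected sample means the variant cannot be confirmed shared
(strict: drop). At the *exclusion* stage a missing genotype in an unaffected
sample means absence cannot be confirmed (strict: drop as well — the sample
is treated as a potential carrier). Records whose depth is missing in
*every* design sample are kept with a warning: coverage data that was never
loaded is not evidence of low coverage.

## The synthetic generator and the packaged fixture

`generate_family_vcf()` emits a VCF + sidecar annotation TSV + PED trio
with a ground-truth table. Planted records satisfy all five predicates;
each distractor class violates exactly one — common AF, not shared by one
sibling, carried by an unaffected control, benign classification, silent
consequence, or depth forced into 5–19 reads. Default study conditions:
two affected siblings and one unaffected father; rare AF uniform on
[1e-5, 5e-3] and common AF on [0.05, 0.5] (strictly below and above the 1%
cut-off, so class membership is never ambiguous); per-sample depth Poisson
with mean 100 floored at 30, matching a modern 100×-target exome well clear
of the 20-read minimum. Output is byte-deterministic given the seed:
records are emitted in coordinate-sorted order (never generation order),
and the generator restores the caller's RNG state.

What the generator deliberately does **not** emulate: linkage
disequilibrium, mutation-rate heterogeneity, genotyping error correlated
with depth, population stratification of allele frequencies, or any
relationship between consequence and frequency. Passing the planted-truth
property therefore demonstrates that the cascade's logic is exact, not that
the thresholds are well calibrated for real exomes.

The packaged fixture (`build_family_fixture()`) reconstructs the
case-study's inputs from the transcribed 27-variant candidate table (25
genes; one gene contributes three adjacent variants), heterozygous in both
siblings and hom-ref in the father. Population AF (1e-4), classification
(`uncertain`) and depth (100) for these records are synthetic fixture
metadata chosen safely inside the passing region — the study printed
neither AF nor per-variant depth. Twelve distractors make the cascade do
real work: six common benign APOH variants shared by the siblings
(stand-ins for the study's six unpublished common APOH polymorphisms),
three common variants in thrombophilia-panel genes carried by all three
family members, and three rare missense variants also carried by the
father. Where the source table printed only c.-notation, ref/alt alleles
are derived from that notation on the transcript strand and flagged
`cdna_notation` in the transcription table; they are stand-ins, not
validated genomic alleles.

## Panels and known-variant matching

Three panels ship with the package: an 8-gene thrombophilia panel (F5, F2,
MTHFR, F13A1, PROC, PROS1, FGB, SERPINE1), a 16-gene thrombotic-PAPS
panel, and the 7 case-study genes of interest. Legacy symbols (B2GP1,
"GP Ia", "GP IIIa", ZPI) resolve through an explicit, versioned alias
table. The known-variant catalogue anchors each entry by rsID where one
exists; the rsID is authoritative — coordinate agreement never overrides an
rsID mismatch and a record with no rsID cannot match an rsID-anchored
entry. Entries with a printed coordinate but no rsID match positionally;
haplotype/promoter entries with neither (a protein C receptor haplotype)
match at gene level only, a documented coarsening.

`gene_level_report()` intentionally reads the *pre-cascade* variant set
restricted to records shared by the affected samples: its purpose is to
show everything on one gene, including the common, benign polymorphisms
the cascade exists to discard.

## Numerical and degenerate-input choices

* Chromosome ordering is numeric-aware (1–22, X, Y, MT, then others);
  record order is always (chromosome, position, ref, alt).
* Ties cannot arise in identity: duplicate (chrom, pos, ref, alt) keys are
  fatal at construction, as are ref = alt, AF outside [0, 1], and labels
  outside the 5-tier / consequence vocabularies.
* An empty VCF body is a valid empty variant set that remembers its
  samples; an empty variant set runs through the cascade with all stage
  counts zero.
* A design with zero unaffected members makes the exclusion stage the
  identity; zero affected members is fatal at validation (the sharing
  stage would be vacuous and the screen meaningless).
* Annotation joins are exact on the coordinate key; on conflict the
  sidecar table wins with a warning, making re-annotation idempotent.

## Problem sizes used by the shipped checks

The test suite exercises the cascade against an independently written
brute-force oracle on 100 random inputs of 20–200 records, permutes all
120 stage orders on 10 small inputs, and re-runs the generator across 20
seed/planted-count combinations with 30 distractors each; the end-to-end
fixture run covers 39 records. These sizes were chosen to enumerate the
combinatorics exhaustively at small scale, where the brute-force reference
is exact; the per-record predicates are vectorized and scale linearly, so
exome-scale inputs (tens of thousands of records after annotation) differ
only in constant factors.

## Known limitations

* No liftover: coordinates are GRCh37/hg19 throughout.
* Naive multi-allelic splitting without realignment.
* No phasing, so compound heterozygosity and haplotype-level entries are
  out of reach; the one haplotype catalogue entry degrades to gene-level
  matching.
* Consequence and classification are consumed as annotations, never
  predicted; the package trusts its annotation source.
* The frequency filter uses a single AF field; population-maximum AF
  filtering can be emulated by pre-computing that field into the sidecar
  table.
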