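Package: trioscreen
Title: Family-Based Whole-Exome Variant Filtering and Panel Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rare-variant prioritization for small family designs (affected
    siblings with unaffected relatives) from multi-sample whole-exome VCFs.
    Implements a five-stage filter cascade (population allele frequency,
    sharing among affected members, exclusion of unaffected carriers,
    pathogenicity class and coding consequence, sequencing depth) with
    per-variant filter provenance, curated gene-panel and known-variant
    screens for thrombophilia and antiphospholipid-syndrome risk loci, a
    deterministic synthetic family VCF generator with planted ground truth,
    and a packaged fixture reconstructing a published sibling-pair candidate
    variant list.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
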