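#' Gene symbol alias resolution
#'
#' Curated panels and older literature mix legacy and HGNC gene names (for
#' example B2GP1 for APOH, "GP Ia" for ITGA2). The packaged alias table maps
#' each legacy form to exactly one canonical HGNC symbol.
#'
#' @param path Path to an alias TSV (columns `alias`, `canonical`); the
#'   packaged table is used when `NULL`.
#' @return Named character vector, alias -> canonical symbol.
#' @export
load_gene_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_aliases.tsv", package = "trioscreen",
                        mustWork = TRUE)
  }
  tab <- read_tsv(path)
  stats::setNames(as.character(tab$canonical), as.character(tab$alias))
}

canonical_gene <- function(symbols, aliases = load_gene_aliases()) {
  hit <- match(symbols, names(aliases))
  ifelse(is.na(hit), symbols, unname(aliases[hit]))
}

#' Construct a gene panel
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols; legacy names are resolved
#'   through the alias table. A symbol that is neither plain-HGNC-shaped
#'   (letters, digits, `-`) nor a known alias is fatal at load.
#' @param aliases Alias map from [load_gene_aliases()].
#' @return Object of class `gene_panel` with canonical, deduplicated
#'   symbols.
#' @export
gene_panel <- function(name, genes, aliases = load_gene_aliases()) {
  genes <- trimws(as.character(genes))
  if (any(!nzchar(genes))) stop("empty gene symbol in panel '", name, "'")
  resolved <- canonical_gene(genes, aliases)
  plain <- grepl("^[A-Za-z][A-Za-z0-9-]*$", resolved)
  if (any(!plain)) {
    stop("unknown gene alias in panel '", name, "': ",
         paste(unique(genes[!plain]), collapse = ", "))
  }
  structure(list(name = name, genes = unique(resolved)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$genes), " genes (",
      paste(x$genes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read gene panels from a TSV file
#'
#' @param path TSV with columns `panel_name`, `gene_symbol`; the packaged
#'   panel file is used when `NULL`. It ships three panels:
#'   `thrombophilia` (8 genes with established pro-thrombotic variants),
#'   `thrombotic_paps` (16 genes associated with thrombotic primary
#'   antiphospholipid syndrome), and `genes_of_interest` (7 candidate genes
#'   from the familial case study).
#' @param aliases Alias map from [load_gene_aliases()].
#' @return Named list of [gene_panel()] objects.
#' @export
read_gene_panels <- function(path = NULL, aliases = load_gene_aliases()) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_panels.tsv", package = "trioscreen",
                        mustWork = TRUE)
  }
  tab <- read_tsv(path)
  out <- lapply(split(tab$gene_symbol, tab$panel_name),
                function(g) NULL)
  for (nm in names(out)) {
    out[[nm]] <- gene_panel(nm, tab$gene_symbol[tab$panel_name == nm], aliases)
  }
  out
}

#' Read a known-variant catalogue from a TSV file
#'
#' @param path TSV with columns `gene`, `rsid`, `chrom`, `pos`,
#'   `transcript`, `effect`, `reference` (`.` for missing); the packaged
#'   catalogue of variants reported in association with antiphospholipid
#'   syndrome is used when `NULL`. Entries may be anchored by rsid, by
#'   coordinate, or — for haplotype/promoter entries with no point
#'   coordinate — by gene only.
#' @param aliases Alias map used to canonicalize the gene column.
#' @return data.frame of catalogue entries.
#' @export
read_known_variants <- function(path = NULL, aliases = load_gene_aliases()) {
  if (is.null(path)) {
    path <- system.file("extdata", "aps_known_variants.tsv",
                        package = "trioscreen", mustWork = TRUE)
  }
  tab <- read_tsv(path)
  need <- c("gene", "rsid", "chrom", "pos", "transcript", "effect")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("known-variant catalogue lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(is.na(tab$gene) | !nzchar(tab$gene))) {
    stop("known-variant catalogue entry without a gene symbol")
  }
  tab$gene <- canonical_gene(as.character(tab$gene), aliases)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab
}

new_screen_report <- function(panel_name, hits, extra = list()) {
  structure(c(list(panel = panel_name, hits = hits,
                   n_hits = nrow(hits)), extra),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> panel '", x$panel, "': ", x$n_hits, " hit",
      if (x$n_hits != 1) "s", "\n", sep = "")
  if (x$n_hits > 0) print.data.frame(x$hits, row.names = FALSE)
  if (!is.null(x$misses)) {
    cat("catalogue entries not observed:", nrow(x$misses), "\n")
  }
  invisible(x)
}

#' Screen a variant set against a gene panel
#'
#' Reports every record whose (alias-resolved) gene symbol belongs to the
#' panel, with its population AF, classification and per-sample zygosity.
#' Zero hits is a valid, explicit result.
#'
#' @param vset A [variant_set()] with gene annotations attached.
#' @param panel A [gene_panel()].
#' @param aliases Alias map used to canonicalize record gene symbols.
#' @return A `screen_report` with a `hits` data.frame.
#' @export
screen_panel_genes <- function(vset, panel, aliases = load_gene_aliases()) {
  gene <- canonical_gene(vset$variants$gene, aliases)
  idx <- which(!is.na(gene) & gene %in% panel$genes)
  hits <- data.frame(gene = gene[idx],
                     chrom = vset$variants$chrom[idx],
                     pos = vset$variants$pos[idx],
                     ref = vset$variants$ref[idx],
                     alt = vset$variants$alt[idx],
                     rsid = vset$variants$rsid[idx],
                     pop_af = vset$variants$pop_af[idx],
                     classification = vset$variants$classification[idx],
                     stringsAsFactors = FALSE)
  for (s in vset$sample_ids) {
    hits[[paste0("zygosity_", s)]] <- zygosity_labels(vset$gt[idx, s])
  }
  new_screen_report(panel$name, hits)
}

#' Match a variant set against a known-variant catalogue
#'
#' A record matches a catalogue entry by rsid equality when the entry
#' carries an rsid (the rsid is authoritative: coordinate agreement never
#' overrides an rsid mismatch, and a record without an rsid cannot match an
#' rsid-anchored entry); by (chrom, pos) when the entry has a coordinate but
#' no rsid; and by gene symbol alone for gene-level-only entries (haplotype
#' or promoter variants without a point coordinate).
#'
#' @param vset A [variant_set()].
#' @param catalogue data.frame from [read_known_variants()].
#' @param aliases Alias map used to canonicalize record gene symbols.
#' @return A `screen_report`; `hits` pairs each matched record with its
#'   catalogue entry (`match_type` one of rsid/position/gene), `misses`
#'   lists catalogue entries with no match.
#' @export
match_known_variants <- function(vset, catalogue,
                                 aliases = load_gene_aliases()) {
  v <- vset$variants
  vgene <- canonical_gene(v$gene, aliases)
  hit_rows <- list()
  matched_entry <- logical(nrow(catalogue))
  for (j in seq_len(nrow(catalogue))) {
    entry <- catalogue[j, ]
    if (!is.na(entry$rsid)) {
      idx <- which(!is.na(v$rsid) & v$rsid == entry$rsid)
      type <- "rsid"
    } else if (!is.na(entry$pos)) {
      idx <- which(v$chrom == entry$chrom & v$pos == entry$pos)
      type <- "position"
    } else {
      idx <- which(!is.na(vgene) & vgene == entry$gene)
      type <- "gene"
    }
    if (length(idx)) {
      matched_entry[j] <- TRUE
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        gene = entry$gene, catalogue_rsid = entry$rsid,
        catalogue_effect = entry$effect, match_type = type,
        chrom = v$chrom[idx], pos = v$pos[idx],
        ref = v$ref[idx], alt = v$alt[idx], rsid = v$rsid[idx],
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(gene = character(), catalogue_rsid = character(),
               catalogue_effect = character(), match_type = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), rsid = character(),
               stringsAsFactors = FALSE)
  new_screen_report("known_variants", hits,
                    extra = list(misses = catalogue[!matched_entry, ,
                                                    drop = FALSE]))
}

#' Gene-level report of variants shared by the affected samples
#'
#' Lists every record on one gene that is carried by all affected samples,
#' regardless of allele frequency or classification — this deliberately
#' operates on the pre-cascade variant set, so common and benign variants
#' (invisible to the cascade's candidate list) are reported. Each row is
#' flagged `common` (AF >= `af_common`) or `rare` (below, or AF missing)
#' and carries its classification tier.
#'
#' @param vset The pre-cascade [variant_set()] (annotations attached).
#' @param design A [family_design()].
#' @param gene HGNC symbol (aliases resolved).
#' @param af_common Frequency at or above which a variant is flagged common
#'   (default 0.01, i.e. 1%).
#' @param aliases Alias map.
#' @return data.frame with one row per shared record on the gene.
#' @export
gene_level_report <- function(vset, design, gene, af_common = 0.01,
                              aliases = load_gene_aliases()) {
  target <- canonical_gene(gene, aliases)
  vgene <- canonical_gene(vset$variants$gene, aliases)
  aff <- affected_samples(design)
  g <- vset$gt[, aff, drop = FALSE]
  carries <- g >= 1
  carries[is.na(carries)] <- FALSE
  shared <- if (length(aff)) rowSums(carries) == length(aff) else
    rep(TRUE, n_variants(vset))
  idx <- which(!is.na(vgene) & vgene == target & shared)
  v <- vset$variants
  out <- data.frame(gene = vgene[idx], chrom = v$chrom[idx], pos = v$pos[idx],
                    ref = v$ref[idx], alt = v$alt[idx], rsid = v$rsid[idx],
                    pop_af = v$pop_af[idx],
                    frequency_flag = ifelse(!is.na(v$pop_af[idx]) &
                                              v$pop_af[idx] >= af_common,
                                            "common", "rare"),
                    classification = v$classification[idx],
                    stringsAsFactors = FALSE)
  for (s in aff) {
    out[[paste0("zygosity_", s)]] <- zygosity_labels(vset$gt[idx, s])
  }
  out
}

#' Write a screen report's hits as TSV
#' @param report A `screen_report`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_screen_report <- function(report, path) {
  write_tsv(report$hits, path)
}
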