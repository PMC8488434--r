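#' Annotate a call with overlapping genes
#'
#' A gene is included iff its interval intersects the call interval by
#' at least 1 bp (so a deletion covering only part of a gene, e.g. a
#' run of internal exons, still counts).
#'
#' @param call one-row call data.frame (`chrom`, `start`, `end`).
#' @param gene_table data.frame with `symbol`, `chrom`, `start`, `end`,
#'   `is_disease_gene` (logical), `dosage_mechanism` (one of
#'   `"haploinsufficiency"`, `"triplosensitivity"`, `"recessive"`,
#'   `"none"`).
#' @return the overlapping rows of `gene_table`.
#' @export
annotate_genes <- function(call, gene_table) {
  hit <- gene_table$chrom == call$chrom &
    gene_table$end >= call$start & gene_table$start <= call$end
  gene_table[hit, , drop = FALSE]
}

#' Does a call require parental inheritance assignment?
#'
#' True iff any overlapped gene is a known disease gene, or has a
#' dosage mechanism matching the call direction (haploinsufficiency for
#' losses, triplosensitivity for gains). These are the calls whose mode
#' of inheritance is crucial for interpretation and recurrence-risk
#' counselling.
#'
#' @param call one-row call data.frame with a `type` column.
#' @param genes gene rows from [annotate_genes()].
#' @return logical scalar.
#' @export
flag_requires_parental_analysis <- function(call, genes) {
  if (!nrow(genes)) return(FALSE)
  dirn <- .type_class(call$type)
  any(genes$is_disease_gene) ||
    any(dirn == "loss" & genes$dosage_mechanism == "haploinsufficiency") ||
    any(dirn == "gain" & genes$dosage_mechanism == "triplosensitivity")
}

#' Classify a rare CNV into a clinical category
#'
#' A deterministic five-outcome rule cascade driven by gene dosage
#' evidence, mode of inheritance and rarity (a documented simplification
#' of ACMG-style judgment; the full point-based scoring needs external
#' database evidence that arrives here only as input flags):
#'
#' 1. Loss over a haploinsufficient disease gene, or gain over a
#'    triplosensitive one: `pathogenic` if de novo or inside a
#'    configured established syndrome region, else `likely_pathogenic`.
#' 2. Any other disease-gene overlap (uncertain dosage evidence):
#'    `VUS`.
#' 3. No disease gene, matching a configured common/benign region:
#'    `benign`.
#' 4. No disease gene, inherited: `likely_benign`.
#' 5. Remaining (de novo, no disease gene): `VUS`.
#'
#' @param call one-row call data.frame with `type` and an `inheritance`
#'   column (from [assign_inheritance()]).
#' @param genes gene rows from [annotate_genes()].
#' @param rare logical: did the call survive [filter_rare()]?
#' @param syndrome_regions optional data.frame (`chrom`, `start`, `end`,
#'   `type`) of established syndrome regions.
#' @param benign_regions optional data.frame of known benign regions.
#' @return list with `category` (one of `pathogenic`,
#'   `likely_pathogenic`, `VUS`, `likely_benign`, `benign`),
#'   `rationale` (character vector of rule codes fired) and
#'   `requires_parental_analysis`.
#' @export
classify_variant <- function(call, genes, rare = TRUE,
                             syndrome_regions = NULL,
                             benign_regions = NULL) {
  inh <- call$inheritance
  if (is.null(inh) || is.na(inh) || !nzchar(inh))
    stop("mode of inheritance is required for classification",
         call. = FALSE)
  de_novo <- identical(inh, "de_novo")
  dirn <- .type_class(call$type)
  rationale <- character()
  if (!rare) rationale <- c(rationale, "not_rare")

  dosage_hit <- nrow(genes) > 0 && any(
    genes$is_disease_gene &
      ((dirn == "loss" & genes$dosage_mechanism == "haploinsufficiency") |
         (dirn == "gain" & genes$dosage_mechanism == "triplosensitivity")))
  disease_hit <- nrow(genes) > 0 && any(genes$is_disease_gene)
  in_region <- function(tbl) !is.null(tbl) && nrow(tbl) > 0 &&
    !is.na(match_calls(call, tbl))

  category <- if (dosage_hit) {
    rationale <- c(rationale, "dosage_sensitive_disease_gene")
    if (de_novo || in_region(syndrome_regions)) {
      rationale <- c(rationale,
                     if (de_novo) "de_novo" else "established_syndrome")
      "pathogenic"
    } else {
      rationale <- c(rationale, "inherited")
      "likely_pathogenic"
    }
  } else if (disease_hit) {
    rationale <- c(rationale, "disease_gene_uncertain_dosage")
    "VUS"
  } else if (in_region(benign_regions)) {
    rationale <- c(rationale, "known_benign_region")
    "benign"
  } else if (!de_novo) {
    rationale <- c(rationale, "inherited_no_disease_gene")
    "likely_benign"
  } else {
    rationale <- c(rationale, "de_novo_no_disease_gene")
    "VUS"
  }
  list(category = category, rationale = rationale,
       requires_parental_analysis =
         flag_requires_parental_analysis(call, genes))
}

#' Read a UCSC cytoBand table
#'
#' @param path cytoBand.txt-format file (tab-separated: chrom,
#'   0-based start, end, band name, Giemsa stain), plain or gzipped.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `band`.
#' @export
read_cytoband <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = x[[1]], start = x[[2]] + 1, end = x[[3]],
             band = x[[4]], stringsAsFactors = FALSE)
}

.band_of <- function(cytobands, chrom, pos) {
  hit <- cytobands$chrom == chrom & cytobands$start <= pos &
    cytobands$end >= pos
  if (!any(hit))
    stop("no cytoband covers ", chrom, ":", pos, call. = FALSE)
  cytobands$band[which(hit)[1]]
}

#' Render ISCN/HGVS-style nomenclature for a call
#'
#' Produces strings such as
#' `seq[GRCh37/hg19] del(9)(q34.3)dn chr9:g.140608441_140673160del` or,
#' for a 50% mosaic,
#' `... chr20:g.61942378_62945038del[0.5]`. A call spanning several
#' bands joins the first and last band with no separator
#' (`del(Y)(q11.221q12)` style); `dn` is appended for de novo calls;
#' the mosaic fraction is bracketed only when below 1.
#'
#' @param call one-row call data.frame with `chrom`, `start`, `end`,
#'   `type`, `mosaic_fraction`, and `inheritance`.
#' @param cytobands table from [read_cytoband()].
#' @param build_label genome build label (default `"GRCh37/hg19"`).
#' @return the nomenclature string.
#' @export
format_nomenclature <- function(call, cytobands,
                                build_label = "GRCh37/hg19") {
  kind <- if (.type_class(call$type) == "loss") "del" else "dup"
  chrom_short <- sub("^chr", "", call$chrom)
  b1 <- .band_of(cytobands, call$chrom, call$start)
  b2 <- .band_of(cytobands, call$chrom, call$end)
  bands <- if (identical(b1, b2)) b1 else paste0(b1, b2)
  dn <- if (identical(call$inheritance, "de_novo")) "dn" else ""
  # mosaic level at reporting precision (2 decimals); estimates that
  # round to 1 are reported constitutional, i.e. without the bracket
  frac <- round(call$mosaic_fraction, 2)
  mos <- if (is.finite(frac) && frac < 1)
    paste0("[", format(frac, trim = TRUE), "]") else ""
  sprintf("seq[%s] %s(%s)(%s)%s chr%s:g.%s_%s%s%s",
          build_label, kind, chrom_short, bands, dn, chrom_short,
          format(call$start, scientific = FALSE, trim = TRUE),
          format(call$end, scientific = FALSE, trim = TRUE),
          kind, mos)
}

#' Parse a nomenclature string back to its fields
#'
#' Inverse of [format_nomenclature()]; used to guarantee the rendered
#' grammar is lossless.
#'
#' @param x a nomenclature string.
#' @return list with `build`, `chrom`, `bands`, `start`, `end`, `type`
#'   (`del`/`dup`), `de_novo`, `mosaic_fraction` (1 when absent).
#' @export
parse_nomenclature <- function(x) {
  m <- regmatches(x, regexec(
    "^seq\\[([^]]+)\\] (del|dup)\\(([^)]+)\\)\\(([^)]+)\\)(dn)? chr([^:]+):g\\.([0-9]+)_([0-9]+)(del|dup)(\\[([0-9.]+)\\])?$",
    x))[[1]]
  if (!length(m)) stop("unparseable nomenclature: ", x, call. = FALSE)
  list(build = m[2], chrom = paste0("chr", m[7]), bands = m[5],
       start = as.numeric(m[8]), end = as.numeric(m[9]), type = m[10],
       de_novo = identical(m[6], "dn"),
       mosaic_fraction = if (nzchar(m[12])) as.numeric(m[12]) else 1)
}

#' Human-readable CNV size
#'
#' One-decimal kb below 1 Mb, one-decimal Mb above; the convention used
#' in clinical reports (64,720 bp renders as "64.7 kb", 1,002,661 bp as
#' "1.0 Mb").
#'
#' @param size_bp size in bp.
#' @return character.
#' @export
format_cnv_size <- function(size_bp) {
  ifelse(size_bp < 1e6,
         sprintf("%.1f kb", size_bp / 1e3),
         sprintf("%.1f Mb", size_bp / 1e6))
}
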