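#' Write a per-sample count table
#'
#' TSV with columns `chrom`, `start`, `end`, `gc`, `count` (1-based
#' inclusive coordinates); readable back through
#' [count_reads_in_windows()] (schema-validated pass-through) or
#' [read_count_table()].
#'
#' @param counts raw fine-window counts.
#' @param model `genome_model` supplying the grid.
#' @param path output path.
#' @export
write_count_table <- function(counts, model, path) {
  w <- model$windows
  utils::write.table(
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               gc = w$gc, count = counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample count table written by [write_count_table()]
#' @param path TSV path.
#' @return data.frame with `chrom`, `start`, `end`, `gc`, `count`.
#' @export
read_count_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a CNV truth set as BED-like TSV
#'
#' Columns: `chrom`, BED-style `start0` (0-based) and `end`, 1-based
#' `start`, `type`, `copy`, `mosaic_fraction`, `carrier`, `transmitted`.
#'
#' @param truth a `cnv_truth` data.frame.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(
    data.frame(chrom = truth$chrom, start0 = truth$start - 1,
               end = truth$end, start = truth$start,
               type = ifelse(truth$copy < 2, "del", "dup"),
               copy = truth$copy,
               mosaic_fraction = truth$mosaic_fraction,
               carrier = truth$carrier, transmitted = truth$transmitted),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as BED-like TSV
#'
#' Keeps the 1-based inclusive `start`/`end` pair the reporting
#' nomenclature uses and adds the BED 0-based `start0` column.
#'
#' @param calls call data.frame from [call_cnvs()] (optionally with
#'   inheritance/classification columns).
#' @param path output path.
#' @export
write_calls_table <- function(calls, path) {
  calls$start0 <- calls$start - 1
  cols <- c("chrom", "start0", "end", "start",
            setdiff(names(calls), c("chrom", "start0", "end", "start")))
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a call table written by [write_calls_table()]
#' @param path TSV path.
#' @return data.frame (without the BED `start0` column).
#' @export
read_calls_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$start0 <- NULL
  x
}

#' Read a gene annotation table
#'
#' TSV with `symbol`, `chrom`, `start`, `end`, `is_disease_gene`,
#' `dosage_mechanism`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$is_disease_gene <- as.logical(x$is_disease_gene)
  x
}

#' Read a CNV carrier-frequency table
#'
#' TSV with `chrom`, `start`, `end`, `type`, `frequency` (and
#' optionally `panel_size`).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_frequency_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a QC report as structured JSON-like text
#'
#' @param qc a `qc_result`.
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  txt <- paste0(
    "{\n",
    sprintf('  "genome_sd": %.6f,\n', qc$genome_sd),
    sprintf('  "excluded_chromosomes": [%s],\n',
            paste(sprintf('"%s"', qc$excluded_chromosomes),
                  collapse = ", ")),
    sprintf('  "pass": %s\n', if (qc$pass) "true" else "false"),
    "}\n")
  writeLines(txt, path)
  invisible(path)
}
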