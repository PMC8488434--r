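#' Estimate fold coverage from read count and length
#'
#' `fold = n_reads * read_length / genome_size`; e.g. 15 million 50-bp
#' reads on a 3-Gb genome give 0.25-fold.
#'
#' @param n_reads number of reads (may be 0).
#' @param read_length_bp read length in bp (> 0).
#' @param genome_size_bp genome size in bp (> 0).
#' @return fold coverage (numeric scalar).
#' @examples
#' estimate_fold_coverage(15e6, 50, 3e9)  # 0.25
#' @export
estimate_fold_coverage <- function(n_reads, read_length_bp, genome_size_bp) {
  if (n_reads < 0) stop("n_reads must be non-negative", call. = FALSE)
  if (read_length_bp <= 0 || genome_size_bp <= 0)
    stop("read length and genome size must be positive", call. = FALSE)
  n_reads * read_length_bp / genome_size_bp
}

#' Deposit uniquely aligned reads into fine windows
#'
#' Counts retained reads per fine window of the model grid. A read is
#' assigned to the single window containing its leftmost mapped base;
#' "uniquely aligned" is operationalized as mapping quality >=
#' `min_mapping_quality` and not flagged secondary or supplementary.
#'
#' @param x one of: a path to a SAM or BAM file (read via Rsamtools); a
#'   data.frame of reads with columns `chrom`, `pos` (1-based leftmost
#'   mapped base) and optionally `mapq`; or a precomputed count table
#'   with columns `chrom`, `start`, `end`, `count`, which is validated
#'   against the grid and passed through.
#' @param model a `genome_model`.
#' @param min_mapping_quality minimum mapping quality (default 1).
#' @return integer vector of counts, one per fine window.
#' @export
count_reads_in_windows <- function(x, model, min_mapping_quality = 1) {
  if (is.character(x)) {
    path <- x
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flags,
                                     what = c("rname", "pos", "mapq"))
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    x <- data.frame(chrom = as.character(b$rname), pos = b$pos,
                    mapq = b$mapq, stringsAsFactors = FALSE)
    x <- x[!is.na(x$pos), , drop = FALSE]
  }
  stopifnot(is.data.frame(x))
  if (all(c("chrom", "start", "end", "count") %in% names(x))) {
    w <- model$windows
    if (nrow(x) != nrow(w) ||
        !all(x$chrom == w$chrom & x$start == w$start & x$end == w$end))
      stop("count table does not match the model grid", call. = FALSE)
    if (any(x$count < 0)) stop("negative counts", call. = FALSE)
    return(as.integer(x$count))
  }
  stopifnot(all(c("chrom", "pos") %in% names(x)))
  if ("mapq" %in% names(x))
    x <- x[!is.na(x$mapq) & x$mapq >= min_mapping_quality, , drop = FALSE]
  bad <- setdiff(unique(x$chrom), names(model$chrom_lengths))
  if (length(bad))
    stop("reference names not in the window grid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  fs <- model$fine_window_size
  w <- model$windows
  n_per <- as.integer(table(factor(w$chrom,
                                   levels = names(model$chrom_lengths))))
  offset <- stats::setNames(cumsum(c(0L, n_per[-length(n_per)])),
                            names(model$chrom_lengths))
  win <- (x$pos - 1) %/% fs + 1
  keep <- x$pos >= 1 & win <= n_per[match(x$chrom, names(offset))]
  gi <- offset[x$chrom[keep]] + win[keep]
  as.integer(tabulate(gi, nbins = nrow(w)))
}

#' GC-correct raw window counts by 1%-GC-bin median scaling
#'
#' Windows are grouped into 1%-GC bins; each window's count is scaled by
#' the ratio of the global median count to its bin's median count. Bins
#' whose median is 0 and windows with mappability 0 are masked (`NA`).
#'
#' @param counts raw counts per fine window.
#' @param gc GC fraction per fine window.
#' @param mappability optional weights; windows with weight 0 are masked.
#' @return numeric vector of corrected counts (`NA` where masked).
#' @export
gc_correct <- function(counts, gc, mappability = NULL) {
  stopifnot(length(counts) == length(gc))
  usable <- rep(TRUE, length(counts))
  if (!is.null(mappability)) usable <- mappability > 0
  if (sum(usable) < 100)
    stop("need at least 100 unmasked windows", call. = FALSE)
  if (all(counts[usable] == 0))
    stop("all counts are zero; cannot GC-correct", call. = FALSE)
  bin <- floor(gc * 100)
  med <- tapply(counts[usable], bin[usable], stats::median)
  global <- stats::median(counts[usable])
  fac <- global / med[as.character(bin)]
  fac[!is.finite(fac)] <- NA_real_
  out <- counts * fac
  out[!usable] <- NA_real_
  as.numeric(out)
}

#' Build panel normalization statistics
#'
#' GC-corrects every panel sample, rescales each to a common total, and
#' summarizes the panel per fine window by a robust center (median) and
#' per-sliding-window ratio dispersion (MAD), which the CNV caller uses
#' as its per-window noise scale. The panel's fine copy-ratio matrix is
#' retained for the population U-test screen.
#'
#' @param panel_counts matrix of raw counts, windows x samples.
#' @param model the shared `genome_model`.
#' @return object of class `panel_stats`: list with `center`,
#'   `dispersion_sliding`, `ratios_fine` (windows x samples),
#'   `panel_size`, `model_fingerprint`.
#' @export
build_panel_stats <- function(panel_counts, model) {
  stopifnot(nrow(panel_counts) == nrow(model$windows))
  n <- ncol(panel_counts)
  w <- model$windows
  corr <- apply(panel_counts, 2, gc_correct, gc = w$gc,
                mappability = w$mappability)
  totals <- colSums(corr, na.rm = TRUE)
  target <- stats::median(totals)
  corr <- sweep(corr, 2, target / totals, `*`)
  center <- apply(corr, 1, stats::median, na.rm = TRUE)
  masked <- !is.finite(center) | center <= 0
  center[masked] <- NA_real_
  ratios <- corr / center
  # per-sample autosomal rescale, as applied to query samples
  meds <- apply(ratios, 2, .autosomal_center, chrom = w$chrom)
  ratios <- sweep(ratios, 2, meds, `/`)
  # dispersion from a panel subset: the MAD stabilizes well before a few
  # hundred samples and the full matrix would dominate build time
  sub <- seq_len(min(n, 200L))
  slid <- .sliding_mean(ratios[, sub, drop = FALSE], model)
  disp <- apply(slid, 1, stats::mad, na.rm = TRUE)
  structure(list(center = center,
                 dispersion_sliding = disp,
                 ratios_fine = ratios,
                 panel_size = n,
                 model_fingerprint = .grid_fingerprint(model)),
            class = "panel_stats")
}

# Diploid centring constant: the median of per-autosome median ratios.
# Robust to whole-chromosome aneuploidies (which would drag a plain
# genome-wide median into the background distribution's tail).
.autosomal_center <- function(r, chrom) {
  auto <- !grepl("(^|chr)[XY]$", chrom)
  per <- tapply(r[auto], chrom[auto], stats::median, na.rm = TRUE)
  stats::median(per, na.rm = TRUE)
}

.grid_fingerprint <- function(model) {
  paste0(nrow(model$windows), ":", model$fine_window_size, ":",
         paste(names(model$chrom_lengths), model$chrom_lengths,
               collapse = ";"))
}

# Running mean of n_fine consecutive fine values within each chromosome;
# works on vectors or window x sample matrices. Rows follow sliding_grid().
.sliding_mean <- function(x, model, n_fine = 10L) {
  one <- function(v) {
    out <- lapply(names(model$chrom_lengths), function(ch) {
      idx <- which(model$windows$chrom == ch)
      vv <- v[idx]
      k <- length(vv) - n_fine + 1L
      if (k < 1L) return(numeric(0))
      ok <- is.finite(vv)
      cs <- cumsum(c(0, ifelse(ok, vv, 0)))
      cn <- cumsum(c(0, as.numeric(ok)))
      s <- cs[(n_fine + 1):(length(vv) + 1)] - cs[1:k]
      m <- cn[(n_fine + 1):(length(vv) + 1)] - cn[1:k]
      # a sliding value needs most of its fine windows unmasked
      ifelse(m >= n_fine - 2, s / m, NA_real_)
    })
    unlist(out, use.names = FALSE)
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Normalize corrected counts to copy ratios
#'
#' Divides a sample's GC-corrected counts by the panel center per fine
#' window, rescales so the autosomal median ratio is 1 (diploid
#' expectation), and averages runs of 10 fine ratios into the 50-kb
#' sliding grid. Masked windows propagate as `NA`.
#'
#' @param corrected GC-corrected counts per fine window.
#' @param panel_stats a `panel_stats` built on the same grid.
#' @param model the `genome_model`.
#' @return list with `fine` and `sliding` copy-ratio vectors.
#' @export
normalize_to_copy_ratio <- function(corrected, panel_stats, model) {
  if (!identical(panel_stats$model_fingerprint, .grid_fingerprint(model)))
    stop("panel was built on a different window grid", call. = FALSE)
  r <- corrected / panel_stats$center
  r <- r / .autosomal_center(r, model$windows$chrom)
  list(fine = r, sliding = .sliding_mean(r, model))
}

#' Assemble a per-sample coverage profile
#'
#' Convenience constructor running GC correction and panel normalization
#' and attaching coverage/QC metadata; the unit every calling and trio
#' function consumes.
#'
#' @param raw_counts raw fine-window counts (from
#'   [count_reads_in_windows()] or the simulator).
#' @param model `genome_model`.
#' @param panel_stats `panel_stats`.
#' @param sample_id sample label.
#' @param sex `"XX"` or `"XY"`.
#' @param read_length_bp read length used for fold-coverage (default 50).
#' @return object of class `coverage_profile`.
#' @export
coverage_profile <- function(raw_counts, model, panel_stats,
                             sample_id = "sample", sex = "XX",
                             read_length_bp = 50) {
  w <- model$windows
  corrected <- gc_correct(raw_counts, w$gc, w$mappability)
  ratios <- normalize_to_copy_ratio(corrected, panel_stats, model)
  structure(list(sample_id = sample_id, sex = sex, model = model,
                 raw_counts = as.integer(raw_counts),
                 corrected = corrected,
                 ratio_fine = ratios$fine,
                 ratio_sliding = ratios$sliding,
                 fold_coverage = estimate_fold_coverage(
                   sum(raw_counts), read_length_bp,
                   sum(model$chrom_lengths)),
                 qc = NULL),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile", x$sample_id, sprintf("(%.2f-fold)", x$fold_coverage),
      "on", length(x$raw_counts), "fine windows\n")
  invisible(x)
}

#' Genome-wide copy-ratio standard deviation QC
#'
#' Computes the standard deviation of the sliding-window copy ratios
#' over all windows except those on listed (aneuploid) chromosomes and
#' masked windows. A sample passes QC when the SD is at most `cutoff`
#' (default 0.1).
#'
#' @param profile a `coverage_profile`.
#' @param aneuploid_chromosomes chromosomes to exclude.
#' @param cutoff pass threshold on the SD (default 0.1).
#' @return list of class `qc_result` with `genome_sd`,
#'   `excluded_chromosomes`, `pass`.
#' @export
qc_genome_sd <- function(profile, aneuploid_chromosomes = character(),
                         cutoff = 0.1) {
  sg <- sliding_grid(profile$model)
  keep <- !(sg$chrom %in% aneuploid_chromosomes) &
    is.finite(profile$ratio_sliding)
  if (identical(profile$sex, "XY"))
    keep <- keep & !grepl("(^|chr)[XY]$", sg$chrom)
  if (sum(keep) < 100)
    stop("fewer than 100 usable windows for QC", call. = FALSE)
  sd_ <- stats::sd(profile$ratio_sliding[keep])
  structure(list(genome_sd = sd_,
                 excluded_chromosomes = aneuploid_chromosomes,
                 pass = sd_ <= cutoff),
            class = "qc_result")
}
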