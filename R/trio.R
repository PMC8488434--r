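#' Reciprocal overlap of two intervals
#'
#' `min(overlap/len1, overlap/len2)` for 1-based inclusive intervals;
#' 0 when disjoint. The standard CNV concordance measure.
#'
#' @param s1,e1 first interval.
#' @param s2,e2 second interval.
#' @return numeric in [0, 1].
#' @export
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

.type_class <- function(type) {
  ifelse(type %in% c("het_del", "hom_del", "hemi_del", "del"), "loss", "gain")
}

#' Match a call against a set of candidate calls
#'
#' A candidate matches iff it lies on the same chromosome, is of the
#' same direction class (loss vs gain), and overlaps the call
#' reciprocally by at least `min_reciprocal_overlap`. The best match has
#' the greatest reciprocal overlap; ties break to the candidate with
#' the smallest absolute size difference.
#'
#' @param call one-row call data.frame (`chrom`, `start`, `end`, `type`).
#' @param candidates call data.frame to search.
#' @param min_reciprocal_overlap threshold (default 0.5).
#' @return the matching row index into `candidates`, or `NA` if none.
#' @export
match_calls <- function(call, candidates, min_reciprocal_overlap = 0.5) {
  if (is.null(candidates) || !nrow(candidates)) return(NA_integer_)
  ok <- candidates$chrom == call$chrom &
    .type_class(candidates$type) == .type_class(call$type)
  if (!any(ok)) return(NA_integer_)
  ro <- vapply(which(ok), function(j)
    reciprocal_overlap(call$start, call$end,
                       candidates$start[j], candidates$end[j]),
    numeric(1))
  hit <- ro >= min_reciprocal_overlap
  if (!any(hit)) return(NA_integer_)
  cand <- which(ok)[hit]
  ro <- ro[hit]
  best <- which(ro > max(ro) - 1e-12)
  if (length(best) > 1) {
    dsz <- abs((candidates$end[cand[best]] - candidates$start[cand[best]]) -
                 (call$end - call$start))
    best <- best[which.min(dsz)]
  }
  cand[best[1]]
}

# Mean fine copy ratio of a profile over a region.
.region_ratio <- function(profile, chrom, start, end) {
  r <- profile$ratio_fine[.fine_idx(profile$model, chrom, start, end)]
  mean(r[is.finite(r)])
}

#' Assign mode of inheritance to proband calls
#'
#' Each proband call's coordinates and type class are compared to the
#' parental call sets: matched in one parent gives maternal/paternal, in
#' both biparental. An unmatched call is de novo only if both parents'
#' raw copy ratios over the region stay within the no-evidence band:
#' within 1 +/- half the single-allele deviation the event implies
#' (half the proband deviation for heterozygous events, a quarter for
#' homozygous deletions/triplications, whose carrier parents sit at
#' half the proband deviation). A parent whose region ratio deviates
#' beyond that threshold in the event direction rescues the call as
#' inherited (flagged), guarding against a parental call missed by
#' thresholding.
#'
#' @param proband_calls call data.frame for the proband.
#' @param father_calls,mother_calls parental call data.frames.
#' @param father_profile,mother_profile parental `coverage_profile`s on
#'   the same grid as the proband's.
#' @param min_reciprocal_overlap match threshold (default 0.5).
#' @return `proband_calls` with added columns `inheritance`
#'   (`de_novo`/`maternal`/`paternal`/`biparental`), `rescued`
#'   (logical), `father_ratio`, `mother_ratio`.
#' @export
assign_inheritance <- function(proband_calls, father_calls, mother_calls,
                               father_profile, mother_profile,
                               min_reciprocal_overlap = 0.5) {
  fp <- .grid_fingerprint(father_profile$model)
  if (!identical(fp, .grid_fingerprint(mother_profile$model)))
    stop("parental profiles are on different grids", call. = FALSE)
  n <- nrow(proband_calls)
  inheritance <- character(n); rescued <- logical(n)
  fr <- numeric(n); mr <- numeric(n)
  for (i in seq_len(n)) {
    call <- proband_calls[i, , drop = FALSE]
    in_f <- !is.na(match_calls(call, father_calls, min_reciprocal_overlap))
    in_m <- !is.na(match_calls(call, mother_calls, min_reciprocal_overlap))
    fr[i] <- .region_ratio(father_profile, call$chrom, call$start, call$end)
    mr[i] <- .region_ratio(mother_profile, call$chrom, call$start, call$end)
    if (in_f && in_m) inheritance[i] <- "biparental"
    else if (in_f) inheritance[i] <- "paternal"
    else if (in_m) inheritance[i] <- "maternal"
    else {
      dev <- call$mean_ratio - 1
      sgn <- sign(dev)
      # a transmitting parent carries one changed allele, so its expected
      # deviation is dev / copies_changed; the evidence threshold sits
      # halfway there (dev/2 for het events, dev/4 for hom-del/trp)
      thr <- abs(dev) / (2 * .copies_changed(call$type))
      f_dev <- sgn * (fr[i] - 1) > thr  # deviates in event direction
      m_dev <- sgn * (mr[i] - 1) > thr
      if (f_dev && m_dev) { inheritance[i] <- "biparental"; rescued[i] <- TRUE }
      else if (f_dev) { inheritance[i] <- "paternal"; rescued[i] <- TRUE }
      else if (m_dev) { inheritance[i] <- "maternal"; rescued[i] <- TRUE }
      else inheritance[i] <- "de_novo"
    }
  }
  proband_calls$inheritance <- inheritance
  proband_calls$rescued <- rescued
  proband_calls$father_ratio <- fr
  proband_calls$mother_ratio <- mr
  proband_calls
}

#' Filter assignments to rare CNVs
#'
#' A call is retained iff no frequency-table locus matches it (same
#' chromosome, direction class and reciprocal overlap, per
#' [match_calls()]) with carrier frequency at or above `threshold`
#' (default 1%).
#'
#' @param assignments call data.frame (any schema with `chrom`, `start`,
#'   `end`, `type`).
#' @param frequency_table data.frame with `chrom`, `start`, `end`,
#'   `type`, `frequency`.
#' @param threshold rarity threshold on carrier frequency (default 0.01).
#' @param min_reciprocal_overlap match threshold (default 0.5).
#' @return the rare subset of `assignments`.
#' @export
filter_rare <- function(assignments, frequency_table, threshold = 0.01,
                        min_reciprocal_overlap = 0.5) {
  if (!nrow(assignments)) return(assignments)
  if (is.null(frequency_table) || !nrow(frequency_table))
    return(assignments)
  common <- frequency_table[frequency_table$frequency >= threshold, ,
                            drop = FALSE]
  if (!nrow(common)) return(assignments)
  hit <- vapply(seq_len(nrow(assignments)), function(i)
    !is.na(match_calls(assignments[i, , drop = FALSE], common,
                       min_reciprocal_overlap)),
    logical(1))
  assignments[!hit, , drop = FALSE]
}
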