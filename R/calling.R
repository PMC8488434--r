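#' Caller configuration
#'
#' Thresholds of the CNV caller. Defaults follow the reporting rules of
#' trio low-pass sequencing practice: 50-kb coarse resolution with 5-kb
#' refinement, homozygous/hemizygous deletions called down to 10 kb at
#' copy ratio 0.0-0.1 over two or more consecutive fine windows, and
#' minimal detectable mosaic levels of 30% for events under 2.5 Mb and
#' 20% for larger ones.
#'
#' @param coarse_resolution minimum CNV size reported from the sliding
#'   grid, bp (default 50000).
#' @param fine_resolution fine window size, bp (default 5000).
#' @param homdel_ratio_ceiling copy-ratio ceiling for homozygous
#'   deletion windows (default 0.1).
#' @param homdel_min_windows minimum consecutive fine windows (default 2).
#' @param mosaic_min_small minimal mosaic fraction for events smaller
#'   than `mosaic_size_boundary` (default 0.30).
#' @param mosaic_min_large minimal mosaic fraction for larger events
#'   (default 0.20).
#' @param mosaic_size_boundary size separating the two minima, bp
#'   (default 2.5e6).
#' @param detection_z z-score threshold marking a sliding window as
#'   deviant against the panel dispersion (default 3).
#' @param min_marked_run minimum run of consecutive marked sliding
#'   windows a candidate segment must contain (default 10, one full
#'   sliding span): a real event at the coarse resolution contains at
#'   least one sliding window composed entirely of deviant fine windows
#'   and marks ~13 consecutive windows, while smoothing-correlated noise
#'   excursions rarely persist a full span.
#' @param filter_alpha per-test significance level of the three
#'   statistical screens (default 1e-3).
#' @param refinement_span search span around each coarse boundary for
#'   breakpoint refinement, bp (default 1e5).
#' @param constitutional_min mosaic fraction at or above which a call is
#'   reported constitutional (default 0.9).
#' @param qc_cutoff genome-wide copy-ratio SD cutoff (default 0.1).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(coarse_resolution = 50000,
                          fine_resolution = 5000,
                          homdel_ratio_ceiling = 0.1,
                          homdel_min_windows = 2L,
                          mosaic_min_small = 0.30,
                          mosaic_min_large = 0.20,
                          mosaic_size_boundary = 2.5e6,
                          detection_z = 3,
                          min_marked_run = 10L,
                          filter_alpha = 1e-3,
                          refinement_span = 1e5,
                          constitutional_min = 0.9,
                          qc_cutoff = 0.1) {
  stopifnot(coarse_resolution > 0, fine_resolution > 0,
            homdel_ratio_ceiling > 0, homdel_min_windows >= 1,
            mosaic_min_large <= mosaic_min_small,
            detection_z > 0, filter_alpha > 0, refinement_span > 0)
  structure(as.list(environment()), class = "caller_config")
}

#' Mosaic level from the mean copy ratio
#'
#' A variant present in a fraction `f` of cells shifts the expected copy
#' ratio by `f * copies_changed / 2`, so
#' `f = 2 * |mean_ratio - 1| / copies_changed`, clipped to (0, 1]. A
#' constitutional heterozygous deletion (ratio 0.5) gives 1.0; ratio
#' 0.75 gives 0.5.
#'
#' @param mean_ratio observed mean copy ratio of the event.
#' @param direction `"loss"` or `"gain"`; must agree with the ratio.
#' @param copies_changed copies gained/lost in variant cells (1 for het
#'   deletion or single-copy gain, 2 for homozygous deletion or
#'   triplication).
#' @return mosaic fraction in (0, 1].
#' @export
estimate_mosaic_level <- function(mean_ratio,
                                  direction = c("loss", "gain"),
                                  copies_changed = 1) {
  direction <- match.arg(direction)
  if (mean_ratio < 0) stop("mean_ratio must be >= 0", call. = FALSE)
  dev <- mean_ratio - 1
  if (abs(dev) < 1e-9)
    stop("mosaic level undefined at copy ratio 1", call. = FALSE)
  if ((direction == "loss") != (dev < 0))
    stop("direction inconsistent with mean_ratio", call. = FALSE)
  min(2 * abs(dev) / copies_changed, 1)
}

#' Detect whole-chromosome aneuploidies
#'
#' A chromosome is flagged when its mean fine-window copy ratio deviates
#' from 1 by more than `detection_z` standard errors and by at least
#' half the large-event mosaic floor (so the 20% minimal mosaic level
#' for large events applies, and a focal CNV cannot tip a whole
#' chromosome).
#'
#' @param profile a `coverage_profile`.
#' @param config a `caller_config`.
#' @return data.frame with `chrom`, `mean_ratio`, `direction`,
#'   `mosaic_fraction`, `constitutional` (zero rows if none).
#' @export
detect_aneuploidy <- function(profile, config = caller_config()) {
  w <- profile$model$windows
  floor_dev <- config$mosaic_min_large / 2
  chroms <- names(profile$model$chrom_lengths)
  # X/Y of an XY sample sit at ratio ~0.5/0 against a diploid panel and
  # need a sex-matched panel subset; skipped at this panel's scale
  if (identical(profile$sex, "XY"))
    chroms <- chroms[!grepl("(^|chr)[XY]$", chroms)]
  out <- lapply(chroms, function(ch) {
    r <- profile$ratio_fine[w$chrom == ch]
    r <- r[is.finite(r)]
    if (length(r) < 10) return(NULL)
    m <- mean(r)
    se <- stats::sd(r) / sqrt(length(r))
    if (abs(m - 1) <= max(config$detection_z * se, floor_dev)) return(NULL)
    dirn <- if (m < 1) "loss" else "gain"
    f <- estimate_mosaic_level(m, dirn, 1)
    data.frame(chrom = ch, mean_ratio = m,
               direction = if (m < 1) "loss" else "gain",
               mosaic_fraction = f,
               constitutional = f >= config$constitutional_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), mean_ratio = numeric(),
                      direction = character(), mosaic_fraction = numeric(),
                      constitutional = logical(), stringsAsFactors = FALSE)
  out
}

#' Coarse CNV segmentation on the sliding grid
#'
#' Marks sliding windows whose copy ratio deviates from 1 by more than
#' `detection_z` times the panel's per-window dispersion, merges marked
#' windows of the same direction that overlap or abut, requires each
#' cluster to contain at least `min_marked_run` consecutive marked
#' windows, and drops segments shorter than the coarse resolution.
#'
#' @param profile a `coverage_profile`.
#' @param panel_stats the `panel_stats` the profile was normalized with.
#' @param config a `caller_config`.
#' @param exclude_chromosomes chromosomes (e.g. aneuploid ones) to skip.
#' @return data.frame of coarse segments: `chrom`, `start`, `end`,
#'   `direction`.
#' @export
segment_candidate_cnvs <- function(profile, panel_stats,
                                   config = caller_config(),
                                   exclude_chromosomes = character()) {
  sg <- sliding_grid(profile$model)
  dev <- profile$ratio_sliding - 1
  disp <- panel_stats$dispersion_sliding
  segs <- list()
  chroms <- setdiff(names(profile$model$chrom_lengths),
                    exclude_chromosomes)
  if (identical(profile$sex, "XY"))
    chroms <- chroms[!grepl("(^|chr)[XY]$", chroms)]
  for (ch in chroms) {
    rows <- which(sg$chrom == ch)
    for (dirn in c("loss", "gain")) {
      d <- dev[rows]
      marked <- is.finite(d) & is.finite(disp[rows]) &
        (if (dirn == "loss") -d else d) > config$detection_z * disp[rows]
      idx <- which(marked)
      if (!length(idx)) next
      # cluster marked windows whose intervals overlap or abut:
      # sliding windows i, j overlap/abut iff |i - j| <= n_fine (10)
      brk <- c(0, which(diff(idx) > 10L), length(idx))
      for (b in seq_len(length(brk) - 1L)) {
        members <- idx[(brk[b] + 1L):brk[b + 1L]]
        runs <- rle(diff(members) == 1L)
        max_run <- if (length(members) == 1L) 1L else
          max(c(1L, runs$lengths[runs$values] + 1L))
        if (max_run < config$min_marked_run) next
        s <- sg$start[rows[members[1L]]]
        e <- sg$end[rows[members[length(members)]]]
        if (e - s + 1 < config$coarse_resolution) next
        segs[[length(segs) + 1L]] <-
          data.frame(chrom = ch, start = s, end = e, direction = dirn,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Refine segment breakpoints on the fine grid
#'
#' The increment-rate-of-coverage style refinement: around each coarse
#' boundary, fine-window copy ratios within `refinement_span` are fitted
#' with a two-segment step (cumulative-sum change-point), and the
#' boundary moves to the fine-window edge maximizing the between-segment
#' mean contrast. Ties resolve to the edge closest to the coarse
#' boundary, so a flat profile leaves the boundary unchanged.
#'
#' @param segment one-row data.frame with `chrom`, `start`, `end`.
#' @param profile a `coverage_profile`.
#' @param config a `caller_config`.
#' @return the segment with refined `start` and `end`.
#' @export
refine_breakpoints_irc <- function(segment, profile,
                                   config = caller_config()) {
  w <- profile$model$windows
  fs <- profile$model$fine_window_size
  span_w <- ceiling(config$refinement_span / fs)
  rows <- which(w$chrom == segment$chrom)
  r <- profile$ratio_fine[rows]
  r[!is.finite(r)] <- 1  # masked windows carry no step evidence
  k <- length(r)
  wi_start <- (segment$start - 1) %/% fs + 1  # first fine window inside
  wi_end <- segment$end %/% fs                # last fine window inside
  mid <- (wi_start + wi_end) / 2

  # best split s in (a, b]: boundary sits before fine window s
  best_split <- function(a, b, prefer) {
    a <- max(a, 1L); b <- min(b, k)
    cand <- (a + 1L):b
    if (!length(cand)) return(prefer)
    cs <- cumsum(c(0, r[a:b]))
    n <- b - a + 1L
    i <- cand - a  # left part has i values
    # CUSUM-weighted mean contrast: plain |m1 - m2| is dominated by tiny
    # noisy edge groups; the sqrt(n1 n2 / n) weight makes the maximizer
    # the change point
    contrast <- sqrt(i * (n - i) / n) *
      abs(cs[i + 1] / i - (cs[n + 1] - cs[i + 1]) / (n - i))
    top <- which(contrast > max(contrast) - 1e-12)
    cand[top[which.min(abs(cand[top] - prefer))]]
  }

  # outward reach is the configured span; inward reach extends to the
  # segment midpoint, since coarse segments overshoot true boundaries
  # by however far marked sliding windows extend past the event
  s_new <- best_split(wi_start - span_w, floor(mid), wi_start)
  e_new <- best_split(ceiling(mid), wi_end + span_w + 1L, wi_end + 1L) - 1L
  segment$start <- (s_new - 1) * fs + 1
  segment$end <- e_new * fs
  segment
}

#' Scan for homozygous/hemizygous deletions on the fine grid
#'
#' Maximal runs of at least `homdel_min_windows` consecutive fine
#' windows with copy ratio between 0 and `homdel_ratio_ceiling` are
#' called (>= 10 kb at the defaults). On male X/Y the loss of the single
#' copy is labelled hemizygous.
#'
#' @param profile a `coverage_profile` (its `sex` field drives the
#'   hemizygous label).
#' @param config a `caller_config`.
#' @return data.frame of calls (possibly empty) in the standard call
#'   schema (see [call_cnvs()]).
#' @export
detect_homozygous_deletions <- function(profile, config = caller_config()) {
  w <- profile$model$windows
  fs <- profile$model$fine_window_size
  out <- list()
  for (ch in names(profile$model$chrom_lengths)) {
    rows <- which(w$chrom == ch)
    r <- profile$ratio_fine[rows]
    low <- is.finite(r) & r >= 0 & r <= config$homdel_ratio_ceiling
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (j in which(rl$values & rl$lengths >= config$homdel_min_windows)) {
      i1 <- starts[j]; i2 <- ends[j]
      mr <- mean(r[i1:i2])
      sex_chrom <- grepl("(^|chr)[XY]$", ch)
      type <- if (sex_chrom && identical(profile$sex, "XY"))
        "hemi_del" else "hom_del"
      frac <- tryCatch(
        estimate_mosaic_level(mr, "loss",
                              copies_changed = if (type == "hemi_del") 1 else 2),
        error = function(e) 1)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = w$start[rows[i1]], end = w$end[rows[i2]],
        type = type, mean_ratio = mr, mosaic_fraction = frac,
        size_bp = (i2 - i1 + 1L) * fs,
        n_fine_windows = i2 - i1 + 1L,
        p_utest = NA_real_, p_t_sample = NA_real_, p_t_chrom = NA_real_,
        filter_evaluable = NA, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- .empty_calls()
  out
}

.empty_calls <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             type = character(), mean_ratio = numeric(),
             mosaic_fraction = numeric(), size_bp = numeric(),
             n_fine_windows = integer(), p_utest = numeric(),
             p_t_sample = numeric(), p_t_chrom = numeric(),
             filter_evaluable = logical(), stringsAsFactors = FALSE)
}

# Exact two-sided rank (permutation) p for one observation vs a panel.
.rank_p <- function(x, panel) {
  n <- length(panel)
  lo <- sum(panel <= x) + 1L
  hi <- sum(panel >= x) + 1L
  min(1, 2 * min(lo, hi) / (n + 1))
}

#' Apply the three statistical false-positive screens to calls
#'
#' For each call: a population rank (U) test of the proband's
#' region-mean copy ratio against the panel samples' region means, a
#' whole-sample Welch t of the region's fine ratios against all other
#' autosomal fine ratios, and a whole-chromosome Welch t against the
#' remaining fine ratios of the call's chromosome. A call is kept when
#' all three p-values are at most `filter_alpha`; regions the panel does
#' not cover are marked not evaluable and retained.
#'
#' @param calls call data.frame (see [call_cnvs()]).
#' @param profile the proband's `coverage_profile`.
#' @param panel_stats the `panel_stats` (supplies the panel ratio
#'   matrix).
#' @param config a `caller_config`.
#' @return `calls` with `p_utest`, `p_t_sample`, `p_t_chrom`,
#'   `filter_evaluable` filled and a logical `keep` column.
#' @export
statistical_filter <- function(calls, profile, panel_stats,
                               config = caller_config()) {
  if (!nrow(calls)) { calls$keep <- logical(0); return(calls) }
  w <- profile$model$windows
  auto <- !grepl("(^|chr)[XY]$", w$chrom)
  for (i in seq_len(nrow(calls))) {
    idx <- .fine_idx(profile$model, calls$chrom[i], calls$start[i],
                     calls$end[i])
    reg <- profile$ratio_fine[idx]
    reg <- reg[is.finite(reg)]
    if (length(reg) < 2) {
      calls$filter_evaluable[i] <- FALSE
      next
    }
    pm <- mean(reg)
    panel_reg <- panel_stats$ratios_fine[idx, , drop = FALSE]
    panel_means <- colMeans(panel_reg, na.rm = TRUE)
    panel_means <- panel_means[is.finite(panel_means)]
    if (!length(panel_means)) {
      calls$filter_evaluable[i] <- FALSE
      next
    }
    chrom_rows <- which(w$chrom == calls$chrom[i])
    rest_chrom <- profile$ratio_fine[setdiff(chrom_rows, idx)]
    rest_auto <- profile$ratio_fine[setdiff(which(auto), idx)]
    if (!any(auto)) rest_auto <- rest_chrom  # all-sex-chromosome models
    calls$p_utest[i] <- .rank_p(pm, panel_means)
    calls$p_t_sample[i] <-
      stats::t.test(reg, rest_auto[is.finite(rest_auto)])$p.value
    calls$p_t_chrom[i] <-
      stats::t.test(reg, rest_chrom[is.finite(rest_chrom)])$p.value
    calls$filter_evaluable[i] <- TRUE
  }
  ev <- calls$filter_evaluable %in% TRUE
  keep <- rep(TRUE, nrow(calls))  # non-evaluable calls retained, flagged
  keep[ev] <- calls$p_utest[ev] <= config$filter_alpha &
    calls$p_t_sample[ev] <= config$filter_alpha &
    calls$p_t_chrom[ev] <= config$filter_alpha
  calls$keep <- keep
  calls
}

#' Minimal mosaic-level gate
#'
#' Keeps a call iff its mosaic fraction reaches the detection floor for
#' its size class: `mosaic_min_small` (default 30%) below
#' `mosaic_size_boundary` (2.5 Mb), `mosaic_min_large` (20%) at or
#' above it.
#'
#' @param calls call data.frame with `size_bp` and `mosaic_fraction`.
#' @param config a `caller_config`.
#' @return logical vector, `TRUE` to keep.
#' @export
apply_mosaic_threshold <- function(calls, config = caller_config()) {
  ifelse(calls$size_bp < config$mosaic_size_boundary,
         calls$mosaic_fraction >= config$mosaic_min_small,
         calls$mosaic_fraction >= config$mosaic_min_large)
}

# Type a refined segment from its mean ratio and direction.
.type_call <- function(mean_ratio, direction) {
  if (direction == "loss") {
    if (mean_ratio < 0.25) "hom_del" else "het_del"
  } else {
    if (mean_ratio > 1.75) "trp" else "dup"
  }
}

.copies_changed <- function(type) if (type %in% c("hom_del", "trp")) 2 else 1

#' Call CNVs and aneuploidies from a coverage profile
#'
#' The full calling pipeline: genome-wide QC (with aneuploid
#' chromosomes excluded from the SD), aneuploidy detection, coarse
#' segmentation on the sliding grid, breakpoint refinement on the fine
#' grid, mosaic-level estimation and gating, the three statistical
#' screens, and the homozygous-deletion scan merged in last. Calls are
#' sorted by (chrom, start).
#'
#' @param profile a `coverage_profile`.
#' @param panel_stats a `panel_stats` on the same grid.
#' @param config a `caller_config`.
#' @param override_qc call anyway on a QC-failing profile.
#' @return list with `qc` (a `qc_result`), `aneuploidies` and `calls`
#'   data.frames; `calls` columns: `chrom`, `start`, `end`, `type`
#'   (het_del/hom_del/hemi_del/dup/trp), `mean_ratio`,
#'   `mosaic_fraction`, `size_bp`, `n_fine_windows`, the three filter
#'   p-values, `filter_evaluable`, `keep`.
#' @export
call_cnvs <- function(profile, panel_stats, config = caller_config(),
                      override_qc = FALSE) {
  aneu <- detect_aneuploidy(profile, config)
  qc <- qc_genome_sd(profile, aneu$chrom, cutoff = config$qc_cutoff)
  if (!qc$pass && !override_qc)
    stop("sample failed QC (genome SD ",
         sprintf("%.3f", qc$genome_sd), " > ", config$qc_cutoff,
         "); use override_qc = TRUE to force", call. = FALSE)
  profile$qc <- qc

  segs <- segment_candidate_cnvs(profile, panel_stats, config,
                                 exclude_chromosomes = aneu$chrom)
  calls <- .empty_calls()
  if (nrow(segs)) {
    refined <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i)
      refine_breakpoints_irc(segs[i, , drop = FALSE], profile, config)))
    rec <- lapply(seq_len(nrow(refined)), function(i) {
      idx <- .fine_idx(profile$model, refined$chrom[i], refined$start[i],
                       refined$end[i])
      reg <- profile$ratio_fine[idx]
      mr <- mean(reg[is.finite(reg)])
      type <- .type_call(mr, refined$direction[i])
      frac <- tryCatch(
        estimate_mosaic_level(mr, refined$direction[i],
                              .copies_changed(type)),
        error = function(e) NA_real_)
      data.frame(chrom = refined$chrom[i], start = refined$start[i],
                 end = refined$end[i], type = type, mean_ratio = mr,
                 mosaic_fraction = frac,
                 size_bp = refined$end[i] - refined$start[i] + 1,
                 n_fine_windows = length(idx),
                 p_utest = NA_real_, p_t_sample = NA_real_,
                 p_t_chrom = NA_real_, filter_evaluable = NA,
                 stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rec)
    calls <- calls[!is.na(calls$mosaic_fraction), , drop = FALSE]
    calls <- calls[apply_mosaic_threshold(calls, config), , drop = FALSE]
    calls <- statistical_filter(calls, profile, panel_stats, config)
    calls <- calls[calls$keep, , drop = FALSE]
    calls$keep <- NULL
  }

  hom <- detect_homozygous_deletions(profile, config)
  hom <- hom[!hom$chrom %in% aneu$chrom, , drop = FALSE]
  if (nrow(hom)) {
    # report filter p-values, but the run-length rule is the screen here
    hom <- statistical_filter(hom, profile, panel_stats, config)
    hom$keep <- NULL
    dup_of_coarse <- vapply(seq_len(nrow(hom)), function(i) {
      same <- calls[calls$type %in% c("hom_del", "hemi_del", "het_del"), ,
                    drop = FALSE]
      any(vapply(seq_len(nrow(same)), function(j)
        reciprocal_overlap(hom$start[i], hom$end[i],
                           same$start[j], same$end[j]) >= 0.5 &
          same$chrom[j] == hom$chrom[i], logical(1)))
    }, logical(1))
    hom <- hom[!dup_of_coarse, , drop = FALSE]
    calls <- rbind(calls, hom)
  }
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  list(qc = qc, aneuploidies = aneu, calls = calls)
}
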