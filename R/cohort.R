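#' Wilson score confidence interval for a proportion
#'
#' The Wilson score interval without continuity correction: with
#' `p = x/n` and `z` the two-sided normal quantile,
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @examples
#' wilson_ci(39, 315)   # ~ (0.0919, 0.1648)
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("successes must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  bounds <- c((center - half) / denom, (center + half) / denom)
  pmin(pmax(bounds, 0), 1)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1. Tables with a zero margin are
#' rejected (route those to [fisher_exact_2x2()]).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `statistic` and `p.value`.
#' @export
pearson_chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin; use the Fisher exact test", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables (with
#' the observed margins) no more probable than the observed one — the
#' convention of [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  stats::fisher.test(table)$p.value
}

#' Kruskal-Wallis rank-sum test
#'
#' H with tie correction, p from the chi-square distribution with
#' k - 1 df. If every pooled value is identical, H is 0 and p is 1 by
#' convention (with a warning).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    warning("all values identical; H = 0, p = 1 by convention")
    return(list(statistic = 0, p.value = 1))
  }
  ht <- stats::kruskal.test(groups)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Summarize a cohort of classified calls (referral-table shape)
#'
#' Builds the per-indication incidence table of a trio CNV study: cases
#' enrolled, cases with at least one rare CNV, total rare CNVs and the
#' per-case rate, de novo cases and counts, cases/counts with small
#' (< `small_bp`) or mosaic (fraction < `mosaic_below`) CNVs, cases
#' requiring parental analysis, and the diagnostic (P/LP) yield with a
#' Wilson confidence interval. An overall `Total` row is appended.
#'
#' @param cases data.frame with `case_id` and `indication` (one row per
#'   enrolled case).
#' @param calls data.frame of classified rare calls with `case_id`,
#'   `inheritance`, `size_bp`, `mosaic_fraction`, `category`,
#'   `requires_parental_analysis`.
#' @param small_bp small-CNV boundary in bp (default 1e5).
#' @param mosaic_below constitutional/mosaic boundary on the fraction
#'   (default 0.9).
#' @param confidence level of the Wilson interval (default 0.95).
#' @return data.frame, one row per indication plus `Total`.
#' @export
summarize_cohort <- function(cases, calls, small_bp = 1e5,
                             mosaic_below = 0.9, confidence = 0.95) {
  stopifnot(all(c("case_id", "indication") %in% names(cases)))
  if (nrow(calls) && !all(calls$case_id %in% cases$case_id))
    stop("calls reference unknown case ids", call. = FALSE)
  one <- function(ids, label) {
    cc <- calls[calls$case_id %in% ids, , drop = FALSE]
    n <- length(ids)
    dx_cases <- unique(cc$case_id[cc$category %in%
                                    c("pathogenic", "likely_pathogenic")])
    small_or_mosaic <- cc$size_bp < small_bp |
      cc$mosaic_fraction < mosaic_below
    ci <- if (n > 0) wilson_ci(length(dx_cases), n, confidence) else c(0, 0)
    data.frame(
      indication = label,
      enrolled = n,
      cases_with_rare_cnv = length(unique(cc$case_id)),
      rare_cnvs = nrow(cc),
      rare_cnvs_per_case = if (n > 0) nrow(cc) / n else 0,
      de_novo_cases = length(unique(cc$case_id[cc$inheritance == "de_novo"])),
      de_novo_cnvs = sum(cc$inheritance == "de_novo"),
      small_or_mosaic_cases = length(unique(cc$case_id[small_or_mosaic])),
      small_or_mosaic_cnvs = sum(small_or_mosaic),
      parental_analysis_cases =
        length(unique(cc$case_id[cc$requires_parental_analysis %in% TRUE])),
      diagnostic_cases = length(dx_cases),
      diagnostic_yield = if (n > 0) length(dx_cases) / n else 0,
      yield_ci_lower = ci[1], yield_ci_upper = ci[2],
      stringsAsFactors = FALSE)
  }
  by_ind <- lapply(split(cases$case_id, cases$indication),
                   function(ids) ids)
  out <- do.call(rbind, Map(one, by_ind, names(by_ind)))
  out <- rbind(out, one(cases$case_id, "Total"))
  rownames(out) <- NULL
  out
}
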