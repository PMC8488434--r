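#!/usr/bin/env Rscript
# Step 6 -- cohort statistics: the referral-indication incidence table
# with Wilson confidence intervals, plus the 2x2 and rank-sum
# comparisons the package exposes.
#
# Input:  scratch/cohort_state.rds (after 05_classify.R)
# Output: results/cohort_summary.tsv

library(triocnv)

state <- readRDS("scratch/cohort_state.rds")
if (is.null(state$classified)) stop("run 05_classify.R first")

set.seed(606)
cases <- data.frame(
  case_id = vapply(state$trios, `[[`, "", "trio_id"),
  indication = sample(c("abnormal_ultrasound", "nipt_high_risk",
                        "advanced_maternal_age"), 12, replace = TRUE),
  stringsAsFactors = FALSE)

cc <- state$classified[state$classified$rare, , drop = FALSE]
calls <- data.frame(case_id = cc$trio_id, inheritance = cc$inheritance,
                    size_bp = cc$size_bp,
                    mosaic_fraction = cc$mosaic_fraction,
                    category = cc$category,
                    requires_parental_analysis =
                      cc$requires_parental_analysis,
                    stringsAsFactors = FALSE)

summary_tab <- summarize_cohort(cases, calls)
write.table(summary_tab, "results/cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- summary_tab[summary_tab$indication == "Total", ]
message(sprintf(
  "%d trios: %.1f rare CNVs per case; %.1f%% of cases carry >=1 rare CNV",
  tot$enrolled, tot$rare_cnvs_per_case,
  100 * tot$cases_with_rare_cnv / tot$enrolled))
message(sprintf(
  "diagnostic yield %.1f%% (Wilson 95%% CI %.1f-%.1f%%)",
  100 * tot$diagnostic_yield, 100 * tot$yield_ci_lower,
  100 * tot$yield_ci_upper))

# size comparison: de novo vs inherited call sizes (rank-sum)
dn_sizes <- calls$size_bp[calls$inheritance == "de_novo"]
inh_sizes <- calls$size_bp[calls$inheritance != "de_novo"]
if (length(dn_sizes) >= 2 && length(inh_sizes) >= 2) {
  kw <- kruskal_wallis(list(de_novo = dn_sizes, inherited = inh_sizes))
  message(sprintf("de novo vs inherited size distribution: H = %.2f, p = %.3f",
                  kw$statistic, kw$p.value))
}

# incidence comparison between the two largest indication groups
grp <- table(cases$indication)
if (length(grp) >= 2) {
  top2 <- names(sort(grp, decreasing = TRUE))[1:2]
  n <- as.integer(grp[top2])
  x <- vapply(top2, function(g)
    length(unique(calls$case_id[calls$case_id %in%
                                  cases$case_id[cases$indication == g]])),
    integer(1))
  p <- fisher_exact_2x2(matrix(c(x, n - x), 2))
  message(sprintf(
    "rare-CNV incidence %s vs %s: %d/%d vs %d/%d (Fisher p = %.3f)",
    top2[1], top2[2], x[1], n[1], x[2], n[2], p))
}

message("cohort table written to results/cohort_summary.tsv")
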