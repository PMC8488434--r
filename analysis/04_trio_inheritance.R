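#!/usr/bin/env Rscript
# Step 4 -- assign each proband call a mode of inheritance from the
# parental calls and coverage profiles, filter to rare CNVs against the
# panel frequency table, and score de novo assignment against truth.
#
# Input:  scratch/cohort_state.rds (after 03_call_cnvs.R)
# Output: results/assignments.tsv

library(triocnv)

state <- readRDS("scratch/cohort_state.rds")
if (is.null(state$calls)) stop("run 03_call_cnvs.R first")

get_calls <- function(id) {
  cc <- state$calls[state$calls$sample == id, , drop = FALSE]
  cc$sample <- NULL
  cc
}

asg_rows <- list()
for (t in state$trios) {
  tid <- t$trio_id
  pro <- get_calls(paste0(tid, "_proband"))
  if (!nrow(pro)) next
  asg <- assign_inheritance(pro,
                            get_calls(paste0(tid, "_father")),
                            get_calls(paste0(tid, "_mother")),
                            state$profiles[[paste0(tid, "_father")]],
                            state$profiles[[paste0(tid, "_mother")]])
  rare <- filter_rare(asg, state$frequency_table, threshold = 0.01)
  asg$rare <- seq_len(nrow(asg)) %in%
    which(paste(asg$start, asg$end, asg$type) %in%
            paste(rare$start, rare$end, rare$type))
  asg$trio_id <- tid
  asg_rows[[tid]] <- asg
}
assignments <- do.call(rbind, asg_rows)
rownames(assignments) <- NULL
write.table(assignments, "results/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "%d proband calls: %d de novo, %d maternal, %d paternal, %d biparental (%d rescued from raw parental coverage)",
  nrow(assignments), sum(assignments$inheritance == "de_novo"),
  sum(assignments$inheritance == "maternal"),
  sum(assignments$inheritance == "paternal"),
  sum(assignments$inheritance == "biparental"),
  sum(assignments$rescued)))
message(sprintf("%d calls removed by the <1%% panel-frequency rule",
                sum(!assignments$rare)))
message("(the common 2.6% panel deletion never reaches this filter: its ",
        "carriers sit in the panel, so the population U-test already ",
        "screens it out during calling)")

# score the de novo labels against the simulation truth
truth_dn <- do.call(rbind, lapply(state$trios, function(t) {
  tt <- t$truth
  tt <- tt[tt$carrier == "proband", , drop = FALSE]
  if (!nrow(tt)) return(NULL)
  tt$trio_id <- t$trio_id
  tt
}))
pred_dn <- assignments[assignments$inheritance == "de_novo", , drop = FALSE]
tp <- 0
if (!is.null(truth_dn)) {
  for (i in seq_len(nrow(truth_dn))) {
    hit <- pred_dn$trio_id == truth_dn$trio_id[i] &
      vapply(seq_len(nrow(pred_dn)), function(j)
        reciprocal_overlap(truth_dn$start[i], truth_dn$end[i],
                           pred_dn$start[j], pred_dn$end[j]) >= 0.5,
        logical(1))
    tp <- tp + any(hit)
  }
  message(sprintf("de novo truth events: %d; recovered %d; %d extra de novo labels",
                  nrow(truth_dn), tp, nrow(pred_dn) - tp))
}

state$assignments <- assignments
saveRDS(state, "scratch/cohort_state.rds")
message("assignments written to results/assignments.tsv")
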