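#!/usr/bin/env Rscript
# Step 1 -- simulate the study material: a desk-scale genome, a
# 2,000-sample reference panel with polymorphic CNV loci, and 12
# sequenced trios carrying a mix of inherited, de novo, mosaic and
# biparental events at ~0.25-fold coverage.
#
# Outputs: results/truth_sets.tsv, results/panel_frequencies.tsv
# State for later steps: scratch/cohort_state.rds

library(triocnv)
set.seed(20190101)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

model <- build_genome_model(c(chrA = 50e6), seed = 2019)

# polymorphic panel loci: one common deletion (3% carriers, will fail
# the <1% rarity rule) and one rare duplication (0.4%)
panel_loci <- data.frame(
  chrom = "chrA",
  start = c(15e6 + 1, 35e6 + 1),
  end = c(15.3e6, 35.2e6),
  copy = c(1, 3),
  frequency = c(0.03, 0.004))

config <- sim_config(seed = 2019, panel_size = 2000,
                     panel_loci = panel_loci)

message("simulating ", config$panel_size, "-sample reference panel ...")
panel <- simulate_panel(model, config)
write.table(panel$frequency_table, "results/panel_frequencies.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating 12 trios ...")
trio_specs <- function(k) {
  # every trio: one maternal deletion and one paternal duplication of
  # random size/position; trio-specific extras below
  set.seed(3000 + k)
  pos <- sort(sample(seq(2e6, 44e6, by = 4e6), 4))
  sz <- round(runif(4, 2e5, 9e5) / 5000) * 5000
  par <- rbind(
    cnv_truth(model, "chrA", pos[1] + 1, pos[1] + sz[1], copy = 1,
              carrier = "mother"),
    cnv_truth(model, "chrA", pos[2] + 1, pos[2] + sz[2], copy = 3,
              carrier = "father"))
  dn <- NULL
  if (k == 1) {
    # 64.7-kb de novo deletion (EHMT1-style worked example)
    dn <- cnv_truth(model, "chrA", 20e6 + 1, 20e6 + 65000, copy = 1)
  } else if (k == 2) {
    # 1.0-Mb de novo deletion at 50% mosaic level (20q13.33-style)
    dn <- cnv_truth(model, "chrA", 30e6 + 1, 31e6, copy = 1,
                    mosaic_fraction = 0.5)
  } else if (k == 3) {
    # 20-kb deletion carried by both parents and transmitted twice:
    # homozygous in the proband (SEA-thalassaemia-style)
    par <- rbind(par,
      cnv_truth(model, "chrA", 41e6 + 1, 41.02e6, copy = 1,
                carrier = "father", transmitted = TRUE),
      cnv_truth(model, "chrA", 41e6 + 1, 41.02e6, copy = 1,
                carrier = "mother", transmitted = TRUE))
  } else if (k == 4) {
    # common polymorphism carried by the mother (rarity filter target)
    par <- rbind(par,
      cnv_truth(model, "chrA", 15e6 + 1, 15.3e6, copy = 1,
                carrier = "mother", transmitted = TRUE))
  } else if (k %% 3 == 0) {
    dn <- cnv_truth(model, "chrA", pos[4] + 1, pos[4] + sz[4],
                    copy = sample(c(1, 3), 1))
  }
  list(parental = par, de_novo = dn)
}

trios <- lapply(1:12, function(k) {
  sp <- trio_specs(k)
  cfg <- config; cfg$seed <- 40000 + k
  trio <- simulate_trio(model, cfg, sp$parental, sp$de_novo,
                        sexes = c(father = "XX", mother = "XX",
                                  proband = "XX"))
  trio$trio_id <- sprintf("T%02d", k)
  trio
})

truth_all <- do.call(rbind, lapply(trios, function(t) {
  tt <- t$truth
  if (is.null(tt)) return(NULL)
  tt$trio_id <- t$trio_id
  tt
}))
truth_all <- truth_all[order(truth_all$trio_id, truth_all$start), ]
write.table(
  data.frame(trio_id = truth_all$trio_id, chrom = truth_all$chrom,
             start = truth_all$start, end = truth_all$end,
             type = ifelse(truth_all$copy < 2, "del", "dup"),
             copy = truth_all$copy,
             mosaic_fraction = truth_all$mosaic_fraction,
             carrier = truth_all$carrier,
             transmitted = truth_all$transmitted),
  "results/truth_sets.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message("panel realized frequencies:")
print(panel$frequency_table)
message(nrow(truth_all), " implanted events across 12 trios; truth in ",
        "results/truth_sets.tsv")

saveRDS(list(model = model, config = config, panel_counts = panel$counts,
             frequency_table = panel$frequency_table, trios = trios),
        "scratch/cohort_state.rds")
message("state saved to scratch/cohort_state.rds")
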