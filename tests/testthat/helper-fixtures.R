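# Shared simulation fixtures, built lazily and cached for the whole run.
# The "big" fixture matches the study conditions the package targets:
# a 50-Mb chromosome at 0.25-fold coverage with a 2,000-sample panel
# (the population scale the rarity and U-test screens assume).

.fixture_cache <- new.env(parent = emptyenv())

big_fixture <- function() {
  if (!exists("big", envir = .fixture_cache)) {
    model <- build_genome_model(c(chrA = 50e6), seed = 11)
    config <- sim_config(seed = 11, panel_size = 2000)
    panel <- simulate_panel(model, config)
    ps <- build_panel_stats(panel$counts, model)
    assign("big", list(model = model, config = config, panel_stats = ps),
           envir = .fixture_cache)
  }
  get("big", envir = .fixture_cache)
}

# Small three-chromosome fixture for chromosome-level operations where
# the population U-test is not in play (panel of 30 is plenty for
# normalization statistics).
small_fixture <- function() {
  if (!exists("small", envir = .fixture_cache)) {
    model <- build_genome_model(c(chr1 = 10e6, chr2 = 10e6, chr3 = 10e6),
                                seed = 5)
    config <- sim_config(seed = 5, panel_size = 30)
    panel <- simulate_panel(model, config)
    ps <- build_panel_stats(panel$counts, model)
    assign("small", list(model = model, config = config, panel_stats = ps),
           envir = .fixture_cache)
  }
  get("small", envir = .fixture_cache)
}

# A coverage_profile built directly from a fine copy-ratio vector, for
# tests that probe callers with exactly known input.
fake_profile <- function(model, ratio_fine, sex = "XX") {
  structure(list(sample_id = "fake", sex = sex, model = model,
                 raw_counts = rep(0L, nrow(model$windows)),
                 corrected = ratio_fine,
                 ratio_fine = ratio_fine,
                 ratio_sliding = triocnv:::.sliding_mean(ratio_fine, model),
                 fold_coverage = 0.25, qc = NULL),
            class = "coverage_profile")
}

sim_profile <- function(fx, truth = NULL, seed = 1, sex = "XX",
                        id = "case") {
  cfg <- fx$config
  cfg$seed <- seed
  counts <- simulate_sample(fx$model, cfg, truth, sex, id)
  coverage_profile(counts, fx$model, fx$panel_stats, id, sex)
}

# Synthetic cytoband table carrying the bands the worked examples use.
example_cytobands <- function() {
  data.frame(
    chrom = c("chr9", "chr9", "chr20", "chr20", "chr18", "chr18",
              "chrY", "chrY", "chrY"),
    start = c(1, 140300001, 1, 61800001, 1, 42900001,
              1, 15000001, 26200001),
    end = c(140300000, 141213431, 61800000, 63025520, 42900000, 78077248,
            15000000, 26200000, 59373566),
    band = c("q34.2", "q34.3", "q13.32", "q13.33", "q12.2", "q12.3",
             "q11.1", "q11.221", "q12"),
    stringsAsFactors = FALSE)
}
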