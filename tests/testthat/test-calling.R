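# Aneuploidy and CNV calling: mosaic algebra, segmentation, breakpoint
# refinement, the homozygous-deletion run rule and the statistical
# screens.

test_that("mosaic level follows the mixture algebra", {
  expect_equal(estimate_mosaic_level(0.5, "loss"), 1.0)
  expect_equal(estimate_mosaic_level(0.75, "loss"), 0.5)
  expect_equal(estimate_mosaic_level(1.1, "gain"), 0.2, tolerance = 1e-9)
  # homozygous loss in variant cells: two copies changed
  expect_equal(estimate_mosaic_level(0.5, "loss", copies_changed = 2), 0.5)
  # clipped at 1 when the ratio overshoots the constitutional expectation
  expect_equal(estimate_mosaic_level(0.45, "loss"), 1)
  expect_error(estimate_mosaic_level(1, "loss"), "undefined")
  expect_error(estimate_mosaic_level(1.2, "loss"), "inconsistent")
})

test_that("whole-chromosome gains are detected with the right mosaic level", {
  fx <- small_fixture()
  tr <- cnv_truth(fx$model, "chr2", 1, 10e6, copy = 3)
  prof <- sim_profile(fx, tr, seed = 41)
  an <- detect_aneuploidy(prof)
  expect_equal(an$chrom, "chr2")
  expect_equal(an$direction, "gain")
  expect_equal(an$mosaic_fraction, 1, tolerance = 0.06)
  expect_true(an$constitutional)

  trm <- cnv_truth(fx$model, "chr2", 1, 10e6, copy = 3,
                   mosaic_fraction = 0.5)
  anm <- detect_aneuploidy(sim_profile(fx, trm, seed = 42))
  expect_equal(anm$chrom, "chr2")
  expect_equal(anm$mosaic_fraction, 0.5, tolerance = 0.06)
  expect_false(anm$constitutional)

  clean <- detect_aneuploidy(sim_profile(fx, NULL, seed = 43))
  expect_equal(nrow(clean), 0)
})

test_that("coarse segmentation finds implanted deletions and splits distant ones", {
  fx <- big_fixture()
  tr <- cnv_truth(fx$model, "chrA", 20e6 + 1, 20.5e6, copy = 1)
  prof <- sim_profile(fx, tr, seed = 51)
  segs <- segment_candidate_cnvs(prof, fx$panel_stats)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$direction, "loss")
  ov <- (min(segs$end, 20.5e6) - max(segs$start, 20e6 + 1) + 1) / 0.5e6
  expect_gte(ov, 0.9)

  tr2 <- rbind(cnv_truth(fx$model, "chrA", 10e6 + 1, 10.3e6, copy = 1),
               cnv_truth(fx$model, "chrA", 10.5e6 + 1, 10.8e6, copy = 1))
  segs2 <- segment_candidate_cnvs(sim_profile(fx, tr2, seed = 52),
                                  fx$panel_stats)
  expect_equal(nrow(segs2), 2)
})

test_that("white-noise sliding ratios produce no segments at z = 3", {
  fx <- small_fixture()
  n_fine <- nrow(fx$model$windows)
  disp <- median(fx$panel_stats$dispersion_sliding, na.rm = TRUE)
  n_with_segs <- 0
  set.seed(61)
  for (k in 1:20) {
    prof <- fake_profile(fx$model, rep(1, n_fine))
    sg_len <- length(prof$ratio_sliding)
    prof$ratio_sliding <- 1 + rnorm(sg_len, 0, disp / 1.4826 * 1.4826)
    segs <- segment_candidate_cnvs(prof, fx$panel_stats)
    if (nrow(segs) > 0) n_with_segs <- n_with_segs + 1
  }
  expect_lte(n_with_segs / 20, 0.05)
})

test_that("segment count is monotone in the detection threshold", {
  fx <- big_fixture()
  tr <- rbind(cnv_truth(fx$model, "chrA", 8e6 + 1, 8.4e6, copy = 1),
              cnv_truth(fx$model, "chrA", 30e6 + 1, 30.2e6, copy = 3,
                        mosaic_fraction = 0.6))
  prof <- sim_profile(fx, tr, seed = 53)
  counts <- vapply(c(6, 4, 3, 2.5, 2), function(z)
    nrow(segment_candidate_cnvs(prof, fx$panel_stats,
                                caller_config(detection_z = z))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("breakpoint refinement is exact on a clean step and inert on flat data", {
  gm <- build_genome_model(c(c1 = 5e6), gc_field_params = list(sd = 0),
                           seed = 1)
  n <- nrow(gm$windows)
  r <- rep(1, n)
  # true deletion across fine windows 301..360 (1.5e6+1 .. 1.8e6)
  r[301:360] <- 0.5
  prof <- fake_profile(gm, r)
  seg <- data.frame(chrom = "c1", start = 1.45e6 + 1, end = 1.85e6)
  ref <- refine_breakpoints_irc(seg, prof)
  expect_equal(ref$start, 1.5e6 + 1)
  expect_equal(ref$end, 1.8e6)

  flat <- fake_profile(gm, rep(1, n))
  ref_flat <- refine_breakpoints_irc(seg, flat)
  expect_equal(ref_flat$start, seg$start)
  expect_equal(ref_flat$end, seg$end)
})

test_that("refined boundaries land within 10 kb (median) at low-pass depth", {
  fx <- big_fixture()
  errs <- vapply(1:15, function(k) {
    tr <- cnv_truth(fx$model, "chrA", 12e6 + 1, 12.3e6, copy = 1)
    prof <- sim_profile(fx, tr, seed = 500 + k)
    calls <- call_cnvs(prof, fx$panel_stats)$calls
    if (!nrow(calls)) return(NA_real_)
    j <- which.max(calls$n_fine_windows)
    max(abs(calls$start[j] - (12e6 + 1)), abs(calls$end[j] - 12.3e6))
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 10000)
})

test_that("homozygous-deletion scan applies the exact run-length rule", {
  gm <- build_genome_model(c(c1 = 50000), seed = 1)  # 10 windows
  mk <- function(r) fake_profile(gm, r)
  cc <- caller_config()

  r <- c(1, 0.05, 0.02, 1, rep(1, 6))
  calls <- detect_homozygous_deletions(mk(r), cc)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "hom_del")
  expect_equal(calls$start, 5001)
  expect_equal(calls$end, 15000)
  expect_equal(calls$size_bp, 10000)

  # single isolated low window: no call
  expect_equal(nrow(detect_homozygous_deletions(
    mk(c(1, 0.05, 1, rep(1, 7))), cc)), 0)
  expect_equal(nrow(detect_homozygous_deletions(mk(rep(1, 10)), cc)), 0)

  # brute-force equivalence on random ratio vectors
  brute <- function(r, ceiling_ = 0.1, min_run = 2) {
    low <- is.finite(r) & r >= 0 & r <= ceiling_
    runs <- rle(low)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    keep <- runs$values & runs$lengths >= min_run
    cbind(starts[keep], ends[keep])
  }
  gm2 <- build_genome_model(c(c1 = 500000), seed = 2)  # 100 windows
  set.seed(71)
  for (rep in 1:25) {
    r <- ifelse(runif(100) < 0.25, runif(100, 0, 0.12), runif(100, 0.8, 1.2))
    calls <- detect_homozygous_deletions(fake_profile(gm2, r), cc)
    expected <- brute(r)
    expect_equal(nrow(calls), nrow(expected))
    if (nrow(expected)) {
      expect_equal((calls$start - 1) / 5000 + 1, expected[, 1])
      expect_equal(calls$end / 5000, expected[, 2])
    }
  }
})

test_that("hemizygous deletions are labelled on male sex chromosomes", {
  gm <- build_genome_model(c(chr1 = 1e6, chrX = 1e6), seed = 3)
  r <- rep(1, nrow(gm$windows))
  xw <- which(gm$windows$chrom == "chrX")
  r[xw] <- 0.5            # male baseline against a diploid panel
  r[xw[51:60]] <- 0.02    # lost single copy
  calls <- detect_homozygous_deletions(fake_profile(gm, r, sex = "XY"))
  expect_equal(calls$type, "hemi_del")
  expect_equal(calls$chrom, "chrX")
  f_calls <- detect_homozygous_deletions(fake_profile(gm, r, sex = "XX"))
  expect_equal(f_calls$type, "hom_del")
})

test_that("mosaic-level gate keeps 20%+ large and 30%+ small events only", {
  cc <- caller_config()
  calls <- data.frame(size_bp = c(1e6, 3e6, 1e6, 3e6, 70000),
                      mosaic_fraction = c(0.25, 0.25, 1, 0.15, 1))
  expect_equal(apply_mosaic_threshold(calls, cc),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("statistical screens keep unique events and drop panel polymorphisms", {
  fx <- big_fixture()
  tr <- cnv_truth(fx$model, "chrA", 20e6 + 1, 20.5e6, copy = 1)
  prof <- sim_profile(fx, tr, seed = 81)
  call <- data.frame(chrom = "chrA", start = 20e6 + 1, end = 20.5e6,
                     type = "het_del", mean_ratio = 0.5,
                     mosaic_fraction = 1, size_bp = 0.5e6,
                     n_fine_windows = 100L, p_utest = NA_real_,
                     p_t_sample = NA_real_, p_t_chrom = NA_real_,
                     filter_evaluable = NA, stringsAsFactors = FALSE)
  out <- statistical_filter(call, prof, fx$panel_stats)
  expect_true(out$keep)
  expect_lte(out$p_utest, 1e-3)
  expect_lte(out$p_t_sample, 1e-3)

  # same locus deleted in half the panel: the U-test is non-significant
  ps2 <- fx$panel_stats
  idx <- which(fx$model$windows$start > 20e6 &
                 fx$model$windows$end <= 20.5e6)
  half <- seq(1, ncol(ps2$ratios_fine), by = 2)
  ps2$ratios_fine[idx, half] <- ps2$ratios_fine[idx, half] * 0.5
  out2 <- statistical_filter(call, prof, ps2)
  expect_gt(out2$p_utest, 1e-3)
  expect_false(out2$keep)

  # a background region fails all three screens
  bg <- call
  bg$start <- 40e6 + 1; bg$end <- 40.5e6; bg$mean_ratio <- 1
  out3 <- statistical_filter(bg, prof, fx$panel_stats)
  expect_false(out3$keep)
  expect_gt(out3$p_utest, 1e-3)
  expect_gt(out3$p_t_sample, 1e-3)
})

test_that("the full caller recovers a constitutional deletion and nothing else", {
  fx <- big_fixture()
  tr <- cnv_truth(fx$model, "chrA", 20e6 + 1, 20.5e6, copy = 1)
  prof <- sim_profile(fx, tr, seed = 91)
  res <- call_cnvs(prof, fx$panel_stats)
  expect_true(res$qc$pass)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$type, "het_del")
  expect_lte(abs(res$calls$start - (20e6 + 1)), 10000)
  expect_lte(abs(res$calls$end - 20.5e6), 10000)
  expect_equal(res$calls$mosaic_fraction, 1, tolerance = 0.08)

  clean <- call_cnvs(sim_profile(fx, NULL, seed = 92), fx$panel_stats)
  expect_equal(nrow(clean$calls), 0)
})

test_that("a 1-Mb deletion at 50% mosaic level is called near fraction 0.5", {
  fx <- big_fixture()
  tr <- cnv_truth(fx$model, "chrA", 30e6 + 1, 31e6, copy = 1,
                  mosaic_fraction = 0.5)
  prof <- sim_profile(fx, tr, seed = 93)
  calls <- call_cnvs(prof, fx$panel_stats)$calls
  expect_gte(nrow(calls), 1)
  j <- which.max(calls$n_fine_windows)
  expect_equal(calls$type[j], "het_del")
  expect_lt(abs(calls$mosaic_fraction[j] - 0.5), 0.1)
})

test_that("QC failure blocks calling unless overridden", {
  fx <- small_fixture()
  set.seed(94)
  # fine noise tuned so sliding ratios have SD ~0.15, over the cutoff
  prof <- fake_profile(fx$model,
                       rnorm(nrow(fx$model$windows), 1, 0.15 * sqrt(10)))
  expect_error(call_cnvs(prof, fx$panel_stats), "QC")
  res <- call_cnvs(prof, fx$panel_stats, override_qc = TRUE)
  expect_false(res$qc$pass)
})
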