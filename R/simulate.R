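#' Simulation configuration for low-pass coverage profiles
#'
#' Bundles the sequencing and noise parameters of the synthetic coverage
#' generator. Defaults emulate the study design the package targets:
#' ~15 million single-end 50-bp reads per sample (~0.25-fold on a 3-Gb
#' genome; the per-window expectation scales to whatever genome model is
#' simulated), Poisson-distributed 5-kb bin counts with a smooth
#' quadratic GC bias, and a reference panel of 2,000 samples.
#'
#' @param reads_per_sample expected total retained reads per sample. The
#'   default `NULL` means "0.25-fold on the model being simulated":
#'   `0.25 * genome_size / read_length`.
#' @param read_length read length in bp (default 50).
#' @param depth fold-coverage used when `reads_per_sample` is `NULL`
#'   (default 0.25).
#' @param gc_bias_coefficients numeric `c(b1, b2)` of the smooth bias
#'   `bias(gc) = 1 + b1*(gc-0.5) + b2*(gc-0.5)^2`, truncated below at
#'   0.05. The default `c(0.3, -1.5)` is a gentle unimodal bias peaking
#'   near mid-GC; `c(0, 0)` gives flat (no) bias.
#' @param noise_model `"poisson"` (default) or `"nbinom"`; the negative
#'   binomial hook adds overdispersion with `nb_dispersion` as its `size`
#'   parameter (larger = closer to Poisson).
#' @param nb_dispersion negative-binomial size parameter (default 100).
#' @param seed global integer seed; every sample draws from a named
#'   sub-stream so an individual sample's counts do not depend on how
#'   many other samples are simulated.
#' @param panel_size number of reference-panel samples (default 2000,
#'   the scale of the population datasets the rarity and U-test screens
#'   assume).
#' @param panel_loci data.frame of polymorphic panel CNV loci with
#'   columns `chrom`, `start`, `end`, `copy` (variant copy number) and
#'   `frequency` (carrier frequency in [0,1]); `NULL` for none.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(reads_per_sample = NULL, read_length = 50,
                       depth = 0.25,
                       gc_bias_coefficients = c(0.3, -1.5),
                       noise_model = c("poisson", "nbinom"),
                       nb_dispersion = 100, seed = 1,
                       panel_size = 2000, panel_loci = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.null(reads_per_sample) && reads_per_sample <= 0)
    stop("reads_per_sample must be positive", call. = FALSE)
  if (!is.null(panel_loci)) {
    stopifnot(all(c("chrom", "start", "end", "copy", "frequency") %in%
                    names(panel_loci)))
    if (any(panel_loci$frequency < 0 | panel_loci$frequency > 1))
      stop("panel locus frequencies must lie in [0,1]", call. = FALSE)
  }
  structure(list(reads_per_sample = reads_per_sample,
                 read_length = read_length, depth = depth,
                 gc_bias_coefficients = gc_bias_coefficients,
                 noise_model = noise_model, nb_dispersion = nb_dispersion,
                 seed = seed, panel_size = panel_size,
                 panel_loci = panel_loci),
            class = "sim_config")
}

.reads_for <- function(model, config) {
  if (!is.null(config$reads_per_sample)) return(config$reads_per_sample)
  config$depth * sum(model$chrom_lengths) / config$read_length
}

.gc_bias <- function(gc, coef) {
  pmax(1 + coef[1] * (gc - 0.5) + coef[2] * (gc - 0.5)^2, 0.05)
}

#' Construct a CNV truth table
#'
#' Validates and snaps truth intervals to fine-window boundaries (the
#' resolution limit of read-depth calling). `copy` is the copy number of
#' the variant cell population against a diploid background of 2;
#' `mosaic_fraction` is the proportion of cells carrying it.
#'
#' @param model genome model the intervals must lie in.
#' @param chrom,start,end vectors describing the intervals (1-based
#'   inclusive).
#' @param copy integer vector in `{0,1,3,4}`.
#' @param mosaic_fraction numeric in (0, 1] (default 1, constitutional).
#' @param carrier who carries the event: `"proband"`, `"father"`,
#'   `"mother"` (default `"proband"`).
#' @param transmitted logical; for parental events, whether the event is
#'   passed to the proband (`NA` = decide at random with probability 1/2).
#' @return data.frame of class `cnv_truth`.
#' @export
cnv_truth <- function(model, chrom, start, end, copy,
                      mosaic_fraction = 1, carrier = "proband",
                      transmitted = NA) {
  n <- length(chrom)
  tr <- data.frame(chrom = chrom, start = as.numeric(start),
                   end = as.numeric(end), copy = as.integer(copy),
                   mosaic_fraction = rep_len(mosaic_fraction, n),
                   carrier = rep_len(carrier, n),
                   transmitted = rep_len(transmitted, n),
                   stringsAsFactors = FALSE)
  if (any(tr$start > tr$end)) stop("start > end in truth", call. = FALSE)
  if (any(tr$copy == 2L) || any(!tr$copy %in% c(0L, 1L, 3L, 4L)))
    stop("variant copy number must be in {0,1,3,4}", call. = FALSE)
  if (any(tr$mosaic_fraction <= 0 | tr$mosaic_fraction > 1))
    stop("mosaic_fraction must lie in (0,1]", call. = FALSE)
  if (any(!tr$chrom %in% names(model$chrom_lengths)))
    stop("truth chromosome not in model", call. = FALSE)
  for (i in seq_len(n)) {
    if (tr$end[i] > model$chrom_lengths[[tr$chrom[i]]])
      stop("truth interval outside chromosome", call. = FALSE)
    se <- .snap_interval(model, tr$chrom[i], tr$start[i], tr$end[i])
    tr$start[i] <- se[1]; tr$end[i] <- se[2]
  }
  class(tr) <- c("cnv_truth", "data.frame")
  tr
}

# Per-fine-window expected copy number given a sample's truth set.
# Baseline is 2 on autosomes; on X/Y it follows `sex` ("XX"/"XY").
.window_copy <- function(model, truth, sex = "XX") {
  w <- model$windows
  is_x <- grepl("(^|chr)X$", w$chrom)
  is_y <- grepl("(^|chr)Y$", w$chrom)
  base <- rep(2, nrow(w))
  if (identical(sex, "XY")) { base[is_x] <- 1; base[is_y] <- 1 }
  else base[is_y] <- 0
  cn <- base
  if (!is.null(truth) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      idx <- .fine_idx(model, truth$chrom[i], truth$start[i], truth$end[i])
      f <- truth$mosaic_fraction[i]
      cn[idx] <- f * truth$copy[i] + (1 - f) * base[idx]
    }
  }
  cn
}

.check_no_overlap <- function(truth) {
  if (is.null(truth) || nrow(truth) < 2) return(invisible())
  sp <- split(truth, truth$chrom)
  for (tt in sp) {
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1 && any(tt$start[-1] <= tt$end[-nrow(tt)]))
      stop("overlapping truth intervals on one sample", call. = FALSE)
  }
  invisible()
}

#' Simulate one sample's raw per-window counts
#'
#' Draws the fine-window read counts of one low-pass sample. Window `w`
#' has expectation proportional to
#' `mappability(w) * bias(gc(w)) * c(w)/2`, where `c(w)` is the expected
#' copy number (a mosaic mixture inside truth intervals, the diploid or
#' sex baseline elsewhere); weights are normalized so expected total
#' count equals the configured reads per sample.
#'
#' @param model genome model.
#' @param config `sim_config`.
#' @param truth `cnv_truth` rows carried by this sample (may be `NULL`).
#' @param sex `"XX"` or `"XY"`.
#' @param sample_id label naming the sample's random sub-stream.
#' @return integer vector of counts, one per fine window of the model.
#' @export
simulate_sample <- function(model, config, truth = NULL, sex = "XX",
                            sample_id = "sample") {
  stopifnot(sex %in% c("XX", "XY"))
  .check_no_overlap(truth)
  mu <- expected_window_means(model, config, truth, sex)
  set.seed(.stream_seed(config$seed, paste0("counts:", sample_id)))
  if (config$noise_model == "poisson") stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
}

#' Expected fine-window means for a simulated sample
#'
#' The noiseless expectation `simulate_sample()` draws around; exposed
#' so tests can use it as an oracle.
#' @inheritParams simulate_sample
#' @return numeric vector of expected counts summing to the configured
#'   total read count.
#' @export
expected_window_means <- function(model, config, truth = NULL, sex = "XX") {
  w <- model$windows
  cn <- .window_copy(model, truth, sex)
  wt <- w$mappability * .gc_bias(w$gc, config$gc_bias_coefficients) * cn / 2
  reads <- .reads_for(model, config)
  reads * wt / sum(wt)
}

#' Simulate a sequenced trio with Mendelian CNV transmission
#'
#' Parental events (het or mosaic) are implanted in the stated carrier
#' and transmitted to the proband independently with probability 1/2
#' (or as forced by `transmitted`); de novo events appear only in the
#' proband. When both parents carry and transmit a deletion at the same
#' locus the proband becomes homozygously deleted there.
#'
#' @param model genome model.
#' @param config `sim_config`.
#' @param parental_cnvs `cnv_truth` with carriers `"father"`/`"mother"`
#'   (a locus listed once per carrier; may be `NULL`).
#' @param de_novo_cnvs `cnv_truth` with carrier `"proband"` (may be `NULL`).
#' @param seed optional override of `config$seed` for this trio.
#' @param sexes named character vector of sample sexes (defaults:
#'   father XY, mother XX, proband XX).
#' @return list with integer count vectors `father`, `mother`,
#'   `proband`, and `truth`, the combined truth table whose
#'   `transmitted` column records the realized transmissions.
#' @export
simulate_trio <- function(model, config, parental_cnvs = NULL,
                          de_novo_cnvs = NULL, seed = NULL,
                          sexes = c(father = "XY", mother = "XX",
                                    proband = "XX")) {
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(parental_cnvs) && nrow(parental_cnvs)) {
    if (any(!parental_cnvs$carrier %in% c("father", "mother")))
      stop("parental_cnvs carriers must be father/mother", call. = FALSE)
  }
  if (!is.null(de_novo_cnvs) && nrow(de_novo_cnvs))
    de_novo_cnvs$carrier <- "proband"

  # realize transmissions
  set.seed(.stream_seed(config$seed, "transmission"))
  if (!is.null(parental_cnvs) && nrow(parental_cnvs)) {
    miss <- is.na(parental_cnvs$transmitted)
    parental_cnvs$transmitted[miss] <-
      stats::runif(sum(miss)) < 0.5
  }

  truth <- rbind(if (!is.null(parental_cnvs)) parental_cnvs,
                 if (!is.null(de_novo_cnvs)) de_novo_cnvs)

  # proband inherits one allele delta per transmitting parent
  proband_truth <- NULL
  if (!is.null(truth) && nrow(truth)) {
    inh <- truth[truth$carrier != "proband" & truth$transmitted %in% TRUE, ,
                 drop = FALSE]
    dn <- truth[truth$carrier == "proband", , drop = FALSE]
    if (nrow(inh)) {
      key <- paste(inh$chrom, inh$start, inh$end)
      delta <- ifelse(inh$copy < 2, -1L, +1L)  # one allele lost/gained
      agg <- tapply(delta, key, sum)
      first <- inh[!duplicated(key), , drop = FALSE]
      first_key <- paste(first$chrom, first$start, first$end)
      first$copy <- as.integer(2L + agg[first_key])
      first$mosaic_fraction <- 1
      first$carrier <- "proband"
      inh_pro <- first[first$copy != 2L, , drop = FALSE]
      proband_truth <- rbind(inh_pro, dn)
    } else proband_truth <- dn
    if (!is.null(proband_truth) && !nrow(proband_truth))
      proband_truth <- NULL
  }

  pick <- function(who) {
    if (is.null(truth)) return(NULL)
    tt <- truth[truth$carrier == who, , drop = FALSE]
    if (nrow(tt)) tt else NULL
  }
  list(
    father = simulate_sample(model, config, pick("father"),
                             sexes[["father"]], "father"),
    mother = simulate_sample(model, config, pick("mother"),
                             sexes[["mother"]], "mother"),
    proband = simulate_sample(model, config, proband_truth,
                              sexes[["proband"]], "proband"),
    proband_truth = proband_truth,
    truth = truth
  )
}

#' Simulate a population reference panel
#'
#' Each of `config$panel_size` samples independently carries each panel
#' locus with its stated carrier frequency (as a constitutional event of
#' the stated copy number). Used both to build normalization statistics
#' and as the population behind the rarity and U-test screens.
#'
#' @param model genome model.
#' @param config `sim_config` (needs `panel_size >= 10`).
#' @return list with `counts`, an `n_windows x panel_size` integer
#'   matrix, and `frequency_table`, the realized carrier-frequency table
#'   (`chrom`, `start`, `end`, `type`, `carriers`, `frequency`,
#'   `panel_size`).
#' @export
simulate_panel <- function(model, config) {
  if (config$panel_size < 10)
    stop("panel_size must be at least 10", call. = FALSE)
  loci <- config$panel_loci
  n <- config$panel_size
  carriers <- NULL
  if (!is.null(loci) && nrow(loci)) {
    set.seed(.stream_seed(config$seed, "panel-carriers"))
    carriers <- matrix(stats::runif(nrow(loci) * n) < loci$frequency,
                       nrow = nrow(loci))
  }
  counts <- matrix(0L, nrow(model$windows), n)
  for (j in seq_len(n)) {
    truth <- NULL
    if (!is.null(carriers) && any(carriers[, j])) {
      k <- which(carriers[, j])
      truth <- cnv_truth(model, loci$chrom[k], loci$start[k],
                         loci$end[k], loci$copy[k])
    }
    counts[, j] <- simulate_sample(model, config, truth, "XX",
                                   paste0("panel", j))
  }
  ft <- NULL
  if (!is.null(loci) && nrow(loci)) {
    nc <- if (is.null(carriers)) rep(0L, nrow(loci)) else rowSums(carriers)
    ft <- data.frame(chrom = loci$chrom, start = loci$start,
                     end = loci$end,
                     type = ifelse(loci$copy < 2, "del", "dup"),
                     carriers = nc, frequency = nc / n,
                     panel_size = n, stringsAsFactors = FALSE)
  }
  list(counts = counts, frequency_table = ft)
}
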