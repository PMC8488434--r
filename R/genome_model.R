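#' Build a desk-scale genome model with a fine window grid
#'
#' Constructs the window scaffold every other stage works on: each
#' chromosome is truncated to a whole number of fine (default 5-kb)
#' non-overlapping windows, and each fine window receives a smooth
#' (autocorrelated) GC fraction and a mappability weight. The model is a
#' stand-in for a reference genome such as GRCh37 at a size where
#' simulation and calling run in seconds.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, e.g. `"chr1"`). Each length must be at
#'   least `10 * fine_window_size`.
#' @param fine_window_size fine window size in bp (default 5000).
#' @param gc_field_params list controlling the simulated GC field:
#'   `center` (default 0.5), `sd` (marginal standard deviation of the
#'   field, default 0.06; 0 gives a constant field), `rho` (lag-1
#'   autocorrelation of the underlying AR(1) process, default 0.95) and
#'   `range` (clamp interval, default `c(0.3, 0.7)`).
#' @param seed integer seed; the GC field is deterministic given the seed.
#' @return An object of class `genome_model`: a list with
#'   `chrom_lengths` (truncated), `fine_window_size`, and `windows`, a
#'   data.frame with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `gc` and `mappability`.
#' @examples
#' gm <- build_genome_model(c(chrA = 50e6), seed = 1)
#' nrow(gm$windows)  # 10000 fine windows
#' @export
build_genome_model <- function(chrom_lengths, fine_window_size = 5000,
                               gc_field_params = list(), seed = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  if (fine_window_size <= 0)
    stop("fine_window_size must be positive", call. = FALSE)
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (any(chrom_lengths < 10 * fine_window_size))
    stop("each chromosome must span at least 10 fine windows", call. = FALSE)

  p <- modifyList(list(center = 0.5, sd = 0.06, rho = 0.95,
                       range = c(0.3, 0.7)), gc_field_params)
  n_win <- floor(chrom_lengths / fine_window_size)
  lens <- n_win * fine_window_size

  windows <- do.call(rbind, lapply(seq_along(lens), function(i) {
    k <- n_win[i]
    data.frame(
      chrom = rep(names(lens)[i], k),
      start = (seq_len(k) - 1L) * fine_window_size + 1,
      end = seq_len(k) * fine_window_size,
      stringsAsFactors = FALSE
    )
  }))
  rownames(windows) <- NULL

  set.seed(.stream_seed(seed, "gc-field"))
  windows$gc <- unlist(lapply(n_win, function(k)
    .smooth_gc(k, p$center, p$sd, p$rho, p$range)), use.names = FALSE)
  windows$mappability <- rep(1, nrow(windows))

  structure(list(chrom_lengths = lens, fine_window_size = fine_window_size,
                 windows = windows),
            class = "genome_model")
}

# AR(1)-smoothed Gaussian field rescaled to marginal sd and clamped.
.smooth_gc <- function(n, center, sd, rho, range) {
  if (sd <= 0) return(rep(center, n))
  x <- as.numeric(stats::filter(stats::rnorm(n), rho, method = "recursive"))
  x <- x / sqrt(1 / (1 - rho^2))  # unit marginal sd
  pmin(pmax(center + sd * x, range[1]), range[2])
}

# Deterministic sub-stream seed derived from a global seed and a label,
# kept below 2^31 so set.seed() accepts it on any platform.
.stream_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483563
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483563)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosome(s),",
      nrow(x$windows), "fine windows of", x$fine_window_size, "bp\n")
  invisible(x)
}

#' Sliding-window grid over a genome model
#'
#' The sliding (reporting) grid is built from runs of `n_fine`
#' consecutive fine windows advanced one fine window at a time: with the
#' defaults, 50-kb windows at 5-kb increments. Every sliding window
#' decomposes exactly into its constituent fine windows.
#'
#' @param model a `genome_model`.
#' @param n_fine number of fine windows per sliding window (default 10).
#' @return data.frame with `chrom`, `start`, `end`, and `first_fine`,
#'   the row index in `model$windows` of the first constituent window.
#' @export
sliding_grid <- function(model, n_fine = 10L) {
  w <- model$windows
  out <- lapply(names(model$chrom_lengths), function(ch) {
    idx <- which(w$chrom == ch)
    k <- length(idx) - n_fine + 1L
    if (k < 1L) return(NULL)
    data.frame(chrom = ch,
               start = w$start[idx[seq_len(k)]],
               end = w$end[idx[seq_len(k)] + n_fine - 1L],
               first_fine = idx[seq_len(k)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Row indices of model fine windows overlapping [start, end] on chrom.
.fine_idx <- function(model, chrom, start, end) {
  w <- model$windows
  which(w$chrom == chrom & w$end >= start & w$start <= end)
}

# Snap an interval outward to fine-window boundaries.
.snap_interval <- function(model, chrom, start, end) {
  fs <- model$fine_window_size
  len <- model$chrom_lengths[[chrom]]
  s <- floor((start - 1) / fs) * fs + 1
  e <- ceiling(end / fs) * fs
  c(max(1, s), min(len, e))
}
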