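#' Feature extraction configuration
#'
#' @param window_ms half-open ERP response window, ms post-stimulus.
#' @param decimation_hz target rate of the decimated features. Decimation
#'   uses non-overlapping block means with the integer factor
#'   `round(sample_rate / decimation_hz)`; a trailing partial block is
#'   dropped. `method = "subsample"` keeps the first sample of each block
#'   instead (sensitivity checks only).
#' @param method `"blockmean"` (default) or `"subsample"`.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(window_ms = c(0, 800), decimation_hz = 20,
                           method = c("blockmean", "subsample")) {
  if (window_ms[1] >= window_ms[2]) stop("window start must precede end")
  if (decimation_hz <= 0) stop("decimation_hz must be positive")
  structure(list(window_ms = as.numeric(window_ms),
                 decimation_hz = decimation_hz,
                 method = match.arg(method)),
            class = "feature_config")
}

# Remove the least-squares straight line from each row of a matrix
# (columns = samples). The residual has zero mean and zero linear trend.
detrend_rows <- function(m) {
  ns <- ncol(m)
  tc <- seq_len(ns) - (ns + 1) / 2
  b <- drop(m %*% tc) / sum(tc * tc)
  m - rowMeans(m) - outer(b, tc)
}

#' Linearly detrend a single epoch
#'
#' Removes the least-squares straight line fit to the samples; the result has
#' (numerically) zero mean and zero linear trend, and the operation is
#' idempotent.
#'
#' @param x numeric vector of at least 2 samples.
#' @return numeric vector of the same length.
#' @export
detrend_epoch <- function(x) {
  if (length(x) < 2L) stop("detrending needs at least 2 samples")
  drop(detrend_rows(matrix(as.numeric(x), nrow = 1L)))
}

#' Extract decimated SWLDA features from labeled epochs
#'
#' Per epoch and channel: crop to the feature window, linearly detrend, then
#' decimate by non-overlapping block means with integer factor
#' `f = round(sample_rate / decimation_hz)`, keeping
#' `n_bins = floor(window_samples / f)` bins. Feature columns are
#' channel-major (all bins of channel 1, then channel 2, ...) in montage
#' order, named `CH<electrode>_T<bin>`. Rows are ordered by trial, then flash
#' event.
#'
#' @param es an [epoch_set()] whose window covers `cfg$window_ms`.
#' @param cfg a [feature_config()].
#' @return an object of class `feature_matrix` with elements `X` (epochs x
#'   features), `y` (+1 target / -1 non-target), `trial`, `flash_event`,
#'   `choice`, `occurrence` (per-epoch), `target_choice` (per-trial),
#'   `feature_map`, `channels`, `n_bins`, `n_choices`, `flashes_per_choice`.
#' @export
extract_features <- function(es, cfg = feature_config()) {
  stopifnot(inherits(es, "epoch_set"), inherits(cfg, "feature_config"))
  fs <- es$protocol$sample_rate
  f <- as.integer(round(fs / cfg$decimation_hz))
  if (f < 1L) stop("decimation factor < 1: target rate exceeds sample rate")
  sel <- crop_indices(es$window, cfg$window_ms, fs)
  n_bins <- length(sel) %/% f
  if (n_bins < 1L) stop("feature window shorter than one decimation block")
  d <- dim(es$epochs)
  n_ep <- d[1] * d[2]
  # row order: trial-major, flash event fastest
  perm <- rep(seq_len(d[1]), each = d[2]) + (rep(seq_len(d[2]), d[1]) - 1L) * d[1]
  channels <- es$montage$names
  X <- matrix(0, n_ep, length(channels) * n_bins)
  keep <- seq_len(n_bins * f)
  for (ch in seq_along(channels)) {
    m <- matrix(es$epochs[, , ch, sel], n_ep, length(sel))[perm, , drop = FALSE]
    m <- detrend_rows(m)[, keep, drop = FALSE]
    feats <- if (cfg$method == "blockmean") {
      colMeans(array(t(m), c(f, n_bins, n_ep)), dims = 1L)  # n_bins x n_ep
    } else {
      t(m[, (seq_len(n_bins) - 1L) * f + 1L, drop = FALSE])
    }
    X[, (ch - 1L) * n_bins + seq_len(n_bins)] <- t(feats)
  }
  feature_map <- data.frame(column = seq_len(ncol(X)),
                            channel = rep(channels, each = n_bins),
                            bin = rep(seq_len(n_bins), length(channels)),
                            stringsAsFactors = FALSE)
  colnames(X) <- paste0("CH", feature_map$channel, "_T", feature_map$bin)
  trial <- rep(seq_len(d[1]), each = d[2])
  flash_event <- rep(seq_len(d[2]), d[1])
  choice <- es$flashed_label[cbind(trial, flash_event)]
  occurrence <- stats::ave(seq_along(choice),
                           trial, choice, FUN = seq_along)
  y <- ifelse(choice == es$target_choice[trial], 1, -1)
  structure(list(X = X, y = y, trial = trial, flash_event = flash_event,
                 choice = as.integer(choice),
                 occurrence = as.integer(occurrence),
                 target_choice = es$target_choice,
                 feature_map = feature_map, channels = channels,
                 n_bins = n_bins, n_choices = es$protocol$n_choices,
                 flashes_per_choice = es$protocol$flashes_per_choice,
                 window_ms = cfg$window_ms, decimation_hz = cfg$decimation_hz),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d channels x %d bins), %d trials\n",
              nrow(x$X), ncol(x$X), length(x$channels), x$n_bins,
              length(x$target_choice)))
  invisible(x)
}

# feature column indices of a set of channels, in the given channel order
channel_columns <- function(fm, channels) {
  idx <- match(channels, fm$channels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  as.integer(outer(seq_len(fm$n_bins), (idx - 1L) * fm$n_bins, `+`))
}

# restrict a feature matrix to a subset of trials, re-indexing trials 1..k
subset_trials <- function(fm, trials) {
  trials <- sort(unique(as.integer(trials)))
  keep <- fm$trial %in% trials
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$y <- fm$y[keep]
  fm$trial <- match(fm$trial[keep], trials)
  fm$flash_event <- fm$flash_event[keep]
  fm$choice <- fm$choice[keep]
  fm$occurrence <- fm$occurrence[keep]
  fm$target_choice <- fm$target_choice[trials]
  fm
}

#' Export a feature matrix to CSV
#'
#' Writes one row per epoch with `trial`, `flash_event`, `target` and the
#' feature columns named `CH<electrode>_T<bin>`.
#'
#' @param fm a [extract_features()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  df <- data.frame(trial = fm$trial, flash_event = fm$flash_event,
                   target = as.integer(fm$y > 0), fm$X, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
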