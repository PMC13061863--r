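#' Stimulus-presentation protocol
#'
#' Describes the 4-choice oddball paradigm: each trial presents `n_choices`
#' pictures whose labels flash individually, `flashes_per_choice` times each,
#' in a pseudo-random order where every label flashes once before any label
#' repeats.
#'
#' @param n_choices number of response alternatives per trial.
#' @param flashes_per_choice flashes of each label per trial.
#' @param sample_rate EEG sampling rate in Hz.
#' @param flash_duration_ms,inter_flash_interval_ms stimulus timing metadata.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_choices = 4L, flashes_per_choice = 10L,
                          sample_rate = 600, flash_duration_ms = 50,
                          inter_flash_interval_ms = 116.7) {
  if (n_choices < 2L) stop("n_choices must be >= 2")
  if (flashes_per_choice < 1L) stop("flashes_per_choice must be >= 1")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(n_choices = as.integer(n_choices),
                 flashes_per_choice = as.integer(flashes_per_choice),
                 sample_rate = sample_rate,
                 flash_duration_ms = flash_duration_ms,
                 inter_flash_interval_ms = inter_flash_interval_ms),
            class = "protocol_spec")
}

#' Preset protocols
#'
#' `protocol1()` is the 600 Hz protocol (50 ms flashes, 116.7 ms between
#' flashes); `protocol2()` is the 256 Hz protocol (62.5 ms flashes, 93.75 ms
#' between flashes).
#' @return a [protocol_spec()].
#' @export
protocol1 <- function() protocol_spec(sample_rate = 600,
                                      flash_duration_ms = 50,
                                      inter_flash_interval_ms = 116.7)

#' @rdname protocol1
#' @export
protocol2 <- function() protocol_spec(sample_rate = 256,
                                      flash_duration_ms = 62.5,
                                      inter_flash_interval_ms = 93.75)

# number of samples in a half-open [start_ms, end_ms) window
window_samples <- function(window, sample_rate) {
  as.integer(floor((window[2] - window[1]) * sample_rate / 1000))
}

#' Labeled stimulus-locked epochs for one session
#'
#' @param epochs 4-way numeric array `[trial, flash_event, channel, sample]`
#'   in microvolts. The sample axis covers the half-open window
#'   `[window[1], window[2])` ms relative to flash onset, sample 1 at onset
#'   when `window[1] == 0`.
#' @param flashed_label integer matrix `[trial, flash_event]`: the choice
#'   index (1-based) flashed at each event.
#' @param target_choice integer vector: the correct choice per trial.
#' @param montage a [montage()] matching the channel axis.
#' @param protocol a [protocol_spec()].
#' @param window length-2 numeric, ms relative to flash onset.
#' @param provenance optional list describing how the data were generated.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, flashed_label, target_choice, montage,
                      protocol, window = c(0, 1000), provenance = NULL) {
  es <- structure(list(epochs = epochs,
                       flashed_label = as.matrix(flashed_label),
                       target_choice = as.integer(target_choice),
                       montage = montage, protocol = protocol,
                       window = as.numeric(window),
                       provenance = provenance),
                  class = "epoch_set")
  validate_epoch_set(es)
  es
}

#' Validate an epoch set against its paradigm invariants
#'
#' Checks array dimensions against the montage and protocol, the half-open
#' window sample count, and that every choice is flashed exactly
#' `flashes_per_choice` times per trial (so exactly `flashes_per_choice`
#' flash events per trial are targets).
#'
#' @param es an [epoch_set()].
#' @return `es`, invisibly; signals a classed error `p300select_schema_error`
#'   naming the violated invariant otherwise.
#' @export
validate_epoch_set <- function(es) {
  fail <- function(...) stop(errorCondition(paste0(...),
                                            class = c("p300select_schema_error",
                                                      "error", "condition")))
  d <- dim(es$epochs)
  if (length(d) != 4L) fail("epochs must be a 4-way array")
  if (d[1] < 1L) fail("epoch set has no trials")
  pr <- es$protocol
  n_events <- pr$n_choices * pr$flashes_per_choice
  if (d[2] != n_events)
    fail("expected ", n_events, " flash events per trial, found ", d[2])
  if (d[3] != length(es$montage$names))
    fail("channel axis (", d[3], ") does not match montage (",
         length(es$montage$names), ")")
  ws <- window_samples(es$window, pr$sample_rate)
  if (d[4] != ws)
    fail("sample axis (", d[4], ") does not match window [",
         es$window[1], ", ", es$window[2], ") at ", pr$sample_rate,
         " Hz (expected ", ws, ")")
  if (!all(dim(es$flashed_label) == d[1:2]))
    fail("flashed_label must be a trial x flash_event matrix")
  if (length(es$target_choice) != d[1])
    fail("target_choice must have one entry per trial")
  if (any(es$target_choice < 1L | es$target_choice > pr$n_choices))
    fail("target_choice outside 1..n_choices")
  counts <- t(apply(es$flashed_label, 1L, tabulate, nbins = pr$n_choices))
  if (!all(counts == pr$flashes_per_choice))
    fail("each choice must be flashed exactly ", pr$flashes_per_choice,
         " times per trial")
  invisible(es)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d trials x %d flash events x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  window [%g, %g) ms at %g Hz; %d-choice paradigm\n",
              x$window[1], x$window[2], x$protocol$sample_rate,
              x$protocol$n_choices))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param es an [epoch_set()].
#' @return integer.
#' @export
n_trials <- function(es) dim(es$epochs)[1]

#' Common average reference
#'
#' Re-references every epoch by subtracting, at each sample, the mean across
#' all channels of the epoch set. Apply before any channel subsetting so the
#' reference is computed over the full recorded montage.
#'
#' @param es an [epoch_set()] with at least two channels.
#' @return an [epoch_set()] whose per-sample channel mean is 0.
#' @export
apply_car <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  if (d[3] < 2L) stop("common average reference needs at least 2 channels")
  m <- rowMeans(aperm(es$epochs, c(1, 2, 4, 3)), dims = 3)  # trial x flash x sample
  m <- array(m, c(d[1], d[2], 1L, d[4]))
  out <- es$epochs
  for (ch in seq_len(d[3]))
    out[, , ch, ] <- out[, , ch, , drop = FALSE] - m
  es$epochs <- out
  es
}

#' Select and reorder channels
#'
#' @param es an [epoch_set()].
#' @param subset electrode names (no duplicates) drawn from the montage; the
#'   channel axis is reduced and reordered to this order.
#' @return an [epoch_set()] on the restricted montage.
#' @export
select_channels <- function(es, subset) {
  stopifnot(inherits(es, "epoch_set"))
  subset <- as.character(subset)
  if (anyDuplicated(subset)) stop("duplicate electrode in subset")
  idx <- match(subset, es$montage$names)
  if (anyNA(idx)) stop("unknown electrode(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  es$epochs <- es$epochs[, , idx, , drop = FALSE]
  es$montage <- subset_montage(es$montage, subset)
  es
}

#' Target and non-target ERP averages
#'
#' Each epoch is linearly detrended (least-squares line removed, which also
#' zeroes the epoch mean) per channel, then epochs are averaged separately
#' for target and non-target flashes over a 0-1000 ms post-stimulus window.
#'
#' @param es an [epoch_set()] whose window covers `window`.
#' @param window length-2 numeric (ms).
#' @return an object of class `erp_average`: channel x sample matrices
#'   `target` and `nontarget`, epoch counts, and the sample times in ms.
#' @export
average_erp <- function(es, window = c(0, 1000)) {
  stopifnot(inherits(es, "epoch_set"))
  fs <- es$protocol$sample_rate
  sel <- crop_indices(es$window, window, fs)
  d <- dim(es$epochs)
  is_target <- es$flashed_label == es$target_choice[row(es$flashed_label)]
  tvec <- as.vector(is_target)  # trial varies fastest, matching array layout
  ns <- length(sel)
  target <- nontarget <- matrix(0, d[3], ns,
                                dimnames = list(es$montage$names, NULL))
  for (ch in seq_len(d[3])) {
    m <- matrix(es$epochs[, , ch, sel], d[1] * d[2], ns)
    dm <- detrend_rows(m)
    target[ch, ] <- colMeans(dm[tvec, , drop = FALSE])
    nontarget[ch, ] <- colMeans(dm[!tvec, , drop = FALSE])
  }
  structure(list(target = target, nontarget = nontarget,
                 n_target = sum(tvec), n_nontarget = sum(!tvec),
                 times_ms = window[1] + (seq_len(ns) - 1) * 1000 / fs,
                 channels = es$montage$names),
            class = "erp_average")
}

# sample indices of the half-open feature/ERP window inside the epoch window
crop_indices <- function(epoch_window, window, sample_rate) {
  if (window[1] < epoch_window[1] || window[2] > epoch_window[2])
    stop(sprintf("window [%g, %g) not covered by epochs [%g, %g)",
                 window[1], window[2], epoch_window[1], epoch_window[2]))
  offset <- as.integer(round((window[1] - epoch_window[1]) * sample_rate / 1000))
  offset + seq_len(window_samples(window, sample_rate))
}
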