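#' Save a session bundle
#'
#' A session bundle is a directory holding `metadata.json` (montage, protocol,
#' labels, window, provenance) and `epochs.csv`, a long-format text payload
#' with columns `trial`, `flash_event`, `channel`, `sample`, `value`. Values
#' are written with 17 significant digits so the numeric payload round-trips
#' bit-exactly. The format is self-describing and diff-friendly; it is
#' intended for sessions of laboratory size, not continuous recordings.
#'
#' @param es an [epoch_set()].
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_session_bundle <- function(es, path) {
  validate_epoch_set(es)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    montage = list(names = es$montage$names,
                   positions = unname(es$montage$positions),
                   default16 = es$montage$default16,
                   default8 = es$montage$default8),
    protocol = unclass(es$protocol),
    window = es$window,
    channels = es$montage$names,
    target_choice = es$target_choice,
    flashed_label = unname(apply(es$flashed_label, 1L, c, simplify = FALSE)),
    provenance = es$provenance)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       digits = NA, auto_unbox = FALSE, null = "null")
  d <- dim(es$epochs)
  idx <- arrayInd(seq_along(es$epochs), d)
  dt <- data.table::data.table(trial = idx[, 1], flash_event = idx[, 2],
                               channel = idx[, 3], sample = idx[, 4],
                               value = sprintf("%.17g", as.vector(es$epochs)))
  data.table::setorderv(dt, c("trial", "flash_event", "channel", "sample"))
  data.table::fwrite(dt, file.path(path, "epochs.csv"))
  invisible(path)
}

#' Load a session bundle
#'
#' @param path bundle directory written by [save_session_bundle()].
#' @return an [epoch_set()]; signals a `p300select_schema_error` when files
#'   are missing or the payload violates a paradigm invariant.
#' @export
load_session_bundle <- function(path) {
  fail <- function(...) stop(errorCondition(paste0(...),
                                            class = c("p300select_schema_error",
                                                      "error", "condition")))
  meta_path <- file.path(path, "metadata.json")
  csv_path <- file.path(path, "epochs.csv")
  if (!file.exists(meta_path)) fail("missing metadata.json in ", path)
  if (!file.exists(csv_path)) fail("missing epochs.csv in ", path)
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) fail("corrupt metadata.json: ",
                                            conditionMessage(e)))
  mont <- tryCatch(montage(meta$montage$names, meta$montage$positions,
                           default16 = meta$montage$default16,
                           default8 = meta$montage$default8),
                   error = function(e) fail("invalid montage: ",
                                            conditionMessage(e)))
  if (!all(meta$channels %in% mont$names))
    fail("payload channel name(s) absent from the montage: ",
         paste(setdiff(meta$channels, mont$names), collapse = ", "))
  pr <- do.call(protocol_spec, as.list(meta$protocol))
  dt <- data.table::fread(csv_path, colClasses = list(
    integer = c("trial", "flash_event", "channel", "sample"),
    numeric = "value"))
  need <- c("trial", "flash_event", "channel", "sample", "value")
  if (!all(need %in% names(dt))) fail("epochs.csv lacks required columns")
  n_t <- max(dt$trial); n_f <- max(dt$flash_event)
  n_c <- max(dt$channel); n_s <- max(dt$sample)
  if (nrow(dt) != n_t * n_f * n_c * n_s)
    fail("epochs.csv is not a complete trial x flash x channel x sample grid")
  arr <- array(NA_real_, c(n_t, n_f, n_c, n_s))
  arr[cbind(dt$trial, dt$flash_event, dt$channel, dt$sample)] <- dt$value
  if (anyNA(arr)) fail("epochs.csv has duplicate or missing cells")
  fl <- if (is.matrix(meta$flashed_label)) meta$flashed_label
        else do.call(rbind, meta$flashed_label)
  es <- tryCatch(epoch_set(arr, fl, meta$target_choice, mont, pr,
                           window = meta$window,
                           provenance = meta$provenance),
                 p300select_schema_error = function(e) stop(e),
                 error = function(e) fail(conditionMessage(e)))
  es
}
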