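#' Electrode montage
#'
#' A montage holds ordered electrode labels, schematic 2D scalp coordinates
#' (unitless; used for simulation topographies and plotting, not for source
#' modelling), and the two standard subsets used by P300 BCIs: the 16-channel
#' laboratory default and the 8-channel home-use default.
#'
#' @param names character vector of unique electrode labels.
#' @param positions numeric matrix with one row per electrode and columns
#'   `x` (left negative) and `y` (anterior positive).
#' @param default16,default8 character vectors naming the default subsets;
#'   `default8` must be contained in `default16`, which must be contained in
#'   `names`. Either may be `NULL` for ad-hoc montages.
#' @return an object of class `montage`.
#' @export
montage <- function(names, positions, default16 = NULL, default8 = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("electrode names must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 2L)
    stop("`positions` must be a ", length(names), " x 2 matrix")
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(names, c("x", "y"))
  if (!is.null(default16) && !all(default16 %in% names))
    stop("default16 contains electrodes not in the montage")
  if (!is.null(default8)) {
    if (!all(default8 %in% names))
      stop("default8 contains electrodes not in the montage")
    if (!is.null(default16) && !all(default8 %in% default16))
      stop("default8 must be a subset of default16")
  }
  structure(list(names = names, positions = positions,
                 default16 = as.character(default16),
                 default8 = as.character(default8)),
            class = "montage")
}

#' Standard 32-channel cap montage
#'
#' The 32-location wet-electrode cap used for data acquisition, with the
#' 16-channel laboratory default and the 8-channel home-use default subsets.
#' Coordinates are a schematic planar 10-10 layout (Cz at the origin, left
#' negative x, anterior positive y, unit-order head radius).
#'
#' @param default8 optional override of the home-use 8-electrode subset.
#' @return a [montage()].
#' @export
standard_montage <- function(default8 = c("Fz", "Cz", "P3", "Pz", "P4",
                                          "PO7", "PO8", "Oz")) {
  pos <- rbind(
    F3  = c(-0.45,  0.55), Fz  = c( 0.00,  0.55), F4  = c( 0.45,  0.55),
    FC5 = c(-0.70,  0.30), FC3 = c(-0.45,  0.30), FC1 = c(-0.20,  0.30),
    FCz = c( 0.00,  0.30), FC2 = c( 0.20,  0.30), FC4 = c( 0.45,  0.30),
    FC6 = c( 0.70,  0.30),
    T7  = c(-0.95,  0.00), C5  = c(-0.70,  0.00), C3  = c(-0.45,  0.00),
    C1  = c(-0.20,  0.00), Cz  = c( 0.00,  0.00), C2  = c( 0.20,  0.00),
    C4  = c( 0.45,  0.00), C6  = c( 0.70,  0.00), T8  = c( 0.95,  0.00),
    CP5 = c(-0.70, -0.30), CP3 = c(-0.45, -0.30), CP1 = c(-0.20, -0.30),
    CPz = c( 0.00, -0.30), CP2 = c( 0.20, -0.30), CP4 = c( 0.45, -0.30),
    CP6 = c( 0.70, -0.30),
    P3  = c(-0.45, -0.55), Pz  = c( 0.00, -0.55), P4  = c( 0.45, -0.55),
    PO7 = c(-0.60, -0.80), PO8 = c( 0.60, -0.80), Oz  = c( 0.00, -1.00))
  default16 <- c("F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
                 "CP3", "CP4", "P3", "Pz", "P4", "PO7", "PO8", "Oz")
  montage(rownames(pos), pos, default16 = default16, default8 = default8)
}

#' Restrict a montage to a subset of electrodes
#'
#' @param m a [montage()].
#' @param names electrodes to keep, in the requested order.
#' @return a [montage()] whose default subsets are intersected with `names`.
#' @export
subset_montage <- function(m, names) {
  stopifnot(inherits(m, "montage"))
  if (!all(names %in% m$names)) stop("unknown electrode(s): ",
                                     paste(setdiff(names, m$names), collapse = ", "))
  montage(names, m$positions[names, , drop = FALSE],
          default16 = intersect(m$default16, names),
          default8 = intersect(intersect(m$default8, m$default16), names))
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$names), " electrodes\n", sep = "")
  cat("  default16:", paste(x$default16, collapse = " "), "\n")
  cat("  default8: ", paste(x$default8, collapse = " "), "\n")
  invisible(x)
}

#' Read or write a montage as JSON
#'
#' @param m a [montage()].
#' @param path file path.
#' @return `read_montage_json` returns a [montage()];
#'   `write_montage_json` returns `path` invisibly.
#' @export
write_montage_json <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  jsonlite::write_json(list(names = m$names,
                            positions = unname(m$positions),
                            default16 = m$default16,
                            default8 = m$default8),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  montage(j$names, j$positions, default16 = j$default16, default8 = j$default8)
}
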