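#' Scan calibration metadata
#'
#' Physical sampling of an OCT volume: micrometres per pixel along the axial
#' (depth) direction, along an A-scan row within a B-scan, and between
#' consecutive B-scans, together with the grid counts. This replaces the
#' metadata a tomograph records alongside its proprietary container.
#'
#' @param axial_um_per_px Axial (depth) sampling, micrometres per pixel.
#' @param lateral_um_per_px Lateral sampling within a B-scan, micrometres per
#'   A-scan column.
#' @param bscan_spacing_um Distance between consecutive B-scans, micrometres.
#' @param n_ascans Number of A-scans (columns) per B-scan, or `NA`.
#' @param n_bscans Number of B-scans, or `NA`.
#' @return An object of class `"calibration"` (a named list).
#' @examples
#' calibration(5, 12, 12, n_ascans = 256, n_bscans = 64)
#' @export
calibration <- function(axial_um_per_px, lateral_um_per_px,
                        bscan_spacing_um, n_ascans = NA_integer_,
                        n_bscans = NA_integer_) {
  vals <- c(axial_um_per_px, lateral_um_per_px, bscan_spacing_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration spacings must be strictly positive", call. = FALSE)
  }
  structure(
    list(axial_um_per_px = as.numeric(axial_um_per_px),
         lateral_um_per_px = as.numeric(lateral_um_per_px),
         bscan_spacing_um = as.numeric(bscan_spacing_um),
         n_ascans = as.integer(n_ascans),
         n_bscans = as.integer(n_bscans)),
    class = "calibration"
  )
}

#' OCT volume container
#'
#' A 3-D array of 8-bit gray levels in `(m, n, i)` order -- `m` the axial row
#' within a B-scan, `n` the A-scan column, `i` the B-scan index -- plus its
#' [calibration()].
#'
#' @param data Numeric 3-D array, values in `[0, 255]`.
#' @param cal A [calibration()] object.
#' @return An object of class `"oct_volume"`.
#' @export
oct_volume <- function(data, cal) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3-D array (rows x columns x B-scans)",
         call. = FALSE)
  }
  if (!inherits(cal, "calibration")) stop("cal must be a calibration object",
                                          call. = FALSE)
  rng <- range(data, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("gray levels must lie in [0, 255] (8-bit volume)", call. = FALSE)
  }
  structure(list(data = data, cal = cal), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OCT volume: %d rows x %d A-scans x %d B-scans\n",
              d[1], d[2], d[3]))
  cat(sprintf("  axial %.3g um/px, lateral %.3g um/px, B-scan spacing %.3g um\n",
              x$cal$axial_um_per_px, x$cal$lateral_um_per_px,
              x$cal$bscan_spacing_um))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' Retinal boundary surface
#'
#' Per-(A-scan, B-scan) axial row position of one retinal boundary. Entries
#' are 1-based row indices (fractional values allowed after refinement);
#' columns where the boundary could not be determined carry `NA`.
#'
#' @param rows Numeric `N x I` matrix of row positions (`NA` = undefined).
#' @param label One of `"RPE"`, `"ILM"`, `"RNFL"`.
#' @param n_rows Axial extent `M` of the parent volume (used for validation),
#'   or `NULL` to skip the range check.
#' @return An object of class `"layer_surface"` (a matrix with attributes).
#' @export
layer_surface <- function(rows, label = c("RPE", "ILM", "RNFL"),
                          n_rows = NULL) {
  label <- match.arg(label)
  if (!is.matrix(rows)) stop("rows must be an N x I matrix", call. = FALSE)
  rows <- rows * 1.0
  if (!is.null(n_rows)) {
    bad <- !is.na(rows) & (rows < 1 | rows > n_rows)
    if (any(bad)) {
      stop(sprintf("%d surface entries outside [1, %d]", sum(bad), n_rows),
           call. = FALSE)
    }
  }
  structure(rows, label = label, class = c("layer_surface", "matrix", "array"))
}

#' @export
print.layer_surface <- function(x, ...) {
  nd <- sum(is.na(x))
  cat(sprintf("%s surface: %d x %d columns, %.1f%% undefined\n",
              attr(x, "label"), nrow(x), ncol(x), 100 * nd / length(x)))
  if (nd < length(x)) {
    cat(sprintf("  row range [%.1f, %.1f]\n",
                min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  }
  invisible(x)
}

surface_label <- function(x) attr(x, "label")

#' En-face binary mask
#'
#' Binary `N x I` map in the en-face (A-scan x B-scan) plane marking the
#' optic disk or cup footprint.
#'
#' @param bits Logical (or 0/1) `N x I` matrix.
#' @param label `"disk"` or `"cup"`.
#' @return An object of class `"enface_mask"`.
#' @export
enface_mask <- function(bits, label = c("disk", "cup")) {
  label <- match.arg(label)
  if (!is.matrix(bits)) stop("mask must be an N x I matrix", call. = FALSE)
  bits <- matrix(as.logical(bits), nrow(bits), ncol(bits))
  if (anyNA(bits)) stop("mask entries must be 0/1", call. = FALSE)
  structure(bits, label = label, class = c("enface_mask", "matrix", "array"))
}

#' @export
print.enface_mask <- function(x, ...) {
  cat(sprintf("%s mask: %d x %d en-face, area %d px\n",
              attr(x, "label"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# internal: strip class so base matrix ops don't dispatch
as_mat <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x))
}
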