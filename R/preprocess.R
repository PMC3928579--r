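#' 3-D median filtering of an OCT volume
#'
#' Replaces every voxel by the median of its rectangular neighbourhood,
#' suppressing acquisition noise and small artefacts in the optical path
#' before any boundary is sought. The default mask of 3 x 3 x 3 pixels pools
#' information across the two neighbouring B-scans as well as within the
#' B-scan plane.
#'
#' @param volume An [oct_volume()].
#' @param mask_dims Odd positive mask size `(rows, cols, B-scans)`.
#' @param border `"replicate"` (clamp to edge, default) or `"reflect"`.
#' @return The filtered [oct_volume()] (same dimensions and calibration).
#' @examples
#' cal <- calibration(5, 12, 12)
#' v <- oct_volume(array(100, c(5, 5, 5)), cal)
#' all(median_filter_3d(v)$data == 100)  # constant volume is unchanged
#' @export
median_filter_3d <- function(volume, mask_dims = c(3L, 3L, 3L),
                             border = c("replicate", "reflect")) {
  border <- match.arg(border)
  stopifnot(inherits(volume, "oct_volume"))
  mask_dims <- as.integer(mask_dims)
  if (length(mask_dims) != 3L || any(mask_dims < 1L) ||
      any(mask_dims %% 2L == 0L)) {
    stop("mask dimensions must be three odd positive integers", call. = FALSE)
  }
  d <- dim(volume$data)
  if (any(d < 3L)) {
    stop("volume must be at least 3 voxels in every axis for 3-D filtering",
         call. = FALSE)
  }
  out <- .median3d_cpp(as.numeric(volume$data), d, mask_dims,
                       if (border == "replicate") 0L else 1L)
  oct_volume(out, volume$cal)
}
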