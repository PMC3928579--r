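#' Cup eccentricity score w_g(1)
#'
#' Relative difference in the positions of the centres of gravity of cup and
#' disk: the Euclidean centroid distance divided by the disk equivalent
#' radius. 0 for concentric structures, 1 when the cup centre sits on the
#' disk boundary.
#'
#' @param disk_centroid,cup_centroid Length-2 numeric `(n, i)` centroids.
#' @param r_disk Disk equivalent radius (> 0), same units as the centroids.
#' @return The dimensionless score.
#' @examples
#' wg1(c(0, 0), c(3, 4), 10)  # 0.5
#' @export
wg1 <- function(disk_centroid, cup_centroid, r_disk) {
  if (!is.finite(r_disk) || r_disk <= 0) {
    stop("r_disk must be strictly positive", call. = FALSE)
  }
  sqrt(sum((disk_centroid - cup_centroid)^2)) / r_disk
}

#' Boundary proximity score w_g(2)
#'
#' One minus the ratio of the minimum cup-to-disk boundary distance to the
#' disk radius: 0 when the cup edge stays maximally distant from the disk
#' edge, 1 when the two boundaries touch.
#'
#' @param r_min Minimum boundary distance (>= 0).
#' @param r_disk Disk equivalent radius (>= r_min).
#' @return The dimensionless score in `[0, 1]`.
#' @export
wg2 <- function(r_min, r_disk) {
  if (r_min < 0 || r_min > r_disk) {
    stop("need 0 <= r_min <= r_disk", call. = FALSE)
  }
  1 - r_min / r_disk
}

#' RNFL deviation score w_g(3)
#'
#' Mean absolute relative deviation of the measured peripapillary RNFL
#' thickness profile from the reference profile, over the angular bins. Bins
#' flagged invalid are excluded and the normalizer reduced to the valid-bin
#' count, keeping the score a mean rather than coverage-dependent. Not
#' clamped: thicknesses beyond twice the reference give values above 1.
#'
#' @param profile A [polar_thickness_profile()] result (carries its
#'   reference profile), or a numeric vector of thicknesses.
#' @param reference Reference profile: a function of theta (degrees)
#'   returning micrometres, or a numeric vector matching `profile`. Taken
#'   from the `polar_roi` attribute when omitted.
#' @return The dimensionless score (>= 0).
#' @export
wg3 <- function(profile, reference = NULL) {
  if (inherits(profile, "polar_roi")) {
    if (is.null(reference)) reference <- attr(profile, "reference")
    theta <- profile$theta_deg[profile$valid]
    meas <- profile$thickness_um[profile$valid]
    ref <- if (is.function(reference)) reference(theta) else
      reference[profile$valid]
  } else {
    meas <- profile
    ref <- if (is.function(reference)) {
      reference(seq(0, 360, length.out = length(meas) + 1)[-(length(meas) + 1)])
    } else reference
    keep <- !is.na(meas)
    meas <- meas[keep]; ref <- ref[keep]
  }
  if (length(meas) == 0L) {
    stop("no valid angular bins to score", call. = FALSE)
  }
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference thickness must be strictly positive", call. = FALSE)
  }
  mean(abs(meas - ref) / ref)
}

#' Biomorphological glaucoma advancement ratio
#'
#' Arithmetic mean of the three normalized features: cup eccentricity,
#' boundary proximity and RNFL deviation. Close to 0 for a healthy nerve
#' head, close to 1 when all three features indicate pathology.
#'
#' @param wg1,wg2,wg3 The three non-negative component scores.
#' @return The BGA ratio.
#' @export
bga <- function(wg1, wg2, wg3) {
  v <- c(wg1, wg2, wg3)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("component scores must be finite and non-negative", call. = FALSE)
  }
  mean(v)
}

#' Expected perimetric mean defect from the BGA ratio
#'
#' Linear conversion of the BGA ratio to the expected mean defect (MD) of a
#' static visual-field test, `MD = slope * BGA + intercept`, with the
#' published coefficients (24 dB per unit, -9.34 dB) as defaults.
#'
#' @param w_bga BGA ratio (finite).
#' @param config An [onh_config()] carrying `md_slope` and `md_intercept`.
#' @return Expected MD in dB.
#' @examples
#' predict_md(0)   # intercept
#' predict_md(1) - predict_md(0)  # slope, dB per unit BGA
#' @export
predict_md <- function(w_bga, config = onh_config()) {
  stopifnot(is.finite(w_bga))
  config$md_slope * w_bga + config$md_intercept
}

#' Assemble a BGA result
#'
#' @param wg1,wg2,wg3 Component scores.
#' @param config An [onh_config()] (MD model coefficients).
#' @return An object of class `"bga_result"` with fields `wg1`, `wg2`,
#'   `wg3`, `w_bga`, `predicted_md`.
#' @export
bga_result <- function(wg1, wg2, wg3, config = onh_config()) {
  w <- bga(wg1, wg2, wg3)
  structure(list(wg1 = wg1, wg2 = wg2, wg3 = wg3, w_bga = w,
                 predicted_md = predict_md(w, config)),
            class = "bga_result")
}

#' @export
print.bga_result <- function(x, ...) {
  cat(sprintf("w_g(1) = %.4f  w_g(2) = %.4f  w_g(3) = %.4f\n",
              x$wg1, x$wg2, x$wg3))
  cat(sprintf("w_BGA  = %.4f  ->  expected MD = %.2f dB\n",
              x$w_bga, x$predicted_md))
  invisible(x)
}

#' Classic derived optic-nerve-head features
#'
#' The standard morphometric ratios derivable from the printed components of
#' a tomograph report: cup/disk area ratio, mean diameters, horizontal and
#' vertical cup/disk diameter ratios and the two vertical/horizontal shape
#' ratios. A zero denominator makes the individual feature `NA` rather than
#' failing.
#'
#' @param disk_area,cup_area Areas (mm^2).
#' @param d_h,d_v Disk diameters, horizontal and vertical (mm).
#' @param c_h,c_v Cup diameters, horizontal and vertical (mm).
#' @return A named list: `w5` (cup/disk area), `w12` (mean disk diameter),
#'   `w15` (mean cup diameter), `w16` (C/D horizontal), `w17` (C/D
#'   vertical), `w18` (disk v/h), `w19` (cup v/h).
#' @examples
#' classic_derived_features(2.26, 0.68, 1.57, 1.80, 0.68, 1.23)$w5  # 0.30
#' @export
classic_derived_features <- function(disk_area, cup_area, d_h, d_v,
                                     c_h, c_v) {
  rat <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b
  list(w5 = rat(cup_area, disk_area),
       w12 = (d_h + d_v) / 2,
       w15 = (c_h + c_v) / 2,
       w16 = rat(c_h, d_h),
       w17 = rat(c_v, d_v),
       w18 = rat(d_v, d_h),
       w19 = rat(c_v, c_h))
}
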