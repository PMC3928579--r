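#' Run the full optic-nerve-head analysis pipeline
#'
#' Executes, in order: 3-D median filtering, RPE detection (brightest layer
#' per A-scan), disk mask from the RPE depth excursion, ILM detection by
#' Otsu binarization above the RPE, RNFL lower-boundary detection by the
#' first band-masked gradient edge, active edge correction of the RNFL
#' contour, cup extraction at the offset RPE chord, polar resampling of the
#' RNFL thickness on the 2r-3r annulus, and the three normalized features
#' combined into the BGA ratio with its linear conversion to an expected
#' perimetric mean defect. Per-stage timings and undefined-column
#' percentages are recorded.
#'
#' @param volume An [oct_volume()].
#' @param reference Reference RNFL thickness profile, a function of degrees
#'   (see [reference_profile()]); defaults to a constant 100 um.
#' @param config An [onh_config()].
#' @return An object of class `"onh_analysis"` with elements `surfaces`
#'   (`rpe`, `ilm`, `rnfl_raw`, `rnfl`), `masks` (`disk`, `cup`),
#'   `geometry`, `polar`, `bga`, `log`, `cal`, `config`.
#' @seealso [generate_phantom()] for test volumes, [write_results()] to
#'   persist the outputs.
#' @export
onh_analyze <- function(volume, reference = constant_reference(100),
                        config = onh_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    und <- if (inherits(res, "layer_surface")) 100 * mean(is.na(res)) else NA
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, seconds = proc.time()[["elapsed"]] - t0,
      undefined_pct = und)
    message(sprintf("[stage=%s] %.2fs%s", name,
                    log[[length(log)]]$seconds,
                    if (!is.na(und)) sprintf(" undefined=%.1f%%", und) else ""))
    res
  }
  filtered <- stage("median_filter",
                    median_filter_3d(volume, config$median_mask,
                                     config$border))
  rpe <- stage("detect_rpe", detect_rpe(filtered))
  disk <- stage("disk_mask", disk_mask(rpe, config))
  ilm <- stage("detect_ilm", detect_ilm(filtered, rpe, config))
  rnfl_raw <- stage("detect_rnfl", detect_rnfl(filtered, ilm, rpe, config))
  rnfl <- stage("refine_contour",
                refine_contour(filtered, rnfl_raw, ilm, rpe,
                               config = config))
  cup <- stage("detect_cup", detect_cup(ilm, rpe, disk, volume$cal, config))
  geom <- disk_geometry(disk, cup)
  polar <- stage("polar_profile",
                 polar_thickness_profile(ilm, rnfl, geom, volume$cal,
                                         reference, config))
  w1 <- wg1(c(geom$n_d0, geom$i_d0), c(geom$n_c0, geom$i_c0), geom$r_disk)
  w2 <- wg2(min(geom$r_min, geom$r_disk), geom$r_disk)
  w3 <- wg3(polar)
  res <- bga_result(w1, w2, w3, config)
  structure(list(surfaces = list(rpe = rpe, ilm = ilm, rnfl_raw = rnfl_raw,
                                 rnfl = rnfl),
                 masks = list(disk = disk, cup = cup),
                 geometry = geom, polar = polar, bga = res,
                 log = do.call(rbind, log), cal = volume$cal,
                 config = config),
            class = "onh_analysis")
}

#' @export
print.onh_analysis <- function(x, ...) {
  cat("Optic nerve head analysis\n")
  print(x$geometry)
  print(x$bga)
  invisible(x)
}

#' @export
summary.onh_analysis <- function(object, ...) {
  cat("Optic nerve head analysis\n\n")
  print(object$geometry)
  cat("\n")
  print(object$bga)
  vb <- sum(object$polar$valid)
  cat(sprintf("\npolar profile: %d/%d valid bins", vb, nrow(object$polar)))
  if (vb > 0) {
    cat(sprintf(", mean thickness %.1f um",
                mean(object$polar$thickness_um[object$polar$valid])))
  }
  cat("\n\nstage log:\n")
  print(object$log, row.names = FALSE)
  invisible(object)
}

#' @export
coef.onh_analysis <- function(object, ...) {
  with(object$bga, c(`w_g(1)` = wg1, `w_g(2)` = wg2, `w_g(3)` = wg3,
                     w_BGA = w_bga, predicted_MD = predicted_md))
}

#' Predict the expected mean defect
#'
#' Applies the configured linear BGA-to-MD conversion, either to the
#' analysis's own BGA ratio or to new BGA values.
#'
#' @param object An `"onh_analysis"`.
#' @param newdata Optional numeric vector of BGA ratios.
#' @param ... Unused.
#' @return Expected MD in dB.
#' @export
predict.onh_analysis <- function(object, newdata = NULL, ...) {
  w <- if (is.null(newdata)) object$bga$w_bga else newdata
  object$config$md_slope * w + object$config$md_intercept
}

#' Plot an optic-nerve-head analysis
#'
#' Two panels: the en-face disk/cup footprint with centroids, and the
#' peripapillary thickness profile against its reference (TSNIT-style, over
#' angle).
#'
#' @param x An `"onh_analysis"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.onh_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  disk <- x$masks$disk; cup <- x$masks$cup
  graphics::image(seq_len(nrow(disk)), seq_len(ncol(disk)),
                  as_mat(disk) + as_mat(cup),
                  col = c("black", "grey50", "white"),
                  xlab = "A-scan (n)", ylab = "B-scan (i)",
                  main = "disk / cup footprint", useRaster = TRUE)
  graphics::points(x$geometry$n_d0, x$geometry$i_d0, col = "green", pch = 3)
  graphics::points(x$geometry$n_c0, x$geometry$i_c0, col = "red", pch = 4)
  pr <- x$polar
  ref <- attr(pr, "reference")(pr$theta_deg)
  graphics::plot(pr$theta_deg, pr$thickness_um, type = "l",
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "RNFL thickness (um)",
                 main = "peripapillary profile", ...)
  graphics::lines(pr$theta_deg, ref, col = "green")
  graphics::legend("topright", legend = c("measured", "reference"),
                   col = c("black", "green"), lty = 1, bty = "n")
  invisible(x)
}
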