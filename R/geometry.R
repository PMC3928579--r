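#' @importFrom Rcpp sourceCpp
#' @useDynLib onhbga, .registration = TRUE
NULL

onh_error <- function(msg, class) {
  stop(structure(class = c(class, "onh_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# keep the largest 8-connected component and fill its holes
clean_mask <- function(bits) {
  if (!any(bits)) return(bits)
  lab <- EBImage::bwlabel(matrix(as.numeric(bits), nrow(bits), ncol(bits)))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  filled <- EBImage::fillHull(matrix(as.numeric(keep), nrow(bits), ncol(bits)))
  matrix(as.logical(EBImage::imageData(filled)), nrow(bits), ncol(bits))
}

# Mask pixels whose 4-neighbourhood touches background (image border counts
# as background). With 8-connected foreground regions, digital-topology
# duality pairs the foreground with 4-adjacent background: taking 8-adjacency
# here would also flag pixels lying a full diagonal step inside the rim,
# biasing boundary-to-boundary distances low.
boundary_pixels <- function(bits) {
  M <- nrow(bits); N <- ncol(bits)
  pad <- matrix(FALSE, M + 2L, N + 2L)
  pad[2:(M + 1L), 2:(N + 1L)] <- bits
  all_nb <- matrix(TRUE, M, N)
  for (ab in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    all_nb <- all_nb & pad[(2:(M + 1L)) + ab[1], (2:(N + 1L)) + ab[2]]
  }
  bits & !all_nb
}

#' Optic disk mask from the RPE surface
#'
#' Inside the optic disk the retinal pigment epithelium terminates, and the
#' brightest-layer position detected per A-scan shifts posteriorly (to
#' larger row indices). Columns whose detected RPE row departs from the mean
#' row by more than the configured threshold are flagged as disk, then the
#' largest connected component is kept and its holes filled.
#'
#' Two threshold modes are available. The default (`"reciprocal"`) flags
#' columns deeper than `mean/p_m` (a 50 percent depth excursion at the
#' default `p_m = 2/3`), which selects the excavated region; `"literal"`
#' applies the verbatim `row > p_m * mean` rule.
#'
#' @param rpe The RPE [layer_surface()].
#' @param config An [onh_config()] (`p_m`, `disk_threshold_mode`).
#' @return An [enface_mask()] labelled `"disk"`.
#' @export
disk_mask <- function(rpe, config = onh_config()) {
  stopifnot(inherits(rpe, "layer_surface"))
  if (all(is.na(rpe))) onh_error("RPE fully undefined; cannot locate disk",
                                 "onh_algorithm_error")
  mu <- mean(rpe, na.rm = TRUE)
  thr <- switch(config$disk_threshold_mode,
                reciprocal = mu / config$p_m,
                literal = mu * config$p_m)
  bits <- !is.na(rpe) & rpe > thr
  bits <- clean_mask(bits)
  if (!any(bits)) {
    onh_error("no optic disk found (no RPE depth excursion above threshold)",
              "onh_algorithm_error")
  }
  enface_mask(bits, "disk")
}

#' Centroid and equivalent radius of an en-face mask
#'
#' First image moments give the centre of gravity; the equivalent radius is
#' that of a circle with the mask's pixel area, `sqrt(area / pi)`.
#'
#' @param mask An [enface_mask()].
#' @return A list with `centroid` (`c(n0, i0)`, fractional px) and `r` (px).
#' @examples
#' m <- matrix(FALSE, 20, 20); m[7, 9] <- TRUE
#' mask_centroid_radius(enface_mask(m, "disk"))  # r = 1/sqrt(pi)
#' @export
mask_centroid_radius <- function(mask) {
  stopifnot(inherits(mask, "enface_mask"))
  area <- sum(mask)
  if (area == 0) onh_error("empty mask has no centroid",
                           "onh_algorithm_error")
  n0 <- sum(row(mask)[mask]) / area
  i0 <- sum(col(mask)[mask]) / area
  list(centroid = c(n0 = n0, i0 = i0), r = sqrt(area / pi))
}

#' Cup mask from the ILM and an offset RPE reference chord
#'
#' Per B-scan, a reference chord joins the RPE at the two columns flanking
#' the disk extent; the chord, displaced anteriorly by the configured offset
#' (150 um by default), defines the cup cut level. Disk columns whose ILM
#' lies posterior to (deeper than) the displaced chord belong to the cup.
#' The resulting mask is cleaned like the disk mask. An empty mask (ILM
#' never crossing the cut level, e.g. no excavation) is a valid result, not
#' an error.
#'
#' @param ilm,rpe ILM and RPE [layer_surface()]s.
#' @param disk The disk [enface_mask()].
#' @param cal A [calibration()] (axial scale converts the offset to rows).
#' @param config An [onh_config()] (`cup_offset_um`).
#' @return An [enface_mask()] labelled `"cup"`, contained in the disk mask.
#' @export
detect_cup <- function(ilm, rpe, disk, cal, config = onh_config()) {
  stopifnot(inherits(disk, "enface_mask"))
  if (!inherits(cal, "calibration")) {
    onh_error("missing or invalid calibration", "onh_config_error")
  }
  if (!any(disk)) onh_error("empty disk mask", "onh_algorithm_error")
  N <- nrow(disk); I <- ncol(disk)
  disk_cols <- which(colSums(disk) > 0)
  if (all(is.na(ilm[as.logical(disk)]))) {
    onh_error("ILM undefined across the disk; cannot cut the cup",
              "onh_algorithm_error")
  }
  offset_px <- config$cup_offset_um / cal$axial_um_per_px
  bits <- matrix(FALSE, N, I)
  for (i in disk_cols) {
    in_disk <- which(disk[, i])
    n1 <- min(in_disk); n2 <- max(in_disk)
    anchor <- function(n, dir) {
      # nearest defined RPE at or beyond the disk edge, searching outward
      idx <- if (dir < 0) seq(max(1L, n), 1L) else seq(min(N, n), N)
      idx <- idx[!is.na(rpe[idx, i])]
      if (length(idx) == 0L) NA_real_ else rpe[idx[1L], i]
    }
    a1 <- anchor(n1 - 1L, -1L)
    a2 <- anchor(n2 + 1L, +1L)
    if (is.na(a1) && is.na(a2)) next
    if (is.na(a1)) a1 <- a2
    if (is.na(a2)) a2 <- a1
    chord <- a1 + (a2 - a1) * (in_disk - (n1 - 1L)) / (n2 - n1 + 2L)
    ref <- chord - offset_px
    deeper <- !is.na(ilm[in_disk, i]) & ilm[in_disk, i] > ref
    bits[in_disk[deeper], i] <- TRUE
  }
  bits <- bits & as.logical(disk)
  bits <- clean_mask(bits)
  enface_mask(bits & as.logical(disk), "cup")
}

#' Minimum distance between cup and disk boundaries
#'
#' Boundaries are the mask pixels adjacent to background (4-neighbourhood,
#' the boundary dual to an 8-connected foreground region); the result is
#' the minimum Euclidean distance (en-face px) between the two boundary
#' point sets, computed on an exact Euclidean distance map seeded at the
#' disk boundary.
#'
#' @param cup,disk Cup and disk [enface_mask()]s; the cup must be contained
#'   in the disk.
#' @return `r_min` in en-face pixels (0 if the boundaries share a pixel).
#' @export
min_boundary_distance <- function(cup, disk) {
  stopifnot(inherits(cup, "enface_mask"), inherits(disk, "enface_mask"))
  if (!any(cup) || !any(disk)) {
    onh_error("both masks must be nonempty", "onh_algorithm_error")
  }
  if (any(cup & !disk)) {
    onh_error("cup mask is not contained in the disk mask",
              "onh_algorithm_error")
  }
  db <- boundary_pixels(as.logical_matrix(disk))
  cb <- boundary_pixels(as.logical_matrix(cup))
  seed <- matrix(1, nrow(disk), ncol(disk))
  seed[db] <- 0
  dm <- EBImage::imageData(EBImage::distmap(seed, metric = "euclidean"))
  min(dm[cb])
}

as.logical_matrix <- function(x) matrix(as.logical(x), nrow(x), ncol(x))

#' Disk and cup geometry summary
#'
#' Bundles centroids, equivalent radius and the minimum cup-to-disk boundary
#' distance. With an empty cup mask the cup centroid collapses to the disk
#' centroid and `r_min = r_disk` (no excavation: both eccentricity and
#' boundary-proximity scores are 0).
#'
#' @param disk,cup Disk and cup [enface_mask()]s (`cup` may be empty).
#' @return An object of class `"disk_geometry"`: `n_d0, i_d0, r_disk, n_c0,
#'   i_c0, r_cup, r_min`.
#' @export
disk_geometry <- function(disk, cup = NULL) {
  g <- mask_centroid_radius(disk)
  if (is.null(cup) || !any(cup)) {
    res <- list(n_d0 = g$centroid[["n0"]], i_d0 = g$centroid[["i0"]],
                r_disk = g$r, n_c0 = g$centroid[["n0"]],
                i_c0 = g$centroid[["i0"]], r_cup = 0, r_min = g$r)
  } else {
    gc <- mask_centroid_radius(cup)
    res <- list(n_d0 = g$centroid[["n0"]], i_d0 = g$centroid[["i0"]],
                r_disk = g$r, n_c0 = gc$centroid[["n0"]],
                i_c0 = gc$centroid[["i0"]], r_cup = gc$r,
                r_min = min_boundary_distance(cup, disk))
  }
  structure(res, class = "disk_geometry")
}

#' @export
print.disk_geometry <- function(x, ...) {
  cat(sprintf("disk: centre (%.2f, %.2f), r = %.2f px\n",
              x$n_d0, x$i_d0, x$r_disk))
  cat(sprintf("cup:  centre (%.2f, %.2f), r = %.2f px, r_min = %.2f px\n",
              x$n_c0, x$i_c0, x$r_cup, x$r_min))
  invisible(x)
}

# bilinear interpolation of an N x I matrix at fractional (n, i); NA outside
# the grid or when any of the four neighbours is NA
bilinear <- function(Tm, n, i) {
  N <- nrow(Tm); I <- ncol(Tm)
  out <- rep(NA_real_, length(n))
  ok <- n >= 1 & n <= N & i >= 1 & i <= I & !is.na(n) & !is.na(i)
  if (!any(ok)) return(out)
  n0 <- pmin(floor(n[ok]), N - 1L); i0 <- pmin(floor(i[ok]), I - 1L)
  fn <- n[ok] - n0; fi <- i[ok] - i0
  v00 <- Tm[cbind(n0, i0)]; v10 <- Tm[cbind(n0 + 1L, i0)]
  v01 <- Tm[cbind(n0, i0 + 1L)]; v11 <- Tm[cbind(n0 + 1L, i0 + 1L)]
  out[ok] <- v00 * (1 - fn) * (1 - fi) + v10 * fn * (1 - fi) +
    v01 * (1 - fn) * fi + v11 * fn * fi
  out
}

quadrant_labels <- function(theta_deg, eye = "right") {
  th <- theta_deg %% 360
  q <- ifelse(th < 45 | th >= 315, "TE",
              ifelse(th < 135, "SU", ifelse(th < 225, "NA", "IN")))
  if (eye == "left") q <- c(TE = "NA", SU = "SU", `NA` = "TE", IN = "IN")[q]
  unname(q)
}

#' Peripapillary RNFL thickness profile on the 2r-3r annulus
#'
#' Samples the RNFL thickness (corrected lower boundary minus ILM, converted
#' to micrometres) on a polar grid centred at the disk centroid: angular
#' bins of `360 / polar_bins` degrees, radial steps across the annulus from
#' `2 r_disk` to `3 r_disk`. The angle convention is
#' `theta = atan2(n - n0, i - i0)`, so a displacement purely towards larger
#' A-scan index maps to 90 degrees. When lateral and B-scan spacing differ,
#' radii are laid out in physical micrometres (the annulus is elliptical in
#' pixel space) and the pixel radius is converted through the geometric mean
#' of the two lateral scales. Bins with fewer than the configured fraction
#' of valid samples (surface gaps or samples beyond the image) are flagged
#' invalid.
#'
#' @param ilm The ILM [layer_surface()].
#' @param rnfl_star The corrected RNFL [layer_surface()].
#' @param geom A [disk_geometry()].
#' @param cal A [calibration()].
#' @param reference A reference profile function (see
#'   [reference_profile()]), queried in degrees; stored alongside.
#' @param config An [onh_config()].
#' @return A `data.frame` of class `"polar_roi"` with columns `theta_deg`,
#'   `thickness_um`, `quadrant`, `valid`, and the reference profile in
#'   attribute `"reference"`.
#' @export
polar_thickness_profile <- function(ilm, rnfl_star, geom, cal,
                                    reference = constant_reference(100),
                                    config = onh_config()) {
  stopifnot(inherits(geom, "disk_geometry"), inherits(cal, "calibration"))
  N <- nrow(ilm); I <- ncol(ilm)
  thick <- (as_mat(rnfl_star) - as_mat(ilm)) * cal$axial_um_per_px
  thick[thick < 0] <- NA_real_
  lat <- cal$lateral_um_per_px; bsp <- cal$bscan_spacing_um
  r_um <- geom$r_disk * sqrt(lat * bsp)
  n0_um <- (geom$n_d0 - 1) * lat
  i0_um <- (geom$i_d0 - 1) * bsp
  rho_step_um <- config$rho_step_px * sqrt(lat * bsp)
  rho_um <- seq(2 * r_um, 3 * r_um, by = rho_step_um)
  bins <- config$polar_bins
  theta <- (seq_len(bins) - 1L) * 360 / bins
  th_rad <- theta * pi / 180
  thickness <- rep(NA_real_, bins)
  valid <- logical(bins)
  for (b in seq_len(bins)) {
    n_px <- (n0_um + rho_um * sin(th_rad[b])) / lat + 1
    i_px <- (i0_um + rho_um * cos(th_rad[b])) / bsp + 1
    v <- bilinear(thick, n_px, i_px)
    frac <- mean(!is.na(v))
    if (frac >= config$min_valid_fraction) {
      thickness[b] <- mean(v, na.rm = TRUE)
      valid[b] <- TRUE
    }
  }
  if (!any(valid)) {
    onh_error("measurement annulus lies fully outside the image",
              "onh_algorithm_error")
  }
  out <- data.frame(theta_deg = theta, thickness_um = thickness,
                    quadrant = quadrant_labels(theta, config$eye),
                    valid = valid, stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  attr(out, "r_disk_px") <- geom$r_disk
  class(out) <- c("polar_roi", "data.frame")
  out
}
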