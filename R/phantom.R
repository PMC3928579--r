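#' Synthetic optic-nerve-head phantom specification
#'
#' Defines the geometry, optics and noise of a synthetic ONH OCT volume with
#' analytic ground truth. The rendered scene mimics the features the
#' pipeline keys on: a bright RNFL band starting at the ILM, a dark gap, the
#' brightest (RPE) band, an RPE opening at the disk where the brightest
#' reflector shifts posteriorly (the excavation), an ILM dip of the stated
#' depth inside the cup, optional vessel shadows, and additive Gaussian
#' noise clipped to the 8-bit range.
#'
#' @param volume_dims `c(M, N, I)`: axial rows, A-scan columns, B-scans.
#' @param axial_um_per_px,lateral_um_per_px,bscan_spacing_um Calibration.
#' @param ilm_base_row ILM row outside the cup.
#' @param rnfl_thickness_um RNFL thickness: a constant (um) or a function of
#'   theta (degrees, measured around the disk centre) returning um.
#' @param rpe_depth_row RPE row outside the disk.
#' @param disk_center,disk_radius_px En-face disk circle `(n0, i0)`, px.
#' @param cup_center,cup_radius_px En-face cup circle; must lie inside (or
#'   on) the disk boundary.
#' @param cup_depth_um ILM dip inside the cup, micrometres (steep-walled).
#' @param disk_excavation_um Posterior shift of the brightest band inside
#'   the disk opening.
#' @param vessel_shadows List of shadows, each
#'   `list(n =, width_px =, attenuation =, i_range = NULL)`: columns within
#'   `width_px / 2` of `n` (optionally restricted to B-scans `i_range`) are
#'   attenuated multiplicatively below the ILM.
#' @param noise_sd Additive Gaussian noise, gray levels (0 = none).
#' @param layer_brightness Named gray levels: `background`, `rnfl` (band),
#'   `inner` (sub-RNFL retina), `cavity` (below the membrane inside the
#'   disk), `rpe` (the brightest; required maximum).
#' @param membrane_px Thickness of the thin inner surface rendered across
#'   the disk opening.
#' @param rpe_sigma_px Gaussian axial profile sigma of the RPE band.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `"phantom_spec"`; invariants are validated.
#' @export
phantom_spec <- function(volume_dims = c(256L, 256L, 64L),
                         axial_um_per_px = 5,
                         lateral_um_per_px = 12,
                         bscan_spacing_um = 12,
                         ilm_base_row = 40,
                         rnfl_thickness_um = 100,
                         rpe_depth_row = 120,
                         disk_center = c(128, 32),
                         disk_radius_px = 20,
                         cup_center = c(128, 32),
                         cup_radius_px = 10,
                         cup_depth_um = 400,
                         disk_excavation_um = 450,
                         vessel_shadows = list(),
                         noise_sd = 0,
                         layer_brightness = c(background = 10, rnfl = 150,
                                              inner = 40, cavity = 20,
                                              rpe = 230),
                         membrane_px = 3L,
                         rpe_sigma_px = 2,
                         seed = 1L) {
  spec <- structure(
    list(volume_dims = as.integer(volume_dims),
         axial_um_per_px = axial_um_per_px,
         lateral_um_per_px = lateral_um_per_px,
         bscan_spacing_um = bscan_spacing_um,
         ilm_base_row = ilm_base_row,
         rnfl_thickness_um = rnfl_thickness_um,
         rpe_depth_row = rpe_depth_row,
         disk_center = as.numeric(disk_center),
         disk_radius_px = disk_radius_px,
         cup_center = as.numeric(cup_center),
         cup_radius_px = cup_radius_px,
         cup_depth_um = cup_depth_um,
         disk_excavation_um = disk_excavation_um,
         vessel_shadows = vessel_shadows,
         noise_sd = noise_sd,
         layer_brightness = layer_brightness,
         membrane_px = as.integer(membrane_px),
         rpe_sigma_px = rpe_sigma_px,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

thickness_fun <- function(spec) {
  t <- spec$rnfl_thickness_um
  if (is.function(t)) t else function(theta) rep(t, length(theta))
}

validate_phantom_spec <- function(spec) {
  d <- spec$volume_dims
  fail <- function(field, msg) {
    stop(sprintf("invalid phantom spec: %s (%s)", msg, field), call. = FALSE)
  }
  if (length(d) != 3L || any(d < 3L)) fail("volume_dims", "dims must be >= 3")
  if (spec$cup_radius_px > spec$disk_radius_px) {
    fail("cup_radius_px", "cup radius exceeds disk radius")
  }
  sep <- sqrt(sum((spec$cup_center - spec$disk_center)^2))
  if (sep + spec$cup_radius_px > spec$disk_radius_px + 1e-9) {
    fail("cup_center", "cup protrudes outside the disk boundary")
  }
  lb <- spec$layer_brightness
  need <- c("background", "rnfl", "inner", "cavity", "rpe")
  if (!all(need %in% names(lb))) fail("layer_brightness", "missing levels")
  if (lb[["rpe"]] < max(lb)) {
    fail("layer_brightness", "RPE must be the brightest layer")
  }
  tf <- thickness_fun(spec)
  tmax <- max(tf(seq(0, 359.5, by = 0.5)))
  if (any(tf(seq(0, 359.5, by = 0.5)) <= 0)) {
    fail("rnfl_thickness_um", "thickness must be positive")
  }
  cup_ilm <- spec$ilm_base_row + round(spec$cup_depth_um / spec$axial_um_per_px)
  rpe_deep <- spec$rpe_depth_row +
    round(spec$disk_excavation_um / spec$axial_um_per_px)
  if (spec$ilm_base_row < 2) fail("ilm_base_row", "too close to image top")
  if (spec$ilm_base_row + round(tmax / spec$axial_um_per_px) >=
      spec$rpe_depth_row) {
    fail("rnfl_thickness_um", "RNFL lower boundary reaches the RPE")
  }
  if (cup_ilm + spec$membrane_px >= rpe_deep) {
    fail("cup_depth_um", "cup floor reaches the excavated bright band")
  }
  if (rpe_deep > d[1] - 1L) {
    fail("disk_excavation_um", "excavated band exceeds the axial extent")
  }
  for (vs in spec$vessel_shadows) {
    if (is.null(vs$n) || is.null(vs$width_px) || is.null(vs$attenuation) ||
        vs$attenuation < 0 || vs$attenuation > 1) {
      fail("vessel_shadows", "each shadow needs n, width_px, attenuation in [0,1]")
    }
  }
  invisible(spec)
}

# en-face helper grids around the disk centre
enface_geometry <- function(spec) {
  N <- spec$volume_dims[2]; I <- spec$volume_dims[3]
  n <- matrix(seq_len(N), N, I)
  i <- matrix(seq_len(I), N, I, byrow = TRUE)
  dn <- n - spec$disk_center[1]; di <- i - spec$disk_center[2]
  theta <- (atan2(dn, di) * 180 / pi) %% 360
  disk <- if (spec$disk_radius_px > 0) {
    dn^2 + di^2 <= spec$disk_radius_px^2
  } else matrix(FALSE, N, I)   # radius 0: phantom without a disk
  dcn <- n - spec$cup_center[1]; dci <- i - spec$cup_center[2]
  cup <- dcn^2 + dci^2 <= spec$cup_radius_px^2
  list(theta = theta, disk = disk, cup = cup & disk)
}

# true surfaces implied by the spec, as N x I row matrices
phantom_surfaces <- function(spec) {
  g <- enface_geometry(spec)
  ax <- spec$axial_um_per_px
  tf <- thickness_fun(spec)
  t_px <- matrix(round(tf(as.vector(g$theta)) / ax),
                 spec$volume_dims[2], spec$volume_dims[3])
  t_px[g$disk] <- spec$membrane_px
  ilm <- matrix(spec$ilm_base_row, spec$volume_dims[2], spec$volume_dims[3])
  ilm[g$cup] <- ilm[g$cup] + round(spec$cup_depth_um / ax)
  rnfl <- ilm + t_px
  rpe <- matrix(spec$rpe_depth_row, spec$volume_dims[2], spec$volume_dims[3])
  rpe[g$disk] <- rpe[g$disk] + round(spec$disk_excavation_um / ax)
  list(ilm = ilm, rnfl = rnfl, rpe = rpe, geom = g)
}

#' Generate a synthetic ONH volume with ground truth
#'
#' Renders the scene described by a [phantom_spec()] and returns both the
#' 8-bit volume and the exact surfaces, masks and analytic feature values it
#' encodes. Deterministic for a fixed seed; without noise the output is
#' independent of the seed.
#'
#' @param spec A [phantom_spec()].
#' @param reference Reference RNFL profile used for the analytic deviation
#'   score (defaults to a constant 100 um).
#' @param config An [onh_config()] (MD model for the analytic truth).
#' @return A list with `volume` (an [oct_volume()]) and `truth` (surfaces
#'   `ilm`, `rnfl`, `rpe` as [layer_surface()]; `disk_mask`, `cup_mask` as
#'   [enface_mask()]; `true_features` as [bga_result()]).
#' @examples
#' p <- generate_phantom(phantom_spec(volume_dims = c(96, 64, 16),
#'   ilm_base_row = 20, rnfl_thickness_um = 50, rpe_depth_row = 50,
#'   disk_center = c(32, 8), disk_radius_px = 6, cup_center = c(32, 8),
#'   cup_radius_px = 3, cup_depth_um = 100, disk_excavation_um = 150))
#' dim(p$volume)
#' @export
generate_phantom <- function(spec, reference = constant_reference(100),
                             config = onh_config()) {
  validate_phantom_spec(spec)
  d <- spec$volume_dims
  M <- d[1]; N <- d[2]; I <- d[3]
  sur <- phantom_surfaces(spec)
  lb <- spec$layer_brightness
  vol <- array(lb[["background"]], d)
  rowidx <- matrix(seq_len(M), M, N)
  gauss_off <- -ceiling(3 * spec$rpe_sigma_px):ceiling(3 * spec$rpe_sigma_px)
  gauss_val <- lb[["rpe"]] * exp(-gauss_off^2 / (2 * spec$rpe_sigma_px^2))
  for (i in seq_len(I)) {
    ilm <- matrix(sur$ilm[, i], M, N, byrow = TRUE)
    rnfl <- matrix(sur$rnfl[, i], M, N, byrow = TRUE)
    rpe <- matrix(sur$rpe[, i], M, N, byrow = TRUE)
    S <- matrix(lb[["background"]], M, N)
    S[rowidx >= ilm & rowidx < rnfl] <- lb[["rnfl"]]
    inner_val <- matrix(ifelse(sur$geom$disk[, i], lb[["cavity"]],
                               lb[["inner"]]), M, N, byrow = TRUE)
    gap <- rowidx >= rnfl & rowidx < rpe
    S[gap] <- inner_val[gap]
    for (k in seq_along(gauss_off)) {
      r <- sur$rpe[, i] + gauss_off[k]
      ok <- r >= 1 & r <= M
      idx <- cbind(r[ok], which(ok))
      S[idx] <- pmax(S[idx], gauss_val[k])
    }
    for (vs in spec$vessel_shadows) {
      if (!is.null(vs$i_range) && (i < vs$i_range[1] || i > vs$i_range[2])) next
      cols <- which(abs(seq_len(N) - vs$n) <= vs$width_px / 2)
      if (length(cols) == 0L) next
      shade <- rowidx[, cols] >= matrix(sur$ilm[cols, i], M, length(cols),
                                        byrow = TRUE)
      S[, cols][shade] <- S[, cols][shade] * (1 - vs$attenuation)
    }
    vol[, , i] <- S
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + stats::rnorm(length(vol), sd = spec$noise_sd)
    vol[vol < 0] <- 0
    vol[vol > 255] <- 255
  }
  vol <- round(vol)
  cal <- calibration(spec$axial_um_per_px, spec$lateral_um_per_px,
                     spec$bscan_spacing_um, n_ascans = N, n_bscans = I)
  truth <- list(
    ilm = layer_surface(sur$ilm, "ILM", n_rows = M),
    rnfl = layer_surface(sur$rnfl, "RNFL", n_rows = M),
    rpe = layer_surface(sur$rpe, "RPE", n_rows = M),
    disk_mask = enface_mask(sur$geom$disk, "disk"),
    cup_mask = enface_mask(sur$geom$cup, "cup"),
    true_features = if (spec$disk_radius_px > 0) {
      analytic_truth(spec, reference, config)
    }
  )
  list(volume = oct_volume(vol, cal), truth = truth)
}

#' Analytic feature values of a phantom
#'
#' Closed-form scores for the circular disk/cup geometry of a
#' [phantom_spec()]: the eccentricity score is the centre separation over
#' the disk radius; the boundary score uses
#' `r_min = r_disk - (separation + r_cup)` for an interior cup; the
#' deviation score averages `|profile - reference| / reference` over 1-degree
#' bins.
#'
#' @inheritParams generate_phantom
#' @return A [bga_result()].
#' @export
analytic_truth <- function(spec, reference = constant_reference(100),
                           config = onh_config()) {
  validate_phantom_spec(spec)
  if (spec$disk_radius_px <= 0) {
    stop("analytic truth needs a disk of positive radius", call. = FALSE)
  }
  sep <- sqrt(sum((spec$cup_center - spec$disk_center)^2))
  r_d <- spec$disk_radius_px
  w1 <- sep / r_d
  r_min <- r_d - (sep + spec$cup_radius_px)
  w2 <- wg2(max(r_min, 0), r_d)
  theta <- 0:359
  tf <- thickness_fun(spec)
  w3 <- mean(abs(tf(theta) - reference(theta)) / reference(theta))
  bga_result(w1, w2, w3, config)
}

#' @export
print.phantom_spec <- function(x, ...) {
  d <- x$volume_dims
  cat(sprintf("ONH phantom spec: %d x %d x %d, disk r=%g px at (%g, %g)\n",
              d[1], d[2], d[3], x$disk_radius_px, x$disk_center[1],
              x$disk_center[2]))
  cat(sprintf("  cup r=%g px at (%g, %g), depth %g um; noise sd %g; %d shadow(s)\n",
              x$cup_radius_px, x$cup_center[1], x$cup_center[2],
              x$cup_depth_um, x$noise_sd, length(x$vessel_shadows)))
  invisible(x)
}
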