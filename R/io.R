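#' Read an OCT volume from open image formats
#'
#' Accepts either a multi-page TIFF file or a directory of numbered
#' single-page grayscale images (PNG or TIFF); pages / numerically sorted
#' files map to ascending B-scan index. Gray values are returned on the
#' 8-bit scale in `(m, n, i)` order.
#'
#' @param path A multi-page TIFF file or a directory of numbered images.
#' @param cal A [calibration()]; A-scan/B-scan counts are filled in when
#'   absent.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, cal) {
  if (!file.exists(path)) {
    onh_error(sprintf("volume path not found: %s", path), "onh_format_error")
  }
  pages <- if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      jpgs <- list.files(path, pattern = "\\.jpe?g$", ignore.case = TRUE)
      if (length(jpgs) > 0L) {
        onh_error("JPEG stacks are not supported; convert to PNG or TIFF",
                  "onh_format_error")
      }
      onh_error(sprintf("empty image stack: %s", path), "onh_format_error")
    }
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    files <- files[order(num, basename(files))]
    lapply(files, read_gray_page)
  } else {
    img <- tiff::readTIFF(path, all = TRUE)
    if (length(img) == 0L) onh_error("empty TIFF stack", "onh_format_error")
    lapply(img, flatten_gray)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    onh_error("B-scan pages have mixed sizes", "onh_format_error")
  }
  vol <- array(unlist(pages, use.names = FALSE),
               c(dims[1, 1], dims[2, 1], length(pages)))
  if (is.na(cal$n_ascans)) cal$n_ascans <- dims[2, 1]
  if (is.na(cal$n_bscans)) cal$n_bscans <- length(pages)
  oct_volume(vol, cal)
}

read_gray_page <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  flatten_gray(img)
}

# accept grayscale matrices or RGB(A) arrays with identical channels
flatten_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
    if (max(abs(sweep(rgb, 1:2, rgb[, , 1]))) > 1e-9) {
      onh_error("non-grayscale image with no safe conversion",
                "onh_format_error")
    }
    img <- rgb[, , 1]
  }
  round(img * 255)
}

#' Write an OCT volume as a multi-page TIFF
#'
#' @param volume An [oct_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  pages <- lapply(seq_len(dim(volume$data)[3]),
                  function(i) volume$data[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read / write a calibration file
#'
#' INI-style emulation of the metadata a tomograph stores alongside its
#' scans: a `[scan]` section with the axial and lateral sampling, B-scan
#' spacing, and A-scan/B-scan counts. Unknown keys are ignored with a
#' warning.
#'
#' @param path File path.
#' @return `read_calibration` returns a [calibration()];
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    onh_error(sprintf("calibration file not found: %s", path),
              "onh_config_error")
  }
  ini <- read_ini(path)
  sc <- ini$scan
  if (is.null(sc)) {
    onh_error("calibration file has no [scan] section", "onh_format_error")
  }
  known <- c("axial_um_per_px", "lateral_um_per_px", "bscan_spacing_um",
             "n_ascans", "n_bscans")
  extra <- setdiff(names(sc), known)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring unknown calibration keys: %s",
                    paste(extra, collapse = ", ")))
  }
  need <- c("axial_um_per_px", "lateral_um_per_px", "bscan_spacing_um")
  if (!all(need %in% names(sc))) {
    onh_error(sprintf("calibration missing required keys: %s",
                      paste(setdiff(need, names(sc)), collapse = ", ")),
              "onh_format_error")
  }
  gi <- function(k) if (is.null(sc[[k]])) NA_integer_ else
    as.integer(as.numeric(sc[[k]]))
  calibration(as.numeric(sc$axial_um_per_px),
              as.numeric(sc$lateral_um_per_px),
              as.numeric(sc$bscan_spacing_um),
              n_ascans = gi("n_ascans"), n_bscans = gi("n_bscans"))
}

#' @rdname read_calibration
#' @param cal A [calibration()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  lines <- c("# scan calibration (1-based indices elsewhere)",
             "[scan]",
             sprintf("axial_um_per_px = %.10g", cal$axial_um_per_px),
             sprintf("lateral_um_per_px = %.10g", cal$lateral_um_per_px),
             sprintf("bscan_spacing_um = %.10g", cal$bscan_spacing_um))
  if (!is.na(cal$n_ascans)) {
    lines <- c(lines, sprintf("n_ascans = %d", cal$n_ascans))
  }
  if (!is.na(cal$n_bscans)) {
    lines <- c(lines, sprintf("n_bscans = %d", cal$n_bscans))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Periodic reference RNFL thickness profile
#'
#' Builds a periodic piecewise-linear interpolant over angle from control
#' points, the form in which normative peripapillary ("TSNIT") profiles are
#' distributed. Queries are taken modulo 360 degrees.
#'
#' @param theta_deg Angles in `[0, 360)`, no duplicates.
#' @param thickness_um Strictly positive thicknesses.
#' @return A function `f(theta_deg)` returning micrometres.
#' @examples
#' f <- reference_profile(c(0, 90), c(80, 120))
#' f(45)  # 100
#' @export
reference_profile <- function(theta_deg, thickness_um) {
  if (length(theta_deg) != length(thickness_um) || length(theta_deg) < 1L) {
    stop("theta and thickness must be equal-length, nonempty", call. = FALSE)
  }
  th <- theta_deg %% 360
  if (anyDuplicated(th)) {
    stop("duplicate angles in reference profile", call. = FALSE)
  }
  if (any(!is.finite(thickness_um)) || any(thickness_um <= 0)) {
    stop("reference thickness must be strictly positive", call. = FALSE)
  }
  o <- order(th)
  th <- th[o]; tk <- thickness_um[o]
  # wrap one point on each side for periodic interpolation
  th_ext <- c(th[length(th)] - 360, th, th[1] + 360)
  tk_ext <- c(tk[length(tk)], tk, tk[1])
  function(theta) {
    stats::approx(th_ext, tk_ext, xout = theta %% 360, rule = 2)$y
  }
}

#' @rdname reference_profile
#' @param thickness_um Constant thickness in micrometres.
#' @export
constant_reference <- function(thickness_um = 100) {
  force(thickness_um)
  function(theta) rep(thickness_um, length(theta))
}

#' Read a reference RNFL profile from CSV
#'
#' Expects columns `theta_deg` (degrees in `[0, 360)`) and `thickness_um`
#' (strictly positive). Returns the periodic interpolant of
#' [reference_profile()].
#'
#' @param path CSV path.
#' @return A function `f(theta_deg)`.
#' @export
read_reference_profile <- function(path) {
  if (!file.exists(path)) {
    onh_error(sprintf("reference profile not found: %s", path),
              "onh_format_error")
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("theta_deg", "thickness_um") %in% names(df))) {
    onh_error("reference CSV needs columns theta_deg, thickness_um",
              "onh_format_error")
  }
  tryCatch(reference_profile(df$theta_deg, df$thickness_um),
           error = function(e) onh_error(conditionMessage(e),
                                         "onh_format_error"))
}

#' Surface CSV round trip
#'
#' Long-format CSV `(n, i, row)` with 1-based indices; undefined entries are
#' written as empty cells and read back as `NA`.
#'
#' @param surface A [layer_surface()].
#' @param path CSV path.
#' @return `write_surface_csv` returns `path` invisibly; `read_surface_csv`
#'   the [layer_surface()].
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "layer_surface"))
  df <- data.frame(n = as.vector(row(surface)),
                   i = as.vector(col(surface)),
                   row = as.vector(as_mat(surface)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s surface; 1-based indices; empty row = undefined",
                     surface_label(surface)), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_surface_csv
#' @param label Boundary label for the surface being read.
#' @export
read_surface_csv <- function(path, label = c("RPE", "ILM", "RNFL")) {
  label <- match.arg(label)
  df <- utils::read.csv(path, comment.char = "#")
  N <- max(df$n); I <- max(df$i)
  rows <- matrix(NA_real_, N, I)
  rows[cbind(df$n, df$i)] <- df$row
  layer_surface(rows, label)
}

#' En-face mask PNG round trip
#'
#' @param mask An [enface_mask()].
#' @param path PNG path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png` the
#'   [enface_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "enface_mask"))
  png::writePNG(as_mat(mask), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param label `"disk"` or `"cup"`.
#' @export
read_mask_png <- function(path, label = c("disk", "cup")) {
  label <- match.arg(label)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  enface_mask(img > 0.5, label)
}

#' Write the full set of pipeline outputs
#'
#' Persists an analysis: boundary surfaces as CSV, en-face masks as PNG, the
#' polar profile as CSV, and a one-row feature CSV keyed by the customary
#' feature symbols (`w_g(1)`, `w_g(2)`, `w_g(3)`, `w_BGA`, `predicted_MD`,
#' plus any classic features supplied).
#'
#' @param analysis An [onh_analyze()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "onh_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surface_csv(analysis$surfaces$rpe, file.path(dir, "rpe.csv"))
  write_surface_csv(analysis$surfaces$ilm, file.path(dir, "ilm.csv"))
  write_surface_csv(analysis$surfaces$rnfl, file.path(dir, "rnfl.csv"))
  write_mask_png(analysis$masks$disk, file.path(dir, "disk_mask.png"))
  write_mask_png(analysis$masks$cup, file.path(dir, "cup_mask.png"))
  pr <- analysis$polar
  utils::write.csv(as.data.frame(pr), file.path(dir, "polar_profile.csv"),
                   row.names = FALSE)
  feats <- data.frame(`w_g(1)` = analysis$bga$wg1,
                      `w_g(2)` = analysis$bga$wg2,
                      `w_g(3)` = analysis$bga$wg3,
                      w_BGA = analysis$bga$w_bga,
                      predicted_MD = analysis$bga$predicted_md,
                      check.names = FALSE)
  utils::write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  log <- analysis$log
  utils::write.csv(log, file.path(dir, "stages.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a morphometric feature table
#'
#' CSV with one row per eye and columns named by the customary feature
#' symbols (`w(1)` ... `w(30)`); names are preserved verbatim.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    onh_error(sprintf("feature table not found: %s", path),
              "onh_format_error")
  }
  utils::read.csv(path, check.names = FALSE, comment.char = "#")
}

#' Phantom spec INI round trip
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` the [phantom_spec()]. A thickness profile given as
#'   a function is serialized by sampling at 1-degree resolution.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  num <- function(v) paste(format(v, digits = 10, trim = TRUE), collapse = ",")
  tf <- spec$rnfl_thickness_um
  thick <- if (is.function(tf)) num(tf(0:359)) else num(tf)
  sh <- vapply(spec$vessel_shadows, function(v) {
    sprintf("%g:%g:%g", v$n, v$width_px, v$attenuation)
  }, character(1))
  lines <- c(
    "# ONH phantom specification",
    "[phantom]",
    sprintf("volume_dims = %s", num(spec$volume_dims)),
    sprintf("axial_um_per_px = %s", num(spec$axial_um_per_px)),
    sprintf("lateral_um_per_px = %s", num(spec$lateral_um_per_px)),
    sprintf("bscan_spacing_um = %s", num(spec$bscan_spacing_um)),
    sprintf("ilm_base_row = %s", num(spec$ilm_base_row)),
    sprintf("rnfl_thickness_um = %s", thick),
    sprintf("rpe_depth_row = %s", num(spec$rpe_depth_row)),
    sprintf("disk_center = %s", num(spec$disk_center)),
    sprintf("disk_radius_px = %s", num(spec$disk_radius_px)),
    sprintf("cup_center = %s", num(spec$cup_center)),
    sprintf("cup_radius_px = %s", num(spec$cup_radius_px)),
    sprintf("cup_depth_um = %s", num(spec$cup_depth_um)),
    sprintf("disk_excavation_um = %s", num(spec$disk_excavation_um)),
    sprintf("noise_sd = %s", num(spec$noise_sd)),
    sprintf("layer_brightness = %s", num(spec$layer_brightness)),
    sprintf("membrane_px = %s", num(spec$membrane_px)),
    sprintf("rpe_sigma_px = %s", num(spec$rpe_sigma_px)),
    sprintf("seed = %s", num(spec$seed)),
    if (length(sh) > 0L) sprintf("vessel_shadows = %s",
                                 paste(sh, collapse = ";"))
  )
  writeLines(lines[!vapply(lines, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  ini <- read_ini(path)
  ph <- ini$phantom
  if (is.null(ph)) {
    onh_error("phantom spec file has no [phantom] section", "onh_format_error")
  }
  num <- function(k) as.numeric(strsplit(ph[[k]], ",")[[1]])
  thick <- num("rnfl_thickness_um")
  if (length(thick) > 1L) {
    thick <- reference_profile(seq(0, 360, length.out = length(thick) + 1L
                                   )[-(length(thick) + 1L)], thick)
  }
  shadows <- list()
  if (!is.null(ph$vessel_shadows)) {
    shadows <- lapply(strsplit(ph$vessel_shadows, ";")[[1]], function(s) {
      v <- as.numeric(strsplit(s, ":")[[1]])
      list(n = v[1], width_px = v[2], attenuation = v[3])
    })
  }
  lb <- num("layer_brightness")
  names(lb) <- c("background", "rnfl", "inner", "cavity", "rpe")
  phantom_spec(volume_dims = num("volume_dims"),
               axial_um_per_px = num("axial_um_per_px"),
               lateral_um_per_px = num("lateral_um_per_px"),
               bscan_spacing_um = num("bscan_spacing_um"),
               ilm_base_row = num("ilm_base_row"),
               rnfl_thickness_um = thick,
               rpe_depth_row = num("rpe_depth_row"),
               disk_center = num("disk_center"),
               disk_radius_px = num("disk_radius_px"),
               cup_center = num("cup_center"),
               cup_radius_px = num("cup_radius_px"),
               cup_depth_um = num("cup_depth_um"),
               disk_excavation_um = num("disk_excavation_um"),
               vessel_shadows = shadows,
               noise_sd = num("noise_sd"),
               layer_brightness = lb,
               membrane_px = num("membrane_px"),
               rpe_sigma_px = num("rpe_sigma_px"),
               seed = num("seed"))
}

#' Ground truth JSON round trip
#'
#' Serializes phantom ground truth (surfaces as row matrices, masks as 0/1
#' matrices, analytic features) to JSON.
#'
#' @param truth The `truth` element of [generate_phantom()].
#' @param path JSON path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the reconstructed list.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    ilm = as_mat(truth$ilm), rnfl = as_mat(truth$rnfl),
    rpe = as_mat(truth$rpe),
    disk_mask = as_mat(truth$disk_mask) * 1,
    cup_mask = as_mat(truth$cup_mask) * 1,
    true_features = truth$true_features[c("wg1", "wg2", "wg3", "w_bga",
                                          "predicted_md")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(ilm = layer_surface(obj$ilm, "ILM"),
       rnfl = layer_surface(obj$rnfl, "RNFL"),
       rpe = layer_surface(obj$rpe, "RPE"),
       disk_mask = enface_mask(obj$disk_mask == 1, "disk"),
       cup_mask = enface_mask(obj$cup_mask == 1, "cup"),
       true_features = do.call(bga_result, obj$true_features[c("wg1", "wg2",
                                                               "wg3")]))
}
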