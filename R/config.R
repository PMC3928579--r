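#' Pipeline configuration
#'
#' All tunable constants of the analysis pipeline, with the published
#' defaults. Every stage reads its constants from this object rather than
#' from hard-coded literals, so a re-tuned pipeline (or a re-fitted MD model)
#' can be dropped in through a config file.
#'
#' @param median_mask 3-D median mask size `(rows, cols, B-scans)`; odd,
#'   default `c(3, 3, 3)`.
#' @param border Convolution/filter border handling, `"replicate"` or
#'   `"reflect"`.
#' @param p_m Disk threshold fraction (default `2/3`).
#' @param disk_threshold_mode `"reciprocal"` (default; flag columns whose RPE
#'   row exceeds `mean/p_m`, i.e. a depth excursion) or `"literal"`
#'   (verbatim `> p_m * mean` rule).
#' @param otsu_scope `"bscan"` (threshold per B-scan, default) or `"volume"`.
#' @param gradient_floor Minimum gradient magnitude (gray levels) treated as
#'   an edge; `0` reproduces the strict "any positive gradient" rule.
#' @param refine_window Height (px) of each averaging window above/below a
#'   candidate contour position in the active edge correction.
#' @param cup_offset_um Anterior offset (micrometres) of the RPE reference
#'   chord used to cut the cup; default 150.
#' @param polar_bins Number of angular bins of the peripapillary profile
#'   (default 360, i.e. 1 degree).
#' @param rho_step_px Radial sampling step (px) across the 2r-3r annulus.
#' @param min_valid_fraction Minimum fraction of valid radial samples for an
#'   angular bin to be kept.
#' @param md_slope,md_intercept Coefficients of the linear BGA-to-MD
#'   conversion, dB; defaults 24 and -9.34.
#' @param eye `"right"` (temporal quadrant centred at theta = 0) or
#'   `"left"` (temporal/nasal labels mirrored).
#' @param seed Optional integer seed recorded with results.
#' @return A named list of class `"onh_config"`.
#' @examples
#' cfg <- onh_config(gradient_floor = 0)   # strict edge rule
#' cfg$md_slope
#' @export
onh_config <- function(median_mask = c(3L, 3L, 3L),
                       border = c("replicate", "reflect"),
                       p_m = 2 / 3,
                       disk_threshold_mode = c("reciprocal", "literal"),
                       otsu_scope = c("bscan", "volume"),
                       gradient_floor = 2,
                       refine_window = 5L,
                       cup_offset_um = 150,
                       polar_bins = 360L,
                       rho_step_px = 1,
                       min_valid_fraction = 0.5,
                       md_slope = 24,
                       md_intercept = -9.34,
                       eye = c("right", "left"),
                       seed = NULL) {
  border <- match.arg(border)
  disk_threshold_mode <- match.arg(disk_threshold_mode)
  otsu_scope <- match.arg(otsu_scope)
  eye <- match.arg(eye)
  if (any(median_mask %% 2 == 0) || any(median_mask < 1)) {
    stop("median_mask dimensions must be odd and positive", call. = FALSE)
  }
  if (p_m <= 0) stop("p_m must be positive", call. = FALSE)
  if (cup_offset_um < 0) stop("cup_offset_um must be >= 0", call. = FALSE)
  structure(
    list(median_mask = as.integer(median_mask), border = border, p_m = p_m,
         disk_threshold_mode = disk_threshold_mode, otsu_scope = otsu_scope,
         gradient_floor = gradient_floor,
         refine_window = as.integer(refine_window),
         cup_offset_um = cup_offset_um, polar_bins = as.integer(polar_bins),
         rho_step_px = rho_step_px, min_valid_fraction = min_valid_fraction,
         md_slope = md_slope, md_intercept = md_intercept, eye = eye,
         seed = seed),
    class = "onh_config"
  )
}

#' @export
print.onh_config <- function(x, ...) {
  cat("ONH pipeline configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "NULL"
    cat(sprintf("  %-20s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration file
#'
#' INI-style round trip of [onh_config()]. Sections group the stages
#' (`[preprocess]`, `[segmentation]`, `[geometry]`, `[md_model]`, `[general]`).
#'
#' @param config An [onh_config()] object.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   [onh_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "onh_config"))
  num <- function(v) paste(format(v, digits = 17, trim = TRUE), collapse = ",")
  lines <- c(
    "# onhbga pipeline configuration (indices are 1-based)",
    "[preprocess]",
    sprintf("median_mask = %s", num(config$median_mask)),
    sprintf("border = %s", config$border),
    "[segmentation]",
    sprintf("p_m = %s", num(config$p_m)),
    sprintf("disk_threshold_mode = %s", config$disk_threshold_mode),
    sprintf("otsu_scope = %s", config$otsu_scope),
    sprintf("gradient_floor = %s", num(config$gradient_floor)),
    sprintf("refine_window = %s", num(config$refine_window)),
    "[geometry]",
    sprintf("cup_offset_um = %s", num(config$cup_offset_um)),
    sprintf("polar_bins = %s", num(config$polar_bins)),
    sprintf("rho_step_px = %s", num(config$rho_step_px)),
    sprintf("min_valid_fraction = %s", num(config$min_valid_fraction)),
    sprintf("eye = %s", config$eye),
    "[md_model]",
    sprintf("slope = %s", num(config$md_slope)),
    sprintf("intercept = %s", num(config$md_intercept)),
    "[general]",
    if (!is.null(config$seed)) sprintf("seed = %d", config$seed)
  )
  writeLines(lines[!vapply(lines, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ini <- read_ini(path)
  g <- function(section, key, default) {
    v <- ini[[section]][[key]]
    if (is.null(v)) default else v
  }
  num <- function(v) as.numeric(strsplit(v, ",")[[1]])
  d <- onh_config()
  onh_config(
    median_mask = if (is.null(ini$preprocess$median_mask)) d$median_mask else
      as.integer(num(ini$preprocess$median_mask)),
    border = g("preprocess", "border", d$border),
    p_m = as.numeric(g("segmentation", "p_m", d$p_m)),
    disk_threshold_mode = g("segmentation", "disk_threshold_mode",
                            d$disk_threshold_mode),
    otsu_scope = g("segmentation", "otsu_scope", d$otsu_scope),
    gradient_floor = as.numeric(g("segmentation", "gradient_floor",
                                  d$gradient_floor)),
    refine_window = as.integer(as.numeric(g("segmentation", "refine_window",
                                            d$refine_window))),
    cup_offset_um = as.numeric(g("geometry", "cup_offset_um",
                                 d$cup_offset_um)),
    polar_bins = as.integer(as.numeric(g("geometry", "polar_bins",
                                         d$polar_bins))),
    rho_step_px = as.numeric(g("geometry", "rho_step_px", d$rho_step_px)),
    min_valid_fraction = as.numeric(g("geometry", "min_valid_fraction",
                                      d$min_valid_fraction)),
    eye = g("geometry", "eye", d$eye),
    md_slope = as.numeric(g("md_model", "slope", d$md_slope)),
    md_intercept = as.numeric(g("md_model", "intercept", d$md_intercept)),
    seed = if (is.null(ini$general$seed)) NULL else
      as.integer(ini$general$seed)
  )
}

# Minimal INI parser: sections in [brackets], key = value pairs, '#' or ';'
# comments. Values kept as strings; callers coerce.
read_ini <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}
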