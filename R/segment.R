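#' Otsu threshold of a gray-level sample
#'
#' Threshold maximizing the between-class variance over the 256-bin gray
#' histogram. Used to binarize the region above the RPE when locating the
#' inner limiting membrane.
#'
#' @param values Numeric vector of gray levels in `[0, 255]`; must contain at
#'   least two distinct values.
#' @return The threshold level `p_r`; foreground is `value > p_r`. When a
#'   plateau of cut levels attains the maximal between-class variance (as in
#'   perfectly bimodal samples) the mean of the tied levels is returned, so
#'   the threshold sits centrally between the modes.
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L) {
    stop("degenerate input: Otsu threshold needs >= 2 distinct gray levels",
         call. = FALSE)
  }
  if (min(values) < 0 || max(values) > 255) {
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  }
  h <- tabulate(floor(values) + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  # between-class variance for cut after level t (t = 0..254)
  w0c <- w0[1:255]
  muc <- mu[1:255]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0c[valid] - muc[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  top <- max(sigma_b)
  mean(lev[sigma_b >= top - 1e-8 * top])
}

# replicate-padded 3x3 Prewitt gradient magnitude of one B-scan
prewitt_magnitude <- function(S) {
  M <- nrow(S); N <- ncol(S)
  P <- S[c(1L, 1:M, M), c(1L, 1:N, N)]
  sub <- function(a, b) P[(1:M) + 1L + a, (1:N) + 1L + b]
  gv <- (sub(1L, -1L) + sub(1L, 0L) + sub(1L, 1L)) -
    (sub(-1L, -1L) + sub(-1L, 0L) + sub(-1L, 1L))
  gh <- (sub(-1L, 1L) + sub(0L, 1L) + sub(1L, 1L)) -
    (sub(-1L, -1L) + sub(0L, -1L) + sub(1L, -1L))
  sqrt(gv^2 + gh^2)
}

# first row index per column where `mask` is TRUE; NA if none
first_true_row <- function(mask) {
  M <- nrow(mask)
  # smallest m with TRUE: last TRUE of the row-reversed mask
  idx <- (M + 1L) -
    max.col(t(mask[M:1, , drop = FALSE]) * 1L, ties.method = "last")
  any_true <- colSums(mask) > 0L
  idx[!any_true] <- NA_integer_
  idx
}

#' Detect the RPE boundary
#'
#' The retinal pigment epithelium is the brightest layer of an OCT B-scan;
#' its position is taken per A-scan as the row of maximum brightness of the
#' (median-filtered) volume. Columns with several tied global maxima are
#' resolved towards the median RPE position of the 5 x 5 en-face
#' neighbourhood of unambiguous columns; all-zero columns are undefined.
#'
#' @param volume A (filtered) [oct_volume()].
#' @return A [layer_surface()] labelled `"RPE"`.
#' @export
detect_rpe <- function(volume) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  M <- d[1]; N <- d[2]; I <- d[3]
  rows <- matrix(NA_real_, N, I)
  tied <- matrix(FALSE, N, I)
  tie_rows <- vector("list", 0L)
  for (i in seq_len(I)) {
    S <- volume$data[, , i]
    first_max <- max.col(t(S), ties.method = "first")
    colmax <- S[cbind(first_max, seq_len(N))]
    n_at_max <- colSums(S == matrix(colmax, M, N, byrow = TRUE))
    rows[, i] <- first_max
    rows[colmax == 0, i] <- NA_real_
    tied[, i] <- n_at_max > 1L & colmax > 0
  }
  if (any(tied)) {
    base <- rows
    base[tied] <- NA_real_  # tie columns are not "already solved"
    for (k in which(tied)) {
      n <- (k - 1L) %% N + 1L
      i <- (k - 1L) %/% N + 1L
      S_col <- volume$data[, n, i]
      cand <- which(S_col == max(S_col))
      nb <- base[max(1L, n - 2L):min(N, n + 2L),
                 max(1L, i - 2L):min(I, i + 2L)]
      ref <- stats::median(nb, na.rm = TRUE)
      if (is.na(ref)) {
        rows[n, i] <- cand[1L]       # no solved neighbour: smallest row
      } else {
        rows[n, i] <- cand[which.min(abs(cand - ref))]
      }
    }
  }
  layer_surface(rows, "RPE", n_rows = M)
}

#' Detect the ILM boundary
#'
#' The region strictly above the detected RPE is binarized at an Otsu
#' threshold; per A-scan, the ILM is the smallest (most anterior) row index
#' of a foreground pixel. Columns whose above-RPE region is entirely
#' background, and columns with undefined RPE, are undefined.
#'
#' @param volume A (filtered) [oct_volume()].
#' @param rpe The RPE [layer_surface()].
#' @param config An [onh_config()]; `otsu_scope` selects per-B-scan (default)
#'   or per-volume thresholding.
#' @return A [layer_surface()] labelled `"ILM"`; ILM is strictly above the
#'   RPE wherever both are defined.
#' @export
detect_ilm <- function(volume, rpe, config = onh_config()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(rpe, "layer_surface"))
  d <- dim(volume$data)
  M <- d[1]; N <- d[2]; I <- d[3]
  if (all(is.na(rpe))) stop("RPE surface is fully undefined", call. = FALSE)
  if (mean(is.na(rpe)) > 0.5) {
    warning("RPE undefined on a majority of columns; ILM will be sparse")
  }
  rowidx <- matrix(seq_len(M), M, N)
  p_vol <- NULL
  if (config$otsu_scope == "volume") {
    vals <- unlist(lapply(seq_len(I), function(i) {
      rmat <- matrix(rpe[, i], M, N, byrow = TRUE)
      volume$data[, , i][rowidx < rmat & !is.na(rmat)]
    }), use.names = FALSE)
    p_vol <- otsu_threshold(vals)
  }
  rows <- matrix(NA_real_, N, I)
  for (i in seq_len(I)) {
    S <- volume$data[, , i]
    rmat <- matrix(rpe[, i], M, N, byrow = TRUE)
    region <- rowidx < rmat & !is.na(rmat)
    if (!any(region)) next
    p_r <- if (is.null(p_vol)) {
      vals <- S[region]
      if (length(unique(vals)) < 2L) next   # flat B-scan: leave undefined
      otsu_threshold(vals)
    } else p_vol
    rows[, i] <- first_true_row(S > p_r & region)
  }
  layer_surface(rows, "ILM", n_rows = M)
}

#' Gradient magnitude restricted to the ILM-RPE band
#'
#' Magnitude of two orthogonal 3 x 3 Prewitt responses, set to zero at every
#' voxel on or outside the open band between the ILM and the RPE. This
#' masking prevents the subsequent edge search from locking onto the
#' boundaries of the band itself.
#'
#' @inheritParams detect_ilm
#' @param ilm,rpe ILM and RPE [layer_surface()]s.
#' @return A 3-D array of non-negative gradient magnitudes.
#' @export
gradient_volume <- function(volume, ilm, rpe) {
  d <- dim(volume$data)
  M <- d[1]; N <- d[2]; I <- d[3]
  G <- array(0, d)
  rowidx <- matrix(seq_len(M), M, N)
  for (i in seq_len(I)) {
    g <- prewitt_magnitude(volume$data[, , i])
    imat <- matrix(ilm[, i], M, N, byrow = TRUE)
    rmat <- matrix(rpe[, i], M, N, byrow = TRUE)
    keep <- !is.na(imat) & !is.na(rmat) & rowidx > imat & rowidx < rmat
    g[!keep] <- 0
    G[, , i] <- g
  }
  G
}

#' Detect the lower RNFL boundary
#'
#' The retinal nerve fibre layer appears as a bright band under the ILM; its
#' lower boundary is the first light-to-dark transition below the ILM. Per
#' A-scan the boundary is the smallest row, strictly between ILM and RPE,
#' whose band-masked gradient magnitude exceeds the configured floor.
#'
#' @inheritParams gradient_volume
#' @param config An [onh_config()]; `gradient_floor` is the minimum gradient
#'   magnitude accepted as an edge (0 = any positive gradient).
#' @return A [layer_surface()] labelled `"RNFL"`; columns with no edge in the
#'   band (or an empty band) are undefined.
#' @export
detect_rnfl <- function(volume, ilm, rpe, config = onh_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  M <- d[1]; N <- d[2]; I <- d[3]
  eps <- config$gradient_floor
  rows <- matrix(NA_real_, N, I)
  rowidx <- matrix(seq_len(M), M, N)
  for (i in seq_len(I)) {
    g <- prewitt_magnitude(volume$data[, , i])
    imat <- matrix(ilm[, i], M, N, byrow = TRUE)
    rmat <- matrix(rpe[, i], M, N, byrow = TRUE)
    keep <- !is.na(imat) & !is.na(rmat) & rowidx > imat & rowidx < rmat
    rows[, i] <- first_true_row(g > eps & keep)
  }
  layer_surface(rows, "RNFL", n_rows = M)
}

# linear bridge over NA entries of a vector (ends extended flat);
# returns NULL when nothing is defined
bridge_na <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0L) return(NULL)
  if (length(ok) == 1L) return(rep(v[ok], length(v)))
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' Active edge correction of a boundary contour
#'
#' Re-positions each contour point to the row maximizing the difference
#' between the mean brightness in a window just above and a window just
#' below the candidate position -- the signature of a light-to-dark layer
#' boundary. Candidate rows span an offset range of +/- the per-B-scan
#' median ILM-RPE separation around the input contour (gaps in the input are
#' first bridged by linear interpolation) and are kept strictly inside the
#' open (ILM, RPE) band, mirroring the edge protections of the initial
#' detection. This repairs contour gaps and displacements caused by vessel
#' shadows or low contrast.
#'
#' @inheritParams gradient_volume
#' @param contour The [layer_surface()] to correct (typically the RNFL lower
#'   boundary).
#' @param window Height in px of each averaging window (above and below);
#'   defaults to the configured `refine_window`.
#' @param search Optional fixed offset range in px overriding the median
#'   ILM-RPE separation.
#' @param config An [onh_config()].
#' @return The corrected [layer_surface()] (same label), defined wherever
#'   the band and the bridged contour are defined.
#' @export
refine_contour <- function(volume, contour, ilm, rpe, window = NULL,
                           search = NULL, config = onh_config()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(contour, "layer_surface"))
  d <- dim(volume$data)
  M <- d[1]; N <- d[2]; I <- d[3]
  h <- if (is.null(window)) config$refine_window else as.integer(window)
  if (h < 1L) stop("window must be >= 1 px", call. = FALSE)
  out <- matrix(NA_real_, N, I)
  for (i in seq_len(I)) {
    c0 <- bridge_na(contour[, i])
    if (is.null(c0)) next
    ilm_i <- bridge_na(ilm[, i])
    rpe_i <- bridge_na(rpe[, i])
    lo <- if (is.null(ilm_i)) rep(1, N) else floor(ilm_i) + 1L
    hi <- if (is.null(rpe_i)) rep(M, N) else ceiling(rpe_i) - 1L
    lo <- pmax(lo, 2L)
    hi <- pmin(hi, M - 1L)
    band <- if (!is.null(ilm_i) && !is.null(rpe_i)) {
      stats::median(abs(ilm_i - rpe_i))
    } else M / 4
    W <- if (is.null(search)) max(1L, round(band)) else as.integer(search)
    # offsets ordered by |offset| so ties keep the input position
    offs <- order(abs(seq(-W, W)))
    offs <- seq(-W, W)[offs]
    CS <- rbind(0, apply(volume$data[, , i], 2, cumsum))
    p0 <- round(c0)
    cols <- rep(seq_len(N), each = length(offs))
    p <- pmin(pmax(rep(p0, each = length(offs)) + offs, lo[cols]), hi[cols])
    u_lo <- pmax(p - h, 1L)
    d_hi <- pmin(p + h - 1L, M)
    mu_u <- (CS[cbind(p, cols)] - CS[cbind(u_lo, cols)]) / (p - u_lo)
    mu_d <- (CS[cbind(d_hi + 1L, cols)] - CS[cbind(p, cols)]) / (d_hi - p + 1L)
    obj <- matrix(mu_u - mu_d, nrow = length(offs))
    obj[!is.finite(obj)] <- -Inf
    best <- max.col(t(obj), ties.method = "first")
    pmat <- matrix(p, nrow = length(offs))
    res <- pmat[cbind(best, seq_len(N))]
    res[lo > hi] <- NA_real_   # empty band at this column
    out[, i] <- res
  }
  layer_surface(out, surface_label(contour), n_rows = M)
}
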