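#' Exploratory factor model of a morphometric feature table
#'
#' Reproduces the classic feature-selection workflow on a table of
#' optic-nerve-head and perimetric features: Pearson correlation matrix,
#' eigen-decomposition, principal-component-based loadings for the retained
#' classes, and varimax rotation. The number of classes defaults to the
#' Kaiser rule (eigenvalues above 1); the Cattell elbow is available via
#' [select_n_classes_scree()]. Factor scores use the regression method.
#'
#' @param table Numeric `data.frame` or matrix, rows = eyes/patients,
#'   columns = features. Constant columns are dropped with a warning;
#'   missing values are handled by pairwise-complete correlations.
#' @param n_classes Number of classes `k`, or `NULL` for the Kaiser rule.
#' @return An object of class `"onh_factor_model"`: `correlation_matrix`,
#'   `eigenvalues` (descending), `n_classes`, `loadings` (p x k, rotated),
#'   `communalities`, `rotation`, scaling (`center`, `scale`) and `scores`
#'   for the fitted rows.
#' @export
fit_factor_model <- function(table, n_classes = NULL) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("feature table must be numeric", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 rows to fit a factor model",
                         call. = FALSE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  p <- ncol(x)
  if (p < 3L) stop("need at least 3 non-constant features", call. = FALSE)
  if (nrow(x) <= p) {
    warning("fewer rows than features; loadings will be unstable")
  }
  n_miss <- sum(is.na(x))
  if (n_miss > 0L) {
    message(sprintf("[factor] %d missing values; pairwise-complete correlations",
                    n_miss))
  }
  R <- stats::cor(x, use = "pairwise.complete.obs")
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (is.null(n_classes)) {
    k <- sum(ev > 1)
    gap_lo <- if (k < p) ev[k + 1L] else -Inf
    gap_hi <- if (k >= 1L) ev[k] else Inf
    if (k == 0L || abs(gap_hi - 1) < 0.1 || abs(gap_lo - 1) < 0.1) {
      warning("Kaiser criterion is ambiguous (eigenvalues near 1); ",
              "consider the scree elbow")
      k <- max(k, 1L)
    }
  } else {
    k <- as.integer(n_classes)
    if (k < 1L || k > p) stop("n_classes out of range", call. = FALSE)
  }
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rot <- diag(1, k)
  if (k > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- unclass(vm$loadings)
    rot <- vm$rotmat
  }
  # orient each class so its dominant feature loads positively
  signs <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  signs[signs == 0] <- 1
  L <- sweep(L, 2, signs, `*`)
  rownames(L) <- colnames(x)
  colnames(L) <- paste0("class", seq_len(k))
  ctr <- colMeans(x, na.rm = TRUE)
  xs <- sweep(sweep(x, 2, ctr), 2, sds[!const], `/`)
  xs[is.na(xs)] <- 0   # regression scores: missing standardized values at 0
  scores <- xs %*% solve(R, L)
  structure(list(correlation_matrix = R, eigenvalues = ev, n_classes = k,
                 loadings = L, communalities = rowSums(L^2),
                 rotation = rot, center = ctr, scale = sds[!const],
                 features = colnames(x), scores = scores),
            class = "onh_factor_model")
}

#' @export
print.onh_factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d features, %d classes\n",
              length(x$features), x$n_classes))
  cat("eigenvalues:", paste(sprintf("%.2f", utils::head(x$eigenvalues, 8)),
                            collapse = " "),
      if (length(x$eigenvalues) > 8) "...\n" else "\n")
  cat("rotated loadings (|loading| > 0.5 marked *):\n")
  L <- round(x$loadings, 2)
  mark <- ifelse(abs(x$loadings) > 0.5, "*", " ")
  out <- matrix(paste0(format(L), mark), nrow(L), ncol(L),
                dimnames = dimnames(L))
  print(out, quote = FALSE)
  invisible(x)
}

#' Class counts from the scree of eigenvalues
#'
#' Returns both the Kaiser count (eigenvalues above 1) and the Cattell
#' elbow, located as the index maximizing the second difference of the
#' descending eigenvalue sequence.
#'
#' @param eigenvalues Numeric vector, descending, length >= 3.
#' @return A list with `kaiser` and `cattell`.
#' @examples
#' select_n_classes_scree(c(10, 1.5, 0.3, 0.2))$cattell  # 2
#' @export
select_n_classes_scree <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p < 3L) stop("need at least 3 eigenvalues", call. = FALSE)
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be in descending order", call. = FALSE)
  }
  if (diff(range(eigenvalues)) < 1e-12) {
    stop("degenerate scree: all eigenvalues equal, no elbow", call. = FALSE)
  }
  d2 <- eigenvalues[1:(p - 2L)] - 2 * eigenvalues[2:(p - 1L)] +
    eigenvalues[3:p]
  list(kaiser = sum(eigenvalues > 1), cattell = which.max(d2) + 1L)
}

# scores for new data under a fitted model
factor_scores <- function(model, table) {
  x <- as.matrix(as.data.frame(table)[, model$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  xs[is.na(xs)] <- 0
  xs %*% solve(model$correlation_matrix, model$loadings)
}

#' Correlation of factor classes with perimetry
#'
#' Correlates the rotated-factor scores of each class with the perimetric
#' mean defect (MD), and reports the joint multiple correlation of all
#' classes with MD.
#'
#' @param model An [fit_factor_model()] result.
#' @param table The feature table (must contain the model's features and the
#'   MD column).
#' @param md_column Name of the MD column.
#' @return A list with `per_class` (named Pearson correlations) and
#'   `multiple` (multiple correlation of MD on all class scores).
#' @export
class_perimetry_correlation <- function(model, table, md_column = "w(29)") {
  stopifnot(inherits(model, "onh_factor_model"))
  df <- as.data.frame(table)
  if (!md_column %in% names(df)) {
    stop(sprintf("MD column '%s' not present", md_column), call. = FALSE)
  }
  md <- df[[md_column]]
  if (stats::sd(md, na.rm = TRUE) == 0 || all(is.na(md))) {
    stop("MD is constant; correlation undefined", call. = FALSE)
  }
  sc <- factor_scores(model, df)
  per_class <- apply(sc, 2, function(s) {
    stats::cor(s, md, use = "complete.obs")
  })
  ok <- stats::complete.cases(md, sc)
  fit <- stats::lm(md[ok] ~ sc[ok, , drop = FALSE])
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((md[ok] - mean(md[ok]))^2)
  list(per_class = per_class, multiple = sqrt(max(r2, 0)))
}

#' Linear structure-function regression of MD on the BGA ratio
#'
#' Ordinary least squares of the perimetric mean defect on the BGA ratio,
#' the relation used to read an expected visual-field result off an OCT
#' scan. Returns the Pearson correlation alongside the line.
#'
#' @param bga_values,md_values Paired numeric vectors (>= 3 pairs; BGA not
#'   constant).
#' @return An object of class `"bga_md_fit"`: `slope` (dB per unit BGA),
#'   `intercept` (dB), `r`, `n`, and the underlying `lm` fit.
#' @examples
#' f <- fit_bga_md_regression(c(0, 0.5, 1), 24 * c(0, 0.5, 1) - 9.34)
#' coef(f)
#' @export
fit_bga_md_regression <- function(bga_values, md_values) {
  ok <- stats::complete.cases(bga_values, md_values)
  x <- bga_values[ok]; y <- md_values[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("BGA values are constant; no regression",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y), n = length(x), lm = fit),
            class = "bga_md_fit")
}

#' @export
print.bga_md_fit <- function(x, ...) {
  cat(sprintf("MD = %.3f * BGA + %.3f  (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' @export
coef.bga_md_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.bga_md_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  object$slope * newdata + object$intercept
}

#' Simulate a morphometric cohort with planted latent classes
#'
#' Generates a feature table driven by `n_classes` independent standard
#' normal latent factors; each feature is its class factor (with a block
#' sign) plus Gaussian noise. Useful for validating that the factor model
#' recovers a known block structure.
#'
#' @param n Rows (eyes).
#' @param n_classes Latent classes.
#' @param features_per_class Features per class.
#' @param noise_sd Feature noise standard deviation.
#' @param block_signs Optional sign (+1/-1) per feature (recycled within a
#'   class).
#' @param seed Integer seed.
#' @return A list with `table` (data.frame) and `class_of` (integer vector
#'   mapping feature to its generating class).
#' @export
simulate_feature_cohort <- function(n = 200, n_classes = 3,
                                    features_per_class = 3, noise_sd = 0.1,
                                    block_signs = NULL, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n_classes), n, n_classes)
  p <- n_classes * features_per_class
  class_of <- rep(seq_len(n_classes), each = features_per_class)
  if (is.null(block_signs)) block_signs <- rep(1, p)
  block_signs <- rep_len(block_signs, p)
  x <- sapply(seq_len(p), function(j) {
    block_signs[j] * z[, class_of[j]] + stats::rnorm(n, sd = noise_sd)
  })
  colnames(x) <- sprintf("w(%d)", seq_len(p))
  list(table = as.data.frame(x), class_of = class_of)
}

#' Simulate a BGA / perimetry cohort
#'
#' BGA ratios uniform on `[0, 1]` and MD values generated from the linear
#' conversion plus Gaussian scatter. The default scatter (4.1 dB) yields a
#' structure-function correlation of about 0.86 at the default cohort size,
#' the strength typical of this relation.
#'
#' @param n Eyes (default 110).
#' @param slope,intercept Line coefficients (defaults 24, -9.34).
#' @param noise_sd MD scatter around the line, dB.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `w_BGA` and `w(29)`.
#' @export
simulate_md_cohort <- function(n = 110, slope = 24, intercept = -9.34,
                               noise_sd = 4.1, seed = 1) {
  set.seed(seed)
  bga <- stats::runif(n)
  md <- slope * bga + intercept + stats::rnorm(n, sd = noise_sd)
  data.frame(w_BGA = bga, `w(29)` = md, check.names = FALSE)
}
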