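test_that("a planted 3-block structure is recovered with high loadings", {
  sim <- simulate_feature_cohort(n = 200, n_classes = 3,
                                 features_per_class = 3, noise_sd = 0.1,
                                 seed = 1)
  model <- fit_factor_model(sim$table)
  expect_equal(model$n_classes, 3)
  # each feature's dominant class matches its generating block
  dominant <- apply(abs(model$loadings), 1, which.max)
  blocks <- split(dominant, sim$class_of)
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1, TRUE)))
  own <- vapply(seq_along(dominant), function(j) {
    abs(model$loadings[j, dominant[j]])
  }, numeric(1))
  expect_true(all(own > 0.7))
})

test_that("independent features trigger the Kaiser ambiguity warning", {
  set.seed(2)
  x <- as.data.frame(matrix(rnorm(2000 * 6), 2000, 6))
  expect_warning(model <- fit_factor_model(x), "ambiguous")
  expect_true(all(abs(model$eigenvalues - 1) < 0.25))
})

test_that("eigenvalues of the correlation matrix sum to the feature count", {
  set.seed(3)
  for (p in c(4, 7, 12)) {
    x <- matrix(rnorm(60 * p), 60, p) %*% matrix(runif(p * p), p)
    m <- fit_factor_model(as.data.frame(x), n_classes = 2)
    expect_equal(sum(m$eigenvalues), p)
  }
})

test_that("constant columns are dropped and tiny tables rejected", {
  x <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50), d = 1)
  expect_warning(m <- fit_factor_model(x, n_classes = 1), "constant")
  expect_false("d" %in% m$features)
  expect_error(fit_factor_model(data.frame(a = 1:2, b = 2:1, c = 1:2)),
               "at least 3 rows")
})

test_that("scree selection reports Kaiser and the Cattell elbow", {
  s <- select_n_classes_scree(c(5, 4, 3, 0.2, 0.1))
  expect_equal(s$kaiser, 3)
  s2 <- select_n_classes_scree(c(10, 1.5, 0.3, 0.2))
  expect_equal(s2$cattell, 2)
  # brute-force second-difference scan agrees on random screes
  set.seed(4)
  for (k in 1:20) {
    ev <- sort(rexp(8, 0.5), decreasing = TRUE)
    d2 <- vapply(2:7, function(j) ev[j - 1] - 2 * ev[j] + ev[j + 1],
                 numeric(1))
    expect_equal(select_n_classes_scree(ev)$cattell,
                 which.max(d2) + 1L)
  }
  expect_error(select_n_classes_scree(c(2, 1)), "at least 3")
  expect_error(select_n_classes_scree(rep(1, 5)), "no elbow")
})

test_that("varimax rotation preserves communalities", {
  set.seed(5)
  for (k in 1:5) {
    sim <- simulate_feature_cohort(n = 120, n_classes = 3,
                                   features_per_class = 4,
                                   noise_sd = 0.5, seed = k)
    x <- as.matrix(sim$table)
    R <- cor(x)
    e <- eigen(R, symmetric = TRUE)
    L_raw <- e$vectors[, 1:3] %*% diag(sqrt(e$values[1:3]))
    model <- fit_factor_model(sim$table, n_classes = 3)
    expect_equal(model$communalities, rowSums(L_raw^2),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("loadings reproduce the correlation structure better as k grows", {
  sim <- simulate_feature_cohort(n = 300, n_classes = 3,
                                 features_per_class = 3, noise_sd = 0.3,
                                 seed = 6)
  R <- cor(as.matrix(sim$table))
  resid <- vapply(1:3, function(k) {
    L <- fit_factor_model(sim$table, n_classes = k)$loadings
    norm(R - L %*% t(L), "F")
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("block signs are reflected in the recovered loading pattern", {
  signs <- c(1, 1, -1, 1, 1, -1, 1, 1, -1)
  sim <- simulate_feature_cohort(n = 300, n_classes = 3,
                                 features_per_class = 3, noise_sd = 0.1,
                                 block_signs = signs, seed = 7)
  model <- fit_factor_model(sim$table, n_classes = 3)
  dominant <- apply(abs(model$loadings), 1, which.max)
  for (cls in 1:3) {
    l <- model$loadings[cbind(which(sim$class_of == cls),
                              dominant[sim$class_of == cls])]
    expect_equal(sign(l), sign(l[1]) * signs[sim$class_of == cls] /
                   signs[sim$class_of == cls][1], ignore_attr = TRUE)
  }
})

test_that("class scores correlate exactly with an MD built from them", {
  sim <- simulate_feature_cohort(n = 150, n_classes = 3,
                                 features_per_class = 3, noise_sd = 0.1,
                                 seed = 8)
  model <- fit_factor_model(sim$table, n_classes = 3)
  tab <- sim$table
  tab$`w(29)` <- 2 * model$scores[, 1] - 5
  cors <- class_perimetry_correlation(model, tab)
  expect_equal(unname(cors$per_class[1]), 1, tolerance = 1e-6)
  expect_equal(cors$multiple, 1, tolerance = 1e-6)
  # affine rescaling of MD leaves correlations unchanged
  tab2 <- tab; tab2$`w(29)` <- -3 * tab$`w(29)` + 7
  cors2 <- class_perimetry_correlation(model, tab2)
  expect_equal(abs(unname(cors2$per_class)), abs(unname(cors$per_class)),
               tolerance = 1e-8)
  tab3 <- tab; tab3$`w(29)` <- 1
  expect_error(class_perimetry_correlation(model, tab3), "constant")
  expect_error(class_perimetry_correlation(model, sim$table), "not present")
})

test_that("an MD independent of the features shows no class correlation", {
  sim <- simulate_feature_cohort(n = 500, n_classes = 3,
                                 features_per_class = 3, noise_sd = 0.2,
                                 seed = 9)
  set.seed(10)
  tab <- sim$table
  tab$`w(29)` <- rnorm(500)
  model <- fit_factor_model(sim$table, n_classes = 3)
  cors <- class_perimetry_correlation(model, tab)
  expect_true(all(abs(cors$per_class) < 0.15))
})

test_that("the BGA-MD regression recovers lines and is axis-aware", {
  b <- c(0, 0.25, 0.5, 0.75, 1)
  md <- 24 * b - 9.34
  fit <- fit_bga_md_regression(b, md)
  expect_equal(fit$slope, 24)
  expect_equal(fit$intercept, -9.34)
  expect_equal(fit$r, 1)
  expect_equal(unname(predict(fit, 0.5)), 24 * 0.5 - 9.34)

  cohort <- simulate_md_cohort(n = 110, seed = 3)
  f1 <- fit_bga_md_regression(cohort$w_BGA, cohort$`w(29)`)
  f2 <- fit_bga_md_regression(cohort$`w(29)`, cohort$w_BGA)
  expect_false(isTRUE(all.equal(f1$slope, f2$slope)))
  expect_equal(f1$r, f2$r)
  expect_error(fit_bga_md_regression(rep(0.5, 10), rnorm(10)), "constant")
  expect_error(fit_bga_md_regression(c(0, 1), c(0, 1)), "3 complete")
})
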