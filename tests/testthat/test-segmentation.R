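cal <- calibration(5, 12, 12)

test_that("Otsu threshold separates bimodal samples and rejects constants", {
  t <- otsu_threshold(c(rep(0, 50), rep(200, 50)))
  expect_gt(t, 0)
  expect_lt(t, 200)   # central cut of the tied plateau
  expect_error(otsu_threshold(c(5, 5, 5)), "degenerate")
})

test_that("Otsu threshold equals the exhaustive sweep oracle", {
  set.seed(21)
  for (k in 1:20) {
    vals <- sample(0:255, sample(20:200, 1), replace = TRUE)
    if (length(unique(vals)) < 2) next
    expect_identical(otsu_threshold(vals), oracle_otsu(vals))
  }
})

test_that("RPE detection finds a single bright band and flags empty columns", {
  vol <- array(0, c(50, 8, 4))
  vol[33, , ] <- 200
  vol[, 3, 2] <- 0                      # an all-zero column
  s <- detect_rpe(oct_volume(vol, cal))
  expect_true(is.na(s[3, 2]))
  expect_true(all(s[!is.na(s)] == 33))
})

test_that("tied maxima resolve towards the solved neighbourhood", {
  vol <- array(0, c(100, 5, 5))
  vol[41, , ] <- 180                    # unambiguous neighbours near row 41
  vol[c(40, 90), 3, 3] <- 200           # tie at rows 40 and 90
  s <- detect_rpe(oct_volume(vol, cal))
  expect_equal(s[3, 3], 40)
  others <- unclass(s); others[3, 3] <- NA
  expect_true(all(others == 41, na.rm = TRUE))
})

test_that("ILM and RNFL track the phantom bands within tolerance", {
  env <- analyzed_small_phantom()
  ph <- env$phantom; res <- env$analysis
  e_ilm <- surface_abs_error(res$surfaces$ilm, ph$truth$ilm)
  e_rnfl <- surface_abs_error(res$surfaces$rnfl, ph$truth$rnfl)
  expect_gte(mean(e_ilm <= 1, na.rm = TRUE), 0.99)
  expect_gte(mean(e_rnfl <= 2, na.rm = TRUE), 0.99)
  # ILM strictly above the RPE wherever both are defined
  both <- !is.na(res$surfaces$ilm) & !is.na(res$surfaces$rpe)
  expect_true(all(res$surfaces$ilm[both] < res$surfaces$rpe[both]))
})

test_that("columns with an empty or featureless band are undefined", {
  ilm <- layer_surface(matrix(10, 6, 4), "ILM")
  rpe <- layer_surface(matrix(55, 6, 4), "RPE")
  # a uniform band between ILM and RPE: no interior edge anywhere
  flat <- array(0, c(60, 6, 4))
  flat[10:55, , ] <- 90
  expect_true(all(is.na(detect_rnfl(oct_volume(flat, cal), ilm, rpe))))
  # a light-to-dark transition inside the band is found everywhere
  vol <- array(0, c(60, 6, 4))
  vol[10:30, , ] <- 150
  vol[31:55, , ] <- 30
  v <- oct_volume(vol, cal)
  rnfl <- detect_rnfl(v, ilm, rpe)
  expect_true(all(abs(unclass(rnfl) - 31) <= 1))
  # empty band (ILM meets RPE) is undefined too
  rpe2 <- layer_surface(matrix(11, 6, 4), "RPE")
  expect_true(all(is.na(detect_rnfl(v, ilm, rpe2))))
  # above-RPE region entirely background -> undefined ILM
  vol2 <- array(0, c(60, 6, 4))
  vol2[10, c(1:2, 4:6), ] <- 150
  vol2[40, , ] <- 220
  v2 <- oct_volume(vol2, cal)
  ilm2 <- detect_ilm(v2, detect_rpe(v2))
  expect_true(all(is.na(ilm2[3, ])))
  expect_true(all(ilm2[c(1, 5), ] == 10))
})

test_that("the band-masked gradient vanishes on and outside ILM/RPE", {
  env <- analyzed_small_phantom()
  ph <- env$phantom
  filt <- median_filter_3d(ph$volume)
  ilm <- env$analysis$surfaces$ilm
  rpe <- env$analysis$surfaces$rpe
  G <- gradient_volume(filt, ilm, rpe)
  d <- dim(G)
  rowidx <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  ilm_arr <- array(rep(unclass(ilm), each = d[1]), d)
  rpe_arr <- array(rep(unclass(rpe), each = d[1]), d)
  outside <- rowidx <= ilm_arr | rowidx >= rpe_arr
  expect_true(all(G[outside] == 0))
  expect_gt(max(G), 0)
})

test_that("active edge correction is exact on clean step edges", {
  M <- 80; N <- 20
  vol <- array(0, c(M, N, 3))
  vol[10, , ] <- 140                    # anchor surfaces for the band
  vol[11:44, , ] <- 120                 # bright plateau
  vol[45:M, , ] <- 15                   # dark below: edge at row 45
  vol[70, , ] <- 200                    # bright floor (acts as RPE)
  v <- oct_volume(vol, cal)
  ilm <- layer_surface(matrix(10, N, 3), "ILM")
  rpe <- layer_surface(matrix(70, N, 3), "RPE")
  on_edge <- layer_surface(matrix(45, N, 3), "RNFL")
  expect_equal(unclass(refine_contour(v, on_edge, ilm, rpe)),
               unclass(on_edge), ignore_attr = TRUE)
  displaced <- layer_surface(matrix(49, N, 3), "RNFL")
  expect_equal(unclass(refine_contour(v, displaced, ilm, rpe)),
               unclass(on_edge), ignore_attr = TRUE)
})

test_that("correction bridges and repairs shadow-induced contour gaps", {
  spec <- small_spec(vessel_shadows = list(list(n = 30, width_px = 5,
                                                attenuation = 0.9)))
  ph <- generate_phantom(spec)
  filt <- median_filter_3d(ph$volume)
  rpe <- detect_rpe(filt)
  ilm <- detect_ilm(filt, rpe)
  raw <- detect_rnfl(filt, ilm, rpe)
  expect_gt(sum(is.na(raw[28:32, ])), 0)   # the shadow breaks the contour
  fixed <- refine_contour(filt, raw, ilm, rpe)
  shadow_cols <- 28:32
  err <- abs(unclass(fixed)[shadow_cols, ] -
               unclass(ph$truth$rnfl)[shadow_cols, ])
  expect_true(all(!is.na(err)))            # corrected contour is continuous
  expect_lte(max(err), 2)
})

test_that("ordering ILM <= RNFL* <= RPE holds after refinement", {
  env <- analyzed_small_phantom()
  s <- env$analysis$surfaces
  ok <- !is.na(s$ilm) & !is.na(s$rnfl) & !is.na(s$rpe)
  expect_true(all(s$ilm[ok] <= s$rnfl[ok]))
  expect_true(all(s$rnfl[ok] <= s$rpe[ok]))
})

test_that("moderate noise degrades median surface errors by at most 1 px", {
  clean <- analyzed_small_phantom()
  noisy_ph <- generate_phantom(small_spec(cup_center = c(50, 16),
                                          noise_sd = 5, seed = 2))
  noisy <- suppressMessages(onh_analyze(noisy_ph$volume))
  med_err <- function(res, truth) {
    vapply(c(rpe = "rpe", ilm = "ilm", rnfl = "rnfl"), function(k) {
      median(surface_abs_error(res$surfaces[[k]], truth[[k]]), na.rm = TRUE)
    }, numeric(1))
  }
  e0 <- med_err(clean$analysis, clean$phantom$truth)
  e5 <- med_err(noisy, noisy_ph$truth)
  expect_true(all(e5 - e0 <= 1))
})
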