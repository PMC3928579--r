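test_that("a disk-free flat phantom has its brightest row at the RPE", {
  spec <- small_spec(disk_radius_px = 0, cup_radius_px = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  bright <- apply(ph$volume$data, c(2, 3), which.max)
  expect_true(all(bright == spec$rpe_depth_row))
  expect_false(any(ph$truth$disk_mask))
})

test_that("rendering is deterministic and seed-independent without noise", {
  a <- generate_phantom(small_spec(seed = 1))
  b <- generate_phantom(small_spec(seed = 999))
  expect_identical(a$volume$data, b$volume$data)

  n1 <- generate_phantom(small_spec(noise_sd = 5, seed = 4))
  n2 <- generate_phantom(small_spec(noise_sd = 5, seed = 4))
  n3 <- generate_phantom(small_spec(noise_sd = 5, seed = 5))
  expect_identical(n1$volume$data, n2$volume$data)
  expect_false(identical(n1$volume$data, n3$volume$data))
})

test_that("analytic truth matches the closed-form circular geometry", {
  base <- small_spec(disk_radius_px = 10, cup_radius_px = 5)
  tr <- analytic_truth(base)   # concentric, thickness == reference
  expect_equal(tr$wg1, 0)
  expect_equal(tr$wg2, 0.5)    # r_min = 10 - 5
  expect_equal(tr$wg3, 0)
  expect_equal(tr$w_bga, 1 / 6)

  expect_equal(analytic_truth(small_spec(cup_radius_px = 0))$wg2, 0)
  tangent <- small_spec(cup_radius_px = 4, cup_center = c(54, 16))
  expect_equal(analytic_truth(tangent)$wg2, 1)  # cup touches the disk edge

  off <- small_spec(cup_center = c(51, 12))     # displacement (3, -4)
  expect_equal(analytic_truth(off)$wg1, 0.5)
})

test_that("coincident centroids give zero eccentricity in the ground truth", {
  ph <- generate_phantom(small_spec())
  expect_equal(ph$truth$true_features$wg1, 0)
})

test_that("surface ordering ILM <= RNFL <= RPE holds for random valid specs", {
  set.seed(11)
  for (k in 1:8) {
    r_c <- runif(1, 0, 9)
    ecc <- runif(1, 0, 0.95)
    ang <- runif(1, 0, 2 * pi)
    spec <- small_spec(
      cup_radius_px = r_c,
      cup_center = c(48, 16) + ecc * (10 - r_c) * c(sin(ang), cos(ang)),
      rnfl_thickness_um = runif(1, 50, 150),
      cup_depth_um = runif(1, 0, 450))
    sur <- generate_phantom(spec)$truth
    expect_true(all(unclass(sur$ilm) <= unclass(sur$rnfl)))
    expect_true(all(unclass(sur$rnfl) <= unclass(sur$rpe)))
  }
})

test_that("cup eccentricity never decreases the analytic scores", {
  seps <- seq(0, 5, by = 1)   # cup r = 5, disk r = 10
  w1 <- w2 <- numeric(length(seps))
  for (j in seq_along(seps)) {
    tr <- analytic_truth(small_spec(cup_center = c(48 + seps[j], 16)))
    w1[j] <- tr$wg1; w2[j] <- tr$wg2
  }
  expect_true(all(diff(w1) >= 0))
  expect_true(all(diff(w2) >= 0))
})

test_that("invalid specs fail with the offending field named", {
  expect_error(small_spec(cup_center = c(58, 16)), "cup_center")
  expect_error(small_spec(cup_radius_px = 12), "cup_radius_px")
  expect_error(small_spec(disk_excavation_um = 5000), "disk_excavation_um")
  expect_error(small_spec(layer_brightness = c(background = 10, rnfl = 250,
                                               inner = 40, cavity = 20,
                                               rpe = 230)),
               "layer_brightness")
  expect_error(analytic_truth(small_spec(disk_radius_px = 0,
                                         cup_radius_px = 0)),
               "positive")
})

test_that("vessel shadows attenuate columns below the ILM only", {
  spec <- small_spec(vessel_shadows = list(list(n = 20, width_px = 4,
                                                attenuation = 0.9)))
  ph <- generate_phantom(spec)
  clean <- generate_phantom(small_spec())
  ilm <- spec$ilm_base_row
  expect_equal(ph$volume$data[1:(ilm - 1), 20, 5],
               clean$volume$data[1:(ilm - 1), 20, 5])
  band <- ilm:(ilm + 10)
  expect_true(all(ph$volume$data[band, 20, 5] <
                    clean$volume$data[band, 20, 5]))
  expect_equal(ph$volume$data[, 60, 5], clean$volume$data[, 60, 5])
})
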