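cal <- calibration(5, 12, 12)

test_that("a flat RPE yields a no-disk error", {
  flat <- layer_surface(matrix(90, 40, 30), "RPE")
  expect_error(disk_mask(flat), class = "onh_algorithm_error")
})

test_that("the disk mask recovers a circular excavation", {
  env <- analyzed_small_phantom()
  m <- env$analysis$masks$disk
  r_true <- 10
  expect_lt(abs(sum(m) - pi * r_true^2) / (pi * r_true^2), 0.1)
  g <- mask_centroid_radius(m)
  expect_lt(max(abs(g$centroid - c(48, 16))), 1)
})

test_that("only the largest of two excavations survives cleanup", {
  rows <- matrix(90, 60, 40)
  rows[disc_matrix(60, 40, c(20, 20), 8)] <- 170    # large excavation
  rows[disc_matrix(60, 40, c(45, 20), 4)] <- 170    # 4x smaller area
  m <- disk_mask(layer_surface(rows, "RPE"))
  expect_true(all(which(m, arr.ind = TRUE)[, 1] < 35))
  expect_equal(sum(m), sum(disc_matrix(60, 40, c(20, 20), 8)))
})

test_that("centroid and equivalent radius have their closed forms", {
  one <- matrix(FALSE, 20, 20); one[7, 9] <- TRUE
  g <- mask_centroid_radius(enface_mask(one, "disk"))
  expect_equal(unname(g$centroid), c(7, 9))
  expect_equal(g$r, 1 / sqrt(pi))

  sq <- matrix(FALSE, 20, 20); sq[6:15, 3:12] <- TRUE
  expect_equal(mask_centroid_radius(enface_mask(sq, "disk"))$r,
               sqrt(100 / pi))

  circ <- enface_mask(disc_matrix(64, 64, c(32, 32), 20), "disk")
  expect_lt(abs(mask_centroid_radius(circ)$r - 20) / 20, 0.01)
  expect_error(mask_centroid_radius(enface_mask(matrix(FALSE, 4, 4),
                                                "disk")),
               class = "onh_algorithm_error")
})

test_that("cup extraction responds to depth and offset as a level set", {
  flatcup <- generate_phantom(small_spec(cup_depth_um = 0))
  filt <- median_filter_3d(flatcup$volume)
  rpe <- detect_rpe(filt)
  ilm <- detect_ilm(filt, rpe)
  disk <- disk_mask(rpe)
  cup0 <- detect_cup(ilm, rpe, disk, cal)
  expect_equal(sum(cup0), 0)   # no excavation: empty cup is not an error

  env <- analyzed_small_phantom()
  cup <- env$analysis$masks$cup
  expect_lt(abs(mask_centroid_radius(cup)$r - 5), 2)
  # raising the cut level (larger anterior offset) can only admit more of
  # the dipping ILM, so the cup grows or is preserved, never shrinks
  deeper <- detect_cup(env$analysis$surfaces$ilm,
                       env$analysis$surfaces$rpe,
                       env$analysis$masks$disk, cal,
                       onh_config(cup_offset_um = 300))
  expect_gte(sum(deeper), sum(cup))
  shallower <- detect_cup(env$analysis$surfaces$ilm,
                          env$analysis$surfaces$rpe,
                          env$analysis$masks$disk, cal,
                          onh_config(cup_offset_um = 600))
  expect_gte(sum(shallower), sum(deeper))

  expect_error(detect_cup(env$analysis$surfaces$ilm,
                          env$analysis$surfaces$rpe,
                          env$analysis$masks$disk, NULL),
               class = "onh_config_error")
})

test_that("boundary distance matches geometry and the all-pairs oracle", {
  disk <- enface_mask(disc_matrix(40, 40, c(20, 20), 10), "disk")
  cup <- enface_mask(disc_matrix(40, 40, c(20, 20), 5), "cup")
  d <- min_boundary_distance(cup, disk)
  expect_lte(abs(d - 5), 1)
  expect_equal(d, oracle_min_boundary_distance(unclass(cup), unclass(disk)))

  # cup touching the disk boundary
  cup2 <- enface_mask(disc_matrix(40, 40, c(25, 20), 5), "cup")
  expect_equal(min_boundary_distance(cup2, disk), 0)

  outside <- enface_mask(disc_matrix(40, 40, c(28, 20), 5), "cup")
  expect_error(min_boundary_distance(outside, disk),
               class = "onh_algorithm_error")
})

test_that("r_min shrinks as the cup approaches the disk radius", {
  disk <- enface_mask(disc_matrix(64, 64, c(32, 32), 20), "disk")
  rmins <- vapply(c(4, 8, 12, 16, 19), function(r) {
    min_boundary_distance(enface_mask(disc_matrix(64, 64, c(32, 32), r),
                                      "cup"), disk)
  }, numeric(1))
  expect_true(all(diff(rmins) < 0))
})

test_that("a rotationally symmetric thickness field gives a flat profile", {
  N <- 96; I <- 96
  ilm <- layer_surface(matrix(20, N, I), "ILM")
  rnfl <- layer_surface(matrix(40, N, I), "RNFL")   # 20 px * 5 um = 100 um
  disk <- enface_mask(disc_matrix(N, I, c(48, 48), 12), "disk")
  geom <- disk_geometry(disk, enface_mask(disc_matrix(N, I, c(48, 48), 6),
                                          "cup"))
  pr <- polar_thickness_profile(ilm, rnfl, geom, cal)
  expect_true(all(pr$valid))
  expect_true(all(abs(pr$thickness_um - 100) / 100 <= 0.02))
  expect_equal(wg3(pr), 0)
})

test_that("the angular convention sends +n displacements to 90 degrees", {
  N <- 96; I <- 96
  ilm <- matrix(20, N, I)
  # thicker wedge on the +n side of the centroid
  th <- (atan2(row(ilm) - 48, col(ilm) - 48) * 180 / pi) %% 360
  rnfl <- 40 + 10 * (abs(((th + 180) %% 360) - 180 - 90) < 20)
  geom <- disk_geometry(enface_mask(disc_matrix(N, I, c(48, 48), 12),
                                    "disk"))
  pr <- polar_thickness_profile(layer_surface(ilm, "ILM"),
                                layer_surface(rnfl, "RNFL"), geom, cal)
  # the thickened wedge sits on the +n side, i.e. around theta = 90
  wedge <- pr$theta_deg > 75 & pr$theta_deg < 105
  away <- pr$theta_deg > 255 & pr$theta_deg < 285
  expect_true(all(pr$thickness_um[wedge] > 140))
  expect_true(all(abs(pr$thickness_um[away] - 100) < 5))
  expect_equal(pr$quadrant[pr$theta_deg == 90], "SU")
  expect_equal(pr$quadrant[pr$theta_deg == 0], "TE")
})

test_that("anisotropic sampling measures the annulus in physical units", {
  cal_aniso <- calibration(5, 10, 40)
  N <- 160; I <- 48
  ilm <- layer_surface(matrix(20, N, I), "ILM")
  rnfl <- layer_surface(matrix(40, N, I), "RNFL")
  disk <- enface_mask(disc_matrix(N, I, c(80, 24), 8), "disk")
  geom <- disk_geometry(disk)
  pr <- polar_thickness_profile(ilm, rnfl, geom, cal_aniso)
  expect_gt(mean(pr$valid), 0.5)
  expect_true(all(abs(pr$thickness_um[pr$valid] - 100) / 100 <= 0.02))
})

test_that("an annulus fully outside the image is an error", {
  ilm <- layer_surface(matrix(20, 30, 30), "ILM")
  rnfl <- layer_surface(matrix(40, 30, 30), "RNFL")
  geom <- disk_geometry(enface_mask(disc_matrix(30, 30, c(15, 15), 14),
                                    "disk"))
  expect_error(polar_thickness_profile(ilm, rnfl, geom, cal),
               class = "onh_algorithm_error")
})
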