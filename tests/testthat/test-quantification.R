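test_that("band definitions span the documented surfaces", {
  expect_equal(band_definition("ELM_MZ")[c("anterior", "posterior")],
               list(anterior = "ELM", posterior = "EZ_inner"))
  # the EZ band includes the interdigitation zone: down to RPE_inner
  expect_equal(band_definition("EZ")[c("anterior", "posterior")],
               list(anterior = "EZ_inner", posterior = "RPE_inner"))
  expect_equal(band_definition("RPE")[c("anterior", "posterior")],
               list(anterior = "RPE_inner", posterior = "RPE_outer"))
  expect_error(band_definition("IZ"))
})

test_that("thickness maps are surface differences", {
  ss <- flat_surface_set(t_rpe = 16)   # High-Res-like RPE magnitude
  th <- thickness_map(ss, "RPE")
  expect_true(all(th$values == 16))
  # anterior == posterior everywhere -> all-zero map
  ss0 <- flat_surface_set(t_rpe = 0)
  expect_true(all(thickness_map(ss0, "RPE")$values == 0))
})

test_that("worked example thicknesses match direct subtraction", {
  we <- worked_example_eye()
  ss <- we$standard
  th_ez <- thickness_map(ss, "EZ")$values
  th_rpe <- thickness_map(ss, "RPE")$values
  idx <- rbind(c(2, 10), c(5, 33), c(8, 60), c(1, 1), c(9, 64))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    expect_equal(th_ez[i, j],
                 ss$surfaces$RPE_inner[i, j] - ss$surfaces$EZ_inner[i, j])
    expect_equal(th_rpe[i, j],
                 ss$surfaces$RPE_outer[i, j] - ss$surfaces$RPE_inner[i, j])
  }
})

test_that("complete surfaces give an all-zero loss mask", {
  ss <- flat_surface_set()
  for (b in BAND_NAMES)
    expect_true(all(loss_mask(ss, b)$values == 0))
})

test_that("lesion loss area matches the fine-grid ellipse oracle", {
  sp <- phantom_spec(seed = 11, n_patients = 1, prob_both_eyes = 0,
                     semi_axis_sd_log = 0, sdd_count = 0L,
                     drusen_count = 0L, jitter_sd_um = 0,
                     devices = "standard",
                     device_thickness_offset_um =
                       list(standard = c(ELM_MZ = 0, EZ = 0, RPE = 0)),
                     device_sdd_visibility = c(standard = 1))
  coh <- generate_cohort(sp)
  ss <- coh$surface_sets[[1]]
  q <- quantify_eye(ss)
  oracle <- rasterize_ellipse_area_mm2(1.0, 0.5)
  expect_equal(q$bands$RPE$loss_area_mm2, oracle, tolerance = 0.02)
  # and the oracle agrees with the closed form used by the truth table
  expect_equal(oracle, ellipse_area_mm2(1.0, 0.5), tolerance = 0.005)
})

test_that("SDD-disruption flags mark EZ loss despite present surfaces", {
  ss <- flat_surface_set()
  ss$sdd_disrupted[4, 7] <- TRUE
  m <- loss_mask(ss, "EZ")
  expect_equal(m$values[4, 7], 1)
  expect_equal(sum(m$values), 1)
  # the flagged column is excluded from EZ thickness too
  expect_true(is.na(thickness_map(ss, "EZ")$values[4, 7]))
})

test_that("loss area is count times cell area", {
  g <- make_geometry()
  full <- enface_map(matrix(1, 49, 1024), "loss", g, c(25L, 513L))
  expect_equal(loss_area_mm2(full, g),
               49 * 1024 * column_cell_area_mm2(g))
  empty <- enface_map(matrix(0, 49, 1024), "loss", g, c(25L, 513L))
  expect_equal(loss_area_mm2(empty, g), 0)
  one_row <- matrix(0, 49, 1024); one_row[7, ] <- 1
  expect_equal(loss_area_mm2(enface_map(one_row, "loss", g, c(25L, 513L)), g),
               1024 * column_cell_area_mm2(g))
})

test_that("SDD threshold is strict and gaps propagate", {
  gap <- matrix(0, 9, 32)
  gap[2, 2] <- 4      # exactly at threshold -> 0
  gap[3, 3] <- 10     # above threshold -> kept at full gap
  gap[4, 4] <- 4.001  # just over -> kept
  ss <- flat_surface_set(gap = gap)
  m <- sdd_thickness_map(ss, threshold_um = 4)
  expect_equal(m$values[2, 2], 0)
  expect_equal(m$values[3, 3], 10)
  expect_equal(m$values[4, 4], 4.001)
  expect_true(all(m$values[gap == 0] == 0))
  # missing bounding surfaces give missing SDD thickness
  ss$surfaces$RPE_inner[5, 5] <- NA
  ss$surfaces$RPE_outer[5, 5] <- NA
  expect_true(is.na(sdd_thickness_map(ss)$values[5, 5]))
})

test_that("raising the SDD threshold never increases the volume", {
  set.seed(42)
  gap <- matrix(rexp(9 * 32, rate = 1 / 5), 9, 32)
  ss <- flat_surface_set(gap = gap)
  vols <- vapply(c(0, 2, 4, 6, 10, 20), function(t)
    sdd_volume_nl(sdd_thickness_map(ss, t), ss$geometry), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("SDD volume integrates thickness times cell area", {
  # 10 um uniform over exactly 1 mm^2 of columns -> 10 nL
  g1 <- make_geometry(fov_deg = 10, n_ascans = 11, n_bscans = 11,
                      mm_per_deg = 0.2, bscan_spacing_um = 200)
  # cell = 200 um x 200 um = 0.04 mm^2 -> 25 columns = 1 mm^2
  v <- matrix(0, 11, 11); v[1:5, 1:5] <- 10
  m <- enface_map(v, "SDD_thickness_um", g1, c(6L, 6L))
  expect_equal(sdd_volume_nl(m, g1), 10)
  # region mask restricts the integral; wrong shape errors
  mask <- matrix(FALSE, 11, 11); mask[1:5, 1:2] <- TRUE
  expect_equal(sdd_volume_nl(m, g1, mask), 4)
  expect_error(sdd_volume_nl(m, g1, matrix(TRUE, 2, 2)), "shape")
})

test_that("phantom mound profile matches the closed form where over threshold", {
  g <- make_geometry(n_ascans = 256, n_bscans = 49)
  fov <- c(25L, 129L)
  gap <- mound_gap_matrix(g, fov, 1.2, 0.8, 30, 0.5)
  s <- list(RPE_inner = matrix(200, 49, 256))
  s$RPE_outer <- s$RPE_inner + 21
  s$EZ_outer <- s$RPE_inner - gap
  s$EZ_inner <- s$EZ_outer - 27
  s$ELM <- s$EZ_inner - 20
  ss <- surface_set(s[SURFACE_NAMES], g, fov)
  m <- sdd_thickness_map(ss, 4)
  expect_equal(m$values[gap > 4], gap[gap > 4])
  expect_true(all(m$values[gap <= 4] == 0))
  # integrated volume close to the closed-form visible volume
  expect_equal(sdd_volume_nl(m, g),
               mound_visible_volume_um3(30, 500, 4) / 1e6,
               tolerance = 0.05)
})

test_that("thickness missingness and loss masks cohere per band", {
  sp <- small_phantom_spec(seed = 5, n_patients = 2)
  coh <- generate_cohort(sp)
  for (ss in coh$surface_sets[1:2]) {
    q <- quantify_eye(ss)
    for (b in c("EZ", "RPE")) {
      expect_identical(is.na(q$bands[[b]]$thickness$values),
                       q$bands[[b]]$loss$values == 1)
    }
    # for ELM+MZ, loss implies missing thickness (the converse can fail
    # where only the EZ boundary is lost in the wider EZ lesion)
    lost <- q$bands$ELM_MZ$loss$values == 1
    expect_true(all(is.na(q$bands$ELM_MZ$thickness$values[lost])))
  }
})

test_that("loss areas are additive over a partition of the field", {
  sp <- small_phantom_spec(seed = 6, n_patients = 1, prob_both_eyes = 0)
  coh <- generate_cohort(sp)
  q <- quantify_eye(coh$surface_sets[[1]])
  g <- q$geometry
  m <- q$bands$EZ$loss$values
  halves <- list(seq_len(32), 33:64)
  parts <- vapply(halves, function(cols)
    sum(m[, cols] > 0) * column_cell_area_mm2(g), numeric(1))
  expect_equal(sum(parts), q$bands$EZ$loss_area_mm2)
})

test_that("quantification ignores the device label", {
  ss <- flat_surface_set(device = "standard")
  ss2 <- flat_surface_set(device = "imaginary_device")
  q1 <- quantify_eye(ss); q2 <- quantify_eye(ss2)
  for (b in BAND_NAMES) {
    expect_identical(q1$bands[[b]]$thickness$values,
                     q2$bands[[b]]$thickness$values)
    expect_identical(q1$bands[[b]]$loss_area_mm2, q2$bands[[b]]$loss_area_mm2)
  }
  expect_identical(q1$sdd_volume_nl, q2$sdd_volume_nl)
})

test_that("97-B-scan volumes subsample to 49 with doubled slab width", {
  ss <- flat_surface_set(n_bscans = 97, n_ascans = 32)
  sub <- subsample_bscans(ss, 2L)
  expect_equal(sub$geometry$n_bscans, 49L)
  expect_equal(sub$geometry$bscan_spacing_um,
               2 * ss$geometry$bscan_spacing_um)
  expect_identical(sub$surfaces$ELM, ss$surfaces$ELM[seq(1, 97, 2), ])
})
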