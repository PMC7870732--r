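test_that("SUV to SUL conversion and LBM rescaling are pure ratios", {
  expect_equal(suv_to_sul(5, 42, 60), 3.5)
  expect_equal(suv_to_sul(5, 60, 60), 5)
  expect_error(suv_to_sul(5, 42, 0), class = "lbmct_domain_error")

  expect_equal(rescale_sul_peak(4, 47.01, 42.26), 4 * 42.26 / 47.01)
  expect_equal(rescale_sul_peak(4, 50, 50), 4)
  # rescale then reverse-rescale returns the original
  x <- rescale_sul_peak(rescale_sul_peak(3.7, 47, 42.3), 42.3, 47)
  expect_equal(x, 3.7, tolerance = 1e-12)
  expect_error(rescale_sul_peak(-1, 47, 42), class = "lbmct_domain_error")
})

test_that("percent change is the standard relative difference", {
  expect_equal(percent_change(5, 3.5), -30)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(5, 6.5), 30)
  expect_error(percent_change(0, 5), class = "lbmct_domain_error")
})

test_that("response classification applies inclusive thresholds and the
           absolute-change gate", {
  expect_equal(as.character(classify_response(5, 3.5)$response), "PMR")
  expect_equal(as.character(classify_response(2, 1.4)$response), "SMD")
  expect_equal(as.character(classify_response(5, 6.4)$response), "SMD")
  expect_equal(as.character(classify_response(5, 6.5)$response), "PMD")
  expect_equal(as.character(classify_response(5, 5 * 0.7001)$response),
               "SMD")
  expect_equal(as.character(classify_response(5, 5 * 1.2999)$response),
               "SMD")
  # sign coherence between percent and absolute change
  res <- classify_response(c(5, 5), c(3, 8))
  expect_identical(sign(res$percent_change), sign(res$abs_change))
})

test_that("increasing follow-up SUL never moves the class toward PMR", {
  followups <- seq(1, 12, by = 0.1)
  cls <- classify_response(5, followups)$response
  expect_true(all(diff(as.integer(cls)) <= 0))
})

test_that("target-lesion selection takes the hottest lesion with
           deterministic ties", {
  lesions <- tibble::tibble(
    lesion_id = c("b", "a", "c"),
    sul_peak = c(4.2, 7.1, 3.3),
    timepoint = "baseline"
  )
  expect_identical(select_target_lesion(lesions)$lesion_id, "a")
  expect_identical(select_target_lesion(lesions[1, ])$lesion_id, "b")
  tie <- tibble::tibble(lesion_id = c("zz", "aa"), sul_peak = c(5, 5))
  expect_identical(select_target_lesion(tie)$lesion_id, "aa")
  expect_error(select_target_lesion(lesions[0, ]),
               class = "lbmct_content_error")
  expect_error(select_target_lesion(
    tibble::tibble(lesion_id = "a", sul_peak = 1,
                   timepoint = c("baseline"))[c(1, 1), ] |>
      dplyr::mutate(timepoint = c("baseline", "followup"))
  ), "same timepoint")
})

test_that("adaptive segmentation reaches the two-level and constant
           fixpoints", {
  vox <- array(1, c(12, 12, 12))
  vox[5:8, 5:8, 5:8] <- 10
  pet <- image_volume(vox, c(3, 3, 3), modality = "PET")
  seed <- array(TRUE, c(12, 12, 12))  # seed covers lesion and background
  m <- adaptive_threshold_segment(pet, seed)
  expect_identical(which(m), which(vox == 10))
  expect_equal(attr(m, "threshold"), 10)  # w*10 + (1-w)*10 at the fixpoint
  expect_true(attr(m, "converged"))

  flat <- image_volume(array(3, c(6, 6, 6)), c(3, 3, 3), modality = "PET")
  m2 <- adaptive_threshold_segment(flat, array(TRUE, c(6, 6, 6)))
  expect_true(all(m2))
  expect_equal(attr(m2, "threshold"), 3)
})

test_that("adaptive segmentation lands on a brute-force threshold fixpoint", {
  set.seed(12)
  vox <- array(runif(10^3, 0, 2), c(10, 10, 10))
  ramp <- seq(2, 9, length.out = 5)
  vox[4:8, 5, 5] <- ramp  # linear ramp lesion
  pet <- image_volume(vox, c(2, 2, 2), modality = "PET")
  seed <- array(FALSE, c(10, 10, 10)); seed[3:9, 4:6, 4:6] <- TRUE
  m <- adaptive_threshold_segment(pet, seed, weight_factor = 0.5)

  # oracle: enumerate all candidate thresholds; a fixpoint is a threshold
  # whose seed-connected mask regenerates (to tolerance) the same threshold
  seed_idx <- which(seed)[which.max(vox[seed])]
  mask_at <- function(t) {
    cand <- vox >= t
    labs <- lbmct:::label_components_3d(as.logical(cand),
                                       as.integer(dim(vox)), 26L)
    array(labs == labs[seed_idx], dim(vox))
  }
  fixpoints <- list()
  for (t in sort(unique(as.vector(vox)))) {
    mk <- mask_at(t)
    vals <- vox[mk]
    u <- 0.5 * max(vals) + 0.5 * mean(vals)
    if (identical(mask_at(u), mk)) fixpoints <- c(fixpoints, list(mk))
  }
  expect_true(any(vapply(fixpoints, identical, TRUE, y = array(as.logical(m),
                                                               dim(vox)))))
  # recorded threshold satisfies its own fixpoint equation
  vals <- vox[m]
  expect_equal(attr(m, "threshold"), 0.5 * max(vals) + 0.5 * mean(vals),
               tolerance = 1e-6)
})

test_that("SUL peak is the highest sphere-mean inside the lesion", {
  pp <- make_pet_phantom(lesion_sul = 8, lesion_diameter_mm = 30)
  expect_equal(sul_peak(pp$volume, pp$truth$lesion_mask), 8.0)
  expect_lte(sul_peak(pp$volume, pp$truth$lesion_mask),
             max(pp$volume$voxels))

  # single hot voxel: peak = value / sphere voxel count
  vox <- array(0.001, c(21, 21, 21))
  vox[11, 11, 11] <- 10
  pet <- image_volume(vox, c(2, 2, 2), modality = "PET")
  mask <- vox == 10
  # independent sphere voxel count: centers within 6 mm at 2 mm spacing
  g <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  n_sphere <- sum((2 * g$i)^2 + (2 * g$j)^2 + (2 * g$k)^2 <= 6^2)
  got <- sul_peak(pet, mask)
  expect_equal(got, (10 + (n_sphere - 1) * 0.001) / n_sphere)

  # invariant under changes far outside any candidate sphere
  vox2 <- vox; vox2[1, 1, 1] <- 5
  pet2 <- image_volume(vox2, c(2, 2, 2), modality = "PET")
  expect_equal(sul_peak(pet2, mask), got)

  expect_error(sul_peak(pet, mask, sphere_diameter_mm = 500),
               class = "lbmct_geometry_error")
  expect_error(sul_peak(pet, array(FALSE, dim(vox))),
               class = "lbmct_content_error")
})

test_that("liver background statistics match closed forms", {
  pp <- make_pet_phantom(liver_sul = c(2, 0))
  bg <- liver_background(pp$volume, pp$truth$liver_center_mm, 30)
  expect_equal(bg$liver_sul_mean, 2.0)
  expect_equal(bg$liver_sul_sd, 0.0)

  # two-value sphere: half 1, half 3 -> mean 2, population sd 1
  vox <- array(1, c(15, 15, 15))
  pet <- image_volume(vox, c(2, 2, 2), modality = "PET")
  center <- c(14, 14, 14)
  idx <- which(array(TRUE, dim(vox)), arr.ind = TRUE)
  pos <- (idx - 1) * 2
  inside <- which(rowSums(sweep(pos, 2, center)^2) <= 15^2)
  half <- inside[seq_len(floor(length(inside) / 2))]
  vox[half] <- 3
  pet <- image_volume(vox, c(2, 2, 2), modality = "PET")
  v_in <- vox[inside]
  bg2 <- liver_background(pet, center, 30, sd_type = "population")
  expect_equal(bg2$liver_sul_mean, mean(v_in))
  expect_equal(bg2$liver_sul_sd, sqrt(mean((v_in - mean(v_in))^2)))
  if (length(v_in) %% 2 == 0) {
    expect_equal(bg2$liver_sul_mean, 2.0)
    expect_equal(bg2$liver_sul_sd, 1.0)
  }
  bg3 <- liver_background(pet, center, 30)  # sample sd default
  expect_equal(bg3$liver_sul_sd, sd(v_in))

  expect_error(liver_background(pet, c(200, 200, 200), 30),
               class = "lbmct_geometry_error")
})

test_that("PERCIST measurability rules use the stated thresholds", {
  bg <- background_stats(2.0, 0.3)
  r1 <- is_measurable(3.7, bg)
  expect_true(r1$measurable)
  expect_equal(r1$threshold, 1.5 * 2.0 + 2 * 0.3)
  expect_false(is_measurable(3.5, bg)$measurable)
  # boundary is inclusive for the liver rule
  expect_true(is_measurable(3.6, bg)$measurable)
  # alternate parse is stricter here
  r_alt <- is_measurable(3.7, bg, alternate_parse = TRUE)
  expect_equal(r_alt$threshold, 1.5 * (2.0 + 2 * 0.3))
  expect_false(r_alt$measurable)

  bgb <- background_stats(2.0, 0.3, blood_sul_mean = 1.5)
  expect_true(is_measurable(3.01, bgb, use_blood_pool = TRUE)$measurable)
  expect_false(is_measurable(3.0, bgb, use_blood_pool = TRUE)$measurable)
  expect_error(is_measurable(3.01, bg, use_blood_pool = TRUE),
               class = "lbmct_config_error")
})

test_that("classification is invariant to LBM rescaling only when LBM is
           unchanged between timepoints", {
  set.seed(77)
  b <- runif(40, 2, 10)
  f <- b * runif(40, 0.4, 1.8)
  base_cls <- classify_response(b, f)$response
  # same LBM at both timepoints: ratio cancels, classes identical
  same <- classify_response(b * 42 / 47, f * 42 / 47,
                            min_abs_change = 0.8 * 42 / 47)$response
  expect_identical(base_cls, same)
  # LBM changes between timepoints: percent change shifts
  shifted <- classify_response(b, f * (1 - 0.028) / (1 - 0.072))
  expect_false(isTRUE(all.equal(classify_response(b, f)$percent_change,
                                shifted$percent_change)))
})

test_that("percist_compare runs the dual-algorithm pipeline per patient", {
  lesions <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 4),
    timepoint = rep(c("baseline", "baseline", "followup", "followup"), 2),
    lesion_id = rep(c("L1", "L2"), 4),
    sul_peak_pe = c(6, 5, 4, 4.2,   5, 5.5, 7.8, 7.2),
    lbm_pe_kg = c(50, 50, 46, 46,   48, 48, 48, 48),
    lbm_lc_kg = c(45, 45, 44, 44,   43, 43, 43, 43)
  )
  res <- percist_compare(lesions)
  expect_equal(nrow(res), 2)
  p1 <- res[res$patient_id == "p1", ]
  # hottest lesion: baseline L1 (6), follow-up L2 (4.2)
  expect_identical(p1$lesion_id_baseline, "L1")
  expect_identical(p1$lesion_id_followup, "L2")
  expect_equal(p1$percent_change_pe, 100 * (4.2 - 6) / 6)
  # LC change folds in the LBM ratio shift
  expect_equal(p1$percent_change_lc,
               100 * ((4.2 * 44 / 46) - (6 * 45 / 50)) / (6 * 45 / 50))
  # p2: identical LBMs at both timepoints -> concordant by construction
  p2 <- res[res$patient_id == "p2", ]
  expect_identical(as.character(p2$response_pe),
                   as.character(p2$response_lc))
  expect_error(percist_compare(lesions[, -4]), "missing columns")
})
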