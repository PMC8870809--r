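test_that("binarization is strict at the probability threshold", {
  p <- prob_mask(array(c(0, 0.25, 0.5, 0.75, 1, 0.51, 0, 0), c(2, 2, 2)),
                 c(4, 4, 4))
  m <- binarize_prediction(p)
  expect_identical(as.logical(m$values),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(binarize_prediction(prob_mask(array(0, c(2, 2, 2)),
                                                 c(4, 4, 4)))$values))
  pos <- prob_mask(array(0.1, c(2, 2, 2)), c(4, 4, 4))
  expect_true(all(binarize_prediction(pos, t = 0)$values))
})

test_that("connected components separate distant lesions", {
  spec <- phantom_spec(c(24, 24, 24), c(4, 4, 4),
                       lesions = list(lesion_spec(c(25, 25, 25), 10, 10),
                                      lesion_spec(c(70, 70, 70), 10, 10)),
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  mask <- binary_mask(as_label_array(ph$truth_masks) > 0, c(4, 4, 4))
  comps <- connected_components(mask, ph$pet)
  expect_length(comps, 2)
  expect_equal(sum(vapply(comps, `[[`, 0, "volume_ml")), volume_ml(mask))
  expect_equal(comps[[1]]$suvmax, 10, tolerance = 1e-9)
  # empty and single-voxel masks
  empty <- binary_mask(array(FALSE, c(24, 24, 24)), c(4, 4, 4))
  expect_length(connected_components(empty, ph$pet), 0)
  one <- array(FALSE, c(24, 24, 24)); one[5, 5, 5] <- TRUE
  cc1 <- connected_components(binary_mask(one, c(4, 4, 4)), ph$pet)
  expect_length(cc1, 1)
  expect_equal(cc1[[1]]$volume_ml, 0.064)   # 4^3 mm^3
})

test_that("26-connectivity joins diagonal bridges that 6 splits", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE     # corner neighbours
  pet <- make_pet(array(1, c(4, 4, 4)))
  mask <- binary_mask(m, c(4, 4, 4))
  expect_length(connected_components(mask, pet, connectivity = 26), 1)
  expect_length(connected_components(mask, pet, connectivity = 6), 2)
})

test_that("watershed leaves small components unchanged and splits peaks", {
  # ~20 mL single-peak component passes through untouched
  ph1 <- generate_phantom(
    phantom_spec(c(24, 24, 24), c(4, 4, 4),
                 lesions = list(lesion_spec(c(46, 46, 46), 17, 10, "gaussian")),
                 noise_sd = 0.05, seed = 2))
  mask1 <- binary_mask(ph1$truth_masks$rois[[1]], c(4, 4, 4))
  comp1 <- connected_components(mask1, ph1$pet)[[1]]
  expect_lt(comp1$volume_ml, 30)
  expect_identical(watershed_split(comp1, ph1$pet), list(comp1))

  # ~50 mL coalescent double-peak mass splits into one subpart per peak
  les <- lesion_spec(c(54, 64, 100), c(28, 28, 28), 12, "gaussian",
                     partner_offset_mm = c(40, 0, 10))
  ph2 <- generate_phantom(phantom_spec(c(32, 32, 64), c(4, 4, 4),
                                       lesions = list(les), noise_sd = 0.1,
                                       seed = 3))
  mask2 <- binary_mask(ph2$truth_masks$rois[[1]], c(4, 4, 4))
  comp2 <- connected_components(mask2, ph2$pet)[[1]]
  expect_gt(comp2$volume_ml, 30)
  subs <- watershed_split(comp2, ph2$pet)
  expect_length(subs, 2)
  peak_idx <- function(mm) {
    i <- round(mm / 4) + 1
    (i[3] - 1) * 32 * 32 + (i[2] - 1) * 32 + i[1]
  }
  in_sub <- function(mm) which(vapply(subs, function(s)
    peak_idx(mm) %in% s$voxel_idx, TRUE))
  expect_length(in_sub(c(54, 64, 100)), 1)
  expect_length(in_sub(c(94, 64, 110)), 1)
  expect_false(in_sub(c(54, 64, 100)) == in_sub(c(94, 64, 110)))
  # exact partition
  all_vox <- unlist(lapply(subs, `[[`, "voxel_idx"))
  expect_identical(sort(all_vox), sort(comp2$voxel_idx))
  expect_equal(sum(vapply(subs, `[[`, 0, "volume_ml")), comp2$volume_ml)
})

test_that("cutoff methodologies re-threshold the raw mask globally", {
  d <- c(10, 10, 10)
  raw <- binary_mask(array(TRUE, d), c(4, 4, 4))
  pet <- make_pet(array(5, d))
  res <- apply_methodology(raw, pet, method_cutoff(4.0))
  expect_equal(res$tmtv_ml, 1000 * 0.064)   # all 1000 voxels pass
  # nesting of cutoffs
  set.seed(7)
  pet2 <- make_pet(array(runif(prod(d), 0, 8), d))
  t25 <- apply_methodology(raw, pet2, method_cutoff(2.5))
  t40 <- apply_methodology(raw, pet2, method_cutoff(4.0))
  expect_lte(t40$tmtv_ml, t25$tmtv_ml)
  expect_true(all(t25$final_mask$values[t40$final_mask$values]))
  # idempotence: applying the cutoff to its own result changes nothing
  again <- apply_methodology(t25$final_mask, pet2, method_cutoff(2.5))
  expect_identical(again$final_mask$values, t25$final_mask$values)
})

test_that("empty raw masks give TMTV 0 without error", {
  d <- c(6, 6, 6)
  raw <- binary_mask(array(FALSE, d), c(4, 4, 4))
  pet <- make_pet(array(5, d))
  for (meth in list(method_cutoff(2.5), method_percent41())) {
    res <- apply_methodology(raw, pet, meth)
    expect_equal(res$tmtv_ml, 0)
    expect_equal(count_rois(res), 0)
  }
})

test_that("the 41% methodology thresholds each lesion by its own SUVmax", {
  # two separated lesions, SUVmax ~10 and ~4: thresholds 4.1 and 1.64
  spec <- phantom_spec(c(24, 24, 48), c(4, 4, 4),
                       lesions = list(lesion_spec(c(48, 48, 40), 14, 10,
                                                  "gaussian"),
                                      lesion_spec(c(48, 48, 140), 14, 4,
                                                  "gaussian")),
                       background_suv = 0.5, noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  raw <- binary_mask(as_label_array(ph$truth_masks) > 0, c(4, 4, 4))
  res <- apply_methodology(raw, ph$pet, method_percent41())
  expect_equal(count_rois(res), 2)
  expect_length(res$components, 2)
  suvmaxes <- sort(vapply(res$components, `[[`, 0, "suvmax"), decreasing = TRUE)
  expect_equal(suvmaxes, c(10, 4), tolerance = 1e-6)
  for (comp in res$components) {
    vals <- ph$pet$values[comp$voxel_idx]
    expect_true(all(vals >= 0.41 * comp$suvmax - 1e-9))
  }
  # the hot lesion keeps only voxels >= 4.1; the faint one >= 1.64
  hot <- res$components[[which.max(vapply(res$components, `[[`, 0, "suvmax"))]]
  faint <- res$components[[which.min(vapply(res$components, `[[`, 0, "suvmax"))]]
  expect_true(any(ph$pet$values[faint$voxel_idx] < 4.1))
  expect_true(all(ph$pet$values[hot$voxel_idx] >= 4.1 - 1e-9))
  # final mask stays inside the raw mask
  expect_true(all(raw$values[res$final_mask$values]))
})

test_that("41% methodology is invariant to PET rescaling", {
  spec <- random_phantom_spec(21, grid_shape = c(16, 16, 24),
                              voxel_spacing_mm = c(8, 8, 8),
                              radii_range_mm = c(20, 40))
  ph <- generate_phantom(spec)
  raw <- binarize_prediction(ground_truth_for_case(
    ph$pet, manual_roi_boxes(ph$truth_masks, 10)))
  r1 <- apply_methodology(raw, ph$pet, method_percent41())
  pet_scaled <- volume_grid(ph$pet$values * 3.7, ph$pet$spacing,
                            ph$pet$origin, "PET_SUV")
  r2 <- apply_methodology(raw, pet_scaled, method_percent41())
  expect_identical(r1$final_mask$values, r2$final_mask$values)
  # cutoff results are allowed to change; the relative rule is not
})

test_that("tmtv result serialization writes mask and report", {
  d <- c(6, 6, 6)
  raw <- binary_mask(array(TRUE, d), c(4, 4, 4))
  pet <- make_pet(array(5, d))
  res <- apply_methodology(raw, pet, method_cutoff(2.5))
  dir <- withr::local_tempdir()
  write_tmtv_result(res, dir)
  rep <- jsonlite::read_json(file.path(dir, "tmtv_report.json"))
  expect_equal(rep$tmtv_ml, res$tmtv_ml)
  expect_equal(rep$n_rois, count_rois(res))
  expect_true(file.exists(file.path(dir, "tmtv_mask.nii.gz")))
})
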