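test_that("base patients are deterministic, disjoint and non-empty", {
  p <- small_phantom_params()
  cs1 <- generate_base_patient(p, patient_seed = 5L)
  cs2 <- generate_base_patient(p, patient_seed = 5L)
  expect_identical(lapply(cs1$masks, `[[`, "voxels"),
                   lapply(cs2$masks, `[[`, "voxels"))
  cs3 <- generate_base_patient(p, patient_seed = 6L)
  expect_false(identical(cs1$masks$bladder$voxels, cs3$masks$bladder$voxels))

  expect_setequal(names(cs1$masks), oar_structures())
  total <- Reduce(`+`, lapply(cs1$masks, `[[`, "voxels"))
  expect_lte(max(total), 1L)                       # pairwise disjoint
  expect_true(all(vapply(cs1$masks, volume_mm3, 1) > 0))
})

test_that("the rasterized bladder ellipsoid matches its analytic volume", {
  p <- phantom_params(
    grid_shape = c(128L, 128L, 48L), spacing = c(1, 1, 3),
    bladder_semiaxes = c(25, 25, 20), bladder_center = c(64, 40, 96),
    rectum_center_xy = c(64, 92), femoral_centers = rbind(c(20, 90, 84),
                                                          c(108, 90, 84)),
    size_jitter = 0, center_jitter = 0
  )
  cs <- generate_base_patient(p, patient_seed = 1L)
  analytic <- 4 / 3 * pi * 25 * 25 * 20
  expect_lt(abs(volume_mm3(cs$masks$bladder) - analytic) / analytic, 0.03)
})

test_that("impossible geometry errors instead of clipping", {
  p <- small_phantom_params(size_jitter = 0, center_jitter = 0)
  p$femoral_radius <- 60
  expect_error(generate_base_patient(p, 1L), "grid|overlap")
})

test_that("the zero perturbation model is the identity", {
  p <- small_phantom_params()
  bl <- generate_base_patient(p, 2L)$masks$bladder
  out <- perturb(bl, perturbation_model(), seed = 9L)
  expect_identical(out$voxels, bl$voxels)
})

test_that("dilation bias grows volume; erosion shrinks it", {
  cube <- array(0L, c(16, 16, 16))
  cube[4:13, 4:13, 4:13] <- 1L
  v <- label_volume(cube)
  grown <- perturb(v, perturbation_model(dilation_bias = 1), seed = 1L)
  shrunk <- perturb(v, perturbation_model(dilation_bias = -1), seed = 1L)
  expect_gt(volume_mm3(grown), volume_mm3(v))
  expect_lt(volume_mm3(shrunk), volume_mm3(v))
})

test_that("perturbation is deterministic in its seed and errors on emptied masks", {
  p <- small_phantom_params()
  bl <- generate_base_patient(p, 3L)$masks$bladder
  m <- perturbation_model(translation_sd = 1, boundary_sd = 2)
  a <- perturb(bl, m, seed = 11L)
  b <- perturb(bl, m, seed = 11L)
  expect_identical(a$voxels, b$voxels)
  c <- perturb(bl, m, seed = 12L)
  expect_false(identical(a$voxels, c$voxels))

  tiny <- array(0L, c(8, 8, 8))
  tiny[4, 4, 4] <- 1L
  expect_error(perturb(label_volume(tiny),
                       perturbation_model(dilation_bias = -3), seed = 1L),
               "emptied")
})

test_that("larger boundary noise monotonically degrades agreement", {
  p <- small_phantom_params()
  bl <- generate_base_patient(p, 4L)$masks$bladder
  sds <- c(0.5, 1, 2, 4)
  n_seeds <- 8
  mean_dsc <- mean_hd <- numeric(length(sds))
  for (i in seq_along(sds)) {
    d <- h <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      pb <- perturb(bl, perturbation_model(boundary_sd = sds[i]), seed = s)
      d[s] <- dsc(bl, pb)
      h[s] <- hd95(bl, pb)
    }
    mean_dsc[i] <- mean(d)
    mean_hd[i] <- mean(h)
  }
  expect_true(all(diff(mean_dsc) < 0))
  expect_true(all(diff(mean_hd) > 0))
  expect_equal(cor(sds, mean_hd, method = "spearman"), 1)
})

test_that("generate_cohort writes the full layout with a readable manifest", {
  out <- file.path(tempdir(), "cohort-count")
  on.exit(unlink(out, recursive = TRUE))
  preset <- perturbation_preset("paper_like")
  idx <- generate_cohort(
    n_patients = 2, params = small_phantom_params(),
    observer_models = preset$observer_models,
    sequence_multipliers = preset$sequence_multipliers,
    out_dir = out, seed = 7L
  )
  # 2 patients x 3 sequences x (3 observers + GT) x 5 structures
  expect_equal(nrow(idx), 2 * 3 * 4 * 5)
  expect_equal(sum(idx$observer != "GT"), 90)
  expect_true(all(file.exists(file.path(out, idx$path))))

  re <- read_cohort_manifest(file.path(out, "manifest.csv"))
  expect_equal(nrow(re), nrow(idx))
  disc <- discover_cohort(out)
  expect_equal(nrow(disc), nrow(idx))

  cs <- load_contour_set(idx, "P01", "R1", "T1WI")
  expect_setequal(names(cs$masks), oar_structures())
})

test_that("cohort generation is a pure function of its seed and extends stably", {
  out1 <- file.path(tempdir(), "cohort-det1")
  out2 <- file.path(tempdir(), "cohort-det2")
  out3 <- file.path(tempdir(), "cohort-det3")
  on.exit(unlink(c(out1, out2, out3), recursive = TRUE))
  p <- small_phantom_params()
  models <- list(R1 = perturbation_model(boundary_sd = 1))
  i1 <- generate_cohort(2, p, models, c(T1WI = 1), out1, seed = 3L,
                        sequences = "T1WI")
  i2 <- generate_cohort(2, p, models, c(T1WI = 1), out2, seed = 3L,
                        sequences = "T1WI")
  for (r in seq_len(nrow(i1))) {
    a <- load_label_volume(file.path(out1, i1$path[r]))
    b <- load_label_volume(file.path(out2, i2$path[r]))
    expect_identical(a$voxels, b$voxels)
  }
  # adding a patient never reshuffles existing ones
  i3 <- generate_cohort(3, p, models, c(T1WI = 1), out3, seed = 3L,
                        sequences = "T1WI")
  for (r in seq_len(nrow(i1))) {
    a <- load_label_volume(file.path(out1, i1$path[r]))
    b <- load_label_volume(file.path(out3, i1$path[r]))
    expect_identical(a$voxels, b$voxels)
  }
})
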