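# Preference labeling uses a hand-built dataset in which voxel responses
# are fully controlled, plus small simulated scenarios.

test_that("labels follow the signed training contrast, patch-relatively", {
  # every voxel responds more to the plus45 grating by 2*ix (t units)
  ds <- handmade_dataset(function(info, vox) {
    if (info$condition == "plus45") 2 * vox$ix else 0
  })
  lb <- label_voxel_preferences(ds, 1, "grating")
  # plus45 is radial in patches 1 and 3, tangential in 2 and 4
  expect_equal(lb$delta_t,
               ifelse(ds$voxels$patch_id %in% c(1, 3), 2, -2) *
                 ds$voxels$ix)
  expect_equal(lb$label,
               ifelse(ds$voxels$patch_id %in% c(1, 3), "radial",
                      "tangential"))
  # label/contrast consistency invariant
  expect_true(all((lb$delta_t > 0) == (lb$label == "radial")))
})

test_that("exact ties carry no label and training subsets are honoured", {
  # contrast only in subrun 4; zero elsewhere
  ds <- handmade_dataset(function(info, vox) {
    if (info$subrun == 4 && info$condition == "plus45") 1 else 0
  })
  lb_all <- label_voxel_preferences(ds, 1, "grating")
  expect_true(all(!is.na(lb_all$label)))
  lb_train <- label_voxel_preferences(ds, 1, "grating", subruns = 1:3)
  expect_true(all(is.na(lb_train$label)))
  expect_true(all(lb_train$delta_t == 0))
  expect_error(label_voxel_preferences(ds, 1, "grating",
                                       subruns = integer(0)), "empty")
})

test_that("labels depend on training data only", {
  sc <- tiny_scenario(seed = 9, n_subjects = 1, kinds = "grating")
  ds <- generate_dataset(sc)
  lb <- label_voxel_preferences(ds, 1, "grating", subruns = c(1, 2, 3))
  # perturb the held-out subrun arbitrarily
  ds2 <- ds
  rows <- ds2$info$subrun == 4
  set.seed(1)
  ds2$t[rows, ] <- matrix(rnorm(sum(rows) * ncol(ds2$t)) * 100, sum(rows))
  lb2 <- label_voxel_preferences(ds2, 1, "grating", subruns = c(1, 2, 3))
  expect_identical(lb, lb2)
})

test_that("voxel sets are disjoint, exhaustive and flag emptiness", {
  ds <- handmade_dataset(function(info, vox) {
    s <- if (vox$ix == 2) -1 else 1           # voxels with ix == 2 invert
    if (info$condition == "plus45") s else 0
  })
  lb <- label_voxel_preferences(ds, 1, "grating")
  sets <- split_voxel_sets(lb)
  expect_length(intersect(sets$A, sets$B), 0)
  expect_setequal(c(sets$A, sets$B), lb$voxel[!is.na(lb$label)])
  expect_false(any(sets$empty))
  # all voxels one label: the other set is empty and flagged
  ds1 <- handmade_dataset(function(info, vox) {
    if (info$condition == "plus45") ifelse(vox$patch_id %in% c(1, 3), 1, -1)
    else 0
  })
  sets1 <- split_voxel_sets(label_voxel_preferences(ds1, 1, "grating"))
  expect_length(sets1$B, 0)
  expect_true(sets1$empty[["B"]])
})

test_that("proportion summaries count labels correctly", {
  # 3 voxels radial-preferring, 1 tangential-preferring, per subject
  ds <- handmade_dataset(function(info, vox) {
    pref <- if (vox$patch_id == 1 && vox$ix == 1) -1 else 1
    s <- if (vox$patch_id %in% c(1, 3)) 1 else -1   # patch-relative sign
    if (info$condition == "plus45") pref * s else 0
  }, n_subjects = 2)
  # only patch 1 has a tangential voxel: over all 12 voxels, 11 vs 1
  ps <- preference_proportions(ds)
  expect_equal(ps$per_subject$n_ref, c(11, 11))
  expect_equal(ps$per_subject$n_anti, c(1, 1))
  expect_equal(ps$per_subject$pct_ref, c(100 * 11 / 12, 100 * 11 / 12))
  # histogram pooling count = sum over subjects of labeled voxels
  expect_equal(nrow(ps$histogram), 24L)
  # 3 radial vs 1 tangential toy: 75% / 25%
  ds2 <- handmade_dataset(function(info, vox) {
    pref <- if (vox$ix == 1 && vox$patch_id != 1) -1 else 1
    s <- if (vox$patch_id %in% c(1, 3)) 1 else -1
    if (info$condition == "plus45") pref * s else 0
  }, n_subjects = 2)
  ps2 <- preference_proportions(ds2)
  expect_equal(ps2$per_subject$pct_ref[1], 75)
  expect_equal(ps2$per_subject$pct_anti[1], 25)
})

test_that("mixed worlds show the radial and vertical biases at n = 18", {
  ds <- generate_dataset(scenario_mixed(seed = 4))
  ps <- preference_proportions(ds)
  g <- ps$group
  # radial and vertical majorities with a significant group test
  expect_true(all(g$pooled_pct_ref > 50))
  one_sided <- vapply(c("grating", "spiral"), function(k) {
    d <- ps$per_subject[ps$per_subject$kind == k, ]
    across_subject_ttest(d$diff_pct, two_sided = FALSE)$p
  }, numeric(1))
  expect_true(all(one_sided < 0.05))
  # amplitude-channel contrasts at the calibrated order (percent signal
  # change)
  expect_equal(g$mean_contrast_psc[g$kind == "grating"], 0.038,
               tolerance = 0.2)
  expect_equal(g$mean_contrast_psc[g$kind == "spiral"], 0.031,
               tolerance = 0.2)
})

test_that("coarse-only noise-free labeling is unanimous", {
  ds <- generate_dataset(scenario_coarse_only(
    seed = 2, n_subjects = 2, nu = 6L, nv = 4L,
    noise = noise_params(sigma_pattern = 0, sigma_subject = 0)))
  for (s in 1:2) for (k in c("grating", "spiral")) {
    lb <- label_voxel_preferences(ds, s, k)
    expect_true(all(lb$label == orivox:::reference_labels(k)[["ref"]]))
  }
})
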