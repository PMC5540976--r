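test_that("the replicability index is the normalised inner product", {
  expect_equal(replicability_index(c(1, 3, -2), c(1, 3, -2)), 1)
  expect_equal(replicability_index(c(1, 3, -2), -c(1, 3, -2)), -1)
  expect_equal(replicability_index(c(1, 2), c(2, 1)), 0.8)
  expect_error(replicability_index(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(replicability_index(1:3, 1:2), "same voxels")
  expect_error(replicability_index(numeric(0), numeric(0)), "empty")
})

test_that("the index is scale-invariant up to sign", {
  set.seed(42)
  for (i in 1:25) {
    u <- rnorm(10)
    v <- rnorm(10)
    a <- runif(1, -5, 5)
    b <- runif(1, -5, 5)
    if (a == 0 || b == 0) next
    expect_equal(replicability_index(a * u, b * v),
                 sign(a * b) * replicability_index(u, v), tolerance = 1e-12)
  }
})

test_that("the index is unbiased under independence and differs from Pearson", {
  set.seed(7)
  n_draws <- 10000
  vals <- vapply(seq_len(n_draws), function(i)
    replicability_index(rnorm(20), rnorm(20)), numeric(1))
  expect_true(all(vals >= -1 & vals <= 1))
  se <- sd(vals) / sqrt(n_draws)
  expect_lt(abs(mean(vals)), 3 * se)
  # positive Pearson correlation but sign-mismatched vectors: the
  # no-centering contract forces the index below the Pearson r
  u <- c(1, 2)
  v <- c(-3, -1)
  expect_gt(stats::cor(u, v), 0)
  expect_lt(replicability_index(u, v), stats::cor(u, v))
  expect_lt(replicability_index(u, v), 0)
})

test_that("noise-free mixed worlds replicate perfectly", {
  ds <- generate_dataset(scenario_mixed(
    seed = 5, n_subjects = 2, nu = 6L, nv = 4L,
    noise = noise_params(sigma_pattern = 0, sigma_subject = 0)))
  res <- crossval_replicability(ds)
  expect_true(all(abs(res$index[!is.na(res$index)] - 1) < 1e-9))
  expect_true(all(res$n_folds[!is.na(res$index)] >= 1))
})

test_that("noise-selected minority voxels revert in coarse-only worlds", {
  vals <- vapply(1:10, function(i) {
    ds <- generate_dataset(scenario_coarse_only(seed = 400 + i,
                                                n_subjects = 3, nu = 6L,
                                                nv = 4L,
                                                kinds = "grating"))
    res <- crossval_replicability(ds)
    mean(res$index[res$set == "tangential" & res$roi == "combined"],
         na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(vals), 0)
})

test_that("participant bootstrap has add-one one-sided p and honest CIs", {
  bt <- bootstrap_group_test(rep(0.3, 18), n_boot = 10000, seed = 2)
  expect_equal(bt$p, 1 / 10001)
  expect_equal(bt$mean, 0.3)
  expect_true(bt$ci_lo <= bt$mean && bt$mean <= bt$ci_hi)
  # values symmetric about 0: p close to 1/2
  set.seed(6)
  half <- rnorm(9)
  bt2 <- bootstrap_group_test(c(half, -half), n_boot = 10000, seed = 3)
  expect_lt(abs(bt2$p - 0.5), 0.02)
  # deterministic given seed
  x <- rnorm(12)
  expect_identical(bootstrap_group_test(x, 500, seed = 11),
                   bootstrap_group_test(x, 500, seed = 11))
  expect_error(bootstrap_group_test(0.3), "at least 2")
})

test_that("group summaries cover every orientation set and ROI", {
  ds <- generate_dataset(tiny_scenario(seed = 14, n_subjects = 3))
  res <- crossval_replicability(ds)
  summ <- replicability_summary(res, n_boot = 200, seed = 1)
  # 4 orientation sets x (1 combined + 4 quarterfields + 3 bands)
  expect_equal(nrow(summ), 32L)
  expect_setequal(unique(summ$set),
                  c("radial", "tangential", "vertical", "horizontal"))
  expect_setequal(unique(summ$roi),
                  c("combined", paste0("Q", 1:4), paste0("E", 1:3)))
  ok <- !is.na(summ$mean)
  expect_true(all(summ$ci_lo[ok] <= summ$mean[ok] &
                    summ$mean[ok] <= summ$ci_hi[ok]))
  expect_true(all(summ$p[ok] > 0 & summ$p[ok] <= 1))
  # point estimates do not depend on n_boot
  summ2 <- replicability_summary(res, n_boot = 400, seed = 1)
  expect_equal(summ$mean, summ2$mean)
})

test_that("ROI ANOVAs are calibrated and reject separated means", {
  fake <- function(values, rois) {
    d <- expand.grid(subject = seq_len(length(values) / length(rois)),
                     roi = rois)
    d$index <- values
    d$kind <- "grating"
    d$set <- "radial"
    class(d) <- c("replicability_result", "data.frame")
    d
  }
  set.seed(511)
  rej <- mean(vapply(1:1000, function(i) {
    r <- fake(rnorm(72), paste0("Q", 1:4))
    roi_effect_anova(r, "quarterfield")$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # strong separation: tiny p
  r <- fake(c(rnorm(18), rnorm(18, 5), rnorm(18), rnorm(18, 5)),
            paste0("Q", 1:4))
  expect_lt(roi_effect_anova(r, "quarterfield")$p, 0.001)
  # single factor level is rejected
  r1 <- fake(rnorm(18), "Q1")
  expect_error(roi_effect_anova(r1, "quarterfield"), "levels")
})
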