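test_that("gamma HRF kernels are normalised, delayed and peak at the mode", {
  h <- boynton_hrf(hrf_params(), dt = 0.1, duration = 32)
  expect_true(all(h >= 0))
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # gamma mode: argmax at (n-1)*tau within one sample
  t <- seq(0, 32, by = 0.1)
  expect_lt(abs(t[which.max(h)] - 2 * 1.25), 0.1 + 1e-9)
  # pure delay: kernel identically zero before onset_delay
  h5 <- boynton_hrf(hrf_params(onset_delay = 5), dt = 0.1, duration = 32)
  expect_true(all(h5[t < 5] == 0))
  expect_error(hrf_params(tau = 0), "tau")
  expect_error(hrf_params(n = 0), "n must be")
})

test_that("block schedule honours both alternation rules", {
  sched <- block_schedule(block_design())
  expect_equal(nrow(sched), 24L) # 4 subruns x 6 blocks
  for (k in 1:4) {
    conds <- sched$condition[sched$subrun == k]
    expect_equal(as.vector(table(conds)), c(3L, 3L)) # 3 blocks per exemplar
    expect_true(all(abs(diff(conds)) == 1L))         # alternating
    expect_equal(conds[1], ((k - 1L) %% 2L) + 1L)    # leading alternates
  }
  expect_error(block_design(gap_s = -1), "overlap")
})

test_that("design matrices have the canonical predictor layout", {
  X <- build_design_matrix()
  expect_equal(ncol(X), 9L) # 2 conditions x 4 subruns + intercept
  expect_equal(length(attr(X, "task_cols")), 8L)
  expect_equal(nrow(X), 240L)
  # column count = conditions*subruns + confounds + 1 across designs
  X3 <- build_design_matrix(confounds = 3)
  expect_equal(ncol(X3), 12L)
  d2 <- block_design(subruns_per_run = 2L)
  expect_equal(ncol(build_design_matrix(d2, confounds = 1)), 6L)
  # unconvolved boxcars: one 14-s block at TR 2 covers 7 volumes, and each
  # predictor holds 3 blocks
  B <- build_design_matrix(convolve = FALSE)
  task <- B[, attr(B, "task_cols")]
  expect_equal(unname(colSums(task)), rep(3 * 7, 8))
  # predictors of different subruns have disjoint pre-convolution support
  lab <- attr(B, "labels")
  for (i in 1:8) for (j in seq_len(8)[-i]) {
    if (lab$subrun[i] != lab$subrun[j])
      expect_equal(sum(task[, i] * task[, j]), 0)
  }
  expect_error(build_design_matrix(confounds = -1), "confounds")
})

test_that("OLS recovers noise-free effects exactly", {
  X <- build_design_matrix()
  beta_true <- c(5, seq(0.5, 4, by = 0.5))
  y <- X %*% beta_true
  fit <- fit_tpatterns(y, X)
  expect_equal(as.vector(fit$beta_all), beta_true, tolerance = 1e-8)
  # exactly zero residual variance is flagged
  expect_warning(fit_tpatterns(matrix(0, nrow(X), 2), X),
                 "zero residual variance")
  # rank-deficient designs are rejected
  expect_error(fit_tpatterns(y, cbind(X, X[, 2])), "singular")
})

test_that("t-values match a long-hand normal-equations oracle", {
  # printed 12-sample fixture
  X <- cbind(1,
             c(0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0),
             c(0.2, 0.5, 1.1, 0.4, -0.3, 0.9, 1.4, 0.1, -0.2, 0.7, 1.2, 0))
  y <- cbind(c(1.2, 3.4, 2.9, 0.8, 0.4, 3.8, 3.1, 1.1, 0.6, 3.3, 3.5, 0.9),
             c(0.1, -0.4, 0.3, 0.2, -0.1, 0.5, -0.6, 0.0, 0.2, -0.2, 0.4,
               0.1))
  # brute-force oracle: normal equations and t computed long-hand
  xtx <- t(X) %*% X
  xtx_inv <- solve(xtx)
  bhat <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% bhat
  s2 <- colSums(resid^2) / (12 - 3)
  t_oracle <- bhat / sqrt(outer(diag(xtx_inv), s2))
  fit <- fit_tpatterns(y, X)
  expect_equal(unname(fit$t), unname(t_oracle), tolerance = 1e-10)
  expect_equal(fit$dof, 9L)
})

test_that("pure-noise t-values follow the Student-t reference", {
  X <- build_design_matrix()
  set.seed(914)
  Y <- matrix(rnorm(nrow(X) * 10000), nrow(X))
  fit <- fit_tpatterns(Y, X)
  ks <- suppressWarnings(stats::ks.test(fit$t[3, ], stats::pt,
                                        df = fit$dof))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated time series equal the convolution oracle", {
  design <- block_design()
  hrf <- hrf_params()
  amp <- matrix(c(1, 0), 1) # one voxel responds to condition 1 only
  Y <- generate_timeseries(design, amp, hrf, noise_sd = 0, seed = 1)
  # direct-summation oracle at one voxel: sum over block onsets of the
  # sampled kernel
  dt <- 0.1
  kern <- boynton_hrf(hrf, dt = dt, duration = 32)
  sched <- block_schedule(design)
  on1 <- sched$onset_s[sched$condition == 1]
  tvol <- (seq_len(design$run_volumes) - 1) * design$TR
  oracle <- vapply(tvol, function(tt) {
    s <- 0
    for (on in on1) {
      lag <- tt - (on + (seq_along(kern) - 1) * dt)
      s <- s + sum(kern[lag >= 0 & lag < design$block_s])
    }
    s
  }, numeric(1))
  expect_equal(as.vector(Y[, 1]), oracle, tolerance = 1e-10)
  # zero amplitudes, zero noise: identically zero series
  Y0 <- generate_timeseries(design, matrix(0, 3, 2), hrf, noise_sd = 0,
                            seed = 1)
  expect_equal(max(abs(Y0)), 0)
})

test_that("pattern-level and timeseries-level modes agree in expectation", {
  set.seed(77)
  design <- block_design()
  nvox <- 100
  amp <- cbind(2 + rnorm(nvox, 0, 0.05), 2 + rnorm(nvox, 0, 0.05))
  X <- build_design_matrix(design)
  lab <- attr(X, "labels")
  tc <- matrix(0, 200, nvox)
  for (i in 1:200) {
    Y <- generate_timeseries(design, amp, noise_sd = 1, seed = 5000 + i)
    f <- fit_tpatterns(Y, X)
    tc[i, ] <- colMeans(f$t[lab$condition == 1, , drop = FALSE]) -
      colMeans(f$t[lab$condition == 2, , drop = FALSE])
  }
  expected <- (amp[, 1] - amp[, 2]) /
    orivox:::amplitude_t_scale(design, noise_params())
  expect_gt(stats::cor(colMeans(tc), expected, method = "spearman"), 0.95)
})

test_that("timeseries-fidelity datasets carry the same structure", {
  sc <- scenario_mixed(seed = 19, n_subjects = 1, nu = 3L, nv = 2L,
                       kinds = "grating", fidelity = "timeseries")
  ds <- generate_dataset(sc)
  expect_equal(nrow(ds$t), 16L)
  expect_true(all(is.finite(ds$t)))
  expect_identical(ds$t, generate_dataset(sc)$t)
})
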