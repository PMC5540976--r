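test_that("orientation maps are deterministic, uniform and band-pass", {
  grid <- voxel_grid()
  m <- neural_map_params()
  th1 <- generate_orientation_map(m, grid, seed = 1)
  th2 <- generate_orientation_map(m, grid, seed = 1)
  expect_identical(th1, th2)
  expect_true(all(th1 >= 0 & th1 < 180))
  # preference histogram uniform on [0, 180): chi-square GoF over 18 bins
  cnt <- table(cut(as.vector(th1), breaks = seq(0, 180, by = 10)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
  # radially averaged power spectrum of exp(2i theta) peaks near the
  # columnar frequency (within 20%)
  z <- exp(2i * th1 * pi / 180)
  P <- Mod(stats::fft(z))^2
  P[1, 1] <- 0
  fm <- sqrt(outer(orivox:::fft_freq(nrow(z), grid$column_pitch_mm)^2,
                   orivox:::fft_freq(ncol(z), grid$column_pitch_mm)^2, "+"))
  br <- seq(0, max(fm), length.out = 40)
  pw <- tapply(as.vector(P), cut(as.vector(fm), br), mean)
  peak <- ((br[-1] + br[-length(br)]) / 2)[which.max(pw)]
  f0 <- 1 / m$columnar_period_mm
  expect_lt(abs(peak - f0) / f0, 0.2)
  # unresolvable columnar period is rejected
  bad <- neural_map_params(columnar_period_mm = 0.3)
  expect_error(generate_orientation_map(bad, grid, seed = 1), "resolvable")
})

test_that("columnar responses follow the cosine model closed forms", {
  grid <- voxel_grid(nu = 3L, nv = 2L)
  coords <- patch_column_coords(grid, 1)
  b <- 2
  # tuning maximum: preference equals stimulus orientation everywhere
  m <- neural_map_params(a_col = 0.4, a_rad = 0, a_vert = 0, baseline = b)
  stim <- stimulus_spec("grating", "plus45")
  pref <- matrix(45, nrow(coords$ecc), ncol(coords$ecc))
  expect_equal(columnar_response(pref, stim, m, coords),
               matrix(b * 1.4, nrow(pref), ncol(pref)))
  # coarse radial term only: radial grating at columns on the patch meridian
  m2 <- neural_map_params(a_col = 0, a_rad = 0.01, a_vert = 0, baseline = b)
  R1 <- columnar_response(pref, stim, m2, coords)
  R2 <- columnar_response(pref, stimulus_spec("grating", "minus45"), m2,
                          coords)
  onaxis <- abs(coords$polar - 45) < 1e-9
  expect_equal(R1[onaxis], rep(b * 1.01, sum(onaxis)))
  # gratings contrast: exactly 2*b*a_rad at the patch meridian, and
  # sign-uniform (the coarse-scale homogeneous effect) across the patch
  expect_equal((R1 - R2)[onaxis], rep(2 * b * 0.01, sum(onaxis)))
  expect_true(all(R1 - R2 > 0))
  # a narrow patch makes the closed form hold everywhere to high accuracy
  coords_narrow <- coords
  coords_narrow$polar[] <- 45 + (coords$polar - 45) * 1e-3
  Rn <- columnar_response(pref, stim, m2, coords_narrow) -
    columnar_response(pref, stimulus_spec("grating", "minus45"), m2,
                      coords_narrow)
  expect_equal(Rn, matrix(2 * b * 0.01, nrow(Rn), ncol(Rn)),
               tolerance = 1e-6)
  # spirals are radially balanced: the a_rad term cancels exactly
  sp <- columnar_response(pref, stimulus_spec("spiral", "clockwise"), m2,
                          coords) -
    columnar_response(pref, stimulus_spec("spiral", "anticlockwise"), m2,
                      coords)
  expect_equal(sp, matrix(0, nrow(sp), ncol(sp)), tolerance = 1e-12)
})

test_that("voxel sampling is gain-weighted footprint averaging", {
  # uniform response: every voxel is gain * constant
  R <- matrix(3, 8, 8)
  g <- c(0.5, 1, 2, 4)
  expect_equal(sample_voxels(R, g, 4L), 3 * g)
  # identity gains: plain footprint means
  R2 <- matrix(seq_len(16), 4, 4)
  expect_equal(sample_voxels(R2, rep(1, 4), 2L),
               c(mean(R2[1:2, 1:2]), mean(R2[3:4, 1:2]),
                 mean(R2[1:2, 3:4]), mean(R2[3:4, 3:4])))
  # 4x4 column sheet, 2x2-column voxels, hand-set R and gains:
  # hand-computed products (arithmetic oracle)
  R3 <- matrix(c(1, 2, 3, 4,
                 5, 6, 7, 8,
                 9, 10, 11, 12,
                 13, 14, 15, 16), 4, 4, byrow = TRUE)
  g3 <- c(2, 0.5, 3, 10)
  # voxel means (column-major voxel order, rows = first axis):
  # [1:2,1:2]=(1+2+5+6)/4=3.5, [3:4,1:2]=(9+10+13+14)/4=11.5,
  # [1:2,3:4]=(3+4+7+8)/4=5.5, [3:4,3:4]=(11+12+15+16)/4=13.5
  expect_equal(sample_voxels(R3, g3, 2L),
               c(2 * 3.5, 0.5 * 11.5, 3 * 5.5, 10 * 13.5))
  expect_error(sample_voxels(matrix(1, 5, 4), rep(1, 4), 2L), "tile")
  expect_error(sample_voxels(matrix(1, 4, 4), c(1, 1, 1, 0), 2L),
               "positive")
})

test_that("datasets have the canonical shape and are bit-reproducible", {
  sc <- tiny_scenario(seed = 42, n_subjects = 2)
  ds <- generate_dataset(sc)
  # 8 t-patterns per condition per subject per stimulus kind
  for (k in unique(ds$info$kind)) {
    sub <- ds$info[ds$info$kind == k, ]
    expect_true(all(table(sub$subject, sub$condition) == 8L))
  }
  expect_true(all(is.finite(ds$t)))
  expect_identical(ds$t, generate_dataset(sc)$t)
  # adding subjects never perturbs existing ones
  ds3 <- generate_dataset(tiny_scenario(seed = 42, n_subjects = 3))
  expect_identical(ds$t, ds3$t[ds3$info$subject <= 2, ])
  # strictly positive gains
  expect_true(all(ds$gains > 0))
})

test_that("no signal and no noise gives identical patterns within subject", {
  m <- neural_map_params(a_col = 0, a_rad = 0, a_vert = 0)
  sc <- scenario("mixed", n_subjects = 1, seed = 3, map = m,
                 noise = noise_params(sigma_pattern = 0, sigma_subject = 0),
                 nu = 3L, nv = 2L, kinds = "grating")
  ds <- generate_dataset(sc)
  expect_equal(max(apply(ds$t, 2, function(x) diff(range(x)))), 0)
})

test_that("pattern-mode noise SD matches sigma_pattern", {
  # ~1000 noise-only subrun patterns: empirical per-voxel SD within 5%
  m <- neural_map_params(a_col = 0, a_rad = 0, a_vert = 0)
  sc <- scenario("mixed", n_subjects = 63, seed = 8, map = m,
                 noise = noise_params(sigma_pattern = 0.8,
                                      sigma_subject = 0),
                 nu = 3L, nv = 1L, kinds = "grating")
  ds <- generate_dataset(sc)
  # remove the per-subject deterministic amplitude component (gains differ
  # across subjects), pool residuals
  ss <- 0
  n <- 0
  for (s in unique(ds$info$subject)) {
    r <- ds$t[ds$info$subject == s, , drop = FALSE]
    r <- sweep(r, 2, colMeans(r))
    ss <- ss + sum(r^2)
    n <- n + (nrow(r) - 1) * ncol(r)
  }
  expect_lt(abs(sqrt(ss / n) - 0.8) / 0.8, 0.05)
})

test_that("positive gain fields preserve contrast signs", {
  # identical scenario except gain dispersion: noise-free amplitude
  # contrasts must agree in sign voxel by voxel
  base <- list(n_subjects = 2, nu = 6L, nv = 4L, kinds = "grating",
               noise = noise_params(sigma_pattern = 0, sigma_subject = 0))
  d1 <- generate_dataset(do.call(scenario_mixed,
                                 c(list(seed = 21), base,
                                   list(gain = gain_field_params(0.6)))))
  d0 <- generate_dataset(do.call(scenario_mixed,
                                 c(list(seed = 21), base,
                                   list(gain = gain_field_params(0)))))
  expect_true(all(d0$gains == 1))
  for (s in 1:2) {
    a1 <- d1$amplitude[d1$amp_info$subject == s, ]
    a0 <- d0$amplitude[d0$amp_info$subject == s, ]
    expect_identical(sign(a1[1, ] - a1[2, ]), sign(a0[1, ] - a0[2, ]))
  }
})

test_that("fine-only worlds split preferences 50/50 across seeds", {
  p_ref <- n_lab <- 0
  for (i in 1:40) {
    ds <- generate_dataset(scenario_fine_only(seed = 100 + i,
                                              n_subjects = 2, nu = 6L,
                                              nv = 4L, kinds = "grating"))
    for (s in 1:2) {
      lb <- label_voxel_preferences(ds, s, "grating")
      p_ref <- p_ref + sum(lb$label == "radial", na.rm = TRUE)
      n_lab <- n_lab + sum(!is.na(lb$label))
    }
  }
  # grand-mean radial proportion within the 99% binomial CI of 50%
  expect_lt(abs(p_ref / n_lab - 0.5), 2.576 * 0.5 / sqrt(n_lab))
})

test_that("scenario invariants are enforced", {
  expect_error(scenario("coarse_only", seed = 1), "a_col = 0")
  expect_error(scenario("fine_only", seed = 1), "a_rad = a_vert = 0")
  expect_error(scenario("mixed"), "seed")
  expect_error(neural_map_params(a_col = 0.7, a_rad = 0.2, a_vert = 0.2),
               "< 1")
  expect_error(neural_map_params(a_rad = -0.1), ">= 0")
})
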