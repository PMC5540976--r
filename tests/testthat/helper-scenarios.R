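# Small scenarios and hand-built datasets shared across tests.

tiny_scenario <- function(name = "mixed", seed = 1, n_subjects = 3,
                          kinds = c("grating", "spiral"), ...) {
  ctor <- switch(name, mixed = scenario_mixed,
                 coarse_only = scenario_coarse_only,
                 fine_only = scenario_fine_only)
  ctor(seed = seed, n_subjects = n_subjects, nu = 6L, nv = 4L,
       kinds = kinds, ...)
}

# A minimal hand-built pattern_dataset over a 3x1-voxel-per-patch grid
# (12 voxels), with t-values chosen per test. `maker(info_row, voxel)` fills
# the matrix.
handmade_dataset <- function(maker, kinds = "grating", n_subjects = 1) {
  grid <- voxel_grid(nu = 3L, nv = 1L)
  combos <- expand.grid(condition_i = 1:2, subrun = 1:4, run = 1:2,
                        kind = kinds, subject = seq_len(n_subjects),
                        stringsAsFactors = FALSE)
  info <- data.frame(subject = combos$subject, kind = combos$kind,
                     run = combos$run, subrun = combos$subrun,
                     condition = mapply(function(k, i)
                       orivox:::stimulus_variants(k)[i],
                       combos$kind, combos$condition_i),
                     stringsAsFactors = FALSE)
  ord <- order(info$subject, info$kind, info$run, info$subrun,
               match(info$condition,
                     c("plus45", "minus45", "clockwise", "anticlockwise")))
  info <- info[ord, ]
  rownames(info) <- NULL
  tmat <- matrix(0, nrow(info), nrow(grid$voxels))
  for (i in seq_len(nrow(info)))
    for (v in seq_len(nrow(grid$voxels)))
      tmat[i, v] <- maker(info[i, ], grid$voxels[v, ])
  structure(list(t = tmat, info = info, voxels = grid$voxels,
                 amplitude = NULL, amp_info = NULL, gains = NULL,
                 grid = grid, scenario = NULL, t_scale = NA_real_),
            class = "pattern_dataset")
}

# 95% t-based confidence interval of a mean
ci95 <- function(x) as.numeric(stats::t.test(x)$conf.int)
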