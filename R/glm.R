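# Block-design GLM: design matrices, gamma HRF, per-voxel OLS t-patterns.

#' Gamma hemodynamic response function parameters
#'
#' The single-gamma HRF \eqn{h(t) = ((t-\delta)/\tau)^{n-1}
#' e^{-(t-\delta)/\tau}} for \eqn{t \ge \delta} (0 before the onset delay),
#' rescaled to unit sum when sampled. Defaults `n = 3`, `tau = 1.25` s,
#' `onset_delay = 0` are the simplest published parameterisation of this
#' family; all three are configurable.
#'
#' @param n integer shape parameter (`>= 1`).
#' @param tau time constant in seconds (`> 0`).
#' @param onset_delay pure delay in seconds (`>= 0`).
#' @return an object of class `hrf_params`.
#' @export
hrf_params <- function(n = 3L, tau = 1.25, onset_delay = 0) {
  if (!is_count(n)) stop_("hrf shape parameter n must be an integer >= 1")
  if (!is_num1(tau) || tau <= 0) stop_("hrf tau must be > 0")
  if (!is_num1(onset_delay) || onset_delay < 0)
    stop_("hrf onset_delay must be >= 0")
  structure(list(n = as.integer(n), tau = tau, onset_delay = onset_delay),
            class = "hrf_params")
}

#' Sampled gamma HRF kernel
#'
#' @param params an [hrf_params()].
#' @param dt sampling step in seconds.
#' @param duration kernel support to cover, seconds.
#' @return numeric vector of non-negative samples at `0, dt, 2*dt, ...`
#'   summing to 1.
#' @examples
#' h <- boynton_hrf(hrf_params(), dt = 0.1, duration = 32)
#' sum(h) # 1
#' @export
boynton_hrf <- function(params = hrf_params(), dt, duration = 32) {
  stopifnot(inherits(params, "hrf_params"))
  if (!is_num1(dt) || dt <= 0) stop_("dt must be > 0")
  if (!is_num1(duration) || duration <= dt)
    stop_("duration must cover the kernel support")
  t <- seq(0, duration, by = dt)
  s <- (t - params$onset_delay) / params$tau
  h <- ifelse(s >= 0, s^(params$n - 1L) * exp(-s), 0)
  if (params$n == 1L) h[s < 0] <- 0 # 0^0 guard
  tot <- sum(h)
  if (tot <= 0) stop_("degenerate HRF: kernel sums to zero over 'duration'")
  h / tot
}

#' Block design of one scanner run
#'
#' One run is divided into `subruns_per_run` equal subruns; each subrun
#' contains `blocks_per_subrun` stimulus blocks (half per condition), with
#' conditions alternating across blocks and the leading condition
#' alternating across subruns. Each block lasts `block_s` seconds and is
#' preceded by `gap_s` seconds of fixation, so a subrun lasts
#' `blocks_per_subrun * (block_s + gap_s)` seconds exactly.
#'
#' @param TR repetition time in seconds.
#' @param subruns_per_run number of subruns.
#' @param blocks_per_subrun number of stimulus blocks per subrun (must be a
#'   multiple of `conditions`).
#' @param block_s block duration, seconds.
#' @param gap_s fixation gap before each block, seconds (`>= 0`; a negative
#'   gap would make blocks overlap and is rejected).
#' @param conditions number of stimulus conditions (2: the two orthogonal
#'   variants of one stimulus kind).
#' @param presentation_hz stimulus presentation rate within a block.
#' @return an object of class `block_design`; `$run_volumes` gives the
#'   number of volumes per run and `$presentations_per_block` the number of
#'   stimuli shown per block.
#' @examples
#' block_design()$run_volumes # 240
#' @export
block_design <- function(TR = 2, subruns_per_run = 4L, blocks_per_subrun = 6L,
                         block_s = 14, gap_s = 6, conditions = 2L,
                         presentation_hz = 2) {
  if (!is_num1(TR) || TR <= 0) stop_("TR must be > 0")
  if (!is_count(subruns_per_run) || !is_count(blocks_per_subrun) ||
      !is_count(conditions))
    stop_("counts in a block design must be positive integers")
  if (!is_num1(block_s) || block_s <= 0) stop_("block_s must be > 0")
  if (!is_num1(gap_s) || gap_s < 0)
    stop_("invalid design: blocks overlap (gap_s < 0)")
  if (blocks_per_subrun %% conditions != 0L)
    stop_("blocks_per_subrun must be a multiple of conditions")
  subrun_s <- blocks_per_subrun * (block_s + gap_s)
  run_s <- subruns_per_run * subrun_s
  if (abs(run_s / TR - round(run_s / TR)) > 1e-9)
    stop_("TR must divide the run length")
  structure(list(TR = TR, subruns_per_run = as.integer(subruns_per_run),
                 blocks_per_subrun = as.integer(blocks_per_subrun),
                 block_s = block_s, gap_s = gap_s,
                 conditions = as.integer(conditions),
                 presentation_hz = presentation_hz,
                 subrun_s = subrun_s, run_s = run_s,
                 run_volumes = as.integer(round(run_s / TR)),
                 presentations_per_block = block_s * presentation_hz),
            class = "block_design")
}

#' Block schedule of one run
#'
#' Expands a [block_design()] into one row per block with its onset and
#' condition, honouring the alternation rules: conditions alternate across
#' blocks within a subrun, and the leading condition alternates across
#' subruns (subrun 1 leads with condition 1, subrun 2 with condition 2, ...).
#'
#' @param design a [block_design()].
#' @return data frame with columns `subrun`, `block`, `onset_s`, `condition`.
#' @export
block_schedule <- function(design = block_design()) {
  stopifnot(inherits(design, "block_design"))
  out <- do.call(rbind, lapply(seq_len(design$subruns_per_run), function(k) {
    lead <- ((k - 1L) %% design$conditions) + 1L
    b <- seq_len(design$blocks_per_subrun)
    cond <- ((lead - 1L + (b - 1L)) %% design$conditions) + 1L
    data.frame(subrun = k, block = b,
               onset_s = (k - 1L) * design$subrun_s + design$gap_s +
                 (b - 1L) * (design$block_s + design$gap_s),
               condition = cond)
  }))
  rownames(out) <- NULL
  out
}

#' Build a block-design matrix with subrun-wise condition predictors
#'
#' One predictor per (condition, subrun) pair - boxcars over that
#' condition's blocks within that subrun, convolved with the gamma HRF and
#' sampled at volume acquisition times - plus an intercept and optional
#' polynomial drift columns.
#'
#' @param design a [block_design()].
#' @param hrf an [hrf_params()].
#' @param confounds number of polynomial drift regressors (0 for none).
#' @param convolve if `FALSE`, return the raw boxcars instead of
#'   HRF-convolved predictors (useful for audit).
#' @param dt microtime resolution (seconds) used for convolution.
#' @return numeric matrix `run_volumes x (conditions*subruns + confounds +
#'   1)` with column names; attribute `"task_cols"` indexes the task
#'   predictors and attribute `"labels"` is a data frame mapping task
#'   columns to (condition, subrun).
#' @export
build_design_matrix <- function(design = block_design(), hrf = hrf_params(),
                                confounds = 0L, convolve = TRUE, dt = 0.1) {
  stopifnot(inherits(design, "block_design"))
  if (!is.numeric(confounds) || length(confounds) != 1L || confounds < 0 ||
      confounds != round(confounds))
    stop_("confounds must be a non-negative integer count")
  sched <- block_schedule(design)
  nt <- as.integer(round(design$run_s / dt))
  kern <- boynton_hrf(hrf, dt = dt, duration = 32)
  vol_idx <- as.integer(round((seq_len(design$run_volumes) - 1L) *
                                design$TR / dt)) + 1L
  labels <- expand.grid(subrun = seq_len(design$subruns_per_run),
                        condition = seq_len(design$conditions))
  labels <- labels[, c("condition", "subrun")]
  task <- vapply(seq_len(nrow(labels)), function(j) {
    rows <- sched$condition == labels$condition[j] &
      sched$subrun == labels$subrun[j]
    x <- numeric(nt)
    for (on in sched$onset_s[rows]) {
      i0 <- as.integer(round(on / dt)) + 1L
      i1 <- as.integer(round((on + design$block_s) / dt))
      x[i0:i1] <- 1
    }
    if (convolve)
      x <- stats::convolve(x, rev(kern), type = "open")[seq_len(nt)]
    x[vol_idx]
  }, numeric(design$run_volumes))
  colnames(task) <- sprintf("cond%d_subrun%d", labels$condition,
                            labels$subrun)
  X <- cbind(intercept = 1, task)
  if (confounds > 0L) {
    drift <- stats::poly(seq_len(design$run_volumes), degree = confounds)
    colnames(drift) <- sprintf("drift%d", seq_len(confounds))
    X <- cbind(X, drift)
  }
  attr(X, "task_cols") <- 1L + seq_len(nrow(labels))
  labels$column <- colnames(task)
  attr(X, "labels") <- labels
  X
}

#' Fit per-voxel OLS and return t-value patterns
#'
#' Ordinary least squares of each voxel's time series on the design matrix;
#' `t = beta / SE(beta)` with residual degrees of freedom `volumes -
#' rank(X)`. This is the massively univariate GLM that turns simulated (or
#' imported) time series into the per-subrun t-patterns that are the
#' currency of all downstream analyses.
#'
#' @param series numeric matrix (volumes x voxels) or vector.
#' @param X design matrix from [build_design_matrix()] (must be full column
#'   rank).
#' @return list of class `glm_fit` with elements `beta` and `t` (predictors
#'   x voxels, task predictors only; the full coefficient matrix is in
#'   `beta_all`), `dof`, and `labels` (the task-column map). Voxels with
#'   zero residual variance yield `NA` t-values with a warning.
#' @export
fit_tpatterns <- function(series, X) {
  if (is.vector(series)) series <- matrix(series, ncol = 1L)
  if (nrow(series) != nrow(X))
    stop_("series length does not match the design matrix")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_("rank-deficient (singular) design matrix")
  beta <- qr.coef(qx, series)
  res <- series - X %*% beta
  dof <- nrow(X) - qx$rank
  if (dof <= 0) stop_("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(X))))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- beta / se
  if (any(sigma2 <= 0)) {
    warning("zero residual variance for ", sum(sigma2 <= 0),
            " voxel(s); their t-values are NA", call. = FALSE)
    tval[, sigma2 <= 0] <- NA_real_
  }
  task <- attr(X, "task_cols") %||% seq_len(ncol(X))
  structure(list(beta = beta[task, , drop = FALSE],
                 t = tval[task, , drop = FALSE],
                 beta_all = beta, dof = dof,
                 labels = attr(X, "labels")),
            class = "glm_fit")
}
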