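# Synthetic V1: columnar orientation maps on a flat cortical sheet, coarse
# radial/vertical response biases, strictly positive voxel gain fields, and
# noisy per-subrun t-patterns.
#
# Each quarterfield patch is modeled as a flat 2D sheet. The first sheet
# axis spans the patch's eccentricity range in equal log-eccentricity steps
# (log cortical magnification), the second axis spans its 30 degrees of
# polar angle. Voxels are square 2-mm footprints tiling the sheet; each
# voxel averages a block of columns and is scaled by its own positive gain.

#' Neural map and response parameters
#'
#' Parameters of the columnar orientation-preference map and of the neural
#' response model. The per-column response to a stimulus with local
#' orientation \eqn{\theta_s} is
#' \deqn{R = b\,[1 + a_{col}\cos 2(\theta_{pref}-\theta_s)
#'   + a_{rad}\cos 2(\theta_s-\theta_{radial})
#'   + a_{vert}\cos 2\theta_s]}
#' with baseline \eqn{b} in percent signal change. The columnar term is the
#' fine-grained heterogeneous component; the radial and vertical terms are
#' the coarse, area-wide biases.
#'
#' Default amplitudes place the coarse biases at the empirically observed
#' order for V1 at 3T (between-condition contrasts of roughly 0.03-0.04
#' percent signal change on a ~2 percent response): `a_rad = 0.0095` and
#' `a_vert = 0.0081` yield patch-mean radial and vertical contrasts of
#' about 0.038 and 0.031 percent signal change with the default geometry.
#'
#' @param columnar_period_mm spatial period of the orientation map in mm
#'   (must exceed twice the column pitch to be resolvable).
#' @param a_col columnar tuning amplitude (fraction of baseline).
#' @param a_rad radial-bias amplitude.
#' @param a_vert vertical-bias amplitude.
#' @param baseline baseline response in percent signal change.
#' @return object of class `neural_map_params`.
#' @export
neural_map_params <- function(columnar_period_mm = 0.8, a_col = 0.6,
                              a_rad = 0.0095, a_vert = 0.0081,
                              baseline = 2.0) {
  if (!is_num1(baseline) || baseline <= 0) stop_("baseline must be > 0")
  for (a in c(a_col, a_rad, a_vert))
    if (!is_num1(a) || a < 0) stop_("amplitudes must be >= 0")
  if (a_col + a_rad + a_vert >= 1)
    stop_("a_col + a_rad + a_vert must be < 1 so responses stay positive")
  if (!is_num1(columnar_period_mm) || columnar_period_mm <= 0)
    stop_("columnar_period_mm must be > 0")
  structure(list(columnar_period_mm = columnar_period_mm, a_col = a_col,
                 a_rad = a_rad, a_vert = a_vert, baseline = baseline),
            class = "neural_map_params")
}

#' Voxel gain field parameters
#'
#' Gains are independent log-normal deviates with log-SD `sigma_log`,
#' normalised to mean 1 (`meanlog = -sigma_log^2/2`), hence strictly
#' positive: a gain field re-weights voxels but can never invert the sign of
#' a response contrast. `smoothness_mm > 0` spatially correlates the
#' log-gains over the voxel grid with a Gaussian kernel of that width;
#' the default 0 (i.i.d.) is the worst case for spurious high-spatial-
#' frequency structure.
#'
#' @param sigma_log dispersion of log-gain (`>= 0`).
#' @param smoothness_mm spatial correlation length of the log-gain field in
#'   mm; 0 for i.i.d. gains.
#' @return object of class `gain_field_params`.
#' @export
gain_field_params <- function(sigma_log = 0.4, smoothness_mm = 0) {
  if (!is_num1(sigma_log) || sigma_log < 0) stop_("sigma_log must be >= 0")
  if (!is_num1(smoothness_mm) || smoothness_mm < 0)
    stop_("smoothness_mm must be >= 0")
  structure(list(distribution = "lognormal", sigma_log = sigma_log,
                 smoothness_mm = smoothness_mm),
            class = "gain_field_params")
}

#' Noise parameters
#'
#' `sigma_pattern` is the additive per-voxel, per-subrun noise SD applied in
#' pattern-level simulation; since patterns are expressed on the t scale,
#' the default of 1 matches the unit variance of a t-statistic under
#' noise. `sigma_timeseries` is the white-noise SD (percent signal change)
#' of simulated BOLD time series; it also sets the amplitude-to-t
#' conversion used in pattern mode so the two fidelity modes agree in
#' expectation. `sigma_subject` is the between-subject SD of the
#' multiplicative jitter applied to the neural amplitudes (`a_col`,
#' `a_rad`, `a_vert`), capturing the observation that coarse biases are not
#' equally strong in every participant.
#'
#' @param sigma_pattern per-voxel per-subrun additive noise SD (t units).
#' @param sigma_subject between-subject SD of amplitude scaling factors.
#' @param sigma_timeseries BOLD time-series noise SD (percent signal
#'   change).
#' @return object of class `noise_params`.
#' @export
noise_params <- function(sigma_pattern = 1.0, sigma_subject = 0.3,
                         sigma_timeseries = 1.0) {
  for (s in c(sigma_pattern, sigma_subject, sigma_timeseries))
    if (!is_num1(s) || s < 0) stop_("noise SDs must be >= 0")
  structure(list(sigma_pattern = sigma_pattern,
                 sigma_subject = sigma_subject,
                 sigma_timeseries = sigma_timeseries),
            class = "noise_params")
}

#' Voxel grid over the four quarterfield sheets
#'
#' Builds the voxel lattice: four flat sheets (one per quarterfield patch),
#' each `nu x nv` voxels of `voxel_mm` width, with `columns_per_voxel^2`
#' cortical columns tiling every voxel footprint without overlap. The first
#' sheet axis maps linearly onto log eccentricity across the annulus, so
#' the three equal thirds of the axis are exactly the exponentially spaced
#' eccentricity bands of [build_rois()].
#'
#' @param annulus an [annulus_spec()].
#' @param nu voxels along the eccentricity axis (multiple of 3 so the three
#'   eccentricity bands tile it exactly).
#' @param nv voxels along the polar-angle axis.
#' @param voxel_mm voxel width in mm.
#' @param columns_per_voxel columns per voxel side (column pitch is
#'   `voxel_mm / columns_per_voxel`).
#' @return object of class `voxel_grid`: `$voxels` is a data frame (one row
#'   per voxel: `voxel`, `patch_id`, `ecc_band`, `ix`, `iy`, `ecc`,
#'   `polar`), plus the grid dimensions and the `roi_table`.
#' @export
voxel_grid <- function(annulus = annulus_spec(), nu = 12L, nv = 6L,
                       voxel_mm = 2, columns_per_voxel = 8L) {
  if (!is_count(nu) || nu %% 3L != 0L)
    stop_("nu must be a positive multiple of 3")
  if (!is_count(nv) || !is_count(columns_per_voxel))
    stop_("nv and columns_per_voxel must be positive integers")
  if (!is_num1(voxel_mm) || voxel_mm <= 0) stop_("voxel_mm must be > 0")
  rois <- build_rois(annulus)
  centers <- c(45, 135, 225, 315)
  Lu <- nu * voxel_mm
  Lv <- nv * voxel_mm
  ratio <- annulus$r_outer / annulus$r_inner
  vox <- do.call(rbind, lapply(1:4, function(p) {
    g <- expand.grid(ix = seq_len(nu), iy = seq_len(nv))
    u <- (g$ix - 0.5) * voxel_mm
    v <- (g$iy - 0.5) * voxel_mm
    data.frame(patch_id = p, ecc_band = ceiling(3 * g$ix / nu),
               ix = g$ix, iy = g$iy,
               ecc = annulus$r_inner * ratio^(u / Lu),
               polar = centers[p] - 15 + 30 * v / Lv)
  }))
  vox <- cbind(voxel = seq_len(nrow(vox)), vox)
  rownames(vox) <- NULL
  structure(list(voxels = vox, annulus = annulus, nu = as.integer(nu),
                 nv = as.integer(nv), voxel_mm = voxel_mm,
                 columns_per_voxel = as.integer(columns_per_voxel),
                 column_pitch_mm = voxel_mm / columns_per_voxel,
                 rois = rois, patch_centers = centers),
            class = "voxel_grid")
}

#' Visual-field coordinates of every cortical column in one patch
#'
#' @param grid a [voxel_grid()].
#' @param patch_id patch 1-4.
#' @return list with matrices `ecc` and `polar` of dimension
#'   `(nu*columns_per_voxel) x (nv*columns_per_voxel)` giving each column's
#'   eccentricity (degrees) and polar angle (degrees clockwise from
#'   vertical).
#' @export
patch_column_coords <- function(grid, patch_id) {
  stopifnot(inherits(grid, "voxel_grid"), patch_id %in% 1:4)
  cpv <- grid$columns_per_voxel
  n1 <- grid$nu * cpv
  n2 <- grid$nv * cpv
  pitch <- grid$column_pitch_mm
  Lu <- grid$nu * grid$voxel_mm
  Lv <- grid$nv * grid$voxel_mm
  u <- (seq_len(n1) - 0.5) * pitch
  v <- (seq_len(n2) - 0.5) * pitch
  ratio <- grid$annulus$r_outer / grid$annulus$r_inner
  ecc <- grid$annulus$r_inner * ratio^(u / Lu)
  polar <- grid$patch_centers[patch_id] - 15 + 30 * v / Lv
  list(ecc = matrix(ecc, n1, n2),
       polar = matrix(polar, n1, n2, byrow = TRUE))
}

#' Generate a columnar orientation-preference map
#'
#' Pinwheel-like preference maps are synthesised as half the argument of a
#' complex Gaussian random field band-pass filtered around spatial
#' frequency `1/columnar_period_mm` (relative bandwidth 1/4). Preferences
#' are uniformly distributed on `[0, 180)` and the map's radially averaged
#' power spectrum peaks at the columnar frequency.
#'
#' @param map a [neural_map_params()].
#' @param grid a [voxel_grid()].
#' @param seed integer seed; the map is deterministic given the seed.
#' @return matrix `(nu*columns_per_voxel) x (nv*columns_per_voxel)` of
#'   preferred orientations in `[0, 180)`.
#' @export
generate_orientation_map <- function(map, grid, seed) {
  stopifnot(inherits(map, "neural_map_params"), inherits(grid, "voxel_grid"))
  pitch <- grid$column_pitch_mm
  if (map$columnar_period_mm <= 2 * pitch)
    stop_("columnar_period_mm must exceed twice the column pitch (",
          signif(2 * pitch, 3), " mm) to be resolvable")
  n1 <- grid$nu * grid$columns_per_voxel
  n2 <- grid$nv * grid$columns_per_voxel
  set.seed(seed)
  w <- matrix(complex(real = rnorm(n1 * n2), imaginary = rnorm(n1 * n2)),
              n1, n2)
  f0 <- 1 / map$columnar_period_mm
  fmag <- sqrt(outer(fft_freq(n1, pitch)^2, fft_freq(n2, pitch)^2, "+"))
  H <- exp(-(fmag - f0)^2 / (2 * (f0 / 4)^2))
  z <- stats::fft(stats::fft(w) * H, inverse = TRUE) / (n1 * n2)
  mod180(atan2(Im(z), Re(z)) * 90 / pi)
}

#' Per-column neural response to a stimulus
#'
#' Applies the cosine response model of [neural_map_params()] at every
#' column of a patch: columnar tuning to the local stimulus orientation
#' plus the coarse radial and vertical bias terms. Responses are strictly
#' positive under the amplitude invariant.
#'
#' @param pref matrix of preferred orientations from
#'   [generate_orientation_map()] (or any matrix matching the column grid).
#' @param stim a [stimulus_spec()].
#' @param map a [neural_map_params()].
#' @param coords column coordinates from [patch_column_coords()].
#' @param annulus an [annulus_spec()] (domain check for the stimulus field).
#' @return matrix of responses in percent signal change.
#' @export
columnar_response <- function(pref, stim, map, coords,
                              annulus = annulus_spec()) {
  stopifnot(inherits(stim, "stimulus_spec"),
            inherits(map, "neural_map_params"))
  if (!all(dim(pref) == dim(coords$ecc)))
    stop_("preference map does not match the column grid")
  theta_s <- local_stimulus_orientation(stim, coords$polar, coords$ecc,
                                        annulus)
  theta_s <- matrix(theta_s, nrow(pref), ncol(pref))
  map$baseline * (1 + map$a_col * cos2d(pref - theta_s) +
                    map$a_rad * cos2d(theta_s - coords$polar) +
                    map$a_vert * cos2d(theta_s))
}

#' Average columnar responses into voxels through the gain field
#'
#' Each voxel's amplitude is its gain times the mean response over its
#' (non-overlapping) footprint of columns. Because gains are strictly
#' positive, the sign of any between-condition contrast equals the sign of
#' the footprint-mean neural contrast - the gain field re-weights but never
#' inverts.
#'
#' @param responses matrix of per-column responses for one patch
#'   (`(nu*f) x (nv*f)` for footprint side `f`).
#' @param gains numeric vector of per-voxel gains for that patch, in voxel
#'   order (`ix` fastest), all `> 0`.
#' @param columns_per_voxel footprint side `f` in columns.
#' @return numeric vector of per-voxel amplitudes (`ix` fastest).
#' @export
sample_voxels <- function(responses, gains, columns_per_voxel) {
  f <- as.integer(columns_per_voxel)
  if (!is_count(f)) stop_("invalid footprint: columns_per_voxel must be >= 1")
  if (nrow(responses) %% f != 0L || ncol(responses) %% f != 0L)
    stop_("invalid grid: footprints do not tile the response field")
  n1 <- nrow(responses) %/% f
  n2 <- ncol(responses) %/% f
  if (length(gains) != n1 * n2)
    stop_("gains length does not match the voxel grid")
  if (any(gains <= 0)) stop_("all voxel gains must be strictly positive")
  A1 <- kronecker(diag(n1), matrix(1 / f, 1L, f))
  A2 <- kronecker(diag(n2), matrix(1 / f, f, 1L))
  as.vector(A1 %*% responses %*% A2) * gains
}

# Gaussian smoothing of a per-voxel field over one patch sheet, then
# re-standardisation (used for spatially correlated log-gains).
smooth_patch_field <- function(x, nu, nv, voxel_mm, fwhm_mm) {
  m <- matrix(x, nu, nv)
  sd_vox <- fwhm_mm / voxel_mm
  r <- ceiling(3 * sd_vox)
  k <- dnorm(seq(-r, r), sd = sd_vox)
  pad_conv <- function(v) { # 1-d smooth with renormalised edge kernels
    n <- length(v)
    vapply(seq_len(n), function(i) {
      j <- pmax(1L, pmin(n, i + seq(-r, r)))
      w <- k
      sum(v[j] * w) / sum(w)
    }, numeric(1))
  }
  m <- apply(m, 2L, pad_conv)
  m <- t(apply(m, 1L, pad_conv))
  out <- as.vector(m)
  s <- sd(out)
  if (s > 0) out <- (out - mean(out)) / s * sd(x) + mean(x)
  out
}

sample_gain_field <- function(gain, grid, seed) {
  set.seed(seed)
  n <- nrow(grid$voxels)
  z <- rnorm(n)
  if (gain$smoothness_mm > 0) {
    for (p in 1:4) {
      sel <- grid$voxels$patch_id == p
      z[sel] <- smooth_patch_field(z[sel], grid$nu, grid$nv, grid$voxel_mm,
                                   gain$smoothness_mm)
    }
  }
  exp(z * gain$sigma_log - gain$sigma_log^2 / 2)
}

#' Simulation scenario
#'
#' Bundles all generator parameters. The three named worlds realise the
#' competing accounts of fMRI orientation information:
#' \describe{
#'   \item{`coarse_only`}{no columnar term (`a_col = 0`): all orientation
#'     information is a coarse, sign-homogeneous areal bias. Opposite voxel
#'     preferences can then arise only from noise and must not replicate.}
#'   \item{`fine_only`}{no coarse biases (`a_rad = a_vert = 0`): information
#'     is purely fine-grained; voxel preferences are balanced and opposite
#'     preference sets are both real.}
#'   \item{`mixed`}{both components, the realistic world.}
#' }
#'
#' @param name `"mixed"`, `"coarse_only"` or `"fine_only"`.
#' @param n_subjects number of simulated participants.
#' @param seed master seed (mandatory; every random quantity derives from
#'   it hierarchically, so a scenario is bit-reproducible).
#' @param map,gain,noise,design,annulus parameter objects; see
#'   [neural_map_params()], [gain_field_params()], [noise_params()],
#'   [block_design()], [annulus_spec()].
#' @param nu,nv,voxel_mm,columns_per_voxel voxel-grid geometry, see
#'   [voxel_grid()].
#' @param kinds stimulus kinds to simulate.
#' @param fidelity `"pattern"` (amplitudes + t-scale noise; fast, default)
#'   or `"timeseries"` (full BOLD simulation through the GLM module).
#' @return object of class `scenario`.
#' @export
scenario <- function(name = c("mixed", "coarse_only", "fine_only"),
                     n_subjects = 18L, seed = NULL,
                     map = neural_map_params(), gain = gain_field_params(),
                     noise = noise_params(), design = block_design(),
                     annulus = annulus_spec(), nu = 12L, nv = 6L,
                     voxel_mm = 2, columns_per_voxel = 8L,
                     kinds = c("grating", "spiral"),
                     fidelity = c("pattern", "timeseries")) {
  name <- match.arg(name)
  fidelity <- match.arg(fidelity)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(seed)) stop_("a scenario requires an integer master seed")
  if (!is_count(n_subjects)) stop_("n_subjects must be a positive integer")
  if (name == "coarse_only" && map$a_col != 0)
    stop_("coarse_only requires a_col = 0")
  if (name == "fine_only" && (map$a_rad != 0 || map$a_vert != 0))
    stop_("fine_only requires a_rad = a_vert = 0")
  stopifnot(inherits(map, "neural_map_params"),
            inherits(gain, "gain_field_params"),
            inherits(noise, "noise_params"),
            inherits(design, "block_design"))
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), map = map, gain = gain,
                 noise = noise, design = design, annulus = annulus,
                 nu = as.integer(nu), nv = as.integer(nv),
                 voxel_mm = voxel_mm,
                 columns_per_voxel = as.integer(columns_per_voxel),
                 kinds = kinds, fidelity = fidelity),
            class = "scenario")
}

#' @rdname scenario
#' @param ... passed on to [scenario()].
#' @export
scenario_mixed <- function(seed, ...) scenario("mixed", seed = seed, ...)

#' @rdname scenario
#' @export
scenario_coarse_only <- function(seed, ...) {
  args <- list(...)
  if (is.null(args$map)) {
    m <- neural_map_params()
    m$a_col <- 0
    args$map <- m
  }
  do.call(scenario, c(list(name = "coarse_only", seed = seed), args))
}

#' @rdname scenario
#' @export
scenario_fine_only <- function(seed, ...) {
  args <- list(...)
  if (is.null(args$map)) {
    m <- neural_map_params()
    m$a_rad <- 0
    m$a_vert <- 0
    args$map <- m
  }
  do.call(scenario, c(list(name = "fine_only", seed = seed), args))
}

# amplitude -> t conversion: the OLS standard error of one task predictor
# under the canonical design, times the time-series noise SD. Computed from
# the design so pattern-level and time-series-level simulation agree in
# expectation.
amplitude_t_scale <- function(design, noise, hrf = hrf_params()) {
  X <- build_design_matrix(design, hrf)
  d <- diag(chol2inv(chol(crossprod(X))))[attr(X, "task_cols")]
  se <- noise$sigma_timeseries * sqrt(mean(d))
  if (se <= 0) stop_("sigma_timeseries must be > 0 to define the t scale")
  se
}

#' Generate a synthetic pattern dataset
#'
#' Realises a [scenario()]: for every subject, a subject-specific columnar
#' map per patch, a subject-specific strictly positive voxel gain field and
#' jittered bias amplitudes; for every stimulus kind, run, subrun and
#' condition one t-value pattern over all voxels. In `"pattern"` fidelity
#' the pattern is `amplitude / se + noise` where `se` is the canonical
#' design's OLS standard error (so values are on the t scale); in
#' `"timeseries"` fidelity full BOLD series are simulated and fitted with
#' [fit_tpatterns()].
#'
#' Seeding is hierarchical (master seed, then per-subject streams), so the
#' dataset is bit-reproducible and adding subjects never changes existing
#' ones.
#'
#' @param scen a [scenario()].
#' @return object of class `pattern_dataset`: a list with `t` (patterns x
#'   voxels matrix of t-values), `info` (one row per pattern: `subject`,
#'   `kind`, `run`, `subrun`, `condition`), `voxels` (voxel metadata),
#'   `amplitude` / `amp_info` (the noise-free percent-signal-change
#'   amplitude channel), `gains` (subjects x voxels), `grid`, `scenario`
#'   and `t_scale`.
#' @export
generate_dataset <- function(scen) {
  stopifnot(inherits(scen, "scenario"))
  grid <- voxel_grid(scen$annulus, scen$nu, scen$nv, scen$voxel_mm,
                     scen$columns_per_voxel)
  vox <- grid$voxels
  nvox <- nrow(vox)
  design <- scen$design
  n_runs <- 2L
  se <- amplitude_t_scale(design, scen$noise)
  coords <- lapply(1:4, function(p) patch_column_coords(grid, p))
  patch_sel <- lapply(1:4, function(p) which(vox$patch_id == p))
  X <- if (scen$fidelity == "timeseries")
    build_design_matrix(design) else NULL

  subject_seeds <- draw_seeds(scen$seed, scen$n_subjects)
  info_list <- list()
  t_list <- list()
  amp_list <- list()
  ainfo_list <- list()
  gains_mat <- matrix(NA_real_, scen$n_subjects, nvox)

  for (s in seq_len(scen$n_subjects)) {
    streams <- draw_seeds(subject_seeds[s], 3L + 4L)
    set.seed(streams[1L])
    jit <- pmax(rnorm(3L, 1, scen$noise$sigma_subject), 0)
    m <- scen$map
    m$a_col <- m$a_col * jit[1L]
    m$a_rad <- m$a_rad * jit[2L]
    m$a_vert <- m$a_vert * jit[3L]
    # keep responses positive even under extreme jitter
    tot <- m$a_col + m$a_rad + m$a_vert
    if (tot >= 1) {
      fac <- 0.99 / tot
      m$a_col <- m$a_col * fac
      m$a_rad <- m$a_rad * fac
      m$a_vert <- m$a_vert * fac
    }
    gains <- sample_gain_field(scen$gain, grid, streams[2L])
    gains_mat[s, ] <- gains
    prefs <- lapply(1:4, function(p)
      generate_orientation_map(m, grid, streams[3L + p]))

    # noise-free voxel amplitudes per kind x condition
    amps <- list()
    for (kind in scen$kinds) {
      variants <- stimulus_variants(kind)
      a_kc <- matrix(NA_real_, nvox, 2L,
                     dimnames = list(NULL, variants))
      for (ci in 1:2) {
        stim <- stimulus_spec(kind, variants[ci])
        for (p in 1:4) {
          R <- columnar_response(prefs[[p]], stim, m, coords[[p]],
                                 scen$annulus)
          a_kc[patch_sel[[p]], ci] <-
            sample_voxels(R, gains[patch_sel[[p]]], scen$columns_per_voxel)
        }
      }
      amps[[kind]] <- a_kc
      amp_list[[length(amp_list) + 1L]] <- t(a_kc)
      ainfo_list[[length(ainfo_list) + 1L]] <-
        data.frame(subject = s, kind = kind, condition = variants)
    }

    set.seed(streams[3L]) # measurement-noise stream
    for (kind in scen$kinds) {
      variants <- stimulus_variants(kind)
      if (scen$fidelity == "pattern") {
        for (run in seq_len(n_runs)) for (sub in
          seq_len(design$subruns_per_run)) for (ci in 1:2) {
          t_list[[length(t_list) + 1L]] <- amps[[kind]][, ci] / se +
            rnorm(nvox) * scen$noise$sigma_pattern
          info_list[[length(info_list) + 1L]] <-
            data.frame(subject = s, kind = kind, run = run, subrun = sub,
                       condition = variants[ci])
        }
      } else {
        labels <- attr(X, "labels")
        for (run in seq_len(n_runs)) {
          B <- matrix(0, ncol(X), nvox)
          for (j in seq_len(nrow(labels)))
            B[attr(X, "task_cols")[j], ] <- amps[[kind]][, labels$condition[j]]
          Y <- X %*% B + matrix(rnorm(nrow(X) * nvox), nrow(X)) *
            scen$noise$sigma_timeseries
          fit <- fit_tpatterns(Y, X)
          for (j in seq_len(nrow(labels))) {
            t_list[[length(t_list) + 1L]] <- fit$t[j, ]
            info_list[[length(info_list) + 1L]] <-
              data.frame(subject = s, kind = kind, run = run,
                         subrun = labels$subrun[j],
                         condition = variants[labels$condition[j]])
          }
        }
      }
    }
  }

  info <- do.call(rbind, info_list)
  ord <- order(info$subject, info$kind, info$run, info$subrun,
               match(info$condition, c("plus45", "minus45", "clockwise",
                                       "anticlockwise")))
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  tmat <- do.call(rbind, t_list)[ord, , drop = FALSE]
  structure(list(t = tmat, info = info, voxels = vox,
                 amplitude = do.call(rbind, amp_list),
                 amp_info = do.call(rbind, ainfo_list),
                 gains = gains_mat, grid = grid, scenario = scen,
                 t_scale = se),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("<pattern_dataset>\n")
  cat("  subjects:", length(unique(x$info$subject)),
      " kinds:", paste(unique(x$info$kind), collapse = ", "), "\n")
  cat("  patterns:", nrow(x$t), " voxels:", ncol(x$t),
      " (4 patches x", max(x$voxels$ix), "x", max(x$voxels$iy), "voxels)\n")
  if (!is.null(x$scenario))
    cat("  scenario:", x$scenario$name, " seed:", x$scenario$seed,
        " fidelity:", x$scenario$fidelity, "\n")
  invisible(x)
}

#' Simulate block-design BOLD time series from per-condition amplitudes
#'
#' Builds the design matrix for one run, assigns each (condition, subrun)
#' predictor the corresponding voxel amplitude as its true effect, and adds
#' white noise.
#'
#' @param design a [block_design()].
#' @param amplitudes matrix (voxels x conditions) of response amplitudes in
#'   percent signal change; recycled across subruns.
#' @param hrf an [hrf_params()].
#' @param noise_sd white-noise SD.
#' @param seed integer seed.
#' @return matrix (volumes x voxels) of simulated series, with the design
#'   matrix attached as attribute `"design_matrix"`.
#' @export
generate_timeseries <- function(design, amplitudes, hrf = hrf_params(),
                                noise_sd = 1, seed = 1L) {
  stopifnot(inherits(design, "block_design"))
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != design$conditions)
    stop_("amplitudes must have one column per condition")
  X <- build_design_matrix(design, hrf)
  labels <- attr(X, "labels")
  B <- matrix(0, ncol(X), nrow(amplitudes))
  for (j in seq_len(nrow(labels)))
    B[attr(X, "task_cols")[j], ] <- amplitudes[, labels$condition[j]]
  set.seed(seed)
  Y <- X %*% B + matrix(rnorm(nrow(X) * nrow(amplitudes)), nrow(X)) * noise_sd
  attr(Y, "design_matrix") <- X
  Y
}
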