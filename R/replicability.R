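# Preference replicability: normalised inner product of train/test contrast
# t-vectors per preference voxel set, fold-averaged, with participant
# bootstrap and ROI-effect ANOVAs.

#' Preference replicability index
#'
#' The inner product of the training and test t-value vectors over one
#' voxel set, normalised by the product of their norms:
#' \deqn{r = \langle t_{train}, t_{test}\rangle /
#'   (\|t_{train}\|\,\|t_{test}\|).}
#' Like a Pearson correlation it lies in \eqn{[-1, 1]}, but there is no
#' mean-centering (the regression intercept is fixed at the origin), so a
#' positive index requires the t-values to match in sign. Under
#' independence of train and test the index is unbiased and symmetrically
#' distributed about 0; it is negative when voxels tend to revert to the
#' opposite selectivity.
#'
#' @param t_train,t_test numeric vectors over the same voxels, in the same
#'   order, each with non-zero norm.
#' @return scalar in `[-1, 1]`.
#' @examples
#' replicability_index(c(1, 2), c(2, 1)) # 0.8
#' @export
replicability_index <- function(t_train, t_test) {
  if (length(t_train) != length(t_test))
    stop_("train and test vectors must cover the same voxels")
  if (length(t_train) == 0L) stop_("empty voxel set")
  if (any(!is.finite(t_train)) || any(!is.finite(t_test)))
    stop_("non-finite t-values")
  n1 <- sqrt(sum(t_train^2))
  n2 <- sqrt(sum(t_test^2))
  if (n1 == 0 || n2 == 0)
    stop_("undefined index: zero-norm t-vector")
  sum(t_train * t_test) / (n1 * n2)
}

# contrast t-vector (reference minus anti, patch-relative sign) over given
# pattern rows
contrast_vector <- function(tmat, info, voxels, kind, patch_centers,
                            contrast) {
  label_core(tmat, info, voxels, kind, patch_centers, contrast)$delta_t
}

roi_voxel_sets <- function(voxels) {
  rois <- list(combined = seq_len(nrow(voxels)))
  for (p in 1:4) rois[[paste0("Q", p)]] <- which(voxels$patch_id == p)
  for (b in 1:3) rois[[paste0("E", b)]] <- which(voxels$ecc_band == b)
  rois
}

#' Cross-validated preference replicability
#'
#' For each subject, stimulus kind and cross-validation fold: label voxels
#' from the training subruns only, build the training and test contrast
#' t-vectors (patch-relative reference minus anti-reference), and compute
#' the [replicability_index()] over each preference set restricted to each
#' ROI (all quarterfields combined, each quarterfield, each eccentricity
#' band). Indices are averaged over folds per subject; folds where a set is
#' empty or a vector has zero norm are excluded from the average (missing,
#' not zero).
#'
#' @param dataset a `pattern_dataset`.
#' @param folds from [make_folds()].
#' @param kinds stimulus kinds (default all present).
#' @param contrast `"mean_t_difference"` (default; with t-patterns as
#'   currency the fold contrast map is the mean t-difference across
#'   subruns) or `"t_statistic"`.
#' @return data frame of class `replicability_result`, one row per subject
#'   x orientation set x ROI: `subject`, `kind`, `set` (radial, tangential,
#'   vertical or horizontal), `roi` (`combined`, `Q1`-`Q4`, `E1`-`E3`),
#'   `index` (fold-averaged), `n_folds` (folds contributing).
#' @export
crossval_replicability <- function(dataset, folds = NULL, kinds = NULL,
                                   contrast = "mean_t_difference") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  info <- dataset$info
  vox <- dataset$voxels
  pc <- dataset$grid$patch_centers
  kinds <- kinds %||% unique(info$kind)
  folds <- folds %||% make_folds(length(unique(info$run)),
                                 max(info$subrun))
  rois <- roi_voxel_sets(vox)
  subjects <- sort(unique(info$subject))
  out <- list()
  for (kind in kinds) {
    lab <- reference_labels(kind)
    for (s in subjects) {
      rows <- which(info$subject == s & info$kind == kind)
      tm <- dataset$t[rows, , drop = FALSE]
      im <- info[rows, ]
      acc <- array(NA_real_, c(length(folds), 2L, length(rois)))
      for (fi in seq_along(folds)) {
        te <- which(im$subrun == folds[[fi]]$test_subrun)
        tr <- which(im$subrun != folds[[fi]]$test_subrun)
        labels <- label_core(tm[tr, , drop = FALSE], im[tr, ], vox, kind,
                             pc, contrast)
        v_tr <- labels$delta_t
        v_te <- contrast_vector(tm[te, , drop = FALSE], im[te, ], vox,
                                kind, pc, contrast)
        sets <- list(which(!is.na(labels$label) &
                             labels$label == lab["ref"]),
                     which(!is.na(labels$label) &
                             labels$label == lab["anti"]))
        for (si in 1:2) for (ri in seq_along(rois)) {
          idx <- intersect(sets[[si]], rois[[ri]])
          if (length(idx) == 0L) next
          u <- v_tr[idx]
          w <- v_te[idx]
          if (sum(u^2) == 0 || sum(w^2) == 0) next
          acc[fi, si, ri] <- replicability_index(u, w)
        }
      }
      for (si in 1:2) for (ri in seq_along(rois)) {
        vals <- acc[, si, ri]
        out[[length(out) + 1L]] <- data.frame(
          subject = s, kind = kind,
          set = unname(lab[c("ref", "anti")[si]]),
          roi = names(rois)[ri],
          index = if (all(is.na(vals))) NA_real_ else mean(vals,
                                                           na.rm = TRUE),
          n_folds = sum(!is.na(vals)), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("replicability_result", "data.frame")
  res
}

#' Participant bootstrap test of a group mean
#'
#' Resamples subjects with replacement `n_boot` times, returning the sample
#' mean, the percentile 95 percent confidence interval of the resampled
#' means, and the one-sided add-one bootstrap p-value for the mean being
#' greater than zero: `p = (1 + #{resampled means <= 0}) / (n_boot + 1)`
#' (never exactly zero).
#'
#' @param values one value per subject (`NA`s dropped); at least 2 needed.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (deterministic given the seed).
#' @return data frame with `mean`, `ci_lo`, `ci_hi`, `p`, `n`, `n_boot`.
#' @export
bootstrap_group_test <- function(values, n_boot = 10000L, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop_("need at least 2 subjects for the bootstrap")
  if (!is_count(n_boot)) stop_("n_boot must be a positive integer")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  means <- colMeans(matrix(values[idx], n, n_boot))
  ci <- unname(quantile(means, c(0.025, 0.975), type = 7))
  data.frame(mean = mean(values), ci_lo = ci[1L], ci_hi = ci[2L],
             p = (1 + sum(means <= 0)) / (n_boot + 1), n = n,
             n_boot = as.integer(n_boot))
}

#' Group summary of replicability indices
#'
#' Applies [bootstrap_group_test()] to the per-subject fold-averaged
#' indices of every orientation set x ROI cell.
#'
#' @param result a `replicability_result`.
#' @param n_boot,seed passed to [bootstrap_group_test()]; each cell uses a
#'   seed derived deterministically from `seed`.
#' @return data frame with one row per `kind` x `set` x `roi`
#'   (4 orientation sets x 8 ROIs = 32 rows for a two-kind dataset).
#' @export
replicability_summary <- function(result, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(result, "replicability_result"))
  cells <- unique(result[, c("kind", "set", "roi")])
  cells <- cells[order(cells$kind, cells$set, cells$roi), ]
  seeds <- draw_seeds(seed, nrow(cells))
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- merge(result, cells[i, ])
    bt <- tryCatch(
      bootstrap_group_test(d$index, n_boot = n_boot, seed = seeds[i]),
      error = function(e) data.frame(mean = NA_real_, ci_lo = NA_real_,
                                     ci_hi = NA_real_, p = NA_real_,
                                     n = sum(!is.na(d$index)),
                                     n_boot = as.integer(n_boot)))
    cbind(cells[i, ], bt)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of ROI effects on replicability
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F-test) of the
#' per-subject fold-averaged replicability index across ROI levels -
#' quarterfield (Q1-Q4) or eccentricity band (E1-E3) - run separately for
#' each orientation set. With both factors and both stimulus kinds this is
#' the standard battery of eight tests (4 orientation sets x 2 factors).
#'
#' @param result a `replicability_result`.
#' @param factor `"quarterfield"` or `"eccentricity"`.
#' @return data frame with one row per orientation set: `kind`, `set`,
#'   `factor`, `F`, `df1`, `df2`, `p`.
#' @export
roi_effect_anova <- function(result,
                             factor = c("quarterfield", "eccentricity")) {
  stopifnot(inherits(result, "replicability_result"))
  factor <- match.arg(factor)
  pref <- if (factor == "quarterfield") "^Q" else "^E"
  d <- result[grepl(pref, result$roi) & is.finite(result$index), ]
  if (nrow(d) == 0L) stop_("no ROI-level indices for factor ", factor)
  sets <- unique(d[, c("kind", "set")])
  out <- do.call(rbind, lapply(seq_len(nrow(sets)), function(i) {
    di <- merge(d, sets[i, ])
    lv <- table(di$roi)
    if (length(lv) < 2L || any(lv < 2L))
      stop_("need >= 2 factor levels with >= 2 subjects each")
    ft <- stats::oneway.test(index ~ roi, data = di, var.equal = TRUE)
    cbind(sets[i, ], data.frame(factor = factor,
                                F = unname(ft$statistic),
                                df1 = unname(ft$parameter[1L]),
                                df2 = unname(ft$parameter[2L]),
                                p = ft$p.value))
  }))
  rownames(out) <- NULL
  out
}
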