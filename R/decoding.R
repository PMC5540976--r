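# Cross-validated linear SVM decoding of stimulus condition from voxel
# patterns, under voxel-set selections and spatial shifts of the test
# patterns.

#' Subrun cross-validation folds
#'
#' The canonical plan: four folds, where fold k holds out subrun k of both
#' runs as test data (4 test patterns: 2 conditions x 2 runs) and trains on
#' the remaining subruns (12 patterns). For non-standard designs a
#' generalised k-fold over the subrun index is returned with a warning.
#'
#' @param n_runs number of runs per stimulus kind.
#' @param subruns_per_run number of subruns per run.
#' @return list of folds; each fold is a list with `fold` (index) and
#'   `test_subrun` (the held-out subrun index, same for all runs).
#' @export
make_folds <- function(n_runs = 2L, subruns_per_run = 4L) {
  if (!is_count(n_runs) || !is_count(subruns_per_run))
    stop_("run and subrun counts must be positive integers")
  if (!(n_runs == 2L && subruns_per_run == 4L))
    warning("non-standard design: generalised ", subruns_per_run,
            "-fold cross-validation over the subrun index", call. = FALSE)
  lapply(seq_len(subruns_per_run), function(k)
    list(fold = k, test_subrun = k))
}

# linear maximum-margin classifier with fixed cost 1 and no feature
# scaling (inputs are already on the t scale)
fit_linear_svm <- function(x, y) {
  e1071::svm(x = x, y = factor(y), kernel = "linear", cost = 1,
             scale = FALSE)
}

# Mapping of a spatial shift on the voxel grid. Returns the kept voxel ids
# and, for each, the 1-2 source voxels and interpolation weights that
# produce its shifted test value. Shifts never cross patch boundaries;
# voxels whose shifted sampling window leaves the patch sheet are dropped
# (callers drop them from train and test symmetrically).
shift_index_map <- function(voxels, nu, nv, magnitude, direction) {
  if (!direction %in% c("+x", "-x", "+y", "-y"))
    stop_("direction must be one of +x, -x, +y, -y (grid axes)")
  if (!is_num1(magnitude) || magnitude < 0)
    stop_("shift magnitude must be >= 0")
  ax <- substr(direction, 2L, 2L)
  sgn <- if (substr(direction, 1L, 1L) == "+") 1 else -1
  lo <- floor(magnitude)
  frac <- magnitude - lo
  pos <- if (ax == "x") voxels$ix else voxels$iy
  lim <- if (ax == "x") nu else nv
  p1 <- pos + sgn * lo
  p2 <- p1 + sgn * (frac > 0)
  ok <- p1 >= 1 & p1 <= lim & p2 >= 1 & p2 <= lim
  key <- function(ix, iy) match(paste(voxels$patch_id, ix, iy),
                                paste(voxels$patch_id, voxels$ix, voxels$iy))
  if (ax == "x") {
    src1 <- key(p1, voxels$iy)
    src2 <- key(p2, voxels$iy)
  } else {
    src1 <- key(voxels$ix, p1)
    src2 <- key(voxels$ix, p2)
  }
  keep <- which(ok & !is.na(src1) & !is.na(src2))
  list(keep = keep, src1 = src1[keep], src2 = src2[keep],
       w1 = 1 - frac, w2 = frac)
}

#' Spatially shift voxel patterns
#'
#' Relocates the sampling window of every voxel by `magnitude` voxels along
#' a grid axis. Integer magnitudes take the value of the neighbouring voxel
#' at that offset; half-voxel magnitudes average the two adjacent voxels
#' (linear interpolation). Voxels whose shifted window leaves the patch
#' sheet are dropped, so the returned matrix has (at most) fewer columns;
#' use `keep` to subset unshifted data symmetrically.
#'
#' @param patterns numeric matrix (patterns x voxels) in the voxel order of
#'   `voxels`.
#' @param voxels voxel metadata data frame (columns `patch_id`, `ix`, `iy`).
#' @param nu,nv grid dimensions (voxels per patch along x and y).
#' @param magnitude shift in voxel widths (e.g. 0.5, 1, 2, 3).
#' @param direction `"+x"`, `"-x"`, `"+y"` or `"-y"`.
#' @return list with `patterns` (shifted matrix over kept voxels) and
#'   `keep` (indices of kept voxels in the original order).
#' @export
shift_patterns <- function(patterns, voxels, nu, nv, magnitude, direction) {
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1L)
  if (ncol(patterns) != nrow(voxels))
    stop_("patterns and voxel table sizes differ")
  mp <- shift_index_map(voxels, nu, nv, magnitude, direction)
  shifted <- mp$w1 * patterns[, mp$src1, drop = FALSE]
  if (mp$w2 > 0)
    shifted <- shifted + mp$w2 * patterns[, mp$src2, drop = FALSE]
  list(patterns = shifted, keep = mp$keep)
}

# Decode one subject x kind with one selection rule and optional shift.
# Returns one row per fold.
decode_subject_kind <- function(tmat, info, voxels, patch_centers, nu, nv,
                                kind, folds, selection, magnitude = 0,
                                direction = NULL, contrast =
                                  "mean_t_difference") {
  if (magnitude > 0) {
    mp <- shift_index_map(voxels, nu, nv, magnitude, direction)
  } else {
    mp <- list(keep = seq_len(nrow(voxels)), src1 = seq_len(nrow(voxels)),
               src2 = seq_len(nrow(voxels)), w1 = 1, w2 = 0)
  }
  out <- lapply(folds, function(fd) {
    te <- which(info$subrun == fd$test_subrun)
    tr <- which(info$subrun != fd$test_subrun)
    labels <- label_core(tmat[tr, , drop = FALSE], info[tr, ], voxels, kind,
                         patch_centers, contrast)
    sel <- switch(selection,
      all = labels$voxel[!is.na(labels$delta_t)],
      A = split_voxel_sets(structure(labels, kind = kind))$A,
      B = split_voxel_sets(structure(labels, kind = kind))$B,
      stop_("unknown selection rule: ", selection))
    sel <- intersect(sel, mp$keep)
    if (length(sel) == 0L)
      return(data.frame(fold = fd$fold, n_voxels = 0L, n_test = 0L,
                        n_correct = NA_integer_, accuracy = NA_real_))
    train_x <- tmat[tr, sel, drop = FALSE]
    pos <- match(sel, mp$keep)
    test_x <- mp$w1 * tmat[te, mp$src1[pos], drop = FALSE]
    if (mp$w2 > 0)
      test_x <- test_x + mp$w2 * tmat[te, mp$src2[pos], drop = FALSE]
    fit <- fit_linear_svm(train_x, info$condition[tr])
    pred <- as.character(predict(fit, test_x))
    data.frame(fold = fd$fold, n_voxels = length(sel),
               n_test = length(te),
               n_correct = sum(pred == info$condition[te]),
               accuracy = mean(pred == info$condition[te]))
  })
  do.call(rbind, out)
}

selection_set_label <- function(kind, selection) {
  lab <- reference_labels(kind)
  switch(selection, all = "all", A = unname(lab["ref"]),
         B = unname(lab["anti"]))
}

#' Cross-validated decoding of stimulus condition
#'
#' Trains a linear support-vector machine (fixed cost 1, no feature
#' scaling) per cross-validation fold to decode the stimulus condition from
#' voxel t-patterns, for each subject, stimulus kind and voxel-selection
#' rule. Selections `"A"` (radial/vertical-preferring) and `"B"`
#' (tangential/horizontal-preferring) are recomputed inside every fold from
#' that fold's training subruns only, so test data never influence voxel
#' selection. Empty selections yield missing folds (recorded, not zero).
#'
#' @param dataset a `pattern_dataset`.
#' @param selections subset of `c("all", "A", "B")`.
#' @param kinds stimulus kinds to decode (default: all present).
#' @param folds from [make_folds()].
#' @param contrast labeling contrast, see [label_voxel_preferences()].
#' @return data frame of class `decoding_result`, one row per subject x
#'   kind x selection x fold, with `set_label`, `shift_mm = 0`,
#'   `direction = "none"`, `n_voxels`, `n_test`, `n_correct`, `accuracy`.
#' @seealso [decoding_summary()], [shift_decoding_curve()]
#' @export
train_test_decode <- function(dataset, selections = c("all", "A", "B"),
                              kinds = NULL, folds = NULL,
                              contrast = "mean_t_difference") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  kinds <- kinds %||% unique(dataset$info$kind)
  folds <- folds %||% make_folds(length(unique(dataset$info$run)),
                                 dataset$scenario$design$subruns_per_run %||%
                                   max(dataset$info$subrun))
  res <- decode_grid(dataset, selections, kinds, folds, magnitudes = 0,
                     directions = "none", contrast = contrast)
  class(res) <- c("decoding_result", "data.frame")
  res
}

decode_grid <- function(dataset, selections, kinds, folds, magnitudes,
                        directions, contrast) {
  info <- dataset$info
  vox <- dataset$voxels
  nu <- dataset$grid$nu
  nv <- dataset$grid$nv
  pc <- dataset$grid$patch_centers
  subjects <- sort(unique(info$subject))
  out <- list()
  for (kind in kinds) for (s in subjects) {
    rows <- which(info$subject == s & info$kind == kind)
    tm <- dataset$t[rows, , drop = FALSE]
    im <- info[rows, ]
    for (selection in selections) for (mag in magnitudes) {
      dirs <- if (mag == 0) "none" else directions
      for (dir in dirs) {
        r <- decode_subject_kind(tm, im, vox, pc, nu, nv, kind, folds,
                                 selection,
                                 magnitude = mag,
                                 direction = if (mag == 0) NULL else dir,
                                 contrast = contrast)
        r <- cbind(data.frame(subject = s, kind = kind,
                              selection = selection,
                              set_label = selection_set_label(kind, selection),
                              shift_vox = mag,
                              shift_mm = mag * dataset$grid$voxel_mm,
                              direction = if (mag == 0) "none" else dir,
                              stringsAsFactors = FALSE), r)
        out[[length(out) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decoding under spatial shifts of the test patterns
#'
#' Repeats the cross-validated decoding of [train_test_decode()] with the
#' test patterns spatially shifted by each magnitude along each grid-axis
#' direction (voxels dropped by the shift are removed from training data
#' too). Magnitude 0 reproduces the unshifted analysis exactly. The default
#' direction set is the four in-plane grid directions of the 2D sheet
#' model.
#'
#' @param dataset a `pattern_dataset`.
#' @param magnitudes shift magnitudes in voxel widths.
#' @param directions grid-axis directions.
#' @inheritParams train_test_decode
#' @return `decoding_result` data frame with one row per subject x kind x
#'   selection x shift x direction x fold.
#' @export
shift_decoding_curve <- function(dataset, magnitudes = c(0, 0.5, 1, 2, 3),
                                 directions = c("+x", "-x", "+y", "-y"),
                                 selections = c("all", "A", "B"),
                                 kinds = NULL, folds = NULL,
                                 contrast = "mean_t_difference") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  kinds <- kinds %||% unique(dataset$info$kind)
  folds <- folds %||% make_folds(length(unique(dataset$info$run)),
                                 max(dataset$info$subrun))
  res <- decode_grid(dataset, selections, kinds, folds, magnitudes,
                     directions, contrast)
  class(res) <- c("decoding_result", "data.frame")
  res
}

#' Per-subject and group decoding summary
#'
#' Aggregates a `decoding_result` to per-subject accuracies (fold counts
#' pooled, then averaged over shift directions within each subject, as in
#' the shift analysis) and to a group table with the mean accuracy and a
#' one-sided Wilcoxon signed-rank test against chance (0.5) across
#' subjects.
#'
#' @param result a `decoding_result`.
#' @return list with `per_subject` and `group` data frames.
#' @export
decoding_summary <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  # accuracy per subject x direction = pooled correct / tested over folds
  agg <- aggregate(cbind(n_correct, n_test) ~
                     subject + kind + selection + set_label + shift_mm +
                     direction, data = result, FUN = sum, na.rm = TRUE,
                   na.action = stats::na.pass)
  agg$accuracy <- ifelse(agg$n_test > 0, agg$n_correct / agg$n_test, NA)
  per_subject <- aggregate(accuracy ~ subject + kind + selection +
                             set_label + shift_mm, data = agg, FUN = mean,
                           na.rm = TRUE, na.action = stats::na.pass)
  cells <- unique(per_subject[, c("kind", "selection", "set_label",
                                  "shift_mm")])
  group <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- merge(per_subject, cells[i, ])
    acc <- d$accuracy[is.finite(d$accuracy)]
    p <- tryCatch(
      wilcoxon_signed_rank(acc, mu = 0.5, alternative = "greater")$p,
      error = function(e) NA_real_)
    cbind(cells[i, ], data.frame(n_subjects = length(acc),
                                 mean_accuracy = mean(acc),
                                 p_vs_chance = p))
  }))
  rownames(group) <- NULL
  list(per_subject = per_subject, group = group)
}
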