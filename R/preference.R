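# Voxel orientation-preference labeling and Fig.-style summaries
# (histograms, per-subject proportions, percent-signal-change contrasts).

# Signed patch-relative contrast orientation: +1 where the first variant of
# the kind is the reference (radial/vertical) condition in that patch.
patch_reference_signs <- function(kind, voxels, patch_centers) {
  v1 <- stimulus_variants(kind)[1L]
  signs <- vapply(1:4, function(p) {
    mp <- condition_label_map(kind, patch_centers[p])
    if (mp[[v1]] %in% c("radial", "vertical")) 1 else -1
  }, numeric(1))
  signs[voxels$patch_id]
}

reference_labels <- function(kind) {
  if (kind == "grating") c(ref = "radial", anti = "tangential")
  else c(ref = "vertical", anti = "horizontal")
}

# Core labeling: rows of (t, info) must belong to one subject and kind.
label_core <- function(tmat, info, voxels, kind, patch_centers,
                       contrast = c("mean_t_difference", "t_statistic")) {
  contrast <- match.arg(contrast)
  if (nrow(info) == 0L) stop_("empty training set: no subruns to label from")
  v <- stimulus_variants(kind)
  signs <- patch_reference_signs(kind, voxels, patch_centers)
  r1 <- which(info$condition == v[1L])
  r2 <- which(info$condition == v[2L])
  if (length(r1) == 0L || length(r2) == 0L)
    stop_("training data must contain both conditions")
  if (contrast == "t_statistic") {
    # pair patterns by (run, subrun) and t-test the differences
    k1 <- paste(info$run[r1], info$subrun[r1])
    k2 <- paste(info$run[r2], info$subrun[r2])
    common <- intersect(k1, k2)
    if (length(common) >= 2L) {
      d <- tmat[r1[match(common, k1)], , drop = FALSE] -
        tmat[r2[match(common, k2)], , drop = FALSE]
      mu <- colMeans(d)
      s <- apply(d, 2L, sd)
      delta <- ifelse(s > 0, mu / (s / sqrt(nrow(d))), sign(mu) * Inf)
      delta[mu == 0 & s == 0] <- 0
    } else {
      contrast <- "mean_t_difference"
    }
  }
  if (contrast == "mean_t_difference")
    delta <- colMeans(tmat[r1, , drop = FALSE]) -
      colMeans(tmat[r2, , drop = FALSE])
  delta <- delta * signs
  lab <- reference_labels(kind)
  label <- ifelse(delta > 0, lab["ref"], ifelse(delta < 0, lab["anti"],
                                                NA_character_))
  data.frame(voxel = voxels$voxel, patch_id = voxels$patch_id,
             ecc_band = voxels$ecc_band, delta_t = delta, label = label,
             stringsAsFactors = FALSE)
}

#' Label voxel orientation preferences from training data
#'
#' For each voxel, computes the signed mean t-difference between the
#' patch-relative reference condition (radial for gratings, vertical for
#' spirals; see [condition_label_map()]) and the other condition over the
#' chosen subruns, and labels the voxel by the sign of that contrast. Exact
#' ties (`delta_t == 0`) carry no label. In cross-validated analyses only
#' the training subruns of a fold are passed here, so test data never
#' influence the labels.
#'
#' @param dataset a `pattern_dataset`.
#' @param subject subject id.
#' @param kind stimulus kind.
#' @param subruns subrun indices to use (both runs); default all.
#' @param contrast `"mean_t_difference"` (default) or `"t_statistic"` (a
#'   one-sample t across subrun-wise differences).
#' @return data frame of class `preference_labels`: `voxel`, `patch_id`,
#'   `ecc_band`, `delta_t` (positive = reference-preferring), `label`.
#' @export
label_voxel_preferences <- function(dataset, subject, kind,
                                    subruns = NULL,
                                    contrast = "mean_t_difference") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  info <- dataset$info
  subruns <- subruns %||% sort(unique(info$subrun))
  if (length(subruns) == 0L) stop_("empty training set (no subruns)")
  rows <- which(info$subject == subject & info$kind == kind &
                  info$subrun %in% subruns)
  if (length(rows) == 0L) stop_("no patterns for this subject/kind/subruns")
  out <- label_core(dataset$t[rows, , drop = FALSE], info[rows, ],
                    dataset$voxels, kind, dataset$grid$patch_centers,
                    contrast)
  class(out) <- c("preference_labels", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "subject") <- subject
  out
}

#' Split labeled voxels into the two opposite-preference sets
#'
#' @param labels a `preference_labels` data frame.
#' @return list with `A` (reference-preferring voxel ids: radial or
#'   vertical), `B` (opposite set), the two label names, and logical
#'   `empty` flags. Unlabeled (tied) voxels belong to neither set.
#' @export
split_voxel_sets <- function(labels) {
  lab <- reference_labels(attr(labels, "kind") %||%
                            if (any(labels$label %in% c("radial", "tangential"),
                                    na.rm = TRUE)) "grating" else "spiral")
  A <- labels$voxel[!is.na(labels$label) & labels$label == lab["ref"]]
  B <- labels$voxel[!is.na(labels$label) & labels$label == lab["anti"]]
  list(A = A, B = B, label_A = unname(lab["ref"]), label_B = unname(lab["anti"]),
       empty = c(A = length(A) == 0L, B = length(B) == 0L))
}

#' Preference proportions, pooled histogram and amplitude contrasts
#'
#' Summarises voxel orientation preferences across subjects for each
#' stimulus kind, using all subruns (no cross-validation; this is the
#' descriptive summary, not the replicability analysis). Reports both the
#' voxel-pooled proportion and the mean of per-subject proportions, the
#' per-subject percentage-point difference with a two-sided across-subject
#' t-test against 0 (subject as random effect), and - when the dataset
#' carries the simulator's noise-free amplitude channel - the mean
#' between-condition response difference in percent signal change.
#'
#' @param dataset a `pattern_dataset`.
#' @param contrast passed to [label_voxel_preferences()].
#' @return list of class `preference_summary`: `per_subject` (one row per
#'   subject x kind), `group` (one row per kind), `histogram` (pooled
#'   `delta_t` values, one row per labeled voxel x subject).
#' @export
preference_proportions <- function(dataset, contrast = "mean_t_difference") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  subjects <- sort(unique(dataset$info$subject))
  if (length(subjects) < 2L)
    stop_("need at least 2 subjects for the group test")
  kinds <- unique(dataset$info$kind)
  per_subject <- list()
  hist_rows <- list()
  for (kind in kinds) {
    lab <- reference_labels(kind)
    for (s in subjects) {
      lb <- label_voxel_preferences(dataset, s, kind, contrast = contrast)
      nA <- sum(lb$label == lab["ref"], na.rm = TRUE)
      nB <- sum(lb$label == lab["anti"], na.rm = TRUE)
      if (nA + nB == 0L) {
        warning("subject ", s, " (", kind, ") has no labeled voxels; dropped",
                call. = FALSE)
        next
      }
      psc <- NA_real_
      if (!is.null(dataset$amplitude)) {
        ai <- dataset$amp_info
        v <- stimulus_variants(kind)
        a1 <- dataset$amplitude[which(ai$subject == s & ai$kind == kind &
                                        ai$condition == v[1L]), ]
        a2 <- dataset$amplitude[which(ai$subject == s & ai$kind == kind &
                                        ai$condition == v[2L]), ]
        signs <- patch_reference_signs(kind, dataset$voxels,
                                       dataset$grid$patch_centers)
        psc <- mean((a1 - a2) * signs)
      }
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = s, kind = kind, n_ref = nA, n_anti = nB,
        pct_ref = 100 * nA / (nA + nB), pct_anti = 100 * nB / (nA + nB),
        diff_pct = 100 * (nA - nB) / (nA + nB), mean_contrast_psc = psc,
        stringsAsFactors = FALSE)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        subject = s, kind = kind,
        delta_t = lb$delta_t[!is.na(lb$label)], stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, per_subject)
  histogram <- do.call(rbind, hist_rows)
  group <- do.call(rbind, lapply(kinds, function(kind) {
    d <- per_subject[per_subject$kind == kind, ]
    tt <- tryCatch(across_subject_ttest(d$diff_pct, two_sided = TRUE),
                   error = function(e)
                     data.frame(statistic = NA_real_, p = NA_real_,
                                n = nrow(d)))
    data.frame(kind = kind,
               label_ref = reference_labels(kind)[["ref"]],
               label_anti = reference_labels(kind)[["anti"]],
               pooled_pct_ref = 100 * sum(d$n_ref) /
                 sum(d$n_ref + d$n_anti),
               subject_mean_pct_ref = mean(d$pct_ref),
               t = tt$statistic, p = tt$p, n = tt$n,
               mean_contrast_psc = mean(d$mean_contrast_psc),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_subject = per_subject, group = group,
                 histogram = histogram),
            class = "preference_summary")
}

#' @export
print.preference_summary <- function(x, ...) {
  cat("<preference_summary>\n")
  print(x$group, digits = 4)
  invisible(x)
}
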