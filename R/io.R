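# Serialization: tidy TSV pattern tables and optional NIfTI export.

#' Write a pattern dataset as a tidy TSV
#'
#' Long format, one row per (subject, stimulus kind, run, subrun,
#' condition, voxel): columns `subject`, `stimulus_kind`, `run`, `subrun`,
#' `condition`, `patch_id`, `ecc_band`, `voxel_x`, `voxel_y`, `t_value`.
#' This is the documented interchange format for user-supplied pattern
#' tables.
#'
#' @param dataset a `pattern_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pattern_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  info <- dataset$info
  vox <- dataset$voxels
  n <- nrow(info)
  v <- nrow(vox)
  long <- data.frame(
    subject = rep(info$subject, each = v),
    stimulus_kind = rep(info$kind, each = v),
    run = rep(info$run, each = v),
    subrun = rep(info$subrun, each = v),
    condition = rep(info$condition, each = v),
    patch_id = rep(vox$patch_id, times = n),
    ecc_band = rep(vox$ecc_band, times = n),
    voxel_x = rep(vox$ix, times = n),
    voxel_y = rep(vox$iy, times = n),
    t_value = as.vector(t(dataset$t)))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pattern dataset from a tidy TSV
#'
#' Reads the format written by [write_pattern_tsv()] and reconstructs a
#' `pattern_dataset` (without the simulator-only amplitude and gain
#' channels). Voxel identity is (patch_id, voxel_x, voxel_y); every pattern
#' must cover the same voxel set.
#'
#' @param path TSV file.
#' @param annulus,voxel_mm,columns_per_voxel grid geometry to attach.
#' @return a `pattern_dataset`.
#' @export
read_pattern_tsv <- function(path, annulus = annulus_spec(), voxel_mm = 2,
                             columns_per_voxel = 8L) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "stimulus_kind", "run", "subrun", "condition",
            "patch_id", "ecc_band", "voxel_x", "voxel_y", "t_value")
  if (!all(need %in% names(long)))
    stop_("missing columns: ", paste(setdiff(need, names(long)),
                                     collapse = ", "))
  nu <- max(long$voxel_x)
  nv <- max(long$voxel_y)
  if (nu %% 3L != 0L)
    stop_("voxel_x extent must be a multiple of 3 (eccentricity bands)")
  grid <- voxel_grid(annulus, nu, nv, voxel_mm, columns_per_voxel)
  vox <- grid$voxels
  vkey <- paste(vox$patch_id, vox$ix, vox$iy)
  long$vpos <- match(paste(long$patch_id, long$voxel_x, long$voxel_y), vkey)
  if (any(is.na(long$vpos))) stop_("voxel coordinates outside the grid")
  pkey <- paste(long$subject, long$stimulus_kind, long$run, long$subrun,
                long$condition)
  patterns <- unique(pkey)
  if (nrow(long) != length(patterns) * nrow(vox))
    stop_("every pattern must cover the same complete voxel grid")
  long$ppos <- match(pkey, patterns)
  tmat <- matrix(NA_real_, length(patterns), nrow(vox))
  tmat[cbind(long$ppos, long$vpos)] <- long$t_value
  if (any(!is.finite(tmat))) stop_("patterns contain non-finite t-values")
  first <- long[!duplicated(long$ppos), ]
  first <- first[order(first$ppos), ]
  info <- data.frame(subject = first$subject, kind = first$stimulus_kind,
                     run = first$run, subrun = first$subrun,
                     condition = first$condition, stringsAsFactors = FALSE)
  ord <- order(info$subject, info$kind, info$run, info$subrun,
               match(info$condition, c("plus45", "minus45", "clockwise",
                                       "anticlockwise")))
  structure(list(t = tmat[ord, , drop = FALSE], info = info[ord, ],
                 voxels = vox, amplitude = NULL, amp_info = NULL,
                 gains = NULL, grid = grid, scenario = NULL,
                 t_scale = NA_real_),
            class = "pattern_dataset")
}

#' Export patterns and ROI mask as NIfTI volumes
#'
#' Arranges the four patch sheets as slices of a `nu x nv x 4` volume and
#' writes one 4D NIfTI file of all patterns (in `info` row order) plus an
#' integer ROI label mask volume (patch id 1-4). Requires the RNifti
#' package.
#'
#' @param dataset a `pattern_dataset`.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_patterns_nifti <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_("NIfTI export requires the RNifti package")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_("cannot create directory ", dir)
  vox <- dataset$voxels
  nu <- dataset$grid$nu
  nv <- dataset$grid$nv
  n <- nrow(dataset$t)
  arr <- array(0, c(nu, nv, 4L, n))
  idx <- cbind(vox$ix, vox$iy, vox$patch_id)
  for (i in seq_len(n))
    arr[cbind(idx, i)] <- dataset$t[i, ]
  vsz <- dataset$grid$voxel_mm
  pat <- file.path(dir, "patterns.nii")
  msk <- file.path(dir, "roi_mask.nii")
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(vsz, vsz, vsz, 1)),
                     pat)
  mask <- array(0L, c(nu, nv, 4L))
  mask[idx] <- vox$patch_id
  RNifti::writeNifti(RNifti::asNifti(mask, pixdim = rep(vsz, 3)), msk)
  invisible(c(pat, msk))
}
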