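# Stimulus and retinotopic ROI geometry.
#
# Conventions used throughout the package:
#   * visual-field polar angle is measured in degrees clockwise from the
#     upper vertical meridian;
#   * orientations live in [0, 180), 0 = vertical, increasing clockwise.
# These two conventions make the patch-relative preference examples (e.g.
# "right-tilted grating is radial in the upper-right quarterfield") direct
# consequences of the arithmetic below.

#' Log-polar stimulus annulus
#'
#' Describes the annular aperture in which all stimuli are shown and its
#' log-polar tiling: `n_wedges` radial divisions and `n_rings` concentric
#' tiles whose boundary radii are exponentially spaced between the inner and
#' outer radius (see [logpolar_radii()]).
#'
#' @param r_inner,r_outer inner and outer radius in degrees visual angle.
#' @param n_rings number of concentric tiles.
#' @param n_wedges number of radial divisions.
#' @return an object of class `annulus_spec`.
#' @examples
#' annulus_spec()
#' @export
annulus_spec <- function(r_inner = 1.5, r_outer = 7.04, n_rings = 3L,
                         n_wedges = 12L) {
  if (!is_num1(r_inner) || !is_num1(r_outer) || r_inner <= 0 ||
      r_outer <= r_inner)
    stop_("annulus radii must satisfy r_outer > r_inner > 0")
  if (!is_count(n_rings) || !is_count(n_wedges))
    stop_("n_rings and n_wedges must be positive integers")
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 n_rings = as.integer(n_rings),
                 n_wedges = as.integer(n_wedges)),
            class = "annulus_spec")
}

#' Exponentially spaced ring-boundary radii
#'
#' Radii of the concentric divisions of a log-polar annulus, geometrically
#' spaced so that each ring covers an equal interval of log eccentricity
#' (the standard approximation to equal cortical extent under logarithmic
#' cortical magnification).
#'
#' @param r_inner,r_outer inner and outer radius (degrees visual angle).
#' @param n_rings number of rings.
#' @return numeric vector of `n_rings + 1` strictly increasing radii whose
#'   first and last elements equal `r_inner` and `r_outer` exactly.
#' @examples
#' round(logpolar_radii(1.5, 7.04, 3), 2) # 1.50 2.51 4.20 7.04
#' @export
logpolar_radii <- function(r_inner, r_outer, n_rings) {
  if (!is_num1(r_inner) || !is_num1(r_outer) || r_inner <= 0 ||
      r_outer <= r_inner)
    stop_("invalid radii: need r_outer > r_inner > 0")
  if (!is_count(n_rings)) stop_("n_rings must be a positive integer")
  r <- r_inner * (r_outer / r_inner)^(seq.int(0L, n_rings) / n_rings)
  r[1L] <- r_inner
  r[n_rings + 1L] <- r_outer
  r
}

#' Stimulus specification
#'
#' A stimulus is either a uniform square-wave grating tilted 45 degrees
#' clockwise (`"plus45"`) or anti-clockwise (`"minus45"`) from vertical, or a
#' logarithmic spiral whose edges keep a constant +/-45 degree angle to the
#' radius (`"clockwise"` / `"anticlockwise"` sense). The two variants of each
#' kind are orthogonal to each other at every visual-field location, and the
#' spiral pair is balanced about the radial direction everywhere.
#'
#' @param kind `"grating"` or `"spiral"`.
#' @param variant `"plus45"`/`"minus45"` for gratings,
#'   `"clockwise"`/`"anticlockwise"` for spirals.
#' @param spatial_frequency grating spatial frequency (cycles per degree).
#' @param cycles_per_perimeter number of contrast cycles a spiral completes
#'   along the perimeter.
#' @param phase carrier phase in radians (irrelevant to the analytic
#'   orientation field; kept for raster rendering).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("grating", "spiral"), variant,
                          spatial_frequency = 1.25,
                          cycles_per_perimeter = 22, phase = 0) {
  kind <- match.arg(kind)
  allowed <- if (kind == "grating") c("plus45", "minus45") else
    c("clockwise", "anticlockwise")
  if (!is.character(variant) || length(variant) != 1L || !variant %in% allowed)
    stop_("variant for a ", kind, " must be one of: ",
          paste(allowed, collapse = ", "))
  if (!is_num1(spatial_frequency) || spatial_frequency <= 0)
    stop_("spatial_frequency must be positive")
  if (!is_num1(cycles_per_perimeter) || cycles_per_perimeter <= 0)
    stop_("cycles_per_perimeter must be positive")
  structure(list(kind = kind, variant = variant,
                 spatial_frequency = spatial_frequency,
                 cycles_per_perimeter = cycles_per_perimeter, phase = phase),
            class = "stimulus_spec")
}

#' The orthogonal stimulus pair of one kind
#'
#' @param kind `"grating"` or `"spiral"`.
#' @return list of two `stimulus_spec` objects (the two variants).
#' @export
stimulus_pair <- function(kind = c("grating", "spiral")) {
  kind <- match.arg(kind)
  v <- stimulus_variants(kind)
  list(stimulus_spec(kind, v[1L]), stimulus_spec(kind, v[2L]))
}

stimulus_variants <- function(kind) {
  if (kind == "grating") c("plus45", "minus45") else
    c("clockwise", "anticlockwise")
}

# vectorised orientation field; no domain checks (internal)
orientation_field <- function(kind, variant, polar_angle) {
  switch(kind,
    grating = rep(if (variant == "plus45") 45 else 135,
                  length.out = length(polar_angle)),
    spiral = if (variant == "clockwise") mod180(polar_angle + 45) else
      mod180(polar_angle - 45),
    stop_("unknown stimulus kind: ", kind))
}

#' Local stimulus orientation at a visual-field position
#'
#' Gratings have the same orientation everywhere (45 for `"plus45"`, 135 for
#' `"minus45"`). A logarithmic spiral's local orientation is the polar angle
#' plus or minus 45 degrees (modulo 180), so the two senses are orthogonal
#' and radially balanced at every location.
#'
#' @param stim a [stimulus_spec()].
#' @param polar_angle degrees clockwise from the upper vertical meridian
#'   (vectorised).
#' @param eccentricity degrees visual angle (vectorised); must lie inside
#'   the annulus.
#' @param annulus an [annulus_spec()] defining the valid domain.
#' @return orientation(s) in `[0, 180)`.
#' @examples
#' local_stimulus_orientation(stimulus_spec("spiral", "anticlockwise"), 45, 3)
#' @export
local_stimulus_orientation <- function(stim, polar_angle, eccentricity,
                                       annulus = annulus_spec()) {
  stopifnot(inherits(stim, "stimulus_spec"))
  if (any(eccentricity < annulus$r_inner - 1e-9 |
          eccentricity > annulus$r_outer + 1e-9))
    stop_("location outside the stimulus annulus")
  orientation_field(stim$kind, stim$variant, polar_angle)
}

#' Radial and tangential reference orientations of a patch
#'
#' For a retinotopic patch centred at polar angle `polar_center`, the radial
#' orientation is the orientation of the line from fixation through the
#' patch, and the tangential orientation is orthogonal to it.
#'
#' @param polar_center degrees clockwise from vertical.
#' @return named numeric vector `c(radial = , tangential = )` in `[0, 180)`.
#' @examples
#' patch_reference_orientations(315) # radial 135, tangential 45
#' @export
patch_reference_orientations <- function(polar_center) {
  c(radial = mod180(polar_center), tangential = mod180(polar_center + 90))
}

#' Map stimulus conditions to patch-relative preference labels
#'
#' For gratings the two conditions are labeled `radial`/`tangential`
#' according to which grating's orientation matches the patch's radial
#' reference orientation. For spirals the condition whose local orientation
#' at the patch centre is vertical (0) is labeled `vertical`, the orthogonal
#' one `horizontal`. Both mappings are only defined for diagonal patches
#' (polar centre at 45, 135, 225 or 315 degrees), where the spiral pair is
#' exactly vertical/horizontal and the grating pair exactly
#' radial/tangential.
#'
#' @param kind `"grating"` or `"spiral"`.
#' @param polar_center patch centre, degrees clockwise from vertical.
#' @return named character vector mapping each condition variant to its
#'   label; e.g. `c(plus45 = "radial", minus45 = "tangential")`.
#' @examples
#' condition_label_map("grating", 45)
#' condition_label_map("spiral", 45)
#' @export
condition_label_map <- function(kind = c("grating", "spiral"), polar_center) {
  kind <- match.arg(kind)
  refs <- patch_reference_orientations(polar_center)
  v <- stimulus_variants(kind)
  ori <- vapply(v, function(vv)
    orientation_field(kind, vv, polar_center), numeric(1))
  tol <- 1e-9
  if (kind == "grating") {
    hit <- ang_diff(ori, refs["radial"]) < tol
    if (sum(hit) != 1L)
      stop_("unsupported patch geometry: neither grating is exactly radial ",
            "at polar centre ", polar_center)
    out <- ifelse(hit, "radial", "tangential")
  } else {
    vert <- ang_diff(ori, 0) < tol
    horiz <- ang_diff(ori, 90) < tol
    if (sum(vert) != 1L || sum(horiz) != 1L)
      stop_("unsupported patch geometry: spiral is neither vertical nor ",
            "horizontal at polar centre ", polar_center,
            " (only diagonal patches are supported)")
    out <- ifelse(vert, "vertical", "horizontal")
  }
  stats::setNames(out, v)
}

#' Quarterfield and eccentricity-band ROI layout
#'
#' Builds the patch layout used throughout the package: the central third of
#' each visual quarterfield (polar width 30 degrees, centres at 45, 135, 225
#' and 315 degrees clockwise from vertical), each split into three
#' eccentricity bands at exponentially spaced radii (equal log-eccentricity
#' intervals, the proxy for approximately equal cortical surface area).
#'
#' @param annulus an [annulus_spec()].
#' @return a data frame of class `roi_table` with one row per patch: the four
#'   all-eccentricity quarterfield patches (`ecc_band == "all"`) followed by
#'   the twelve band-specific patches (`ecc_band` `"1"`-`"3"`, inner to
#'   outer). Columns: `patch_id`, `ecc_band`, `polar_center`, `polar_min`,
#'   `polar_max`, `ecc_min`, `ecc_max`.
#' @examples
#' build_rois()
#' @export
build_rois <- function(annulus = annulus_spec()) {
  centers <- c(45, 135, 225, 315)
  half_width <- 15
  bounds <- logpolar_radii(annulus$r_inner, annulus$r_outer, 3L)
  all_patch <- data.frame(
    patch_id = 1:4, ecc_band = "all", polar_center = centers,
    polar_min = centers - half_width, polar_max = centers + half_width,
    ecc_min = annulus$r_inner, ecc_max = annulus$r_outer,
    stringsAsFactors = FALSE)
  bands <- do.call(rbind, lapply(1:3, function(b) {
    d <- all_patch
    d$ecc_band <- as.character(b)
    d$ecc_min <- bounds[b]
    d$ecc_max <- bounds[b + 1L]
    d
  }))
  out <- rbind(all_patch, bands)
  rownames(out) <- NULL
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Write an ROI layout as a tab-separated table
#'
#' @param rois a `roi_table` from [build_rois()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
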