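# End-to-end pipeline: simulate -> patterns -> preference -> decoding
# (including shifts) -> replicability -> group statistics -> tidy reports.

#' Pipeline configuration
#'
#' Bundles a simulation [scenario()] with the analysis switches. The master
#' seed is the scenario's seed; every stochastic stage (data generation,
#' bootstrap) derives its stream from it, so a pipeline run is
#' bit-reproducible.
#'
#' @param scen a [scenario()] (must carry a seed).
#' @param selections voxel selections for decoding.
#' @param shift_magnitudes spatial-shift magnitudes in voxel widths
#'   (`NULL` or empty to skip the shift analysis).
#' @param shift_directions grid-axis shift directions.
#' @param n_boot bootstrap resamples for replicability CIs. Changing
#'   `n_boot` changes only CIs and p-values, never point estimates.
#' @param contrast labeling/replicability contrast, see
#'   [label_voxel_preferences()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scen,
                            selections = c("all", "A", "B"),
                            shift_magnitudes = c(0, 0.5, 1, 2, 3),
                            shift_directions = c("+x", "-x", "+y", "-y"),
                            n_boot = 10000L,
                            contrast = "mean_t_difference") {
  stopifnot(inherits(scen, "scenario"))
  if (is.null(scen$seed)) stop_("configuration error: scenario has no seed")
  structure(list(scenario = scen, selections = selections,
                 shift_magnitudes = shift_magnitudes,
                 shift_directions = shift_directions,
                 n_boot = as.integer(n_boot), contrast = contrast),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  scen <- config$scenario
  list(scenario = list(
         name = scen$name, n_subjects = scen$n_subjects, seed = scen$seed,
         kinds = scen$kinds, fidelity = scen$fidelity,
         map = unclass(scen$map), gain = unclass(scen$gain),
         noise = unclass(scen$noise),
         design = unclass(scen$design)[c("TR", "subruns_per_run",
                                         "blocks_per_subrun", "block_s",
                                         "gap_s", "conditions",
                                         "presentation_hz")],
         annulus = unclass(scen$annulus),
         grid = list(nu = scen$nu, nv = scen$nv, voxel_mm = scen$voxel_mm,
                     columns_per_voxel = scen$columns_per_voxel)),
       analysis = list(selections = config$selections,
                       shift_magnitudes = config$shift_magnitudes,
                       shift_directions = config$shift_directions,
                       n_boot = config$n_boot, contrast = config$contrast))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the nested parameter objects (`scenario:` with `map:`,
#' `gain:`, `noise:`, `design:`, `annulus:`, `grid:` sections, and an
#' optional `analysis:` section). Omitted entries take the package
#' defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- y$scenario %||% list()
  build <- function(ctor, args) {
    args <- args %||% list()
    do.call(ctor, args[names(args) %in% names(formals(ctor))])
  }
  scen_args <- list(
    name = sc$name %||% "mixed", n_subjects = sc$n_subjects %||% 18L,
    seed = sc$seed, map = build(neural_map_params, sc$map),
    gain = build(gain_field_params, sc$gain),
    noise = build(noise_params, sc$noise),
    design = build(block_design, sc$design),
    annulus = build(annulus_spec, sc$annulus),
    kinds = sc$kinds %||% c("grating", "spiral"),
    fidelity = sc$fidelity %||% "pattern")
  g <- sc$grid %||% list()
  scen_args <- c(scen_args, list(nu = g$nu %||% 12L, nv = g$nv %||% 6L,
                                 voxel_mm = g$voxel_mm %||% 2,
                                 columns_per_voxel =
                                   g$columns_per_voxel %||% 8L))
  an <- y$analysis %||% list()
  pipeline_config(do.call(scenario, scen_args),
                  selections = an$selections %||% c("all", "A", "B"),
                  shift_magnitudes = an$shift_magnitudes %||%
                    c(0, 0.5, 1, 2, 3),
                  shift_directions = an$shift_directions %||%
                    c("+x", "-x", "+y", "-y"),
                  n_boot = an$n_boot %||% 10000L,
                  contrast = an$contrast %||% "mean_t_difference")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preference summary -> cross-validated decoding
#' (including the spatial-shift curve) -> replicability (bootstrap, ROI
#' ANOVAs), and writes all tidy report tables, the fully resolved
#' configuration and a run log to `out_dir`. Identical configurations
#' produce byte-identical tables.
#'
#' @param config a [pipeline_config()] (or a [scenario()], which is wrapped
#'   with default analysis settings).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return list of class `pipeline_results` with all result objects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "scenario")) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(proc.time()[3L] - t0), ...)
    message(msg)
    log <<- c(log, msg)
  }
  t0 <- proc.time()[3L]
  note(sprintf("simulate: scenario '%s', %d subjects, seed %d",
               config$scenario$name, config$scenario$n_subjects,
               config$scenario$seed))
  dataset <- generate_dataset(config$scenario)
  note(sprintf("patterns: %d patterns x %d voxels", nrow(dataset$t),
               ncol(dataset$t)))
  note("preference proportions")
  pref <- preference_proportions(dataset, contrast = config$contrast)
  mags <- config$shift_magnitudes %||% 0
  note(sprintf("decoding: selections [%s], shifts [%s] voxels",
               paste(config$selections, collapse = ", "),
               paste(mags, collapse = ", ")))
  decoding <- shift_decoding_curve(dataset, magnitudes = mags,
                                   directions = config$shift_directions,
                                   selections = config$selections,
                                   contrast = config$contrast)
  dec_sum <- decoding_summary(decoding)
  note("replicability")
  repl <- crossval_replicability(dataset, contrast = config$contrast)
  repl_sum <- replicability_summary(repl, n_boot = config$n_boot,
                                    seed = config$scenario$seed)
  anovas <- rbind(roi_effect_anova(repl, "quarterfield"),
                  roi_effect_anova(repl, "eccentricity"))
  note("done")
  results <- structure(list(config = config, dataset = dataset,
                            preference = pref, decoding = decoding,
                            decoding_summary = dec_sum,
                            replicability = repl,
                            replicability_summary = repl_sum,
                            anovas = anovas, log = log),
                       class = "pipeline_results")
  if (!is.null(out_dir)) write_reports(results, out_dir)
  results
}

#' Write tidy report tables
#'
#' One tab-separated table per analysis, plus the fully resolved
#' configuration (YAML) and the run log. Missing cells (e.g. empty
#' preference sets) are written as `NA`, never as zero.
#'
#' @param results a `pipeline_results` object.
#' @param out_dir output directory.
#' @param figures also write PNG figures (requires ggplot2).
#' @return character vector of written paths, invisibly.
#' @export
write_reports <- function(results, out_dir, figures = FALSE) {
  stopifnot(inherits(results, "pipeline_results"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_("cannot create output directory: ", out_dir)
  tsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(
    tsv(results$preference$per_subject, "preference_subject.tsv"),
    tsv(results$preference$group, "preference_group.tsv"),
    tsv(results$preference$histogram, "preference_histogram.tsv"),
    tsv(results$decoding, "decoding_folds.tsv"),
    tsv(results$decoding_summary$per_subject, "decoding_subject.tsv"),
    tsv(results$decoding_summary$group, "decoding_group.tsv"),
    tsv(results$replicability, "replicability_subject.tsv"),
    tsv(results$replicability_summary, "replicability_group.tsv"),
    tsv(results$anovas, "anova.tsv"),
    tsv(as.data.frame(results$dataset$grid$rois), "roi_table.tsv"))
  cfg <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(config_to_list(results$config), cfg)
  lg <- file.path(out_dir, "pipeline_log.txt")
  writeLines(results$log, lg)
  paths <- c(paths, cfg, lg)
  if (figures) {
    for (fg in list(list(plot_replicability_summary(
                           results$replicability_summary),
                         "replicability.png"),
                    list(plot_decoding_summary(
                           results$decoding_summary$group),
                         "decoding.png"),
                    list(plot_preference_histogram(results$preference),
                         "preference_histogram.png"))) {
      p <- file.path(out_dir, fg[[2L]])
      ggplot2::ggsave(p, fg[[1L]], width = 7, height = 4, dpi = 150)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_("figure export requires the ggplot2 package")
}

#' Figure: pooled preference histogram
#'
#' Histogram of the signed voxel preference contrast (reference minus
#' anti-reference mean t-difference), pooled across subjects and patches,
#' one panel per stimulus kind.
#'
#' @param pref a `preference_summary`.
#' @return a ggplot object.
#' @export
plot_preference_histogram <- function(pref) {
  need_ggplot2()
  ggplot2::ggplot(pref$histogram,
                  ggplot2::aes(x = .data$delta_t,
                               fill = .data$delta_t > 0)) +
    ggplot2::geom_histogram(bins = 60, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "preference contrast (t difference)", y = "voxels")
}

#' Figure: group decoding accuracies
#'
#' @param group the `group` table of [decoding_summary()].
#' @return a ggplot object.
#' @export
plot_decoding_summary <- function(group) {
  need_ggplot2()
  ggplot2::ggplot(group,
                  ggplot2::aes(x = factor(.data$shift_mm),
                               y = .data$mean_accuracy,
                               fill = .data$set_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "test-pattern shift (mm)", y = "decoding accuracy",
                  fill = "voxel set")
}

#' Figure: replicability indices with bootstrap CIs
#'
#' @param summ output of [replicability_summary()].
#' @return a ggplot object.
#' @export
plot_replicability_summary <- function(summ) {
  need_ggplot2()
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$roi, y = .data$mean,
                                     fill = .data$roi)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.3) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~set, nrow = 1) +
    ggplot2::labs(x = "ROI", y = "replicability index")
}
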