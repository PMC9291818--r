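# Pipeline orchestration: simulate -> ratios -> mosaic -> roi-stats -> segfit
# (+ root-system table and stats) as a configured, seeded, manifest-logged run.
#
# One global seed deterministically derives per-stage seeds
# (stage_seed = (global*1009 + 1000*stage_index) mod 2^31-1), so stages can be
# re-run in isolation and a repeat run with the same config is byte-identical.

#' Derive a per-stage seed from the global pipeline seed
#'
#' @param global_seed Integer global seed.
#' @param stage_index 1-based stage index.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 1009 + 1000 * stage_index) %% (2^31 - 1))
}

PIPELINE_STAGES <- c("scene", "counts", "mosaic", "maps", "qc", "roi",
                     "segfit", "root_table", "root_stats")

#' Default pipeline configuration
#'
#' Stage toggles, scene/layout/statistics parameter blocks and the global
#' seed. The default layout is a 2 x 2 mosaic of 96 px tiles with a 24 px
#' overlap (desk-scale stand-in for the published 4 x 4 x 512 px geometry);
#' all blocks accept the corresponding constructor's arguments.
#'
#' @param seed Global seed; per-stage seeds derive from it ([derive_seed()]).
#' @param stages Named logical list toggling the stages (in
#'   `PIPELINE_STAGES` order).
#' @param scene List of [scene_config()] overrides (canvas size is derived
#'   from the layout).
#' @param layout List of [mosaic_layout()] arguments (nrow, ncol, tile_px,
#'   overlap_px or overlap_um, pre_sputtered...).
#' @param control List with `at13c`, `at15n` (or a `path` to a control CSV).
#' @param stats List: `criterion` (AIC/BIC), `alpha`, `bootstrap` replicates,
#'   `min_group` (minimum ROIs for a group fit).
#' @param root_system List of [root_system_config()] overrides.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = list(),
                            scene = list(),
                            layout = list(nrow = 2L, ncol = 2L, tile_px = 96L,
                                          overlap_px = 24L),
                            control = list(at13c = 1.07, at15n = 0.37),
                            stats = list(criterion = "AIC", alpha = 0.05,
                                         bootstrap = 199L, min_group = 12L),
                            root_system = list()) {
  st <- stats::setNames(as.list(rep(TRUE, length(PIPELINE_STAGES))), PIPELINE_STAGES)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), stages = st, scene = scene,
                 layout = layout, control = control, stats = stats,
                 root_system = root_system),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

validate_pipeline_config <- function(config) {
  st <- config$stages
  need <- list(counts = "scene", mosaic = "counts", maps = "mosaic",
               qc = "maps", roi = "mosaic", segfit = "roi",
               root_stats = "root_table")
  for (stage in names(need)) {
    if (isTRUE(st[[stage]]) && !isTRUE(st[[need[[stage]]]]))
      stop("pipeline config invalid: stage '", stage,
           "' requires stage '", need[[stage]], "'")
  }
  invisible(config)
}

manifest_entry <- function(stage, seed, params, files) {
  files <- files[file.exists(files)]
  list(stage = stage, seed = seed, params = params,
       outputs = lapply(files, function(f)
         list(file = basename(f), md5 = unname(tools::md5sum(f)))))
}

#' Run the analysis pipeline on a synthetic scene
#'
#' Executes the enabled stages in order — scene generation, count simulation,
#' mosaic assembly, isotope maps, adsorption QC, ROI statistics, segmented
#' fits with model selection, root-system table and per-side statistics —
#' writing each stage's outputs plus a JSON run manifest (parameters, seeds,
#' output checksums) into `out_dir`. Re-running with an identical config
#' reproduces identical outputs. A stage failure aborts with the failing stage
#' named and a FAILED marker in the manifest.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("isopixel_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  st <- config$stages
  env <- new.env(parent = emptyenv())

  control <- if (!is.null(config$control$path))
    load_control_reference(config$control$path)
  else control_reference(config$control$at13c, config$control$at15n)

  run_stage <- function(stage, fun) {
    idx <- match(stage, PIPELINE_STAGES)
    seed <- derive_seed(config$seed, idx)
    files <- tryCatch(fun(seed), error = function(e) {
      manifest$stages[[stage]] <<- list(stage = stage, status = "FAILED",
                                        error = conditionMessage(e))
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    entry <- manifest_entry(stage, seed, list(), files)
    entry$status <- "OK"
    manifest$stages[[stage]] <<- entry
  }

  if (isTRUE(st$scene)) run_stage("scene", function(seed) {
    lay <- do.call(mosaic_layout, config$layout)
    env$layout <- lay
    sc_args <- config$scene
    sc_args$canvas_px <- canvas_dim(lay)[1L]
    sc_args$pixel_size_um <- lay$pixel_size_um
    sc_args$seed <- seed
    env$truth <- generate_root_tip_scene(do.call(scene_config, sc_args))
    f <- file.path(out_dir, c("scene_label.tif", "scene_p13c.tif", "scene_p15n.tif"))
    write_float_map(env$truth$label, f[1L], scale = 8,
                    meta = list(field = "tissue label", seed = seed))
    write_float_map(env$truth$p_c, f[2L], scale = 1.0000001,
                    meta = list(field = "true p13C", seed = seed))
    write_float_map(env$truth$p_n, f[3L], scale = 1.0000001,
                    meta = list(field = "true p15N", seed = seed))
    f
  })

  if (isTRUE(st$counts)) run_stage("counts", function(seed) {
    env$tiles <- simulate_counts(env$truth, env$layout, seed = seed)
    files <- vapply(seq_along(env$tiles), function(k) {
      f <- file.path(out_dir, sprintf("tile_%02d.tif", k))
      write_ion_stack(env$tiles[[k]], f)
      f
    }, character(1))
    c(files, sidecar_path(files))
  })

  if (isTRUE(st$mosaic)) run_stage("mosaic", function(seed) {
    env$mosaic <- assemble_mosaic(env$tiles, env$layout)
    f <- file.path(out_dir, "mosaic.tif")
    write_ion_stack(env$mosaic$canvas, f)
    c(f, sidecar_path(f))
  })

  if (isTRUE(st$maps)) run_stage("maps", function(seed) {
    env$maps <- isotope_pair_map(env$mosaic$canvas, control)
    f13 <- file.path(out_dir, "at13c.tif"); f15 <- file.path(out_dir, "at15n.tif")
    write_float_map(env$maps$at13c, f13, scale = 100.00001,
                    meta = list(field = "at%13C", stack = "mosaic", seed = seed))
    write_float_map(env$maps$at15n, f15, scale = 100.00001,
                    meta = list(field = "at%15N", stack = "mosaic", seed = seed))
    c(f13, f15)
  })

  if (isTRUE(st$qc)) run_stage("qc", function(seed) {
    qc <- adsorption_qc(env$maps$at15n, env$layout, env$mosaic$contribution)
    f <- file.path(out_dir, "adsorption_qc.csv")
    utils::write.csv(qc, f, row.names = FALSE)
    f
  })

  if (isTRUE(st$roi)) run_stage("roi", function(seed) {
    rois <- labels_to_roi_set(env$truth)
    env$roi_table <- roi_composition(env$mosaic$canvas, rois, control)
    f1 <- file.path(out_dir, "roi_table.csv")
    f2 <- file.path(out_dir, "tissue_summary.csv")
    utils::write.csv(env$roi_table, f1, row.names = FALSE)
    utils::write.csv(tissue_summary(env$roi_table), f2, row.names = FALSE)
    f1f2 <- c(f1, f2)
    lf <- file.path(out_dir, "rois.tif"); af <- file.path(out_dir, "rois.csv")
    write_roi_set(rois, lf, af)
    c(f1f2, lf, af)
  })

  if (isTRUE(st$segfit)) run_stage("segfit", function(seed) {
    tab <- env$roi_table
    groups <- list(fungi_CW = tab$tissue %in% c("HE", "HM", "HN") & tab$compartment == "CW",
                   fungi_L = tab$tissue %in% c("HE", "HM", "HN") & tab$compartment == "L",
                   plant_CW = tab$tissue %in% c("PC", "E", "VT") & tab$compartment == "CW",
                   plant_L = tab$tissue %in% c("PC", "E", "VT") & tab$compartment == "L")
    rows <- list()
    for (g in names(groups)) {
      d <- tab[groups[[g]], ]
      if (nrow(d) < config$stats$min_group) next
      fit <- fit_segmented(d$ape13c, d$ape15n,
                           bootstrap = config$stats$bootstrap,
                           alpha = config$stats$alpha, seed = seed)
      ms <- select_model(d$ape13c, d$ape15n, criterion = config$stats$criterion)
      rows[[g]] <- data.frame(
        group = g, n = fit$n, kink = fit$kink,
        breakpoint = fit$breakpoint, se_bp = fit$se_bp,
        slope_low = fit$coefficients[["slope_low"]],
        slope_high = fit$coefficients[["slope_high"]],
        intercept = fit$coefficients[["intercept"]],
        r2_total = fit$r_squared$total, davies_p = fit$davies_p,
        selected_model = ms$selected, stringsAsFactors = FALSE)
    }
    env$segfits <- do.call(rbind, rows)
    f <- file.path(out_dir, "segmented_fits.csv")
    utils::write.csv(env$segfits, f, row.names = FALSE)
    f
  })

  if (isTRUE(st$root_table)) run_stage("root_table", function(seed) {
    rs_args <- config$root_system
    rs_args$seed <- seed
    env$root_table <- generate_root_system_table(do.call(root_system_config, rs_args))
    f1 <- file.path(out_dir, "root_segments.csv")
    f2 <- file.path(out_dir, "root_tips.csv")
    utils::write.csv(env$root_table$segments, f1, row.names = FALSE)
    utils::write.csv(env$root_table$tips, f2, row.names = FALSE)
    c(f1, f2)
  })

  if (isTRUE(st$root_stats)) run_stage("root_stats", function(seed) {
    res <- root_side_analysis(env$root_table$segments)
    f <- file.path(out_dir, "root_side_stats.csv")
    utils::write.csv(res$summary, f, row.names = FALSE)
    f
  })

  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
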