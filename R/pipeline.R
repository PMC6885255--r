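# End-to-end pipeline: simulate -> segment -> extract -> select -> classify.
#
# Every stage reads its inputs from, and writes its outputs to, the run
# directory, so partial reruns can resume: a stage is skipped when all its
# outputs exist and the content hash of its inputs (plus the serialized
# config) is unchanged since they were produced.

#' Pipeline run configuration
#'
#' The serialized config plus the global seed fully determine every
#' artifact byte-for-byte (log timestamps excepted).
#'
#' @param spec A [phantom_spec()] for the simulate stage.
#' @param grow A [grow_options()] for segmentation.
#' @param seg_phase 1-based index of the phase segmented (default 2, the
#'   first post-contrast phase, where the lesion is enhanced).
#' @param glcm_levels GLCM quantization levels.
#' @param models Model ids used in selection and classification.
#' @param model_params Named hyperparameter overrides passed to every
#'   [model_config()].
#' @param step mmRFE elimination step (fraction of surviving features when
#'   < 1).
#' @param theta mmRFE accuracy threshold.
#' @param cv_k Folds of the stratified CV used throughout.
#' @param seed Global integer seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(spec = phantom_spec(),
                            grow = grow_options(),
                            seg_phase = 2,
                            glcm_levels = 16,
                            models = c("lr", "svm", "rf", "gbdt"),
                            model_params = list(),
                            step = 0.2,
                            theta = 0.8,
                            cv_k = 5,
                            seed = 1) {
  structure(list(spec = spec, grow = grow, seg_phase = as.integer(seg_phase),
                 glcm_levels = glcm_levels, models = models,
                 model_params = model_params, step = step, theta = theta,
                 cv_k = as.integer(cv_k), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_models <- function(config) {
  lapply(stats::setNames(config$models, config$models), function(mid)
    do.call(model_config, c(list(model_id = mid, seed = config$seed),
                            config$model_params)))
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(sort(paths)))
}

stage_fresh <- function(state, stage, in_hash, outputs) {
  if (!all(file.exists(outputs))) return(TRUE)
  old <- state[[stage]]
  is.null(old) || !identical(unlist(old), unlist(in_hash))
}

#' Run the full pipeline
#'
#' Executes simulate, segment, extract, select and classify in order,
#' writing `manifest.json`, segmented `masks/`, `dice_report.csv`,
#' `features.csv`, `removed_columns.json`, `trace.json`, `subset.txt`,
#' `report.json` and `run_log.txt` under `out_dir`. Stages whose inputs are
#' unchanged (content hash) and whose outputs exist are skipped.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_file <- file.path(out_dir, "run_state.json")
  state <- if (file.exists(state_file)) jsonlite::read_json(state_file) else list()
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  config_file <- file.path(out_dir, "config.json")
  write_json_artifact(serialize_config(config), config_file)
  cfg_hash <- hash_files(config_file)
  log_msg("run seed %d", config$seed)

  # -- simulate ------------------------------------------------------------
  manifest_file <- file.path(out_dir, "manifest.json")
  in_hash <- list(cfg = cfg_hash)
  if (stage_fresh(state, "simulate", in_hash, manifest_file)) {
    spec <- config$spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
    write_cohort(cohort, out_dir)
    log_msg("simulate: %d cases", spec$n_cases)
  } else log_msg("simulate: up to date, skipped")
  state$simulate <- in_hash

  # -- segment -------------------------------------------------------------
  dice_file <- file.path(out_dir, "dice_report.csv")
  masks_dir <- file.path(out_dir, "masks")
  in_hash <- list(cfg = cfg_hash, manifest = hash_files(manifest_file))
  if (stage_fresh(state, "segment", in_hash, dice_file)) {
    dir.create(masks_dir, showWarnings = FALSE)
    cases <- read_cohort(out_dir)
    rows <- lapply(cases, function(cs) {
      img <- cs$phases[[config$seg_phase]]
      mask <- region_grow(img, cs$roi, config$grow)
      write_mask_png(mask, file.path(masks_dir, paste0(cs$case_id, ".png")))
      data.frame(case_id = cs$case_id,
                 dice = if (is.null(cs$truth_mask)) NA_real_ else
                   dice(mask, cs$truth_mask))
    })
    dice_report <- do.call(rbind, rows)
    utils::write.csv(dice_report, dice_file, row.names = FALSE)
    log_msg("segment: mean dice %.4f", mean(dice_report$dice))
  } else log_msg("segment: up to date, skipped")
  state$segment <- in_hash

  # -- extract -------------------------------------------------------------
  features_file <- file.path(out_dir, "features.csv")
  removed_file <- file.path(out_dir, "removed_columns.json")
  in_hash <- list(cfg = cfg_hash, manifest = hash_files(manifest_file),
                  masks = hash_files(list.files(masks_dir, full.names = TRUE)))
  if (stage_fresh(state, "extract", in_hash, c(features_file, removed_file))) {
    cases <- read_cohort(out_dir, masks_dir = "masks")
    tab <- extract_cohort(cases, glcm_levels = config$glcm_levels)
    tab <- suppressMessages(drop_invalid_columns(tab))
    removed <- attr(tab, "removed")
    write_feature_table(tab, features_file)
    write_json_artifact(list(removed = as.list(removed)), removed_file)
    log_msg("extract: %d cases x %d features; removed %d all-zero columns (%s)",
            nrow(tab), ncol(tab) - 2, length(removed),
            paste(removed, collapse = ", "))
  } else log_msg("extract: up to date, skipped")
  state$extract <- in_hash

  # -- select --------------------------------------------------------------
  trace_file <- file.path(out_dir, "trace.json")
  subset_file <- file.path(out_dir, "subset.txt")
  in_hash <- list(cfg = cfg_hash, features = hash_files(features_file))
  if (stage_fresh(state, "select", in_hash, c(trace_file, subset_file))) {
    tab <- read_feature_table(features_file)
    cv <- cv_scheme("kfold", k = config$cv_k, seed = config$seed)
    res <- mmrfe(config_models(config), tab, step = config$step, cv = cv,
                 theta = config$theta)
    subset <- if (is.null(res$selected)) res$best_available else res$selected
    writeLines(subset, subset_file)
    write_json_artifact(list(
      theta = res$theta,
      selected = as.list(res$selected),
      selected_iteration = res$selected_iteration,
      candidates = as.list(res$candidates),
      iterations = lapply(res$trace, function(it)
        list(n_features = length(it$features),
             features = as.list(it$features),
             accuracy = as.list(it$accuracy),
             removed = as.list(it$removed)))), trace_file)
    log_msg("select: %d features selected (theta %.2f%s)", length(subset),
            config$theta,
            if (is.null(res$selected)) "; no candidate met theta, best available used" else "")
  } else log_msg("select: up to date, skipped")
  state$select <- in_hash

  # -- classify ------------------------------------------------------------
  report_file <- file.path(out_dir, "report.json")
  in_hash <- list(cfg = cfg_hash, features = hash_files(features_file),
                  subset = hash_files(subset_file))
  if (stage_fresh(state, "classify", in_hash, report_file)) {
    tab <- read_feature_table(features_file)
    subset <- readLines(subset_file)
    cv <- cv_scheme("kfold", k = config$cv_k, seed = config$seed)
    reports <- lapply(config_models(config), function(cfg)
      crossval_evaluate(cfg, tab, cv, features = subset))
    reports$ensemble <- crossval_evaluate(
      do.call(model_config, c(list(model_id = "ensemble", seed = config$seed),
                              config$model_params)),
      tab, cv, features = subset)
    write_json_artifact(lapply(reports, report_to_list), report_file)
    log_msg("classify: ensemble accuracy %.4f", reports$ensemble$accuracy)
  } else log_msg("classify: up to date, skipped")
  state$classify <- in_hash

  write_json_artifact(state, state_file)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

# JSON-serializable view of a pipeline config (profiles flattened).
serialize_config <- function(config) {
  sp <- config$spec
  list(
    spec = list(
      n_cases = sp$n_cases, image_size = sp$image_size,
      class_proportions = sp$class_proportions,
      kinetics = lapply(sp$kinetics, unclass),
      shapes = lapply(sp$shapes, unclass),
      textures = lapply(sp$textures, unclass),
      background = sp$background, lesion_baseline = sp$lesion_baseline,
      noise_sd = sp$noise_sd, roi_pad = sp$roi_pad,
      n_phases = sp$n_phases, quantize = sp$quantize),
    grow = unclass(config$grow),
    seg_phase = config$seg_phase,
    glcm_levels = config$glcm_levels,
    models = config$models,
    model_params = config$model_params,
    step = config$step, theta = config$theta, cv_k = config$cv_k,
    seed = config$seed)
}
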