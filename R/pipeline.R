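#' Default pipeline configuration
#'
#' A nested list covering every stage (phantoms, preprocessing, model,
#' sampler, training, post-processing, evaluation) plus a global seed and
#' output directory. All randomness flows from the root seed through
#' per-stage derived seeds. The defaults describe a small end-to-end run
#' that exercises the whole pipeline on one CPU.
#'
#' @param seed root seed; @param out_dir output directory.
#' @return Nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("oarseg_run")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantoms = list(n_train = 3L, n_val = 1L, n_test = 2L,
                    shape = c(64L, 64L, 32L), spacing = c(2.34, 2.34, 3.0),
                    noise_sd = 20),
    model = list(n_levels = 2L, base_filters = 8L, dropout_rate = 0,
                 out_channels = 3L),
    sampler = list(patch_size = c(16L, 16L, 8L), entropy_threshold = 2.0,
                   shell_distances_mm = c(20, 40)),
    training = list(lr_initial = 1e-2, lr_final = 1e-5,
                    planned_epochs = 2L, n_initializations = 2L,
                    tournament_schedule = list(c(1, 1)),
                    batch_size = 1L, steps_per_epoch = 3L, patience = 2L),
    postprocess = list(gaussian_sigma_mm = 1.5, binarize_threshold = 0.5,
                       connectivity = 26L)
  ), class = "run_config")
}

# Recursive schema check against the default config: unknown keys are
# rejected with a field-level message; a few value constraints enforced.
validate_run_config <- function(config) {
  ref <- unclass(default_run_config())
  check <- function(cfg, ref, path) {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown))
      stop("unknown config field(s): ",
           paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
    for (nm in names(cfg))
      if (is.list(ref[[nm]]) && !is.list(cfg[[nm]]) &&
          !nm %in% c("tournament_schedule"))
        stop("config field ", path, nm, " must be a list", call. = FALSE)
    for (nm in intersect(names(cfg), names(ref)))
      if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
          nm != "tournament_schedule")
        check(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  check(config, ref, "")
  dr <- config$model$dropout_rate
  if (!is.null(dr) && (dr < 0 || dr >= 1))
    stop("config field model$dropout_rate must be in [0, 1)", call. = FALSE)
  ns <- config$phantoms$noise_sd
  if (!is.null(ns) && ns < 0)
    stop("config field phantoms$noise_sd must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Run the pipeline end to end on synthetic data
#'
#' Stages: phantom-cohort generation, model initialization, tournament
#' training, full-image inference with post-processing on the test
#' cohort, and cohort evaluation. Artifacts (config, per-epoch training
#' log, evaluation report, per-case masks) are written under
#' `config$out_dir`, stamped with the config file's MD5 hash and the
#' seed; the run is reproducible from (config, seed) alone.
#'
#' @param config a configuration list as from [default_run_config()];
#'   unknown fields are rejected before any stage runs.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fit, the evaluation report and the
#'   output directory.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  stamp <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                seed = config$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage: generate phantoms")
  ph <- config$phantoms
  spec <- phantom_spec(shape = ph$shape, spacing = ph$spacing,
                       noise_sd = ph$noise_sd, seed = config$seed)
  n_all <- ph$n_train + ph$n_val + ph$n_test
  cohort <- generate_cohort(spec, n_all, seed = config$seed)
  train_cohort <- cohort[seq_len(ph$n_train)]
  val_cohort <- cohort[ph$n_train + seq_len(ph$n_val)]
  test_cohort <- cohort[ph$n_train + ph$n_val + seq_len(ph$n_test)]

  say("stage: train")
  organs <- c("left_breast", "right_breast", "heart")
  mcfg <- config$model
  tcfg <- config$training
  scfg <- config$sampler
  cfg <- train_config(
    lr_initial = tcfg$lr_initial, lr_final = tcfg$lr_final,
    planned_epochs = tcfg$planned_epochs,
    tournament_schedule = tcfg$tournament_schedule,
    n_initializations = tcfg$n_initializations,
    patch_size = scfg$patch_size, batch_size = tcfg$batch_size,
    steps_per_epoch = tcfg$steps_per_epoch, patience = tcfg$patience,
    organs = organs,
    sampler = sampler_config(patch_size = scfg$patch_size,
                             entropy_threshold = scfg$entropy_threshold,
                             shell_distances_mm = scfg$shell_distances_mm),
    seed = config$seed)
  factory <- function(seed) {
    blocks <- rep(1L, mcfg$n_levels)
    build_bibnet(bibnet_config(
      n_levels = mcfg$n_levels, base_filters = mcfg$base_filters,
      encoder_blocks = blocks, lateral_blocks = c(1L, rep(0L, mcfg$n_levels - 1L)),
      decoder_blocks = rep(1L, mcfg$n_levels - 1L),
      dropout_rate = mcfg$dropout_rate, out_channels = mcfg$out_channels))
  }
  fit <- tournament_train(factory, train_cohort, val_cohort, cfg,
                          verbose = verbose)
  write.csv(cbind(fit$history, seed = config$seed),
            file.path(config$out_dir, "training_log.csv"),
            row.names = FALSE)
  save_weights(fit$network, file.path(config$out_dir, "weights.rds"))

  say("stage: infer + postprocess")
  pp <- config$postprocess
  pspec <- postprocess_spec(gaussian_sigma_mm = pp$gaussian_sigma_mm,
                            binarize_threshold = pp$binarize_threshold,
                            connectivity = pp$connectivity)
  predictions <- lapply(test_cohort, function(case) {
    probs <- infer_full_image(fit$network, case$image, organs = organs)
    masks <- lapply(probs, function(pr) postprocess(pr, case$image, pspec)$values)
    structure_set(masks, spacing = case$image$spacing,
                  origin = case$image$origin)
  })
  for (id in names(predictions))
    write_structure_set(predictions[[id]],
                        file.path(config$out_dir, "predictions", id))

  say("stage: evaluate")
  truth <- lapply(test_cohort, `[[`, "structures")
  report <- evaluate_cohort(predictions, truth)
  report_path <- file.path(config$out_dir, "report.csv")
  write.csv(cbind(as.data.frame(report), config_md5 = stamp$config_md5,
                  seed = stamp$seed),
            report_path, row.names = FALSE)
  jsonlite::write_json(stamp, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, report = report, out_dir = config$out_dir))
}
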