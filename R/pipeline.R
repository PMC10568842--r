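pipeline_defaults <- function() {
  list(
    out_dir = "octapseudo_run",
    seed = 0L,
    simulate = list(n_eyes = 12L, splits = c(train = 4L, test = 8L),
                    size_px = 256L, n_frames = 4L, noise = list(),
                    pathology_mix = NULL, max_shift_px = 5, max_rot_deg = 1),
    train = list(levels = 5L, base_channels = 16L, epochs = 20L,
                 learning_rate = 0.05, momentum = 0.9, batch_size = 32L,
                 stride = 64L, p2p_ratio = 0.25, augmentations = list()),
    denoise = list(tile = 64L, stride = 32L, match_contrast = FALSE),
    evaluate = list(tau = 0.15, min_component_px = 20L)
  )
}

check_config_fields <- function(cfg, defaults, path = "") {
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad) > 0)
    stop(sprintf("unknown config field%s: %s",
                 if (length(bad) > 1) "s" else "",
                 paste0(path, bad, collapse = ", ")), call. = FALSE)
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm %in% c("simulate", "train", "denoise", "evaluate"))
      check_config_fields(cfg[[nm]], defaults[[nm]], paste0(nm, "."))
  }
  invisible(TRUE)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stage_fresh <- function(stage_dir, hash, outputs, force) {
  hf <- file.path(stage_dir, "config.hash")
  !force && file.exists(hf) && identical(readLines(hf, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

stage_done <- function(stage_dir, hash) {
  writeLines(hash, file.path(stage_dir, "config.hash"))
}

#' Run the full simulate - average - train - denoise - evaluate pipeline
#'
#' Executes the five study stages in order against a single output
#' directory, propagating the global seed. Each stage is cached: if its
#' outputs exist and were produced under the same stage configuration
#' (config hash on disk), it is skipped unless `force` includes it.
#'
#' @param config A YAML file path or a nested list with (optional) sections
#'   `simulate`, `train`, `denoise`, `evaluate` plus top-level `out_dir` and
#'   `seed`; unknown fields are rejected with the offending field named.
#' @param force `TRUE` to re-run everything, or a character vector of stage
#'   names to re-run.
#' @param stages Which stages to execute (in pipeline order).
#' @return Invisibly, a list of artifact paths plus the evaluation summary.
#' @export
run_pipeline <- function(config = list(), force = FALSE,
                         stages = c("simulate", "average", "train",
                                    "denoise", "evaluate")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  check_config_fields(config, defaults)
  cfg <- utils::modifyList(defaults, config)
  stages <- match.arg(stages, several.ok = TRUE)
  forced <- if (isTRUE(force)) stages else if (is.character(force)) force else character(0)

  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  artifacts <- list()

  ## -- simulate ------------------------------------------------------------
  data_dir <- file.path(out_dir, "dataset")
  manifest <- file.path(data_dir, "manifest.json")
  sim_hash <- config_hash(list(cfg$simulate, cfg$seed))
  if ("simulate" %in% stages) {
    if (stage_fresh(data_dir, sim_hash, manifest, "simulate" %in% forced)) {
      log_line("simulate: cached")
    } else {
      t0 <- proc.time()[["elapsed"]]
      dir.create(data_dir, showWarnings = FALSE)
      make_dataset(cfg$simulate$n_eyes, unlist(cfg$simulate$splits),
                   config = list(size_px = cfg$simulate$size_px,
                                 noise = cfg$simulate$noise,
                                 pathology_mix = cfg$simulate$pathology_mix,
                                 n_frames = cfg$simulate$n_frames,
                                 max_shift_px = cfg$simulate$max_shift_px,
                                 max_rot_deg = cfg$simulate$max_rot_deg,
                                 seed = cfg$seed),
                   out_dir = data_dir)
      stage_done(data_dir, sim_hash)
      log_line("simulate: %d eyes -> %s (%.1f s)", cfg$simulate$n_eyes,
               manifest, proc.time()[["elapsed"]] - t0)
    }
    artifacts$manifest <- manifest
  }

  eyes <- NULL
  get_eyes <- function() {
    if (is.null(eyes)) eyes <<- load_dataset(data_dir)
    eyes
  }

  ## -- average -------------------------------------------------------------
  avg_dir <- file.path(out_dir, "averages")
  avg_hash <- config_hash(list(sim_hash))
  avg_json <- file.path(avg_dir, "transforms.json")
  if ("average" %in% stages) {
    if (stage_fresh(avg_dir, avg_hash, avg_json, "average" %in% forced)) {
      log_line("average: cached")
    } else {
      t0 <- proc.time()[["elapsed"]]
      dir.create(avg_dir, showWarnings = FALSE)
      tlog <- list()
      for (e in Filter(function(e) !is.null(e$stack), get_eyes())) {
        avg <- average_frames(e$stack)
        write_enface_tiff(avg, file.path(avg_dir, paste0(e$eye_id, "_avg.tiff")))
        tlog[[e$eye_id]] <- list(
          reference_index = attr(avg, "reference_index"),
          transforms = attr(avg, "transform_log"))
      }
      jsonlite::write_json(tlog, avg_json, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      stage_done(avg_dir, avg_hash)
      log_line("average: %d eyes (%.1f s)", length(tlog),
               proc.time()[["elapsed"]] - t0)
    }
    artifacts$averages <- avg_dir
  }

  ## -- train ---------------------------------------------------------------
  train_dir <- file.path(out_dir, "model")
  weights_file <- file.path(train_dir, "model.rds")
  train_hash <- config_hash(list(sim_hash, cfg$train, cfg$seed))
  if ("train" %in% stages) {
    if (stage_fresh(train_dir, train_hash, weights_file, "train" %in% forced)) {
      log_line("train: cached")
    } else {
      t0 <- proc.time()[["elapsed"]]
      dir.create(train_dir, showWarnings = FALSE)
      corpus <- build_training_pairs(get_eyes(), stride = cfg$train$stride)
      spec <- unet_spec(cfg$train$levels, cfg$train$base_channels)
      tc <- train_config(learning_rate = cfg$train$learning_rate,
                         momentum = cfg$train$momentum,
                         epochs = cfg$train$epochs,
                         batch_size = cfg$train$batch_size,
                         seed = cfg$seed,
                         augmentations = unlist(cfg$train$augmentations),
                         p2p_ratio = cfg$train$p2p_ratio)
      fit <- fit_pseudoaverager(corpus$pairs, spec, tc)
      saveRDS(fit, weights_file, version = 2)
      utils::write.csv(data.frame(epoch = seq_along(fit$loss_history),
                                  masked_l1 = fit$loss_history),
                       file.path(train_dir, "loss.csv"), row.names = FALSE)
      stage_done(train_dir, train_hash)
      log_line("train: %d pairs, %d epochs, final loss %.4f (%.1f s)",
               fit$n_pairs, tc$epochs, fit$loss_history[tc$epochs],
               proc.time()[["elapsed"]] - t0)
    }
    artifacts$model <- weights_file
  }

  ## -- denoise -------------------------------------------------------------
  den_dir <- file.path(out_dir, "pseudoaveraged")
  den_hash <- config_hash(list(train_hash, cfg$denoise))
  den_mark <- file.path(den_dir, "config.hash")
  if ("denoise" %in% stages) {
    test_eyes <- Filter(function(e) !is.null(e$scan), get_eyes())
    outs <- file.path(den_dir, paste0(vapply(test_eyes, `[[`, "", "eye_id"),
                                      "_pseudo.tiff"))
    if (stage_fresh(den_dir, den_hash, outs, "denoise" %in% forced)) {
      log_line("denoise: cached")
    } else {
      t0 <- proc.time()[["elapsed"]]
      dir.create(den_dir, showWarnings = FALSE)
      fit <- readRDS(weights_file)
      for (e in test_eyes) {
        ps <- pseudoaverage(e$scan, fit, tile = cfg$denoise$tile,
                            stride = cfg$denoise$stride,
                            match_contrast = cfg$denoise$match_contrast)
        write_enface_tiff(ps, file.path(den_dir, paste0(e$eye_id, "_pseudo.tiff")))
      }
      stage_done(den_dir, den_hash)
      log_line("denoise: %d scans (%.1f s)", length(test_eyes),
               proc.time()[["elapsed"]] - t0)
    }
    artifacts$pseudoaveraged <- den_dir
  }

  ## -- evaluate ------------------------------------------------------------
  eval_dir <- file.path(out_dir, "report")
  eval_hash <- config_hash(list(train_hash, cfg$denoise, cfg$evaluate))
  report_csv <- file.path(eval_dir, "per_scan.csv")
  summary_json <- file.path(eval_dir, "summary.json")
  if ("evaluate" %in% stages) {
    if (stage_fresh(eval_dir, eval_hash, c(report_csv, summary_json),
                    "evaluate" %in% forced)) {
      log_line("evaluate: cached")
      artifacts$summary <- jsonlite::read_json(summary_json)
    } else {
      t0 <- proc.time()[["elapsed"]]
      dir.create(eval_dir, showWarnings = FALSE)
      fit <- readRDS(weights_file)
      test_eyes <- Filter(function(e) !is.null(e$scan), get_eyes())
      rep <- cohort_report(test_eyes, fit, tau = cfg$evaluate$tau,
                           min_component_px = cfg$evaluate$min_component_px,
                           out_csv = report_csv)
      jsonlite::write_json(rep$summary, summary_json, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      stage_done(eval_dir, eval_hash)
      log_line("evaluate: %d scans (%.1f s)", rep$summary$n_scans,
               proc.time()[["elapsed"]] - t0)
      artifacts$summary <- rep$summary
    }
    artifacts$report <- report_csv
  }

  invisible(artifacts)
}
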