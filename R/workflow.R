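# End-to-end experiment orchestration: generate -> tile -> normalise ->
# prep -> train -> evaluate -> overlay, driven by a single YAML
# configuration. All inter-stage hand-offs are files (CSV/PNG/YAML/GeoJSON);
# the resolved configuration (all defaults materialised) is written next to
# the outputs so a run is reconstructible from that file plus the seed.

#' Default experiment configuration
#'
#' @return Nested list of all configuration fields with their defaults.
#' @export
default_experiment_config <- function() {
  list(
    seed = 1L,
    output_dir = "hawkshead_run",
    cohort = list(
      n_patients_per_class = 12L,
      tiles_per_patient = 40L,
      noise_sd = 3,
      vector_rotation_sd = 0.05,
      concentration_scale_range = c(0.9, 1.1),
      brightness_scale_range = c(0.9, 1.1)
    ),
    normaliser = list(method = "reinhard", stain_target = NULL),
    split = list(ratios = c(0.6, 0.3, 0.1)),
    balance = TRUE,
    network = list(input_size = 128L, dropout_rate = 0.25, l1 = 0, l2 = 0),
    train = list(learning_rate = 1e-4, batch_size = 128L, max_epochs = 8L,
                 early_stop_patience = NULL, verbose = FALSE),
    overlay = list(enabled = TRUE, slide_size = c(1024L, 1024L), opacity = 0.4)
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read and validate an experiment configuration
#'
#' Unspecified fields take the values of [default_experiment_config()].
#'
#' @param path YAML file, or a list already in configuration shape.
#' @return Validated configuration list.
#' @export
read_experiment_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) abort("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else abort("config must be a YAML path or a list")
  cfg <- merge_config(default_experiment_config(), user)
  if (!cfg$normaliser$method %in% c("reinhard", "macenko", "ruifrok", "vahadane", "none"))
    abort("normaliser must be one of reinhard, macenko, ruifrok, vahadane, none")
  if (!is.null(cfg$normaliser$stain_target) && !file.exists(cfg$normaliser$stain_target))
    abort("stain_target file not found: ", cfg$normaliser$stain_target)
  cfg
}

stage_log <- function(log_path, stage, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...))
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

# reference tile with canonical (unjittered) stains, used as the default
# normalisation target for an experiment
reference_target_tile <- function(config) {
  ref <- generate_cohort(
    1L, 1L,
    jitter = stain_jitter(0, c(1, 1), c(1, 1)),
    seed = derive_seed(config$seed, 424243L),
    noise_sd = config$cohort$noise_sd
  )
  render_tile(ref, ref$patients$patient_id[1], 1L)
}

# render -> normalise -> resize a set of manifest rows into a model input
# batch; `profile` may be NULL (no normalisation)
prepare_inputs <- function(cohort, manifest, profile, input_size) {
  n <- nrow(manifest)
  out <- array(0, dim = c(input_size, input_size, 3L, n))
  for (i in seq_len(n)) {
    img <- render_tile(cohort, manifest$patient_id[i], manifest$tile_index[i])
    if (!is.null(profile)) img <- apply_stain_profile(img, profile)
    out[, , , i] <- resize_bilinear_cpp(as.numeric(img), dim(img)[1], dim(img)[2],
                                        3L, input_size, input_size) / 255
  }
  out
}

#' Run a full experiment from a configuration
#'
#' Executes the pipeline end to end: synthetic cohort generation, stain
#' profile fitting on the configured target, median tile capping,
#' patient-level stratified splitting, class balancing of the training and
#' validation sets (the test set is left imbalanced), HawksheadNet training,
#' test-set evaluation, and a prediction overlay of one held-out test slide.
#' The test split is normalised with the same fitted profile as training but
#' only consumed in the final evaluation stage.
#'
#' @param config A configuration list or YAML path (see
#'   [read_experiment_config()]).
#' @return List with the test-set `metrics`, `auroc`, artifact `paths`
#'   (metrics, history, predictions, overlay PNG/GeoJSON, split, resolved
#'   config, log), the trained `model`, and the `predictions` data frame.
#' @export
run_experiment <- function(config) {
  cfg <- read_experiment_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(log = file.path(cfg$output_dir, "run.log"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '", stage, "' failed: ", conditionMessage(e)))
  }

  stage_log(paths$log, "generate", "seed ", cfg$seed, ", ",
            cfg$cohort$n_patients_per_class, " patients/class")
  cohort <- run_stage("generate", generate_cohort(
    n_patients_per_class = cfg$cohort$n_patients_per_class,
    tiles_per_patient = cfg$cohort$tiles_per_patient,
    jitter = stain_jitter(cfg$cohort$vector_rotation_sd,
                          as.numeric(cfg$cohort$concentration_scale_range),
                          as.numeric(cfg$cohort$brightness_scale_range)),
    seed = cfg$seed,
    noise_sd = cfg$cohort$noise_sd
  ))
  manifest <- cohort_manifest(cohort)

  profile <- NULL
  if (cfg$normaliser$method != "none") {
    stage_log(paths$log, "normalise", "fitting ", cfg$normaliser$method, " profile")
    profile <- run_stage("normalise", {
      target <- if (!is.null(cfg$normaliser$stain_target))
        read_image_png(cfg$normaliser$stain_target)
      else reference_target_tile(cfg)
      fit_stain_profile(cfg$normaliser$method, target)
    })
    paths$stain_profile <- file.path(cfg$output_dir, "stain_profile.yaml")
    save_stain_profile(profile, paths$stain_profile)
  } else stage_log(paths$log, "normalise", "skipped (normaliser: none)")

  stage_log(paths$log, "prep", "capping, splitting, balancing")
  prepped <- run_stage("prep", {
    capped <- cap_tiles(manifest, seed = derive_seed(cfg$seed, 11L))
    split <- split_patients(capped, as.numeric(cfg$split$ratios),
                            seed = derive_seed(cfg$seed, 12L))
    capped <- assign_tiles(capped, split)
    train_man <- capped[capped$set == "train", ]
    val_man <- capped[capped$set == "val", ]
    test_man <- capped[capped$set == "test", ]
    if (isTRUE(cfg$balance)) {
      train_man <- balance_classes(train_man, seed = derive_seed(cfg$seed, 13L))
      val_man <- balance_classes(val_man, seed = derive_seed(cfg$seed, 14L))
    }
    list(split = split, train = train_man, val = val_man, test = test_man)
  })
  paths$split <- file.path(cfg$output_dir, "split.csv")
  write_split(prepped$split, paths$split)
  stage_log(paths$log, "prep", "tiles train/val/test: ", nrow(prepped$train), "/",
            nrow(prepped$val), "/", nrow(prepped$test))

  input_size <- cfg$network$input_size
  stage_log(paths$log, "normalise", "rendering + normalising input batches")
  x_train <- run_stage("normalise", prepare_inputs(cohort, prepped$train, profile, input_size))
  x_val <- run_stage("normalise", prepare_inputs(cohort, prepped$val, profile, input_size))

  stage_log(paths$log, "train", "training HawksheadNet, seed ", cfg$seed)
  model <- run_stage("train", {
    spec <- hawkshead_spec(input_size = input_size,
                           dropout_rate = cfg$network$dropout_rate,
                           l1 = cfg$network$l1, l2 = cfg$network$l2)
    m <- build_hawkshead(spec, seed = derive_seed(cfg$seed, 21L))
    tc <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       max_epochs = cfg$train$max_epochs,
                       early_stop_patience = cfg$train$early_stop_patience,
                       seed = derive_seed(cfg$seed, 22L),
                       verbose = isTRUE(cfg$train$verbose))
    train_model(m, x_train, prepped$train$label, x_val, prepped$val$label, tc)
  })
  paths$history <- file.path(cfg$output_dir, "history.csv")
  write_history(model, paths$history)

  stage_log(paths$log, "evaluate", "scoring the held-out test set")
  result <- run_stage("evaluate", {
    x_test <- prepare_inputs(cohort, prepped$test, profile, input_size)
    scores <- predict(model, x_test)
    preds <- data.frame(
      tile_id = prepped$test$tile_id, slide_id = prepped$test$slide_id,
      x_origin = prepped$test$x_origin, y_origin = prepped$test$y_origin,
      score = scores, label = prepped$test$label, stringsAsFactors = FALSE
    )
    mets <- classification_metrics(confusion(preds))
    list(preds = preds, metrics = mets, auroc = auroc(preds$score, preds$label))
  })
  paths$predictions <- file.path(cfg$output_dir, "predictions.csv")
  write_predictions(result$preds, paths$predictions)
  paths$metrics <- file.path(cfg$output_dir, "metrics.csv")
  mrow <- data.frame(
    accuracy = result$metrics$accuracy, precision = result$metrics$precision,
    sensitivity = result$metrics$sensitivity,
    specificity = result$metrics$specificity,
    f1 = result$metrics$f1, auroc = result$auroc
  )
  write.csv(mrow, paths$metrics, row.names = FALSE)
  stage_log(paths$log, "evaluate", sprintf("AUROC %.4f, accuracy %.4f",
                                           result$auroc, result$metrics$accuracy))

  if (isTRUE(cfg$overlay$enabled) && nrow(prepped$test)) {
    stage_log(paths$log, "overlay", "rendering held-out slide overlay")
    ov <- run_stage("overlay", {
      pid <- prepped$test$patient_id[1]
      prow <- cohort$patients[cohort$patients$patient_id == pid, ]
      slide <- generate_slide(cohort, pid, size = as.integer(cfg$overlay$slide_size))
      tiles <- tessellate(slide$image, slide$mask, slide_id = prow$slide_id,
                          patient_id = pid, label = prow$label)
      if (!is.null(profile))
        tiles$pixels <- lapply(tiles$pixels, apply_stain_profile, profile = profile)
      preds <- predict(model, tiles)
      map <- build_overlay(preds)
      rendered <- render_overlay(map, slide$image, opacity = cfg$overlay$opacity)
      list(map = map, rendered = rendered)
    })
    paths$overlay_png <- file.path(cfg$output_dir, "overlay.png")
    png::writePNG(clip8(ov$rendered) / 255, paths$overlay_png)
    paths$overlay_geojson <- file.path(cfg$output_dir, "overlay.geojson")
    export_geojson(ov$map, paths$overlay_geojson)
  }

  paths$config <- file.path(cfg$output_dir, "config_resolved.yaml")
  writeLines(yaml::as.yaml(cfg, precision = 17L), paths$config)
  stage_log(paths$log, "done", "all artifacts in ", cfg$output_dir)
  list(metrics = result$metrics, auroc = result$auroc, paths = paths,
       model = model, predictions = result$preds)
}

#' Write / read a predictions CSV
#'
#' Columns `tile_id, slide_id, x, y, score, label` -- the interchange format
#' between prediction, evaluation and overlay stages.
#'
#' @param preds Prediction data frame (`x_origin`/`y_origin` columns).
#' @param path CSV path.
#' @return `write_predictions()`: `path`, invisibly; `read_predictions()`:
#'   the predictions data frame.
#' @export
write_predictions <- function(preds, path) {
  out <- data.frame(tile_id = preds$tile_id, slide_id = preds$slide_id,
                    x = preds$x_origin, y = preds$y_origin,
                    score = preds$score, label = preds$label)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort("predictions file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(tile_id = x$tile_id, slide_id = x$slide_id,
             x_origin = x$x, y_origin = x$y,
             score = x$score, label = as.integer(x$label),
             stringsAsFactors = FALSE)
}

#' Compare two models' predictions with DeLong's and McNemar's tests
#'
#' @param preds_a,preds_b Prediction data frames or paths to prediction
#'   CSVs, pairable by `tile_id`.
#' @param alpha Significance level for the verdicts.
#' @return List with `delong` and `mcnemar` (`paired_test_result`s) and a
#'   `report` character vector including the discordant counts and
#'   alpha-level verdicts.
#' @export
compare_models <- function(preds_a, preds_b, alpha = 0.05) {
  if (is.character(preds_a)) preds_a <- read_predictions(preds_a)
  if (is.character(preds_b)) preds_b <- read_predictions(preds_b)
  dl <- delong_test(preds_a, preds_b, alpha = alpha)
  mn <- mcnemar_test(preds_a, preds_b, alpha = alpha)
  verdict <- function(p) if (p < alpha) "significant" else "not significant"
  report <- c(
    sprintf("DeLong: AUC A = %.4f, AUC B = %.4f, z = %.4f, p = %.4g (%s at alpha = %g)",
            dl$auc_a, dl$auc_b, dl$statistic, dl$p_value, verdict(dl$p_value), alpha),
    sprintf("McNemar: b = %d, c = %d, exact p = %.4g (%s at alpha = %g)",
            mn$b, mn$c, mn$p_value, verdict(mn$p_value), alpha)
  )
  list(delong = dl, mcnemar = mn, report = report)
}
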