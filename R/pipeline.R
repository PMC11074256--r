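# End-to-end pipeline: simulate -> extract features -> train -> predict on a
# held-out scene -> assess accuracy -> estimate cover. Also the paired
# imbalance experiment comparing positive-class recall with and without
# weighted feature subsampling.

#' Default end-to-end run configuration
#'
#' Nested sections mirroring the generator, forest and EVI configurations.
#' The training and validation scenes follow the study's object counts
#' (932 grassland / 45 forest training objects; 1031 grassland / 23 forest
#' validation objects); scene pixel sizes are chosen so segments average
#' roughly 60-90 pixels.
#'
#' @param seed global seed; section seeds derive from it.
#' @return a nested `run_config` list.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    train_scene = list(height = 256, width = 256, n_segments = 977,
                       n_forest = 45, noise_sd = 0.02),
    validation_scene = list(height = 256, width = 256, n_segments = 1054,
                            n_forest = 23, noise_sd = 0.02),
    forest = list(n_trees = 100, m_features = NULL, lambda_weight = 0.5,
                  positive_class = "forest"),
    cover = list(height = 128, width = 128, noise_sd = 0.01,
                 smoothness = 16, index = "evi"),
    evi = list(O = 2.5, V1 = 6, V2 = 7.5, D = 1)
  ), class = "run_config")
}

run_config_from_file <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_run_config(raw$seed %||% 1L)
  known <- names(base)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in setdiff(names(raw), "seed")) {
    bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
    if (length(bad)) stop("unknown config key(s) in ", sec, ": ",
                          paste(bad, collapse = ", "))
    base[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  base
}

scene_config_from_section <- function(sec, seed) {
  n <- sec$n_segments
  p_forest <- sec$n_forest / n
  scene_config(height = sec$height, width = sec$width, n_segments = n,
               class_names = c("grassland", "forest"),
               class_proportions = c(1 - p_forest, p_forest),
               noise_sd = sec$noise_sd, seed = seed)
}

#' Run the full object-based classification pipeline
#'
#' Simulates a labelled training scene and an independent validation scene,
#' extracts the 85-feature table from each, trains the weighted-feature
#' forest on the training objects, predicts the held-out validation objects,
#' assesses thematic accuracy (overall, per-class producer's/user's, kappa)
#' plus OOB accuracy, and runs the EVI-based fractional-cover estimation
#' against its known truth. Deterministic for a fixed config.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir optional directory; when supplied, scenes, feature tables,
#'   the model bundle, predictions and the JSON summary are written there.
#' @return list of class `pipeline_result` with `report`
#'   (an [accuracy_report()]), `oob`, `cover_validation`, `model`, `summary`
#'   (flat named list of the headline numbers) and `config_hash`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  seed <- config$seed
  train_scene <- generate_scene(
    scene_config_from_section(config$train_scene,
                              substream_seed(seed, "train_scene")))
  val_scene <- generate_scene(
    scene_config_from_section(config$validation_scene,
                              substream_seed(seed, "validation_scene")))
  ep <- do.call(evi_params, config$evi)
  train_ft <- build_feature_table(train_scene, params = ep)
  val_ft <- build_feature_table(val_scene, params = ep)

  fc <- forest_config(n_trees = config$forest$n_trees,
                      m_features = config$forest$m_features,
                      positive_class = config$forest$positive_class,
                      lambda_weight = config$forest$lambda_weight,
                      seed = substream_seed(seed, "forest"))
  model <- train_forest(train_ft, fc)
  oob <- oob_score(model, train_ft)
  pred <- predict_forest(model, val_ft)
  cm <- confusion_matrix(val_ft$label, pred$label, model$classes)
  report <- accuracy_report(cm)

  cov <- generate_cover_scene(height = config$cover$height,
                              width = config$cover$width,
                              noise_sd = config$cover$noise_sd,
                              cover_field_smoothness = config$cover$smoothness,
                              seed = substream_seed(seed, "cover_scene"))
  cov_est <- estimate_cover_scene(cov$scene, index = config$cover$index,
                                  veg_spectrum = default_endmembers()$forest,
                                  soil_spectrum = default_endmembers()$soil,
                                  true_cover = cov$true_cover, params = ep)

  summary <- list(
    n_train_objects = nrow(train_ft),
    n_validation_objects = nrow(val_ft),
    n_features = length(feature_names(train_ft)),
    overall_accuracy = report$overall_accuracy,
    kappa = report$kappa,
    producer_accuracy_forest = unname(report$map_accuracy["forest"]),
    producer_accuracy_grassland = unname(report$map_accuracy["grassland"]),
    user_accuracy_forest = unname(report$user_accuracy["forest"]),
    user_accuracy_grassland = unname(report$user_accuracy["grassland"]),
    oob_accuracy = oob$overall,
    oob_recall_forest = unname(oob$per_class["forest"]),
    cover_r_squared = cov_est$validation$r_squared,
    cover_rmse = cov_est$validation$rmse
  )
  hash <- config_hash(unclass(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scene(train_scene, file.path(out_dir, "train"))
    write_scene(val_scene, file.path(out_dir, "validation"))
    write_feature_csv(train_ft, file.path(out_dir, "train_features.csv"))
    write_feature_csv(val_ft, file.path(out_dir, "validation_features.csv"))
    forest_to_json(model, file.path(out_dir, "model.json"))
    utils::write.csv(
      data.frame(object_id = val_ft$object_id, predicted_label = pred$label,
                 round(pred$votes, 6), check.names = FALSE),
      file.path(out_dir, "predictions.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      c(list(tool = "vegrf", version = "0.1.0", config_hash = hash,
             seed = seed), summary),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  structure(list(report = report, oob = oob,
                 cover_validation = cov_est$validation, model = model,
                 summary = summary, config_hash = hash),
            class = "pipeline_result")
}

#' Paired imbalance experiment: weighted vs uniform feature subsampling
#'
#' For each seed, generates a feature table with the study's training
#' imbalance (932 negative / 45 positive objects, 85 features, 5
#' positive-informative at the configured effect size), trains one forest
#' with `lambda_weight = lambda` and one with `lambda_weight = 0` on
#' identical data, and records the out-of-bag recall of the positive class
#' under each. The experiment's ensemble size defaults to 50 trees per
#' forest (vote stability at desk scale).
#'
#' @param n_seeds number of paired replicates (default 20).
#' @param lambda the weighted arm's mixing fraction (default 0.5).
#' @param effect_size informative-feature mean shift (default 1.5).
#' @param n_trees trees per forest (default 50).
#' @param table_config_fn function(seed) returning the per-replicate
#'   [table_config()]; the default uses the study-shaped counts.
#' @param seed master seed; replicate seeds derive from it.
#' @return data frame with one row per seed: `recall_weighted`,
#'   `recall_uniform`, plus medians in the attributes `median_weighted` /
#'   `median_uniform`.
#' @export
imbalance_experiment <- function(n_seeds = 20, lambda = 0.5,
                                 effect_size = 1.5, n_trees = 50,
                                 table_config_fn = NULL, seed = 1L) {
  if (is.null(table_config_fn))
    table_config_fn <- function(s)
      table_config(n_pos = 45, n_neg = 932, n_feat_total = 85,
                   n_informative_pos = 5, n_informative_neg = 5,
                   effect_size = effect_size, seed = s)
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- substream_seed(seed, paste0("imbalance_", i))
    ft <- generate_feature_table(table_config_fn(s))
    rec <- vapply(c(lambda, 0), function(lw) {
      model <- train_forest(ft, forest_config(
        n_trees = n_trees, lambda_weight = lw,
        positive_class = "forest", seed = s))
      unname(oob_score(model, ft)$per_class["forest"])
    }, numeric(1))
    data.frame(seed = s, recall_weighted = rec[1], recall_uniform = rec[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "median_weighted") <- stats::median(out$recall_weighted)
  attr(out, "median_uniform") <- stats::median(out$recall_uniform)
  out
}
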