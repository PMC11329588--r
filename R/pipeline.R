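#' Run configuration
#'
#' Fully serializable configuration tying the whole pipeline together:
#' phantom cohort, grids, network, training, consensus and output paths.
#' `save_run_config()` / `load_run_config()` round-trip it through YAML;
#' every pipeline run writes its fully resolved configuration back to the
#' output directory.
#'
#' @param output_dir Output directory for all run artifacts.
#' @param seed Global seed; all stage seeds are derived from it.
#' @param n_subjects Development-cohort size (70/30 subject-level
#'   train/test split).
#' @param n_per_group Group-study cohort size per group.
#' @param grid_shape,spacing_mm Phantom/segmentation grid (cubic, isotropic).
#' @param deform_amplitude,noise_sigma Phantom generator parameters.
#' @param channels Encoder channel plan of the U-Net.
#' @param dropout_rate,max_epochs,patience,batch_size,learning_rate,n_folds
#'   Training parameters (see [train_config()]).
#' @param threshold Hard-prediction threshold.
#' @param group_study Also run the two-group volume study after training.
#' @param verbose Print progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = "triseg_run", seed = 1L,
                       n_subjects = 20L, n_per_group = 19L,
                       grid_shape = 64L, spacing_mm = 2,
                       deform_amplitude = 0.05, noise_sigma = 5,
                       channels = c(8L, 16L, 32L), dropout_rate = 0.25,
                       max_epochs = 4L, patience = 2L, batch_size = 16L,
                       learning_rate = 1e-3, n_folds = 5L, threshold = 0.5,
                       group_study = TRUE, verbose = FALSE) {
  structure(list(output_dir = as.character(output_dir), seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 deform_amplitude = as.numeric(deform_amplitude),
                 noise_sigma = as.numeric(noise_sigma),
                 channels = as.integer(channels),
                 dropout_rate = as.numeric(dropout_rate),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 n_folds = as.integer(n_folds),
                 threshold = as.numeric(threshold),
                 group_study = isTRUE(group_study),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_template <- function(config) {
  phantom_spec(grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
               deform_amplitude = config$deform_amplitude,
               noise_sigma = config$noise_sigma)
}

#' Preprocess a cohort for triplanar segmentation
#'
#' Applies the full chain to every subject: isotropic resampling to the
#' working grid, landmark-centered reorientation (the mask centroid when no
#' landmark list is supplied), cohort z-score normalization and
#' crop-and-upsample to the segmentation grid. Normalization statistics are
#' computed from the supplied cohort unless `stats` is given (inference on
#' new data reuses the training-cohort statistics).
#'
#' @param vols Named list of [labeled_volume()].
#' @param working,seg Working and segmentation [grid_spec()]s.
#' @param roi Normalization ROI [grid_spec()] (tongue-centered).
#' @param stats Optional precomputed `normalization_stats`.
#' @param landmarks Optional named list of voxel landmarks; defaults to each
#'   subject's mask centroid.
#' @return List with `vols` (preprocessed volumes) and `stats`.
#' @export
preprocess_cohort <- function(vols, working, seg, roi, stats = NULL,
                              landmarks = NULL) {
  centered <- lapply(names(vols), function(sid) {
    v <- resample_isotropic(vols[[sid]], working)
    lm <- if (!is.null(landmarks)) landmarks[[sid]] else round(mask_centroid(v))
    reorient_center(v, lm)
  })
  names(centered) <- names(vols)
  if (is.null(stats)) stats <- compute_cohort_stats(centered, roi)
  out <- lapply(centered, function(v) to_segmentation_grid(znormalize(v, stats), seg))
  list(vols = out, stats = stats)
}

#' Desk-scale end-to-end experiment
#'
#' The full study protocol in miniature: a development cohort of phantoms is
#' split 70/30 at subject level; the training subjects are preprocessed and
#' used for fivefold cross-validated triplanar training; the held-out test
#' subjects are segmented with all seven strategies and evaluated against
#' their exact truth masks, including paired predicted-vs-truth volume
#' comparisons.
#'
#' @param config A [run_config()].
#' @return List with the trained `ensemble`, per-subject metric `rows`, the
#'   strategy summary `table1`, paired volume comparisons
#'   (`paired_softmax`, `paired_majority`), the cohort `manifest`, test
#'   subject ids and preprocessing `stats`.
#' @export
desk_experiment <- function(config = run_config()) {
  t0 <- Sys.time()
  template <- config_template(config)
  working <- grid_spec(config$grid_shape, config$spacing_mm)
  seg <- grid_spec(config$grid_shape, config$spacing_mm)
  roi <- grid_spec(config$grid_shape %/% 2L, config$spacing_mm)

  ctrl <- volume_to_scale(106, 8, template)
  dev_groups <- data.frame(group = "dev", n = config$n_subjects,
                           scale_mean = ctrl[["mean"]], scale_sd = ctrl[["sd"]])
  cohort <- generate_cohort(cohort_spec(dev_groups, template,
                                        seed = derive_seed(config$seed, 11L)))
  subjects <- names(cohort$volumes)
  n_train <- max(config$n_folds, round(0.7 * length(subjects)))
  train_ids <- with_local_seed(derive_seed(config$seed, 12L),
                               sort(sample(subjects, n_train)))
  test_ids <- setdiff(subjects, train_ids)

  if (config$verbose) message(sprintf("cohort: %d train / %d test subjects",
                                      length(train_ids), length(test_ids)))
  prep_train <- preprocess_cohort(cohort$volumes[train_ids], working, seg, roi)
  ens <- train_cv(prep_train$vols,
                  unet_config(config$channels, config$dropout_rate,
                              input_size = config$grid_shape,
                              seed = derive_seed(config$seed, 13L)),
                  train_config(config$max_epochs, config$patience,
                               config$batch_size, config$learning_rate,
                               config$n_folds, seed = derive_seed(config$seed, 17L)),
                  norm_stats = prep_train$stats, verbose = config$verbose)

  prep_test <- preprocess_cohort(cohort$volumes[test_ids], working, seg, roi,
                                 stats = prep_train$stats)
  rows <- list()
  for (sid in test_ids) {
    pv <- prep_test$vols[[sid]]
    pred <- predict_subject(ens, pv, threshold = config$threshold)
    rows[[sid]] <- evaluate_masks(pred$masks, pv$mask, pv$spacing_mm, subject = sid)
  }
  rows <- do.call(rbind, rows)
  truth_vols <- vapply(test_ids, function(sid)
    tongue_volume(prep_test$vols[[sid]]), numeric(1))
  vol_of <- function(strategy) {
    sub <- rows[rows$strategy == strategy, ]
    sub$volume_cm3[match(test_ids, sub$subject)]
  }
  res <- list(ensemble = ens,
              rows = rows,
              table1 = table1_report(rows),
              paired_softmax = compare_paired(vol_of("softmax"), truth_vols),
              paired_majority = compare_paired(vol_of("majority"), truth_vols),
              truth_volumes = truth_vols,
              manifest = cohort$manifest,
              train_subjects = train_ids, test_subjects = test_ids,
              stats = prep_train$stats,
              grids = list(working = working, seg = seg, roi = roi),
              runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

#' Two-group tongue-volume study
#'
#' Generates a fresh two-group cohort (controls vs atrophic patients, about
#' 14% smaller mean tongue volume), segments every subject with the trained
#' ensemble reusing its stored normalization statistics, and compares the
#' group volumes (softmax and majority consensus, plus the true masks) with
#' the Shapiro-Wilk-gated two-group test.
#'
#' @param ens A trained `ensemble_model` (e.g. from [desk_experiment()]).
#' @param config A [run_config()] (grids must match the ensemble's).
#' @return List with the per-subject `volumes` data frame and
#'   `group_comparison` objects for true, softmax and majority volumes.
#' @export
group_study <- function(ens, config = run_config()) {
  template <- config_template(config)
  working <- grid_spec(config$grid_shape, config$spacing_mm)
  seg <- grid_spec(ens$grid$matrix, ens$grid$spacing_mm)
  roi <- grid_spec(config$grid_shape %/% 2L, config$spacing_mm)
  cs <- cohort_spec(template = template, seed = derive_seed(config$seed, 23L))
  cs$groups$n <- rep(config$n_per_group, nrow(cs$groups))
  cohort <- generate_cohort(cs)
  prep <- preprocess_cohort(cohort$volumes, working, seg, roi,
                            stats = ens$norm_stats)
  rows <- list()
  for (sid in names(prep$vols)) {
    pv <- prep$vols[[sid]]
    pred <- predict_subject(ens, pv, threshold = config$threshold)
    grp <- cohort$manifest$group[cohort$manifest$subject == sid]
    rows[[sid]] <- data.frame(
      subject = sid, group = grp,
      true_cm3 = tongue_volume(pv),
      softmax_cm3 = tongue_volume(pred$masks$softmax, pv$spacing_mm),
      majority_cm3 = tongue_volume(pred$masks$majority, pv$spacing_mm))
  }
  volumes <- do.call(rbind, rows)
  by_group <- function(col) split(volumes[[col]], volumes$group)
  cmp <- function(col) {
    g <- by_group(col)
    compare_groups(g$control, g$patient, labels = c("control", "patient"))
  }
  list(volumes = volumes,
       true = cmp("true_cm3"),
       softmax = cmp("softmax_cm3"),
       majority = cmp("majority_cm3"))
}

#' Detection rate of the group difference on true masks
#'
#' Repeats the two-group cohort draw `reps` times (fresh seeds derived from
#' `seed`) and, per repetition, compares the groups' true mask volumes with
#' [compare_groups()]. Only masks are voxelized (fast path).
#'
#' @param config A [run_config()].
#' @param reps Number of seeded repetitions.
#' @param alpha Significance level tested against.
#' @return List with the vector of `p_values` and the `detection_rate`
#'   (fraction of repetitions with p < `alpha`).
#' @export
true_volume_study <- function(config = run_config(), reps = 20, alpha = 0.005) {
  template <- config_template(config)
  ps <- vapply(seq_len(reps), function(r) {
    cs <- cohort_spec(template = template,
                      seed = derive_seed(config$seed, 100L + r))
    cs$groups$n <- rep(config$n_per_group, nrow(cs$groups))
    man <- generate_cohort(cs, volumes = FALSE)$manifest
    g <- split(man$true_volume_cm3, man$group)
    compare_groups(g$control, g$patient)$p_value
  }, numeric(1))
  list(p_values = ps, detection_rate = mean(ps < alpha))
}

#' Generate and persist a phantom cohort
#'
#' Command-style wrapper: generates the two-group cohort described by the
#' configuration and writes NIfTI pairs plus a manifest CSV under
#' `output_dir/cohort`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest path.
#' @export
cmd_generate <- function(config = run_config()) {
  template <- config_template(config)
  cs <- cohort_spec(template = template, seed = config$seed)
  cs$groups$n <- rep(config$n_per_group, nrow(cs$groups))
  cs <- cohort_spec(cs$groups, template, config$seed)
  cohort <- generate_cohort(cs)
  dir <- file.path(config$output_dir, "cohort")
  mpath <- write_cohort(cohort, dir)
  save_run_config(config, file.path(config$output_dir, "config_resolved.yaml"))
  invisible(mpath)
}

#' Run the full pipeline end to end
#'
#' generate -> preprocess -> fivefold triplanar training -> prediction with
#' all strategies -> strategy metric table -> paired and (optionally)
#' two-group volume statistics. All stage seeds derive from the global seed,
#' every stage is logged with its duration, and all reports (CSV/JSON) plus
#' the resolved configuration are written under `output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the full results list ([desk_experiment()] results
#'   plus `group` when enabled).
#' @export
cmd_pipeline <- function(config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "log.txt")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbose) message(msg)
  }
  logline("pipeline start, seed %d", config$seed)
  save_run_config(config, file.path(config$output_dir, "config_resolved.yaml"))

  t0 <- Sys.time()
  res <- desk_experiment(config)
  logline("desk experiment done in %.1f s (folds w: %s)", res$runtime_s,
          paste(sprintf("%.3f", vapply(res$ensemble$folds, function(f) f$w,
                                       numeric(1))), collapse = ", "))
  write.csv(res$rows, file.path(config$output_dir, "metrics_subjects.csv"),
            row.names = FALSE)
  table1_report(res$rows, file.path(config$output_dir, "metrics_summary.csv"))
  write.csv(res$manifest, file.path(config$output_dir, "manifest.csv"),
            row.names = FALSE)
  write_comparison_json(res$paired_softmax,
                        file.path(config$output_dir, "paired_softmax.json"))
  write_comparison_json(res$paired_majority,
                        file.path(config$output_dir, "paired_majority.json"))
  write_ensemble(res$ensemble, file.path(config$output_dir, "ensemble"))

  if (config$group_study) {
    t1 <- Sys.time()
    grp <- group_study(res$ensemble, config)
    logline("group study done in %.1f s",
            as.numeric(difftime(Sys.time(), t1, units = "secs")))
    write.csv(grp$volumes, file.path(config$output_dir, "group_volumes.csv"),
              row.names = FALSE)
    write_comparison_json(grp$true, file.path(config$output_dir, "group_true.json"))
    write_comparison_json(grp$softmax,
                          file.path(config$output_dir, "group_softmax.json"))
    write_comparison_json(grp$majority,
                          file.path(config$output_dir, "group_majority.json"))
    res$group <- grp
  }
  logline("pipeline done in %.1f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}
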