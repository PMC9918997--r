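# Stepwise experiment orchestration: compare cross-validation strategies,
# sensor setups and model architectures in three chained steps, each fixing
# the previous step's winner, then report metric and load-profile tables for
# the final configuration.

#' Evaluate one pipeline configuration
#'
#' Trains and evaluates one (strategy, setup, architecture) combination over
#' all folds and iterations and returns the prediction table.
#'
#' @param samples Named list of `sjrf_sample` built with the configuration's
#'   sensor setup.
#' @param manifest Cohort manifest.
#' @param strategy `"LOTO"` or `"LOSO"`.
#' @param config An [sjrf_config()] (its `input_width` must match the
#'   samples).
#' @param n_iterations Seeded re-initializations per fold.
#' @param seed Base seed for folds and iterations.
#' @param participants Optional subset of participants to fold over.
#' @param verbose Print per-fold progress.
#' @return An `sjrf_predictions` table with one row per
#'   (test subtrial, iteration).
#' @export
evaluate_configuration <- function(samples, manifest, strategy, config,
                                   n_iterations = 10, seed = 1,
                                   participants = NULL, verbose = FALSE) {
  strategy <- match.arg(strategy, c("LOTO", "LOSO"))
  participants <- participants %||% sort(unique(manifest$participant_id))
  folds <- if (strategy == "LOTO") {
    unlist(lapply(participants, function(p) {
      make_loto_folds(manifest, p, seed = seed)
    }), recursive = FALSE)
  } else {
    make_loso_folds(manifest[manifest$participant_id %in% participants, ,
                             drop = FALSE], seed = seed)
  }
  rows <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (verbose) message(sprintf("fold %d/%d (%s)", f, length(folds),
                                 fold$fold_id))
    models <- run_iterations(fold, samples, config, n_iter = n_iterations,
                             base_seed = child_seed(seed, 101, f))
    for (it in seq_along(models)) {
      for (key in fold$test) {
        s <- samples[[key]]
        rows[[length(rows) + 1L]] <- list(
          participant_id = s$participant_id, activity = s$activity,
          subtrial = s$subtrial, iteration = it,
          pred = predict(models[[it]], s), truth = s$Y)
      }
    }
  }
  prediction_table(
    participant_id = vapply(rows, `[[`, 0, "participant_id"),
    activity = vapply(rows, `[[`, "", "activity"),
    subtrial = vapply(rows, `[[`, 0L, "subtrial"),
    iteration = vapply(rows, `[[`, 0L, "iteration"),
    pred = lapply(rows, `[[`, "pred"),
    truth = lapply(rows, `[[`, "truth"))
}

# mean participant-level metrics of a prediction table
participant_summary <- function(predictions, expected = NULL) {
  rec <- participant_level_metrics(predictions, expected)
  list(records = rec, mean_pcc = mean(rec$pcc, na.rm = TRUE),
       mean_rrmse = mean(rec$rrmse, na.rm = TRUE))
}

#' Run one step of the stepwise model selection
#'
#' Evaluates every candidate configuration of the step and declares the
#' winner: the configuration with the higher mean participant-level PCC,
#' ties broken by lower mean rRMSE.
#'
#' @param candidates Named list of configurations; each element is a list
#'   with `strategy`, `setup` (name), `arch`.
#' @param samples_by_setup List with one named list of samples per setup
#'   name.
#' @param manifest Cohort manifest.
#' @param base_config Function `(arch, input_width) -> sjrf_config`.
#' @param n_iterations,seed,participants,verbose Passed through.
#' @return List of class `sjrf_step`: per-candidate `predictions`,
#'   `summary` rows and the `winner` name.
#' @export
run_step <- function(candidates, samples_by_setup, manifest, base_config,
                     n_iterations = 10, seed = 1, participants = NULL,
                     verbose = FALSE) {
  results <- list()
  summaries <- list()
  expected <- manifest[manifest$valid, c("activity", "subtrial",
                                         "participant_id")]
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    samples <- samples_by_setup[[cand$setup]]
    cfg <- base_config(cand$arch, ncol(samples[[1]]$X))
    preds <- evaluate_configuration(samples, manifest, cand$strategy, cfg,
                                    n_iterations = n_iterations, seed = seed,
                                    participants = participants,
                                    verbose = verbose)
    ps <- participant_summary(preds)
    results[[nm]] <- list(candidate = cand, predictions = preds,
                          metrics = ps$records)
    summaries[[nm]] <- data.frame(candidate = nm, strategy = cand$strategy,
                                  setup = cand$setup, arch = cand$arch,
                                  mean_pcc = ps$mean_pcc,
                                  mean_rrmse = ps$mean_rrmse)
  }
  summary_df <- do.call(rbind, summaries)
  ord <- order(-summary_df$mean_pcc, summary_df$mean_rrmse)
  winner <- summary_df$candidate[ord[1]]
  structure(list(results = results, summary = summary_df, winner = winner),
            class = "sjrf_step")
}

#' @export
print.sjrf_step <- function(x, ...) {
  df <- x$summary
  df$mean_pcc <- round(df$mean_pcc, 3)
  df$mean_rrmse <- round(df$mean_rrmse, 2)
  print(df, row.names = FALSE)
  cat("winner:", x$winner, "\n")
  invisible(x)
}

#' Run the three-step model-selection experiment
#'
#' Step 1 compares LOTO vs LOSO (complete setup, biLSTM); step 2 compares
#' complete vs sparse setups under the step-1 winner; step 3 compares biLSTM
#' vs linear under the winners of steps 1 and 2. Each step fixes the previous
#' winners, and the final configuration is reported with its prediction
#' table.
#'
#' @param cohort An `sjrf_cohort`.
#' @param model_opts Named list of overrides for [sjrf_config()] (e.g.
#'   smaller `bilstm_units`/`max_epochs` for scaled-down runs).
#' @param n_iterations Iterations per fold.
#' @param seed Base seed.
#' @param participants Optional participant subset.
#' @param verbose Progress messages.
#' @return List of class `sjrf_experiment` with `steps`, `final` (strategy,
#'   setup, arch), `predictions` (final configuration) and the cohort
#'   manifest.
#' @export
run_experiment <- function(cohort, model_opts = list(), n_iterations = 10,
                           seed = 1, participants = NULL, verbose = FALSE) {
  aligned <- align_cohort(cohort)
  samples_by_setup <- list(
    complete = build_cohort_samples(cohort, sensor_setup("complete"),
                                    aligned = aligned),
    sparse = build_cohort_samples(cohort, sensor_setup("sparse"),
                                  aligned = aligned))
  base_config <- function(arch, width) {
    do.call(sjrf_config, c(list(architecture = arch, input_width = width),
                           model_opts))
  }
  manifest <- cohort$manifest

  step1 <- run_step(
    list(LOTO = list(strategy = "LOTO", setup = "complete", arch = "bilstm"),
         LOSO = list(strategy = "LOSO", setup = "complete", arch = "bilstm")),
    samples_by_setup, manifest, base_config, n_iterations, seed,
    participants, verbose)
  win_strategy <- step1$results[[step1$winner]]$candidate$strategy

  step2 <- run_step(
    list(complete = list(strategy = win_strategy, setup = "complete",
                         arch = "bilstm"),
         sparse = list(strategy = win_strategy, setup = "sparse",
                       arch = "bilstm")),
    samples_by_setup, manifest, base_config, n_iterations, seed,
    participants, verbose)
  win_setup <- step2$results[[step2$winner]]$candidate$setup

  step3 <- run_step(
    list(bilstm = list(strategy = win_strategy, setup = win_setup,
                       arch = "bilstm"),
         linear = list(strategy = win_strategy, setup = win_setup,
                       arch = "linear")),
    samples_by_setup, manifest, base_config, n_iterations, seed,
    participants, verbose)
  win_arch <- step3$results[[step3$winner]]$candidate$arch

  structure(list(
    steps = list(step1 = step1, step2 = step2, step3 = step3),
    final = list(strategy = win_strategy, setup = win_setup,
                 arch = win_arch),
    predictions = step3$results[[step3$winner]]$predictions,
    manifest = manifest), class = "sjrf_experiment")
}

#' @export
print.sjrf_experiment <- function(x, ...) {
  cat("Stepwise SJRF model selection\n")
  for (nm in names(x$steps)) {
    cat("--", nm, "--\n")
    print(x$steps[[nm]])
  }
  cat(sprintf("final configuration: %s + %s + %s\n", x$final$strategy,
              x$final$setup, x$final$arch))
  invisible(x)
}

#' Probe prediction of an activity unseen in training
#'
#' For a cohort in which one participant retains a single weight-relief
#' subtrial (the other one excluded), compares the leave-one-trial-out fold
#' whose test set is that orphaned subtrial — so no same-activity data are in
#' the training set — against the participant's other folds and against the
#' leave-one-subject-out prediction of the same subtrial (which has seen
#' weight-relief data from other participants).
#'
#' @param cohort An `sjrf_cohort`, typically generated with
#'   `force_orphan = TRUE`.
#' @param model_opts [sjrf_config()] overrides.
#' @param seed Base seed.
#' @param setup_name Sensor setup (default sparse).
#' @return `NULL` (with a message) when no orphaned weight-relief subtrial
#'   exists; otherwise a list with `orphan_key`, `loto_orphan_pcc`,
#'   `loto_other_pcc` (per-fold vector), `loto_median_other`,
#'   `loso_orphan_pcc`.
#' @export
unseen_activity_probe <- function(cohort, model_opts = list(), seed = 1,
                                  setup_name = "sparse") {
  manifest <- cohort$manifest
  wr <- manifest[manifest$activity == "weight_relief", , drop = FALSE]
  n_valid <- tapply(wr$valid, wr$participant_id, sum)
  orph_p <- as.integer(names(n_valid)[n_valid == 1])
  if (length(orph_p) == 0) {
    message("no orphaned weight-relief subtrial in this cohort; probe skipped")
    return(invisible(NULL))
  }
  orph_p <- orph_p[1]
  orphan_key <- wr$key[wr$participant_id == orph_p & wr$valid]

  samples <- build_cohort_samples(cohort, sensor_setup(setup_name))
  cfg <- do.call(sjrf_config, c(
    list(architecture = "bilstm",
         input_width = ncol(samples[[1]]$X)), model_opts))

  folds <- make_loto_folds(manifest, orph_p, seed = seed)
  fold_pcc <- vapply(seq_along(folds), function(f) {
    fold <- folds[[f]]
    model <- fit_fold(fold, samples, local({
      c2 <- cfg
      c2$seed <- child_seed(seed, 301, f)
      c2
    }))
    s <- samples[[fold$test]]
    pearson(compute_ftot(predict(model, s)), compute_ftot(s$Y))
  }, 0)
  test_keys <- vapply(folds, `[[`, "", "test")
  orphan_idx <- which(test_keys == orphan_key)

  loso <- make_loso_folds(manifest, seed = seed)
  loso_fold <- loso[[which(vapply(loso, function(f) {
    orphan_key %in% f$test
  }, TRUE))]]
  c3 <- cfg
  c3$seed <- child_seed(seed, 302)
  loso_model <- fit_fold(loso_fold, samples, c3)
  s <- samples[[orphan_key]]
  loso_pcc <- pearson(compute_ftot(predict(loso_model, s)),
                      compute_ftot(s$Y))

  list(orphan_key = orphan_key,
       loto_orphan_pcc = fold_pcc[orphan_idx],
       loto_other_pcc = fold_pcc[-orphan_idx],
       loto_median_other = stats::median(fold_pcc[-orphan_idx]),
       loso_orphan_pcc = loso_pcc)
}

#' Final report bundle
#'
#' Collects the tables of the final configuration: the resolved
#' configuration, participant-level and activity-level metric records, and
#' the load-profile intersection tables (per participant; per activity for
#' one participant).
#'
#' @param experiment An `sjrf_experiment`.
#' @param bin_width Load-profile bin width in N.
#' @return List with `final_configuration`, `participant_metrics`,
#'   `activity_metrics`, `profile_participants`, `profile_activities`.
#' @export
final_report <- function(experiment, bin_width = 25) {
  preds <- experiment$predictions
  expected <- experiment$manifest[experiment$manifest$valid, ]
  list(final_configuration = experiment$final,
       participant_metrics = participant_level_metrics(preds, expected),
       activity_metrics = activity_level_metrics(preds, expected)$records,
       profile_participants = profile_report(preds, "participants",
                                             bin_width = bin_width,
                                             expected = expected),
       profile_activities = profile_report(preds, "activities",
                                           bin_width = bin_width,
                                           expected = expected))
}

#' Overlay plot of predicted vs ground-truth total force
#'
#' @param predictions An `sjrf_predictions` table.
#' @param participant_id,iteration Which series to draw (all activities
#'   concatenated).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted Ftot pair.
#' @export
plot_prediction_overlay <- function(predictions, participant_id,
                                    iteration = 1, ...) {
  sub <- predictions[predictions$participant_id == participant_id &
                       predictions$iteration == iteration, , drop = FALSE]
  acts <- concatenate_to_activities(sub)
  truth <- compute_ftot(do.call(rbind, lapply(acts, `[[`, "truth")))
  pred <- compute_ftot(do.call(rbind, lapply(acts, `[[`, "pred")))
  tt <- seq_along(truth) / TARGET_FS
  graphics::plot(tt, truth, type = "l", col = "black", xlab = "time (s)",
                 ylab = "Ftot (N)",
                 main = sprintf("Participant %d", participant_id), ...)
  graphics::lines(tt, pred, col = "firebrick")
  graphics::legend("topright", c("ground truth", "predicted"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(list(truth = truth, pred = pred))
}
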