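# Model-ready matrices, cross-validation designs (leave-one-trial-out and
# leave-one-subject-out) and train-fitted standardization.

#' Sensor setups
#'
#' `complete`: all five IMUs plus both EMG channels, 32 input columns.
#' `sparse`: upper-arm IMU, both wheelchair IMUs and both EMG channels,
#' 20 input columns.
#'
#' @param name `"complete"` or `"sparse"`.
#' @return List with `name`, `included_streams` and the fixed input column
#'   names (`columns`).
#' @export
sensor_setup <- function(name = c("complete", "sparse")) {
  name <- match.arg(name)
  streams <- if (name == "complete") {
    IMU_STREAMS
  } else {
    c("upper_arm", "wc_frame", "wc_wheel")
  }
  cols <- c(as.vector(t(outer(streams, IMU_CHANNELS, paste, sep = "_"))),
            paste0("emg_", EMG_STREAMS))
  list(name = name, included_streams = c(streams, EMG_STREAMS),
       columns = cols)
}

#' Build a model-ready sample from an aligned trial
#'
#' @param aligned An `sjrf_aligned` data frame.
#' @param setup A [sensor_setup()].
#' @return List of class `sjrf_sample`: keys, `X` (N x C input matrix, C = 32
#'   complete / 20 sparse, columns in the setup's fixed order) and `Y`
#'   (N x 3 target matrix, Fx/Fy/Fz in N).
#' @export
build_sample <- function(aligned, setup = sensor_setup("complete")) {
  miss <- setdiff(setup$columns, names(aligned))
  if (length(miss)) {
    stop("aligned trial lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(aligned[, setup$columns, drop = FALSE])
  Y <- as.matrix(aligned[, c("Fx", "Fy", "Fz"), drop = FALSE])
  if (anyNA(X) || anyNA(Y)) stop("missing values in aligned trial")
  out <- list(participant_id = attr(aligned, "participant_id"),
              activity = attr(aligned, "activity"),
              subtrial = attr(aligned, "subtrial"),
              setup = setup$name, X = X, Y = Y)
  class(out) <- "sjrf_sample"
  out
}

# internal: valid subtrial keys of a manifest, optionally per participant
valid_keys <- function(manifest, participant_id = NULL) {
  m <- manifest[manifest$valid, , drop = FALSE]
  if (!is.null(participant_id)) {
    m <- m[m$participant_id == participant_id, , drop = FALSE]
  }
  m
}

# hold out roughly `frac` of the training subtrials for early stopping,
# stratified by activity where an activity still keeps at least one
# subtrial in the training set
carve_validation <- function(train_df, frac = 0.15, seed = 1) {
  n_val <- max(1L, round(frac * nrow(train_df)))
  with_seed(seed, {
    val <- character(0)
    acts <- sample(unique(train_df$activity))
    for (a in acts) {
      if (length(val) >= n_val) break
      rows <- train_df$key[train_df$activity == a]
      if (length(rows) >= 2) val <- c(val, sample(rows, 1))
    }
    remaining <- setdiff(train_df$key, val)
    if (length(val) < n_val) {
      pool <- remaining[remaining %in%
        train_df$key[train_df$activity %in%
                       names(which(table(train_df$activity[
                         train_df$key %in% remaining]) >= 2))]]
      if (length(pool) == 0) pool <- remaining
      extra <- sample(pool, min(n_val - length(val), max(length(pool) - 1, 0)))
      val <- c(val, extra)
    }
    val
  })
}

new_split_plan <- function(strategy, fold_id, train, validation, test) {
  stopifnot(!anyDuplicated(c(train, validation, test)))
  structure(list(strategy = strategy, fold_id = fold_id, train = train,
                 validation = validation, test = test),
            class = "sjrf_split")
}

#' Leave-one-trial-out folds for one participant
#'
#' Subject-specific cross-validation: each valid subtrial of the participant
#' is the test set of exactly one fold; a seeded 15% of the remaining
#' subtrials (stratified by activity where counts allow) is held out for
#' early stopping and the rest form the training set.
#'
#' @param manifest Cohort manifest data frame.
#' @param participant_id Participant whose subtrials are folded.
#' @param val_frac Fraction of non-test subtrials held out for validation.
#' @param seed Integer seed for the validation draw.
#' @return List of `sjrf_split` plans, one per valid subtrial.
#' @export
make_loto_folds <- function(manifest, participant_id, val_frac = 0.15,
                            seed = 1) {
  m <- valid_keys(manifest, participant_id)
  if (nrow(m) < 3) {
    stop(sprintf("participant %s has %d valid subtrials; need at least 3",
                 participant_id, nrow(m)), call. = FALSE)
  }
  lapply(seq_len(nrow(m)), function(i) {
    test <- m$key[i]
    rest <- m[-i, , drop = FALSE]
    val <- carve_validation(rest, val_frac,
                            child_seed(seed, participant_id, i))
    new_split_plan("LOTO", sprintf("loto_p%02d_f%02d", participant_id, i),
                   train = setdiff(rest$key, val), validation = val,
                   test = test)
  })
}

#' Leave-one-subject-out folds
#'
#' Generalizable cross-validation: each fold tests on all valid subtrials of
#' one participant and trains on all other participants' valid subtrials
#' (minus a seeded 15% validation hold-out).
#'
#' @param manifest Cohort manifest data frame.
#' @param val_frac Fraction of training subtrials held out for validation.
#' @param seed Integer seed for the validation draw.
#' @return List of `sjrf_split` plans, one per participant.
#' @export
make_loso_folds <- function(manifest, val_frac = 0.15, seed = 1) {
  participants <- sort(unique(manifest$participant_id))
  if (length(participants) < 2) {
    stop("leave-one-subject-out needs at least 2 participants", call. = FALSE)
  }
  lapply(participants, function(p) {
    test <- valid_keys(manifest, p)$key
    rest <- valid_keys(manifest)
    rest <- rest[rest$participant_id != p, , drop = FALSE]
    val <- carve_validation(rest, val_frac, child_seed(seed, 7, p))
    new_split_plan("LOSO", sprintf("loso_p%02d", p),
                   train = setdiff(rest$key, val), validation = val,
                   test = test)
  })
}

#' Serialize / read split plans as JSON
#'
#' @param splits List of `sjrf_split` plans.
#' @param path Output JSON file.
#' @return `path` (write) or the list of plans (read).
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(
    lapply(splits, function(s) s[c("strategy", "fold_id", "train",
                                   "validation", "test")]),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    new_split_plan(raw$strategy[i], raw$fold_id[i],
                   unlist(raw$train[i]), unlist(raw$validation[i]),
                   unlist(raw$test[i]))
  })
}

#' Fit a standardizer on training samples
#'
#' Per-column mean and population standard deviation (divide by N) of the
#' pooled training rows, for inputs and targets separately. Statistics are a
#' pure function of the training samples; test data are always transformed
#' with these training statistics.
#'
#' @param samples List of `sjrf_sample` training samples.
#' @return Object of class `sjrf_standardizer`.
#' @export
fit_standardizer <- function(samples) {
  if (length(samples) == 0) stop("no training samples", call. = FALSE)
  X <- do.call(rbind, lapply(samples, `[[`, "X"))
  Y <- do.call(rbind, lapply(samples, `[[`, "Y"))
  pop_sd <- function(M) sqrt(colMeans(sweep(M, 2, colMeans(M))^2))
  sx <- pop_sd(X)
  sy <- pop_sd(Y)
  bad <- c(colnames(X)[sx == 0], colnames(Y)[sy == 0])
  if (length(bad)) {
    stop("constant column(s), cannot standardize: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(x_mean = colMeans(X), x_sd = sx,
                 y_mean = colMeans(Y), y_sd = sy),
            class = "sjrf_standardizer")
}

#' Apply / invert standardization
#'
#' @param std An `sjrf_standardizer`.
#' @param M Matrix to transform.
#' @param what `"x"` (inputs) or `"y"` (targets).
#' @return Transformed matrix.
#' @export
standardize_apply <- function(std, M, what = c("x", "y")) {
  what <- match.arg(what)
  mu <- std[[paste0(what, "_mean")]]
  sd <- std[[paste0(what, "_sd")]]
  sweep(sweep(as.matrix(M), 2, mu), 2, sd, "/")
}

#' @rdname standardize_apply
#' @export
standardize_invert <- function(std, M, what = c("x", "y")) {
  what <- match.arg(what)
  mu <- std[[paste0(what, "_mean")]]
  sd <- std[[paste0(what, "_sd")]]
  sweep(sweep(as.matrix(M), 2, sd, "*"), 2, mu, "+")
}

#' Build samples for every subtrial of a cohort
#'
#' Convenience driver: [align_cohort()] then [build_sample()] per subtrial.
#'
#' @param cohort An `sjrf_cohort`.
#' @param setup A [sensor_setup()].
#' @param aligned Optional precomputed result of [align_cohort()].
#' @return Named list of `sjrf_sample`, keyed like the manifest.
#' @export
build_cohort_samples <- function(cohort, setup = sensor_setup("complete"),
                                 aligned = NULL) {
  if (is.null(aligned)) aligned <- align_cohort(cohort)
  lapply(aligned$aligned, build_sample, setup = setup)
}
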