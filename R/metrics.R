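# Evaluation metrics: total force Ftot, Pearson correlation, range-normalized
# RMSE, and the activity-level / participant-level aggregations over
# concatenated subtrials and repeated training iterations.

#' Total shoulder-joint reaction force
#'
#' Per-sample Euclidean norm of the three force components.
#'
#' @param F N x 3 matrix (Fx, Fy, Fz in N) or a vector of length 3.
#' @return Numeric vector of length N, non-negative.
#' @export
compute_ftot <- function(F) {
  F <- matrix(F, ncol = 3)
  if (!all(is.finite(F))) stop("non-finite force values", call. = FALSE)
  sqrt(rowSums(F^2))
}

#' Pearson correlation between predicted and ground-truth series
#'
#' Standard product-moment correlation (sample, n - 1 convention). Constant
#' input makes the coefficient undefined; `NA` is returned with a warning.
#'
#' @param pred,truth Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2) {
    stop("pred and truth must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("constant series: Pearson correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred, truth)
}

#' Relative root-mean-squared error
#'
#' RMSE normalized by the range of the ground-truth series, in percent:
#' `100 * RMSE(pred, truth) / (max(truth) - min(truth))`.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return rRMSE in percent (>= 0).
#' @export
rrmse <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  rng <- max(truth) - min(truth)
  if (rng <= 0) stop("ground-truth range is zero", call. = FALSE)
  100 * sqrt(mean((pred - truth)^2)) / rng
}

#' Prediction table constructor
#'
#' One row per (participant, activity, subtrial, iteration) with the
#' predicted and ground-truth force series held as list columns; the unit of
#' account for all aggregation functions.
#'
#' @param participant_id,activity,subtrial,iteration Vectors of keys.
#' @param pred,truth Lists of N x 3 matrices.
#' @return A data frame of class `sjrf_predictions`.
#' @export
prediction_table <- function(participant_id, activity, subtrial, iteration,
                             pred, truth) {
  out <- data.frame(participant_id = participant_id, activity = activity,
                    subtrial = subtrial, iteration = iteration,
                    stringsAsFactors = FALSE)
  out$pred <- pred
  out$truth <- truth
  class(out) <- c("sjrf_predictions", "data.frame")
  out
}

#' Concatenate subtrial predictions back to whole activities
#'
#' For one participant and iteration, subtrials of each activity are
#' concatenated in subtrial order. Activities with missing subtrials
#' (relative to `expected`, typically the manifest's valid subtrials) are
#' flagged incomplete and dropped with a message.
#'
#' @param predictions An `sjrf_predictions` table filtered to one
#'   (participant, iteration).
#' @param expected Optional data frame with columns `activity`, `subtrial`
#'   giving the subtrials that must be present.
#' @return Named list per complete activity: `list(pred, truth)` concatenated
#'   N x 3 matrices.
#' @export
concatenate_to_activities <- function(predictions, expected = NULL) {
  out <- list()
  for (a in unique(predictions$activity)) {
    rows <- predictions[predictions$activity == a, , drop = FALSE]
    rows <- rows[order(rows$subtrial), , drop = FALSE]
    if (!is.null(expected)) {
      need <- sort(expected$subtrial[expected$activity == a])
      if (!identical(sort(rows$subtrial), need)) {
        message(sprintf(
          "activity '%s' incomplete (have subtrials %s, expected %s); dropped",
          a, paste(rows$subtrial, collapse = ","),
          paste(need, collapse = ",")))
        next
      }
    }
    out[[a]] <- list(pred = do.call(rbind, rows$pred),
                     truth = do.call(rbind, rows$truth))
  }
  out
}

# restrict a completeness contract to one participant when it carries a
# participant_id column
expected_for <- function(expected, participant_id) {
  if (is.null(expected) || is.null(expected$participant_id)) return(expected)
  expected[expected$participant_id == participant_id, , drop = FALSE]
}

metric_row <- function(scope, participant_id, activity, iteration, pred,
                       truth) {
  ft_p <- compute_ftot(pred)
  ft_t <- compute_ftot(truth)
  data.frame(scope = scope, participant_id = participant_id,
             activity = activity, iteration = iteration,
             pcc = pearson(ft_p, ft_t), rrmse = rrmse(ft_p, ft_t),
             stringsAsFactors = FALSE)
}

#' Activity-level metrics
#'
#' Per (participant, activity, iteration) the subtrials are concatenated and
#' PCC / rRMSE computed on Ftot; metrics are then averaged over iterations,
#' yielding one record per participant per activity.
#'
#' @param predictions An `sjrf_predictions` table.
#' @param expected Optional completeness contract (see
#'   [concatenate_to_activities()]).
#' @return List with `per_iteration` and `records` (iteration-averaged) data
#'   frames.
#' @export
activity_level_metrics <- function(predictions, expected = NULL) {
  per <- list()
  for (p in unique(predictions$participant_id)) {
    for (it in unique(predictions$iteration)) {
      sub <- predictions[predictions$participant_id == p &
                           predictions$iteration == it, , drop = FALSE]
      acts <- concatenate_to_activities(sub, expected_for(expected, p))
      for (a in names(acts)) {
        per[[length(per) + 1L]] <- metric_row("activity", p, a, it,
                                              acts[[a]]$pred, acts[[a]]$truth)
      }
    }
  }
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0) {
    stop("no complete activities to aggregate", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(pcc, rrmse) ~ participant_id + activity,
                          data = per, FUN = mean)
  agg$scope <- "activity"
  list(per_iteration = per, records = agg)
}

#' Participant-level metrics
#'
#' Per (participant, iteration) all complete activities are concatenated into
#' one series pair and PCC / rRMSE computed on Ftot, yielding one record per
#' participant per iteration.
#'
#' @inheritParams activity_level_metrics
#' @return Data frame with one row per (participant, iteration).
#' @export
participant_level_metrics <- function(predictions, expected = NULL) {
  out <- list()
  for (p in unique(predictions$participant_id)) {
    for (it in unique(predictions$iteration)) {
      sub <- predictions[predictions$participant_id == p &
                           predictions$iteration == it, , drop = FALSE]
      acts <- concatenate_to_activities(sub, expected_for(expected, p))
      if (length(acts) == 0) next
      pred <- do.call(rbind, lapply(acts, `[[`, "pred"))
      truth <- do.call(rbind, lapply(acts, `[[`, "truth"))
      out[[length(out) + 1L]] <- metric_row("participant", p, "all", it,
                                            pred, truth)
    }
  }
  do.call(rbind, out)
}
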