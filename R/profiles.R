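# Shoulder-load profiles: histograms of total force Ftot at a fixed 25 N bin
# width, compared between prediction and ground truth by the Swain-Ballard
# histogram intersection.

#' Build a shoulder-load profile
#'
#' Histogram of Ftot with uniform bins of `bin_width` newton anchored at 0:
#' `[0, 25), [25, 50), ...`, the final bin closed. When two profiles are to
#' be intersected they must share edges; pass `edges` from
#' [shared_profile_edges()].
#'
#' @param ftot Non-negative force series (N).
#' @param bin_width Bin width in N (default 25).
#' @param edges Optional explicit edge vector (overrides `bin_width`).
#' @return Object of class `sjrf_load_profile` with `bin_edges`, `counts`,
#'   `n_bins`, `n_samples`.
#' @export
build_profile <- function(ftot, bin_width = 25, edges = NULL) {
  if (length(ftot) == 0) stop("empty force series", call. = FALSE)
  if (any(!is.finite(ftot))) stop("non-finite force values", call. = FALSE)
  if (any(ftot < 0)) {
    stop("negative force values: Ftot is a Euclidean norm", call. = FALSE)
  }
  if (is.null(edges)) {
    top <- max(bin_width, bin_width * ceiling(max(ftot) / bin_width))
    edges <- seq(0, top, by = bin_width)
  }
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  bins <- findInterval(ftot, edges, rightmost.closed = TRUE)
  if (any(bins == 0 | bins >= length(edges))) {
    stop("force values outside the binning range", call. = FALSE)
  }
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 n_bins = length(edges) - 1L, n_samples = length(ftot)),
            class = "sjrf_load_profile")
}

#' Shared histogram edges for a pair of series
#'
#' Uniform `bin_width` edges from 0 up to the smallest multiple of
#' `bin_width` covering both series.
#'
#' @param f1,f2 Non-negative force series.
#' @param bin_width Bin width in N.
#' @return Numeric edge vector.
#' @export
shared_profile_edges <- function(f1, f2, bin_width = 25) {
  top <- max(bin_width, bin_width * ceiling(max(f1, f2) / bin_width))
  seq(0, top, by = bin_width)
}

#' Histogram intersection of two load profiles
#'
#' The Swain-Ballard intersection
#' `I(y, yhat) = sum_i min(y_i, yhat_i) / sum_i y_i`, where `y` are the
#' ground-truth bin counts and `yhat` the predicted ones. When both profiles
#' bin the same number of samples, `I` lies in `[0, 1]` and `I(y, y) = 1`.
#'
#' @param truth Ground-truth `sjrf_load_profile` (denominator).
#' @param pred Predicted `sjrf_load_profile`; must share the edges of
#'   `truth`.
#' @return Scalar intersection value.
#' @export
histogram_intersection <- function(truth, pred) {
  if (!isTRUE(all.equal(truth$bin_edges, pred$bin_edges))) {
    stop("profiles must share bin edges", call. = FALSE)
  }
  denom <- sum(truth$counts)
  if (denom <= 0) stop("empty ground-truth profile", call. = FALSE)
  sum(pmin(truth$counts, pred$counts)) / denom
}

# intersection for one pair of force series with shared edges
series_intersection <- function(ftot_truth, ftot_pred, bin_width = 25) {
  edges <- shared_profile_edges(ftot_truth, ftot_pred, bin_width)
  histogram_intersection(build_profile(ftot_truth, edges = edges),
                         build_profile(ftot_pred, edges = edges))
}

#' Load-profile intersection report
#'
#' Mean (SD) intersection values over iterations, either per participant
#' (profiles over all concatenated activities; one table row per participant
#' plus a mean row) or per activity for one participant (one row per
#' activity plus a mean row).
#'
#' @param predictions An `sjrf_predictions` table.
#' @param scope `"participants"` or `"activities"`.
#' @param participant_id Participant used for the per-activity table
#'   (defaults to the first).
#' @param bin_width Bin width in N.
#' @param expected Optional completeness contract (manifest's valid
#'   subtrials).
#' @return Data frame with columns `label`, `mean`, `sd` (intersections); the
#'   last row is the mean over rows.
#' @export
profile_report <- function(predictions, scope = c("participants",
                                                  "activities"),
                           participant_id = NULL, bin_width = 25,
                           expected = NULL) {
  scope <- match.arg(scope)
  rows <- list()
  if (scope == "participants") {
    for (p in sort(unique(predictions$participant_id))) {
      vals <- vapply(sort(unique(predictions$iteration)), function(it) {
        sub <- predictions[predictions$participant_id == p &
                             predictions$iteration == it, , drop = FALSE]
        acts <- concatenate_to_activities(sub, expected_for(expected, p))
        pred <- do.call(rbind, lapply(acts, `[[`, "pred"))
        truth <- do.call(rbind, lapply(acts, `[[`, "truth"))
        series_intersection(compute_ftot(truth), compute_ftot(pred),
                            bin_width)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        label = as.character(p), mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0)
    }
  } else {
    p <- participant_id %||% sort(unique(predictions$participant_id))[1]
    sub_p <- predictions[predictions$participant_id == p, , drop = FALSE]
    for (a in unique(sub_p$activity)) {
      vals <- c()
      for (it in sort(unique(sub_p$iteration))) {
        sub <- sub_p[sub_p$iteration == it, , drop = FALSE]
        acts <- concatenate_to_activities(sub, expected_for(expected, p))
        if (!a %in% names(acts)) next
        vals <- c(vals, series_intersection(
          compute_ftot(acts[[a]]$truth), compute_ftot(acts[[a]]$pred),
          bin_width))
      }
      if (length(vals) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        label = a, mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0)
    }
  }
  out <- do.call(rbind, rows)
  rbind(out, data.frame(label = "mean", mean = mean(out$mean),
                        sd = stats::sd(out$mean)))
}
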