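# Metric oracles: Ftot, Pearson correlation, rRMSE, brute-force agreement,
# invariances, and the aggregation bookkeeping.

brute_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}
brute_rrmse <- function(p, t) {
  100 * sqrt(sum((p - t)^2) / length(t)) / (max(t) - min(t))
}

test_that("Ftot is the per-sample Euclidean norm", {
  expect_identical(compute_ftot(c(3, 4, 0)), 5)
  expect_identical(compute_ftot(c(0, 0, 0)), 0)
  expect_identical(compute_ftot(c(1, 2, 2)), 3)
  M <- rbind(c(3, 4, 0), c(1, 2, 2))
  expect_identical(compute_ftot(M), c(5, 3))
  expect_error(compute_ftot(c(1, NA, 2)), "finite")
})

test_that("pearson and rrmse match brute force on random vectors", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    p <- rnorm(n, sd = runif(1, 0.5, 5))
    t <- rnorm(n, sd = runif(1, 0.5, 5))
    expect_equal(pearson(p, t), brute_pearson(p, t), tolerance = 1e-10)
    expect_equal(rrmse(p, t), brute_rrmse(p, t), tolerance = 1e-10)
  }
})

test_that("pearson handles the exact and degenerate cases", {
  t <- c(1, 2, 3, 4)
  expect_equal(pearson(t, t), 1)
  expect_equal(pearson(-t + 10, t), -1)
  expect_equal(pearson(c(1, 2, 3, 5), c(1, 2, 3, 4)), 0.9827, tolerance = 1e-3)
  expect_warning(r <- pearson(rep(2, 4), t), "constant")
  expect_true(is.na(r))
  expect_error(pearson(1:3, 1:4), "equal length")
  # invariance under separate positive affine maps
  set.seed(1)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(pearson(2 * a + 3, 0.5 * b - 1), pearson(a, b),
               tolerance = 1e-12)
})

test_that("rrmse handles offsets, scaling and degenerate range", {
  t <- c(0, 2, 5, 10)
  expect_identical(rrmse(t, t), 0)
  # constant offset c on range R gives exactly 100 c / R
  expect_equal(rrmse(t + 3, t), 100 * 3 / 10, tolerance = 1e-12)
  expect_equal(rrmse(c(0, 0), c(0, 10)), 100 * sqrt(50) / 10,
               tolerance = 1e-12)
  expect_error(rrmse(c(1, 2), c(3, 3)), "zero")
  # invariant under common positive scaling and common shift
  set.seed(2)
  p <- rnorm(40)
  tt <- rnorm(40)
  expect_equal(rrmse(3 * p, 3 * tt), rrmse(p, tt), tolerance = 1e-12)
  expect_equal(rrmse(p + 5, tt + 5), rrmse(p, tt), tolerance = 1e-12)
})

make_preds <- function(n_sub = 3, n_iter = 2, n = 50, activity = "desk_work",
                       participant = 1L, jitter = 0) {
  rows <- expand.grid(subtrial = seq_len(n_sub), iteration = seq_len(n_iter))
  set.seed(99)
  truth <- lapply(seq_len(n_sub), function(i) {
    matrix(abs(rnorm(n * 3, mean = 40, sd = 10)), n, 3)
  })
  prediction_table(
    participant_id = rep(participant, nrow(rows)),
    activity = rep(activity, nrow(rows)),
    subtrial = rows$subtrial, iteration = rows$iteration,
    pred = lapply(seq_len(nrow(rows)), function(i) {
      truth[[rows$subtrial[i]]] + jitter * rnorm(n * 3)
    }),
    truth = truth[rows$subtrial])
}

test_that("subtrials concatenate to whole activities in stable order", {
  preds <- make_preds(n_sub = 3, n_iter = 1, n = 100)
  acts <- concatenate_to_activities(preds)
  expect_identical(nrow(acts$desk_work$pred), 300L)
  # manifest-order stability: blocks appear in subtrial order
  expect_identical(acts$desk_work$truth[1:100, ], preds$truth[[1]])
  # a missing subtrial flags the activity incomplete
  expected <- data.frame(activity = "desk_work", subtrial = 1:3)
  expect_message(
    acts2 <- concatenate_to_activities(preds[-1, ], expected),
    "incomplete")
  expect_length(acts2, 0)
})

test_that("activity- and participant-level aggregation counts records", {
  preds <- make_preds(n_sub = 2, n_iter = 3, jitter = 1)
  al <- activity_level_metrics(preds)
  expect_identical(nrow(al$per_iteration), 3L) # one per iteration
  expect_identical(nrow(al$records), 1L)       # averaged over iterations
  expect_equal(al$records$pcc, mean(al$per_iteration$pcc), tolerance = 1e-12)
  # two iterations with PCC 0.6 / 0.8 average to 0.7
  fake <- al$per_iteration[1:2, ]
  fake$pcc <- c(0.6, 0.8)
  expect_equal(mean(fake$pcc), 0.7)

  pl <- participant_level_metrics(preds)
  expect_identical(nrow(pl), 3L) # one per (participant, iteration)
  expect_identical(unique(pl$activity), "all")
  # perfect prediction scores perfectly after concatenation
  perf <- make_preds(n_sub = 2, n_iter = 1, jitter = 0)
  plp <- participant_level_metrics(perf)
  expect_equal(plp$pcc, 1, tolerance = 1e-12)
  expect_equal(plp$rrmse, 0, tolerance = 1e-12)
})

test_that("activity concatenation order does not change the metrics", {
  set.seed(5)
  n <- 60
  mk <- function(act, sub) {
    list(act = act, sub = sub, truth = matrix(abs(rnorm(n * 3, 50, 12)), n, 3))
  }
  specs <- list(mk("a", 1L), mk("a", 2L), mk("b", 1L))
  build <- function(order_idx) {
    s <- specs[order_idx]
    prediction_table(
      participant_id = rep(1L, 3),
      activity = vapply(s, `[[`, "", "act"),
      subtrial = vapply(s, `[[`, 0L, "sub"),
      iteration = rep(1L, 3),
      pred = lapply(s, function(x) x$truth + 2),
      truth = lapply(s, `[[`, "truth"))
  }
  m1 <- participant_level_metrics(build(1:3))
  m2 <- participant_level_metrics(build(c(3, 1, 2)))
  expect_equal(m1$rrmse, m2$rrmse, tolerance = 1e-12)
  expect_lt(abs(m1$pcc - m2$pcc), 1e-12)
})
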