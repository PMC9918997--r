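# Network construction, gradient correctness, training protocol (early
# stopping, seed determinism), prediction contracts and iteration sets.

test_that("parameter counts match the closed-form arithmetic", {
  cfg_lin <- sjrf_config("linear", input_width = 20)
  expect_identical(n_params(cfg_lin),
                   20L * 250L + 250L + 250L * 100L + 100L + 100L * 3L + 3L)
  expect_identical(n_params(cfg_lin), 30653L)
  # counts of actual parameter arrays agree with the formula
  p <- sjrfest:::init_params(cfg_lin)
  expect_identical(sjrfest:::param_count(p), as.numeric(n_params(cfg_lin)))
  cfg_b20 <- sjrf_config("bilstm", input_width = 20)
  cfg_b32 <- sjrf_config("bilstm", input_width = 32)
  expect_identical(sjrfest:::param_count(sjrfest:::init_params(cfg_b20)),
                   as.numeric(n_params(cfg_b20)))
  # first-layer count differs by 2 directions x 4 gates x 128 units x 12 inputs
  expect_identical(n_params(cfg_b32) - n_params(cfg_b20), 8L * 128L * 12L)
})

test_that("identical seeds give identical initial parameters", {
  cfg <- smoke_config(seed = 5)
  p1 <- sjrfest:::with_seed(5, sjrfest:::init_params(cfg))
  p2 <- sjrfest:::with_seed(5, sjrfest:::init_params(cfg))
  expect_identical(p1, p2)
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  X <- matrix(rnorm(6 * 4), 6, 4)
  Y <- matrix(rnorm(6 * 3), 6, 3)
  for (arch in c("bilstm", "linear")) {
    cfg <- sjrf_config(arch, input_width = 4, bilstm_layers = 2,
                       bilstm_units = 3, dropout = 0, linear_units = c(5, 4),
                       seed = 2)
    params <- sjrfest:::with_seed(2, sjrfest:::init_params(cfg))
    loss_at <- function(p) {
      fw <- sjrfest:::forward_pass(p, cfg, X, training = FALSE)
      mean((fw$Yhat - Y)^2)
    }
    fwd <- sjrfest:::forward_pass(params, cfg, X, training = FALSE)
    g <- sjrfest:::backward_pass(params, cfg, fwd,
                                 2 * (fwd$Yhat - Y) / length(Y))
    # probe a few coordinates per block against central differences
    eps <- 1e-6
    for (l in seq_along(params$layers)) {
      for (nm in names(params$layers[[l]])) {
        idx <- sample(length(params$layers[[l]][[nm]]), 2)
        for (i in idx) {
          p2 <- params
          p2$layers[[l]][[nm]][i] <- p2$layers[[l]][[nm]][i] + eps
          p3 <- params
          p3$layers[[l]][[nm]][i] <- p3$layers[[l]][[nm]][i] - eps
          num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
          ana <- g$layers[[l]][[nm]][i]
          expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3)
        }
      }
    }
  }
})

test_that("early stopping follows the patience-6 / max-200 semantics", {
  # non-improving streak of 6 after the epoch-2 minimum -> stop at 8, best 2
  tr <- early_stopping_trace(c(5, 4, 4.1, 4.2, 4.3, 4.4, 4.5, 4.6),
                             patience = 6, max_epochs = 200)
  expect_identical(tr, list(stop_epoch = 8L, best_epoch = 2L))
  # monotone decrease runs to the cap
  tr2 <- early_stopping_trace(seq(10, 0.05, length.out = 300), 6, 200)
  expect_identical(tr2$stop_epoch, 200L)
  expect_identical(tr2$best_epoch, 200L)
  # exhaustive agreement with a plain reference implementation on random
  # schedules
  ref_trace <- function(v, patience, max_epochs) {
    best <- Inf; best_e <- 0L; run <- 0L
    for (e in seq_len(min(length(v), max_epochs))) {
      if (v[e] < best) { best <- v[e]; best_e <- e; run <- 0L }
      else run <- run + 1L
      if (run >= patience) return(list(stop_epoch = e, best_epoch = best_e))
    }
    list(stop_epoch = min(length(v), max_epochs), best_epoch = best_e)
  }
  set.seed(14)
  for (i in 1:50) {
    v <- cumsum(rnorm(60)) + 10
    expect_identical(early_stopping_trace(v, 6, 50), ref_trace(v, 6, 50))
  }
})

test_that("the training loop stops early and restores the best epoch", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 1, seed = 8,
                     duration_scale = 0.2)
  samples <- smoke_samples(co)
  fold <- make_loto_folds(co$manifest, 1, seed = 2)[[1]]
  cfg <- smoke_config(max_epochs = 300, patience = 3, bilstm_units = 4,
                      seed = 3)
  m <- fit_fold(fold, samples, cfg)
  expect_s3_class(m, "sjrf_net")
  expect_lte(nrow(m$history), 300)
  expect_identical(m$stopped_epoch, nrow(m$history))
  # the recorded history reproduces best_epoch under the stop rule
  tr <- early_stopping_trace(m$history$val_loss, 3, 300)
  expect_identical(m$best_epoch, tr$best_epoch)
  # seed determinism of the whole training
  m2 <- fit_fold(fold, samples, cfg)
  expect_identical(m$best_epoch, m2$best_epoch)
  expect_equal(m$params, m2$params, tolerance = 1e-12)
})

test_that("prediction is deterministic, shaped N x 3, width-checked", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 1, seed = 8,
                     duration_scale = 0.2)
  samples <- smoke_samples(co)
  fold <- make_loto_folds(co$manifest, 1, seed = 2)[[2]]
  m <- fit_fold(fold, samples, smoke_config(max_epochs = 8, seed = 3))
  s <- samples[[fold$test]]
  p1 <- predict(m, s)
  expect_identical(dim(p1), c(nrow(s$X), 3L))
  expect_identical(colnames(p1), c("Fx", "Fy", "Fz"))
  expect_identical(p1, predict(m, s)) # dropout disabled at inference
  wrong <- s
  wrong$X <- s$X[, 1:10]
  expect_error(predict(m, wrong), "width")
  # residuals method is truth minus prediction
  expect_equal(residuals(m, s), s$Y - p1, ignore_attr = TRUE)
})

test_that("a biLSTM fits the low-noise generative mapping closely", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 0.1, seed = 18,
                     duration_scale = 0.2)
  samples <- smoke_samples(co)
  fold <- make_loto_folds(co$manifest, 1, seed = 2)[[4]]
  cfg <- smoke_config(max_epochs = 150, patience = 10, bilstm_units = 32,
                      dropout = 0.05, seed = 7)
  m <- fit_fold(fold, samples, cfg)
  expect_lt(min(m$history$train_loss), 0.05)
  s <- samples[[fold$test]]
  expect_gt(pearson(compute_ftot(predict(m, s)), compute_ftot(s$Y)), 0.9)
})

test_that("iteration sets hold one model per distinct seed", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 1, seed = 8,
                     duration_scale = 0.2)
  samples <- smoke_samples(co)
  fold <- make_loto_folds(co$manifest, 1, seed = 2)[[1]]
  iter <- run_iterations(fold, samples, smoke_config(max_epochs = 4),
                         n_iter = 3, base_seed = 50)
  expect_length(iter, 3)
  seeds <- vapply(iter, function(m) m$config$seed, 0L)
  expect_identical(seeds, c(50L, 51L, 52L))
  expect_length(run_iterations(fold, samples, smoke_config(max_epochs = 3),
                               n_iter = 1), 1)
})
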