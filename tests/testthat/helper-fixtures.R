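# Shared fixtures: small cohorts and model configs, built once per test run.
# Durations are scaled down and networks kept narrow so the suite stays fast;
# the code paths are identical to full scale.

smoke_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n_participants = 2, noise_sd = 1, seed = 42, duration_scale = 0.2,
           n_exclusions = 0, ...) {
    key <- paste(n_participants, noise_sd, seed, duration_scale, n_exclusions,
                 ..., sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(
        n_participants = n_participants, noise_sd = noise_sd, seed = seed,
        duration_scale = duration_scale, n_exclusions = n_exclusions, ...)
    }
    cache[[key]]
  }
})

smoke_samples <- local({
  cache <- new.env(parent = emptyenv())
  function(cohort, setup = "sparse") {
    key <- paste(setup, cohort$params$seed, cohort$params$n_participants,
                 cohort$params$noise_sd, cohort$params$duration_scale,
                 sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_cohort_samples(cohort, sensor_setup(setup))
    }
    cache[[key]]
  }
})

smoke_config <- function(arch = "bilstm", input_width = 20, seed = 1, ...) {
  defaults <- list(architecture = arch, input_width = input_width,
                   bilstm_layers = 1, bilstm_units = 16, dropout = 0.1,
                   linear_units = c(32, 16), max_epochs = 25, patience = 5,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  args$patience <- min(args$patience, args$max_epochs - 1L)
  do.call(sjrf_config, args)
}

# a tiny deterministic sample for shape/contract tests
toy_sample <- function(n = 40, width = 20, seed = 1) {
  set.seed(seed)
  s <- list(participant_id = 1L, activity = "toy", subtrial = 1L,
            setup = "sparse",
            X = matrix(rnorm(n * width), n, width),
            Y = matrix(rnorm(n * 3), n, 3,
                       dimnames = list(NULL, c("Fx", "Fy", "Fz"))))
  class(s) <- "sjrf_sample"
  s
}
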