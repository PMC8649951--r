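# Desk-scale end-to-end training world shared by the acceptance tests:
# ~200 motion-free 64x64 phantom stacks, synthetic smooth deformations of
# up to 3 px, a reduced-width network, and a bounded CPU-budget schedule.
# Trained once per test run and memoized.

desk_env <- new.env(parent = emptyenv())

desk_seed <- 42L

desk_clean_stacks <- function(n = 200) {
  lapply(seq_len(n), function(i) {
    tm <- make_phantom(jitter = 2, seed = i)
    simulate_irw(tm, noise_sigma = 1, seed = i)
  })
}

desk_train_config <- function() {
  train_config(lr_init = 0.002, patience_epochs = 8, max_epochs = 18,
               scheduler = list(factor = 0.5, patience = 4, min_lr = 1e-5),
               amplitude_px = 3, smoothness_px = 12,
               fixed_pairs = TRUE, seed = desk_seed)
}

desk_model <- function() {
  if (!is.null(desk_env$fit)) return(desk_env$fit)
  model <- build_network(network_config(base_channels = 8), seed = desk_seed)
  fit <- train(model, desk_clean_stacks(), desk_train_config())
  desk_env$fit <- fit
  fit
}

# Held-out synthetic evaluation cases (seeds disjoint from training).
desk_motion_cases <- function(n = 20) {
  lapply(seq_len(n), function(i)
    make_test_case(amplitude_px = 3, noise_sigma = 2, seed = 5000 + i))
}

desk_clean_cases <- function(n = 10) {
  lapply(seq_len(n), function(i)
    make_test_case(amplitude_px = 0, noise_sigma = 2, seed = 7000 + i))
}
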