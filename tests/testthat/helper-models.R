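# Shared fixtures built in code: tiny network configs, an untrained model
# wrapper for dimension checks, and a small cached cohort + fit so several
# test files can reuse one (seeded) expensive object.

tiny_net_config <- function(...) {
  msfnet_config(conv1d = list(channels = c(3, 4, 4), kernels = c(3, 3, 3),
                              strides = c(1, 1, 1), pools = c(2, 2, 2)),
                conv2d = list(channels = c(3, 4, 4), kernels = c(3, 3, 3),
                              pools = c(2, 2, 2)),
                embed_1d = 4, embed_2d = 4, handcrafted_dim = 5,
                fused_dim = 13, gate_hidden = 6, classifier = c(7, 5),
                dropout = c(0, 0), input_channels = 2, input_length = 32,
                spec_side = 8, ...)
}

# an msfnet object with freshly initialized (untrained) weights: enough to
# exercise shapes, determinism and the prediction plumbing
untrained_msfnet <- function(cfg = msfnet_config(), seed = 1) {
  set.seed(seed)
  ini <- somnifuse:::.nn_init(cfg)
  structure(list(params = ini$params, state = ini$state, config = cfg,
                 feat_center = rep(0, cfg$handcrafted_dim),
                 feat_scale = rep(1, cfg$handcrafted_dim),
                 class_weights = rep(1, cfg$n_classes),
                 history = data.frame(), best_val_f1 = NA_real_,
                 best_epoch = 0L, val_subjects = character(0),
                 n_train = 0L, n_val = 0L,
                 levels = c("Wake", "NREM", "REM")),
            class = "msfnet")
}

# random inputs of the right shapes for n epochs
random_streams <- function(n, cfg = msfnet_config(), seed = 1) {
  set.seed(seed)
  list(raw = array(stats::rnorm(n * cfg$input_channels * cfg$input_length),
                   c(n, cfg$input_channels, cfg$input_length)),
       spec = array(stats::rnorm(n * cfg$input_channels * cfg$spec_side^2),
                    c(n, cfg$input_channels, cfg$spec_side, cfg$spec_side)),
       feat = matrix(stats::rnorm(n * cfg$handcrafted_dim), n,
                     cfg$handcrafted_dim))
}

.fixture_env <- new.env(parent = emptyenv())

# small synthetic cohort (5 subjects x 24 epochs) shared across test files
small_cohort_dataset <- function() {
  if (is.null(.fixture_env$small_ds)) {
    coh <- simulate_cohort(sim_config(n_subjects = 5, epochs_per_night = 48,
                                      rem_target_mean = 0.3, seed = 41))
    .fixture_env$small_cohort <- coh
    .fixture_env$small_ds <- build_epoch_dataset(coh)
  }
  list(cohort = .fixture_env$small_cohort, ds = .fixture_env$small_ds)
}

# a quickly trained full-dimension model on the small cohort
small_fitted_model <- function() {
  if (is.null(.fixture_env$small_fit)) {
    ds <- small_cohort_dataset()$ds
    cfg <- msfnet_config(max_epochs = 3, patience = 3, seed = 5)
    .fixture_env$small_fit <- msfnet(list(raw = ds$raw, spec = ds$spec,
                                          feat = ds$feat),
                                     ds$y, subjects = ds$subject, config = cfg)
  }
  .fixture_env$small_fit
}
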