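# Shared fixtures: configurations and cached small datasets built in
# code at test time. Problem sizes are scaled to desk scale; the
# generator's physiological parameters keep their defaults.

tiny_sim <- function(seed = 1, n_subjects = 1, n_stop_trials = 6, ...) {
  sim_config(n_subjects = n_subjects, n_stop_trials = n_stop_trials,
             seed = seed, ...)
}

# one cached single-subject dataset reused across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_subject <- function() {
  if (is.null(.fixture_env$subject)) {
    cfg <- tiny_sim(seed = 42, n_stop_trials = 8)
    beh <- simulate_behavior(cfg)
    rec <- simulate_signals(cfg, beh$events, beh$truth)
    .fixture_env$subject <- list(cfg = cfg, events = beh$events,
                                 trials = beh$trials, truth = beh$truth,
                                 recording = rec)
  }
  .fixture_env$subject
}

# simple recording for IO tests
toy_recording <- function(n_chan = 3, n_samp = 1000, seed = 7) {
  set.seed(seed)
  recording(matrix(rnorm(n_chan * n_samp), n_chan),
            names = paste0("ch", seq_len(n_chan)),
            kinds = rep("eeg", n_chan), sample_rate = 100,
            subject_id = "T1")
}
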