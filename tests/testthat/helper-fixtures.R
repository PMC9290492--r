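# Shared fixtures, built in code at test time.

# small simulated session: schedule + stepping outcomes
make_session <- function(n_blocks = 2, seed = 101, truth = ground_truth(seed = seed)) {
  trials <- generate_trial_schedule(n_blocks, seed = seed)
  simulate_stepping(trials, truth)
}

# a preprocessed scalp recording in the reduced basis, plus generator truth
make_reduced_recording <- function(seed = 101, n_blocks = 2) {
  truth <- ground_truth(seed = seed)
  trials <- make_session(n_blocks, seed, truth)
  rec <- generate_eeg(trials, truth)
  sources <- attr(rec, "sources")
  injected <- attr(rec, "injected")
  rec <- rereference_common_average(bandpass_filter(rec))
  scalp <- which(rec$channel_roles == "scalp")
  rec_scalp <- recording(rec$samples[scalp, , drop = FALSE], rec$fs,
                         rec$channel_roles[scalp], rec$events)
  ns <- remove_nullspace(rec_scalp)
  list(reduced = ns$recording, backprojection = ns$backprojection,
       sources = sources, injected = injected, truth = truth,
       trials = trials)
}

# minimal hand-built unmixing model for selection tests
fake_unmixing <- function(n_comp, scalp_maps) {
  structure(list(unmixing = diag(n_comp), mixing = diag(n_comp),
                 scalp_maps = scalp_maps, center = rep(0, n_comp),
                 n1_component = NA_integer_, iterations = 0, vafs = NULL,
                 fs = 512),
            class = "pep_unmixing")
}

# hand-built epochs object (trials x components x time)
fake_epochs <- function(data, fs = 512, window_s = c(-0.5, 0.5)) {
  n_t <- dim(data)[3]
  structure(list(data = data,
                 times_s = seq(window_s[1], window_s[2], length.out = n_t),
                 fs = fs, trial_ids = seq_len(dim(data)[1]),
                 window_s = window_s, n_dropped = 0L),
            class = "pep_epochs")
}
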