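# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_targets <- function() {
  fixture("targets", function() synthesize_targets())
}

# small front end for fast fitting tests: 16 channels x 20 frames
fix_small_fb <- function() {
  fixture("small_fb", function() gammatone_filterbank(16, 100, 8000))
}

fix_full_fb <- function() {
  fixture("full_fb", function() gammatone_filterbank())
}

fix_small_observer <- function() {
  fixture("small_observer", function() {
    ideal_observer(fix_targets(), fix_small_fb(), n_frames = 20)
  })
}

# a 2000-trial experiment on the small lattice, with predictors; reused by
# the fitting, specificity and pipeline unit tests
fix_small_experiment <- function() {
  fixture("small_experiment", function() {
    tg <- fix_targets()
    fb <- fix_small_fb()
    obs <- fix_small_observer()
    trials <- run_experiment(obs, tg, n_trials = 2000,
                             trials_per_session = 500, seed = 5,
                             filterbank = fb, n_frames = 20)
    list(trials = trials,
         predictors = trial_predictors(trials, tg, fb, n_frames = 20),
         observer = obs)
  })
}

# smooth synthetic weight maps: shared pattern + iid noise per observer
make_maps <- function(n, nr = 12, nc = 15, effect = NULL, noise_sd = 1,
                      seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      if (!is.null(effect)) m <- m + effect
      m
    })
  })
}
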