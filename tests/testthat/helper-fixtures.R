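# Shared objects for the suite: the calibrated trial fixtures, the published
# contribution columns, and a tiny fully synthetic pair for fast unit checks.

fixtures <- load_trial_fixtures()
published <- load_published_contributions()

published_col <- function(trial, col) {
  rows <- published[published$trial == trial & published$source != "reported_total", ]
  stats::setNames(rows[[col]], rows$source)
}

reported_totals <- function(col) {
  rows <- published[published$source == "reported_total", ]
  stats::setNames(rows[[col]], rows$trial)
}

# one small deterministic synthetic pair + EF table
tiny_pair <- function(seed = 42, ...) {
  sc <- synthetic_scenario(seed = seed, n_trials = 1, ...)
  gen <- generate_scenario(sc)
  c(gen$pairs[[1]], list(ef = gen$ef))
}
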