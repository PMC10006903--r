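# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 6 subjects x 10 activities, noise-free, 30 s @ 20 Hz -> 360 windows of 5 s.
noisefree_table <- function() {
  fixture("noisefree_table", function() {
    recs <- generate_dataset(6, duration = 30, rate = 20, seed = 3,
                             noise_level = 0)
    features_table(segment_all(recs, 5))
  })
}

# 4 subjects x 10 activities with default noise, 30 s @ 20 Hz.
noisy_table <- function() {
  fixture("noisy_table", function() {
    recs <- generate_dataset(4, duration = 30, rate = 20, seed = 5)
    features_table(segment_all(recs, 5))
  })
}

# Single-intensity (moderate) table for degenerate-cascade checks.
moderate_table <- function() {
  fixture("moderate_table", function() {
    recs <- generate_dataset(4, activities = c("C1", "T3", "T4"),
                             duration = 30, rate = 20, seed = 9)
    features_table(segment_all(recs, 5))
  })
}
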