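# Independent oracles for the scalar descriptors: naive loops and closed
# forms, kept deliberately separate from the implementation's vectorised /
# FFT paths.

oracle_mean <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }
oracle_var <- function(x) {
  m <- oracle_mean(x); s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}
oracle_corr <- function(x, y) {
  mx <- oracle_mean(x); my <- oracle_mean(y); cv <- 0
  for (i in seq_along(x)) cv <- cv + (x[i] - mx) * (y[i] - my)
  (cv / length(x)) / sqrt(oracle_var(x) * oracle_var(y))
}
oracle_entropy <- function(x, K) {
  p <- Mod(stats::fft(x))^2
  p <- p[1:(floor(length(x) / 2) + 1)]
  m <- length(p) %/% K
  e <- numeric(K)
  for (k in 1:K) for (b in ((k - 1) * m + 1):(k * m)) e[k] <- e[k] + p[b]
  n <- e / sum(e)
  h <- 0
  for (k in 1:K) if (n[k] > 0) h <- h - n[k] * log2(n[k])
  h
}

test_that("closed-form examples of the scalar descriptors", {
  expect_equal(signal_mean(c(1, 1, 1, 1)), 1)
  expect_equal(signal_mean(c(0, 2)), 1)
  expect_error(signal_mean(numeric(0)), "empty")
  expect_equal(signal_variance(rep(3.7, 9)), 0)
  expect_equal(signal_variance(c(-1, 1)), 1)
  x <- rnorm(20)
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(correlation_coefficient(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_warning(r <- correlation_coefficient(rep(1, 5), 1:5), "constant")
  expect_equal(r, 0)
  expect_error(correlation_coefficient(1:3, 1:4), "lengths differ")
  expect_equal(signal_energy(rep(0, 8)), 0)
  expect_equal(signal_energy(c(1, 1, 1, 1)), 4)   # sum(x^2), confirmed by DFT
})

test_that("descriptors agree with independent oracles over 1000 random series", {
  worst <- c(mean = 0, var = 0, corr = 0, energy = 0)
  withr::with_seed(421, {
    for (i in 1:1000) {
      n <- sample(16:128, 1)
      x <- rnorm(n, sd = runif(1, 0.1, 5))
      y <- rnorm(n)
      worst["mean"] <- max(worst["mean"], abs(signal_mean(x) - oracle_mean(x)))
      worst["var"] <- max(worst["var"],
                          abs(signal_variance(x) - oracle_var(x)))
      worst["corr"] <- max(worst["corr"],
                           abs(correlation_coefficient(x, y) - oracle_corr(x, y)))
      # Parseval: spectral energy equals the time-domain sum of squares
      worst["energy"] <- max(worst["energy"],
                             abs(signal_energy(x) - sum(x^2)) / sum(x^2))
    }
  })
  expect_lt(worst["mean"], 1e-12)
  expect_lt(worst["var"], 1e-12)
  expect_lt(worst["corr"], 1e-12)
  expect_lt(worst["energy"], 1e-9)
})

test_that("spectral entropy matches a direct-summation oracle and its bounds", {
  withr::with_seed(77, {
    for (i in 1:200) {
      x <- rnorm(sample(32:256, 1))
      h <- spectral_entropy(x, 8)
      expect_equal(h, oracle_entropy(x, 8), tolerance = 1e-9)
      expect_gte(h, 0)
      expect_lte(h, log2(8))
    }
  })
  # energy confined to one subframe -> zero entropy
  expect_equal(spectral_entropy(rep(2, 64), 8), 0)
  # equal-amplitude tones centred in each of the 8 subframes -> log2(8)
  t <- 0:63
  x <- rowSums(sapply(seq(2, 30, by = 4), function(j) cos(2 * pi * j * t / 64)))
  expect_equal(spectral_entropy(x, 8), 3, tolerance = 1e-9)
  expect_warning(h0 <- spectral_entropy(rep(0, 64), 8), "zero-energy")
  expect_equal(h0, 0)
  expect_error(spectral_entropy(rnorm(4), 8), "shorter than K")
})

test_that("dominant frequency finds the right bin, breaks ties low, and
           matches brute force", {
  t <- (0:799) / 20                                  # 40 s @ 20 Hz
  expect_equal(dominant_frequency(sin(2 * pi * 0.25 * t), 20, c(0.1, 1)), 0.25)
  # a unit impulse has exactly equal magnitude in every bin: the lowest
  # in-band frequency wins the tie
  imp <- c(1, rep(0, 799))
  expect_equal(dominant_frequency(imp, 20, c(0.1, 1)), 0.1)
  # brute-force argmax oracle on random signals
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- rnorm(200)
      p <- Mod(stats::fft(x))^2
      freqs <- (0:100) * 20 / 200
      sel <- freqs >= 0.5 & freqs <= 9
      expect_equal(dominant_frequency(x, 20, c(0.5, 9)),
                   freqs[sel][which.max(p[1:101][sel])])
    }
  })
  expect_error(dominant_frequency(rnorm(100), 20, c(0.1, 15)), "rate/2")
  expect_error(dominant_frequency(rnorm(10), 20, c(0.01, 0.05)), "no spectral bins")
})

test_that("the 64-feature descriptor is complete, deterministic and ordered", {
  tab <- noisy_table()
  man <- feature_manifest()
  expect_length(man$names, 64L)
  expect_equal(ncol(tab), 68L)                       # 4 metadata + 64 features
  # 49 time + 1 correlation + 14 frequency
  expect_length(grep("_(mean|sd|p10|p25|p50|p75|p90)$", man$names), 49L)
  expect_length(grep("^corr_", man$names), 1L)
  expect_length(grep("_(energy|entropy|domfreq)$", man$names), 14L)

  prof <- subject_profiles(1, seed = 1)
  rec <- generate_recording(prof[1, ], "MB", 10, 20, seed = 3)
  w <- segment(rec, 5)
  expect_identical(extract_features(w[[1]]), extract_features(w[[1]]))

  # constant channel: all its percentile features equal its mean
  w1 <- w[[1]]
  w1$channels$vent <- rep(2.5, nrow(w1$channels))
  fv <- extract_features(w1)
  expect_equal(unname(fv[paste0("vent_", c("p10", "p25", "p50", "p75", "p90"))]),
               rep(unname(fv["vent_mean"]), 5))

  w2 <- w[[1]]
  w2$channels$hip_y[3] <- NaN
  expect_error(extract_features(w2), "hip_y")
})

test_that("percentile features are monotone within every window", {
  tab <- noisy_table()
  for (ch in channel_names()) {
    q <- as.matrix(tab[, paste0(ch, "_", c("p10", "p25", "p50", "p75", "p90"))])
    expect_true(all(diff(t(q)) >= 0))
  }
})

test_that("min-max normalisation maps training to [0,1], clips test data,
           and is idempotent on normalised data", {
  st <- fit_normalization(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.numeric(apply_normalization(st, matrix(c(2, 4, 6)))),
               c(0, 0.5, 1))
  expect_equal(as.numeric(apply_normalization(st, matrix(8))), 1)   # clipped
  expect_equal(as.numeric(apply_normalization(st, matrix(-1))), 0)

  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  st2 <- fit_normalization(x)
  xn <- apply_normalization(st2, x)
  expect_true(all(xn >= 0 & xn <= 1))
  st3 <- fit_normalization(xn)
  expect_equal(apply_normalization(st3, xn), xn, tolerance = 1e-12)

  xc <- cbind(x, const = 7)
  expect_warning(st4 <- fit_normalization(xc), "constant")
  expect_true(all(apply_normalization(st4, xc)[, "const"] == 0))
})

test_that("feature subsampling is seeded, sized by rounding, and exhaustive
           at fraction 1", {
  expect_equal(subsample_features(64, 1.0, seed = 1), 1:64)
  expect_length(subsample_features(64, 0.7, seed = 5), 45L)  # round(44.8)
  expect_identical(subsample_features(64, 0.7, seed = 5),
                   subsample_features(64, 0.7, seed = 5))
  s1 <- subsample_features(64, 0.7, seed = 5)
  expect_true(all(s1 >= 1 & s1 <= 64) && !anyDuplicated(s1))
  expect_error(subsample_features(64, 0, seed = 1), "fraction")
})
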