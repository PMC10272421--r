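test_that("NaN cleaning replaces missing samples by the channel mean", {
  raw <- raw_recording(rbind(c(1, NaN, 3), c(4, 5, 6)), fs = 10)
  out <- clean_nans(raw)
  expect_equal(out$data[1, ], c(1, 2, 3))
  expect_equal(out$data[2, ], c(4, 5, 6))

  # identity on clean input, bitwise
  raw2 <- raw_recording(matrix(rnorm(20), 2), fs = 10)
  expect_identical(clean_nans(raw2), raw2)

  # an all-NaN channel is an error naming the channel
  raw3 <- raw_recording(rbind(c(NaN, NaN), c(1, 2)), fs = 10,
                        channel_names = c("C3", "C4"))
  expect_error(clean_nans(raw3), "C3")
})

test_that("bandpass passes in-band tones and attenuates out-of-band tones", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  trim <- seq(fs, length(t) - fs)  # discard filter edges

  tone <- function(f) raw_recording(matrix(sin(2 * pi * f * t), 1), fs)
  out10 <- bandpass(tone(10))$data[1, ]
  expect_lt(abs(rms(out10[trim]) / rms(sin(2 * pi * 10 * t[trim])) - 1), 0.05)

  out60 <- bandpass(tone(60))$data[1, ]
  atten_db <- 20 * log10(rms(sin(2 * pi * 60 * t[trim])) / rms(out60[trim]))
  expect_gt(atten_db, 20)

  # linearity: zero in, zero out
  z <- bandpass(raw_recording(matrix(0, 1, 1000), fs))
  expect_equal(z$data, matrix(0, 1, 1000))

  expect_error(bandpass(tone(10), high = 130), "Nyquist")
})

test_that("z-score standardization is a per-channel affine map", {
  st <- structure(list(mu = c(1, 0), sigma = c(1, 2), source = "train"),
                  class = "norm_stats")
  X <- rbind(c(0, 2), c(0, 2))
  expect_equal(standardize(X, st)[1, ], c(-1, 1))
  expect_equal(standardize(X, st)[2, ], c(0, 1))

  # channel equal to its mean everywhere -> zeros
  Xc <- matrix(1, 1, 5)
  stc <- structure(list(mu = 1, sigma = 2, source = "s"), class = "norm_stats")
  expect_equal(standardize(Xc, stc), matrix(0, 1, 5))

  # variance divisor switch
  expect_equal(standardize(X, st, divisor = "var")[2, ], c(0, 0.5))

  # training stats applied to held-out data: finite, order-preserving
  held <- matrix(sort(rnorm(10)), 1)
  sth <- structure(list(mu = 0.3, sigma = 1.7, source = "s"),
                   class = "norm_stats")
  out <- standardize(held, sth)
  expect_true(all(is.finite(out)))
  expect_false(is.unsorted(out[1, ]))

  expect_error(norm_stats(matrix(1, 2, 5)), "standard deviation")
})

test_that("epoching cuts index-exact fixed windows from the cue onsets", {
  fs <- 250
  sig <- matrix(seq_len(3 * fs * 10), 3, byrow = FALSE)  # distinguishable samples
  raw <- raw_recording(matrix(rnorm(2 * 3000), 2), fs = fs,
                       cue_onsets = c(10, 800), labels = c(1, 2))
  es <- epoch_trials(raw, 4)
  expect_equal(dim(es$data), c(2L, 2L, 1000L))

  # index-exactness: sample k of trial i equals raw sample cue[i] + k - 1
  for (i in 1:2)
    expect_equal(es$data[i, , ], raw$data[, raw$cue_onsets[i] + 0:999])

  raw100 <- raw_recording(matrix(rnorm(500), 1), fs = 100, cue_onsets = 50,
                          labels = 1)
  expect_equal(dim(epoch_trials(raw100, 4)$data)[3], 400L)

  # zero cues: empty set, no error
  empty <- epoch_trials(raw_recording(matrix(rnorm(100), 1), fs = 10))
  expect_equal(dim(empty$data)[1], 0L)

  # cue too close to the end errors and names the trial
  bad <- raw_recording(matrix(rnorm(1100), 1), fs = 250,
                       cue_onsets = c(10, 500), labels = c(1, 1))
  expect_error(epoch_trials(bad, 4), "2")
})

test_that("the default filter bank has the ten standard bands", {
  spec <- filter_bank_spec()
  expect_length(spec$bands, 10L)
  expect_equal(spec$bands[[1]], c(1, 4))
  expect_equal(spec$bands[[9]], c(32, 35))
  expect_equal(spec$bands[[10]], c(35, 38))
  expect_error(filter_bank_spec(list(c(8, 4))), "low < high")
})

test_that("filter bank isolates tones into their own band", {
  fs <- 250
  t <- seq_len(1000) / fs
  dat <- array(0, c(1, 2, 1000))
  dat[1, 1, ] <- sin(2 * pi * 10 * t)
  dat[1, 2, ] <- sin(2 * pi * 10 * t + 1)
  es <- epoch_set(dat, 1L, fs)
  for (method in c("filtfilt", "fft")) {
    be <- filter_bank(es, filter_bank_spec(), method = method)
    expect_length(be$data, 10L)
    rms_band <- vapply(be$data, function(a) sqrt(mean(a[1, 1, ]^2)), 0)
    expect_equal(which.max(rms_band), 3L)  # 8-12 Hz band
    atten_db <- 20 * log10(rms_band[3] / rms_band[5])  # vs 16-20 Hz
    expect_gt(atten_db, 20)
  }
  # a band above Nyquist errors
  expect_error(filter_bank(es, filter_bank_spec(list(c(100, 130)))), "Nyquist")
})

test_that("single-band filter bank agrees with the broadband filter", {
  fs <- 64
  set.seed(3)
  x <- matrix(rnorm(2 * 256), 2, 256)
  es <- epoch_set(array(x, c(1, 2, 256)), 1L, fs)
  be <- filter_bank(es, filter_bank_spec(list(c(1, 30))), method = "filtfilt")
  raw <- bandpass(raw_recording(x, fs), low = 1, high = 30, order = 5)
  expect_equal(be$data[[1]][1, , ], raw$data, tolerance = 1e-10)
})

test_that("filtering and standardization commute with trial order", {
  es <- small_dataset()
  perm <- rev(seq_len(dim(es$data)[1]))
  es_p <- epochs_subset(es, perm)
  spec <- filter_bank_spec(small_bands())
  be <- filter_bank(es, spec, method = "fft")
  be_p <- filter_bank(es_p, spec, method = "fft")
  expect_equal(be$data[[2]][perm, , ], be_p$data[[2]])

  st <- norm_stats(es)
  z <- standardize(es, st)
  z_p <- standardize(es_p, st)
  expect_equal(z$data[perm, , ], z_p$data)
})

test_that("preprocess_recording chains cleaning, filtering, scaling, epoching", {
  fs <- 250
  set.seed(9)
  d <- matrix(rnorm(3 * 2000), 3, 2000)
  d[2, 100] <- NaN
  raw <- raw_recording(d, fs, cue_onsets = c(100, 500, 900),
                       labels = c(1, 2, 3))
  es <- preprocess_recording(raw, window_seconds = 4)
  expect_equal(dim(es$data), c(3L, 3L, 1000L))
  expect_true(all(is.finite(es$data)))
  expect_equal(es$labels, c(1L, 2L, 3L))
})
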