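# Shared small fixtures, built once per test session.  All synthetic runs in
# the suite use a reduced geometry (8 channels at 64 Hz, 4-s trials) so the
# whole pipeline is exercised quickly; the full-size 22 x 1000 contracts are
# checked where the architecture itself is under test.

small_bands <- function() list(c(4, 8), c(8, 12), c(12, 16), c(16, 22), c(22, 28))

small_config <- function(n_subjects = 1, trials_per_class = 10, snr = 2,
                         shift = 0, seed = 42) {
  synth_config(n_subjects = n_subjects, trials_per_class = trials_per_class,
               sessions = 1, channels = 8, fs = 64, T_seconds = 4,
               class_bands = list(c(6, 10), c(10, 14), c(14, 20), c(20, 26)),
               snr = snr, subject_shift_sd = shift, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

small_dataset <- function() fixture("small_dataset", function() {
  make_dataset(small_config())[[1]]
})

small_band_epochs <- function() fixture("small_band_epochs", function() {
  filter_bank(small_dataset(), filter_bank_spec(small_bands()), method = "fft")
})

small_stack <- function() fixture("small_stack", function() {
  band_filter_stack(small_band_epochs(), m = 4)
})

small_features <- function() fixture("small_features", function() {
  csp_features(small_band_epochs(), small_stack())
})

small_ssf <- function() fixture("small_ssf", function() {
  sel <- lasso_select(small_features(), small_dataset()$labels, lambda = 0.02)
  sparse_spatial_filter(sel, small_stack())
})

# a hand-built sparse filter whose columns are unit vectors and whose single
# band spans the whole spectrum: projection (given prefiltered data) is plain
# channel selection
identity_ssf <- function(channels, pick) {
  W <- diag(channels)[, pick, drop = FALSE]
  structure(list(W = W,
                 provenance = data.frame(band = 1L, class = 1L,
                                         eig = seq_along(pick)),
                 band_of_column = rep(1L, length(pick)),
                 selected = seq_along(pick),
                 spec = filter_bank_spec(list(c(1, 30)))),
            class = "sparse_spatial_filter")
}

# mean periodogram over trials and channels (frequency, power)
mean_psd <- function(data3, fs) {
  n <- dim(data3)[1L]; C <- dim(data3)[2L]; T <- dim(data3)[3L]
  acc <- 0
  for (i in seq_len(n)) {
    ft <- stats::mvfft(t(data3[i, , , drop = TRUE]))
    acc <- acc + rowMeans(abs(ft)^2)
  }
  f <- (seq_len(T) - 1) / T * fs
  keep <- f > 0 & f <= fs / 2
  list(f = f[keep], p = (acc / n)[keep])
}
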