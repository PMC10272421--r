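#' Continuous multi-channel EEG recording
#'
#' Container for a continuous (not yet epoched) recording: a channels x
#' samples matrix in microvolts, the sampling rate, ordered channel labels,
#' the cue onsets (sample indices, 1-based) and the per-trial class labels.
#'
#' @param data channels x samples numeric matrix
#' @param fs sampling rate in Hz
#' @param channel_names ordered channel labels; defaults to `ch1..chC`
#' @param cue_onsets strictly increasing 1-based sample indices of cue events
#' @param labels per-trial class labels in `1:4` (one per cue)
#' @return an object of class `raw_recording`
#' @export
raw_recording <- function(data, fs, channel_names = NULL,
                          cue_onsets = integer(), labels = integer()) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names must have one entry per data row")
  cue_onsets <- as.integer(cue_onsets)
  if (is.unsorted(cue_onsets, strictly = TRUE))
    stop("cue_onsets must be strictly increasing")
  if (length(labels) && length(labels) != length(cue_onsets))
    stop("labels must have one entry per cue onset")
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 cue_onsets = cue_onsets, labels = as.integer(labels)),
            class = "raw_recording")
}

#' @exportS3Method base::print
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d cues\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$cue_onsets)))
  invisible(x)
}

#' Replace NaN samples by the channel mean
#'
#' Missing samples (`NaN`/`NA`) are replaced by the mean of the remaining
#' samples of the same channel. A channel with no valid sample at all is an
#' error, reported by name.
#'
#' @param raw a [raw_recording()]
#' @return the cleaned recording (identical if no NaN present)
#' @export
clean_nans <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  bad <- is.na(raw$data)
  if (!any(bad)) return(raw)
  for (ch in which(rowSums(bad) > 0L)) {
    ok <- !bad[ch, ]
    if (!any(ok))
      stop(sprintf("channel '%s' contains no valid samples", raw$channel_names[ch]))
    raw$data[ch, !ok] <- mean(raw$data[ch, ok])
  }
  raw
}

#' Butterworth bandpass filter
#'
#' Applies an order-`order` Butterworth bandpass (default 1-38 Hz, the
#' motor-imagery band). By default the filter is applied zero-phase
#' (forward-backward, doubling the effective order); set `zero_phase =
#' FALSE` for a causal single pass.
#'
#' @param raw a [raw_recording()]
#' @param low,high band edges in Hz; requires `0 < low < high < fs/2`
#' @param order filter order (default 5)
#' @param zero_phase forward-backward application (default `TRUE`)
#' @return the filtered recording, metadata preserved
#' @export
bandpass <- function(raw, low = 1, high = 38, order = 5, zero_phase = TRUE) {
  stopifnot(inherits(raw, "raw_recording"))
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= raw$fs / 2)
    stop(sprintf("high edge %g Hz is at or above Nyquist (%g Hz)", high, raw$fs / 2))
  bf <- signal::butter(order, c(low, high) / (raw$fs / 2), type = "pass")
  app <- if (zero_phase) function(x) signal::filtfilt(bf, x)
         else function(x) as.numeric(signal::filter(bf, x))
  raw$data <- t(apply(raw$data, 1L, app))
  raw
}

#' Per-channel normalization statistics
#'
#' Computes the per-channel mean and standard deviation used by
#' [standardize()]. Statistics must come from the training split only; the
#' `source` tag records where they were computed.
#'
#' @param x a [raw_recording()], an [epoch_set()] or a channels x samples matrix
#' @param source identifier of the split the statistics come from
#' @return object of class `norm_stats` with fields `mu`, `sigma`, `source`
#' @export
norm_stats <- function(x, source = "training") {
  m <- if (inherits(x, "raw_recording")) {
    x$data
  } else if (inherits(x, "epoch_set")) {
    # pool all trials and time points per channel
    matrix(aperm(x$data, c(2L, 1L, 3L)), nrow = dim(x$data)[2L])
  } else {
    as.matrix(x)
  }
  mu <- rowMeans(m)
  sigma <- apply(m, 1L, stats::sd)
  if (any(sigma <= 0 | !is.finite(sigma)))
    stop("zero or non-finite channel standard deviation; cannot standardize")
  structure(list(mu = mu, sigma = sigma, source = source), class = "norm_stats")
}

#' Z-score standardization against training statistics
#'
#' `X' = (X - mu) / sigma` per channel. The printed form of the
#' normalization divides by the variance; z-score semantics divide by the
#' standard deviation, which is the default here. `divisor = "var"` gives
#' the literal variance denominator.
#'
#' @param x a [raw_recording()], [epoch_set()] or channels x samples matrix
#' @param stats a [norm_stats()] computed on the training split
#' @param divisor `"std"` (default) or `"var"`
#' @return `x` standardized, same type as the input
#' @export
standardize <- function(x, stats, divisor = c("std", "var")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(stats, "norm_stats"))
  den <- if (divisor == "std") stats$sigma else stats$sigma^2
  if (any(den <= 0)) stop("non-positive denominator in normalization stats")
  if (inherits(x, "raw_recording")) {
    x$data <- (x$data - stats$mu) / den
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    d <- x$data
    for (ch in seq_len(dim(d)[2L])) d[, ch, ] <- (d[, ch, ] - stats$mu[ch]) / den[ch]
    x$data <- d
    return(x)
  }
  (as.matrix(x) - stats$mu) / den
}

#' Labeled trial set
#'
#' Trials x channels x samples array with labels and acquisition metadata.
#' `subject`, `session` and `synthetic` are per-trial vectors (scalars are
#' recycled), so sets can be pooled across subjects while keeping the
#' provenance needed for leakage audits.
#'
#' @param data trials x channels x samples array
#' @param labels per-trial class labels in `1:4`
#' @param fs sampling rate (Hz)
#' @param subject subject identifier(s)
#' @param session session identifier(s)
#' @param channel_names optional channel labels
#' @param synthetic logical: generated (not recorded) trials
#' @return object of class `epoch_set`
#' @export
epoch_set <- function(data, labels, fs, subject = "S1", session = 1L,
                      channel_names = NULL, synthetic = FALSE) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[1L]
  if (length(labels) != n) stop("trial count must equal label count")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  structure(list(data = data, labels = as.integer(labels), fs = fs,
                 subject = rep_len(as.character(subject), n),
                 session = rep_len(as.integer(session), n),
                 synthetic = rep_len(as.logical(synthetic), n),
                 channel_names = channel_names),
            class = "epoch_set")
}

#' @exportS3Method base::print
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%d subject(s)%s)\n",
              d[1L], d[2L], d[3L], x$fs, length(unique(x$subject)),
              if (any(x$synthetic)) sprintf(", %d synthetic", sum(x$synthetic)) else ""))
  invisible(x)
}

n_trials <- function(es) dim(es$data)[1L]

#' Subset trials of an epoch set
#' @param es an [epoch_set()]
#' @param idx trial indices
#' @return the reduced [epoch_set()]
#' @export
epochs_subset <- function(es, idx) {
  es$data <- es$data[idx, , , drop = FALSE]
  es$labels <- es$labels[idx]
  es$subject <- es$subject[idx]
  es$session <- es$session[idx]
  es$synthetic <- es$synthetic[idx]
  es
}

#' Concatenate epoch sets (same channels/samples/fs)
#' @param ... epoch sets
#' @return the pooled [epoch_set()]
#' @export
epochs_bind <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "epoch_set"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L)
  base <- xs[[1L]]
  for (x in xs[-1L]) {
    stopifnot(identical(dim(x$data)[-1L], dim(base$data)[-1L]), x$fs == base$fs)
  }
  dat <- do.call(abind3, lapply(xs, `[[`, "data"))
  epoch_set(dat, unlist(lapply(xs, `[[`, "labels")), base$fs,
            subject = unlist(lapply(xs, `[[`, "subject")),
            session = unlist(lapply(xs, `[[`, "session")),
            channel_names = base$channel_names,
            synthetic = unlist(lapply(xs, `[[`, "synthetic")))
}

# bind 3-d arrays along the first axis
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])[-1L]
  n <- sum(vapply(xs, function(x) dim(x)[1L], integer(1L)))
  out <- array(0, c(n, d))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1L]
    if (k) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

#' Cut trials from a continuous recording
#'
#' Extracts a fixed window starting at each cue onset. At 250 Hz a 4-s
#' window gives 1000 samples per trial.
#'
#' @param raw a [raw_recording()] with cue onsets and labels
#' @param window_seconds trial length in seconds (default 4)
#' @param subject,session metadata attached to the resulting trials
#' @return an [epoch_set()]; zero cues give an empty set
#' @export
epoch_trials <- function(raw, window_seconds = 4, subject = "S1", session = 1L) {
  stopifnot(inherits(raw, "raw_recording"))
  w <- round(window_seconds * raw$fs)
  n <- length(raw$cue_onsets)
  bad <- which(raw$cue_onsets + w - 1L > ncol(raw$data))
  if (length(bad))
    stop(sprintf("window of %d samples does not fit for trial(s): %s",
                 w, paste(bad, collapse = ", ")))
  dat <- array(0, c(n, nrow(raw$data), w))
  for (i in seq_len(n))
    dat[i, , ] <- raw$data[, raw$cue_onsets[i] + seq_len(w) - 1L]
  labs <- if (length(raw$labels)) raw$labels else integer(n)
  epoch_set(dat, labs, raw$fs, subject = subject, session = session,
            channel_names = raw$channel_names)
}

#' The default 10-band motor-imagery filter bank
#'
#' 1-4, 4-8, 8-12, 12-16, 16-20, 20-24, 24-28, 28-32, 32-35 and 35-38 Hz.
#' @return list of `c(low, high)` pairs
#' @export
mi_bands <- function() {
  list(c(1, 4), c(4, 8), c(8, 12), c(12, 16), c(16, 20),
       c(20, 24), c(24, 28), c(28, 32), c(32, 35), c(35, 38))
}

#' Filter bank specification
#'
#' @param bands ordered list of `c(low, high)` pairs in Hz; default [mi_bands()]
#' @param order Butterworth order (default 5)
#' @param design filter family tag
#' @return object of class `filter_bank_spec`
#' @export
filter_bank_spec <- function(bands = mi_bands(), order = 5, design = "butterworth") {
  if (!length(bands)) stop("bands must be non-empty")
  for (b in bands) if (!(length(b) == 2L && b[1L] < b[2L]))
    stop("each band must be c(low, high) with low < high")
  structure(list(bands = bands, order = order, design = design),
            class = "filter_bank_spec")
}

# Zero-phase Butterworth band filter applied in the Fourier domain: the
# squared magnitude response of the analog prototype multiplies the
# spectrum.  The operator is linear and self-adjoint, which makes it usable
# inside gradient-based training (backprop reapplies the same filter).
fft_bandpass_mat <- function(x, low, high, fs, order = 5) {
  T <- ncol(x)
  f <- (seq_len(T) - 1) / T * fs
  f <- pmin(f, fs - f)
  w2 <- (2 * pi * f)^2
  w0sq <- (2 * pi * low) * (2 * pi * high)
  bw <- 2 * pi * (high - low)
  h <- numeric(T)
  nz <- f > 0
  r <- (w2[nz] - w0sq) / (sqrt(w2[nz]) * bw)
  h[nz] <- 1 / (1 + r^(2 * order))
  ft <- t(stats::mvfft(t(x)))
  Re(t(stats::mvfft(t(ft * rep(h, each = nrow(x))), inverse = TRUE))) / T
}

# h must hit even powers only; guard odd orders by squaring the ratio first
fft_band_gain <- function(f, low, high, fs, order = 5) {
  f <- pmin(f, fs - f)
  w2 <- (2 * pi * f)^2
  w0sq <- (2 * pi * low) * (2 * pi * high)
  bw <- 2 * pi * (high - low)
  h <- numeric(length(f))
  nz <- f > 0
  r2 <- ((w2[nz] - w0sq) / (sqrt(w2[nz]) * bw))^2
  h[nz] <- 1 / (1 + r2^order)
  h
}

#' Band-decomposed trials
#'
#' Filters every trial through every band of the spec. `method =
#' "filtfilt"` (default) designs a digital Butterworth filter per band and
#' applies it forward-backward; `method = "fft"` applies the zero-phase
#' Butterworth magnitude response in the Fourier domain (the linear operator
#' also used inside GAN training).
#'
#' @param epochs an [epoch_set()]
#' @param spec a [filter_bank_spec()]
#' @param method `"filtfilt"` or `"fft"`
#' @return object of class `band_epochs`: list of per-band trial arrays
#' @export
filter_bank <- function(epochs, spec = filter_bank_spec(),
                        method = c("filtfilt", "fft")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "filter_bank_spec"))
  for (b in spec$bands)
    if (b[2L] >= epochs$fs / 2)
      stop(sprintf("band %g-%g Hz is at or above Nyquist (%g Hz)",
                   b[1L], b[2L], epochs$fs / 2))
  n <- n_trials(epochs)
  out <- vector("list", length(spec$bands))
  for (bi in seq_along(spec$bands)) {
    b <- spec$bands[[bi]]
    arr <- array(0, dim(epochs$data))
    if (method == "filtfilt") {
      bf <- signal::butter(spec$order, b / (epochs$fs / 2), type = "pass")
      for (i in seq_len(n))
        arr[i, , ] <- t(apply(epochs$data[i, , , drop = TRUE], 1L,
                              function(x) signal::filtfilt(bf, x)))
    } else {
      for (i in seq_len(n))
        arr[i, , ] <- fft_bandpass_mat(epochs$data[i, , , drop = TRUE],
                                       b[1L], b[2L], epochs$fs, spec$order)
    }
    out[[bi]] <- arr
  }
  structure(list(data = out, spec = spec, labels = epochs$labels,
                 fs = epochs$fs), class = "band_epochs")
}

#' @exportS3Method base::print
print.band_epochs <- function(x, ...) {
  cat(sprintf("<band_epochs> %d bands x %d trials\n",
              length(x$data), dim(x$data[[1L]])[1L]))
  invisible(x)
}

#' One-call preprocessing of a continuous recording
#'
#' NaN cleaning, 1-38 Hz bandpass, z-score standardization against the
#' provided (or freshly computed) training statistics, and epoching.
#'
#' @param raw a [raw_recording()]
#' @param stats optional [norm_stats()]; computed from `raw` when missing
#' @param low,high,order broadband filter settings
#' @param window_seconds trial window
#' @param subject,session metadata
#' @return an [epoch_set()]
#' @export
preprocess_recording <- function(raw, stats = NULL, low = 1, high = 38,
                                 order = 5, window_seconds = 4,
                                 subject = "S1", session = 1L) {
  raw <- clean_nans(raw)
  raw <- bandpass(raw, low, high, order)
  if (is.null(stats)) stats <- norm_stats(raw)
  raw <- standardize(raw, stats)
  epoch_trials(raw, window_seconds, subject = subject, session = session)
}
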