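#' Synthetic motor-imagery EEG configuration
#'
#' Describes a multi-subject, multi-class synthetic dataset with the
#' statistical structure the pipeline assumes: each class is a narrowband
#' rhythm (band-limited noise) with a class-specific unit-norm spatial
#' pattern over the electrodes, superimposed on 1/f (pink) background plus
#' white sensor noise. Per-subject perturbation of the patterns and sensor
#' gains creates the cross-subject gap that subject-independent decoding
#' addresses. Defaults mirror the reference recording setting: 9 subjects,
#' 2 sessions of 72 trials per class (288 per session), 22 channels at
#' 250 Hz, 4-s trials, with rhythms in the 8-12 and 16-24 Hz ranges over
#' four distinct sensor neighbourhoods.
#'
#' @param n_subjects number of subjects
#' @param trials_per_class trials per class per session
#' @param sessions sessions per subject
#' @param channels,fs,T_seconds trial geometry
#' @param class_bands list of `c(low, high)` Hz per class
#' @param class_patterns optional channels x classes matrix of unit spatial
#'   patterns; default four smooth bumps over distinct neighbourhoods
#' @param snr ratio of rhythm power to background power
#' @param subject_shift_sd scale of the per-subject pattern perturbation
#'   and log sensor gain
#' @param seed master seed; the dataset is a pure function of the config
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_subjects = 9, trials_per_class = 72, sessions = 2,
                         channels = 22, fs = 250, T_seconds = 4,
                         class_bands = list(c(8, 12), c(8, 12),
                                            c(16, 24), c(16, 24)),
                         class_patterns = NULL, snr = 1,
                         subject_shift_sd = 0.1, seed = 1L) {
  stopifnot(snr > 0)
  K <- length(class_bands)
  for (b in class_bands)
    if (b[2L] >= fs / 2) stop("class band above Nyquist")
  if (is.null(class_patterns)) {
    centers <- round(channels * c(0.36, 0.55, 0.45, 0.15))
    centers <- pmin(pmax(centers, 1L), channels)
    class_patterns <- vapply(seq_len(K), function(k) {
      p <- exp(-((seq_len(channels) - centers[(k - 1L) %% 4L + 1L])^2) / (2 * 1.5^2))
      p / sqrt(sum(p^2))
    }, numeric(channels))
  }
  # distinct (band, pattern) pairs per class
  key <- vapply(seq_len(K), function(k)
    paste(c(class_bands[[k]], round(class_patterns[, k], 6)), collapse = ","), "")
  if (anyDuplicated(key)) stop("classes must differ in their (band, pattern) pair")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 sessions = as.integer(sessions),
                 channels = as.integer(channels), fs = fs,
                 T_seconds = T_seconds, class_bands = class_bands,
                 class_patterns = class_patterns, snr = snr,
                 subject_shift_sd = subject_shift_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited unit-variance noise, length T (columns of n signals)
narrowband_noise <- function(n, T, low, high, fs) {
  x <- matrix(stats::rnorm(n * T), n, T)
  x <- fft_bandpass_mat(x, low, high, fs, order = 4)
  sw <- apply(x, 1L, stats::sd)
  x / pmax(sw, 1e-12)
}

# pink (1/f) noise rows, approximately unit variance
pink_noise <- function(n, T, fs) {
  w <- matrix(stats::rnorm(n * T), n, T)
  f <- (seq_len(T) - 1) / T * fs
  f <- pmin(f, fs - f)
  g <- 1 / sqrt(pmax(f, 1))
  ft <- t(stats::mvfft(t(w))) * rep(g, each = n)
  x <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / T
  sw <- apply(x, 1L, stats::sd)
  x / pmax(sw, 1e-12)
}

#' Generate a synthetic multi-subject dataset
#'
#' Each trial is `a_k s_k(t) + noise`: the class rhythm `s_k` is narrowband
#' noise in the class band, its spatial pattern is the class pattern
#' perturbed per subject, and the background is pink plus white sensor
#' noise scaled so that mean rhythm power over channels equals `snr` times
#' the background power. Deterministic in `config$seed`.
#'
#' @param config a [synth_config()]
#' @return list of [epoch_set()]s, one per subject (sessions concatenated,
#'   balanced labels)
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  C <- config$channels
  T <- round(config$T_seconds * config$fs)
  K <- length(config$class_bands)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    patterns <- config$class_patterns
    if (config$subject_shift_sd > 0) {
      for (k in seq_len(K)) {
        p <- patterns[, k] + config$subject_shift_sd * stats::rnorm(C)
        patterns[, k] <- p / sqrt(sum(p^2))
      }
    }
    gains <- exp(config$subject_shift_sd * stats::rnorm(C))
    n_sess <- config$trials_per_class * K
    n_tot <- n_sess * config$sessions
    dat <- array(0, c(n_tot, C, T))
    labels <- integer(n_tot)
    sess <- integer(n_tot)
    i <- 0L
    for (se in seq_len(config$sessions)) {
      labs <- rep(seq_len(K), config$trials_per_class)
      for (tr in seq_along(labs)) {
        k <- labs[tr]
        bnd <- config$class_bands[[k]]
        src <- narrowband_noise(1L, T, bnd[1L], bnd[2L], config$fs)[1L, ]
        bg <- pink_noise(C, T, config$fs) + 0.3 * matrix(stats::rnorm(C * T), C, T)
        bg_pow <- mean(bg^2)
        amp <- sqrt(config$snr * C * bg_pow)
        X <- amp * (patterns[, k] %o% src) + bg
        X <- X * gains
        i <- i + 1L
        dat[i, , ] <- X
        labels[i] <- k
        sess[i] <- se
      }
    }
    out[[s]] <- epoch_set(dat, labels, config$fs,
                          subject = sprintf("A%d", s), session = sess,
                          channel_names = if (C == 22) bci2a_channels()
                                          else paste0("ch", seq_len(C)))
  }
  out
}

#' Standard 22-electrode montage labels
#'
#' Channel names of the 22-electrode motor-cortex-centred montage used by
#' the reference four-class motor-imagery recordings (C3 is electrode 8,
#' Cz 10, C4 12).
#' @return character vector of length 22
#' @export
bci2a_channels <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1", "Cz",
    "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz",
    "P2", "POz")
}

#' Zero-mean trials with a planted channel covariance
#'
#' Draws Gaussian trials whose expected channel covariance equals `Sigma`
#' (independent across time), the fixture used to test whether generated
#' data reproduces spatial structure.
#'
#' @param n_trials number of trials
#' @param Sigma symmetric positive-definite channels x channels covariance
#' @param T samples per trial
#' @param fs sampling rate
#' @param seed seed
#' @param class_label,subject metadata
#' @return an [epoch_set()]
#' @export
planted_covariance_class <- function(n_trials, Sigma, T = 250, fs = 250,
                                     seed = 1L, class_label = 1L,
                                     subject = "S1") {
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(Sigma, tol = 1e-8)) stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  C <- nrow(Sigma)
  L <- t(chol(Sigma))
  set.seed(seed)
  dat <- array(0, c(n_trials, C, T))
  for (i in seq_len(n_trials))
    dat[i, , ] <- L %*% matrix(stats::rnorm(C * T), C, T)
  epoch_set(dat, rep(as.integer(class_label), n_trials), fs, subject = subject)
}
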