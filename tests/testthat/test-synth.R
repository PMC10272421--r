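test_that("synthetic datasets have the configured geometry and are deterministic", {
  cfg <- small_config(n_subjects = 2, trials_per_class = 3)
  ds <- make_dataset(cfg)
  expect_length(ds, 2L)
  expect_equal(dim(ds[[1]]$data), c(12L, 8L, 256L))
  expect_equal(sort(unique(ds[[1]]$labels)), 1:4)
  expect_equal(as.vector(table(ds[[1]]$labels)), rep(3L, 4))
  ds2 <- make_dataset(cfg)
  expect_identical(ds, ds2)

  cfg250 <- synth_config(n_subjects = 1, trials_per_class = 1, sessions = 1,
                         seed = 2)
  ds250 <- make_dataset(cfg250)
  expect_equal(dim(ds250[[1]]$data)[-1], c(22L, 1000L))
  expect_equal(ds250[[1]]$channel_names[c(8, 10, 12)], c("C3", "Cz", "C4"))

  expect_error(synth_config(class_bands = list(c(8, 12), c(8, 200),
                                               c(16, 24), c(20, 26))),
               "Nyquist")
  expect_error(synth_config(class_bands = list(c(8, 12), c(8, 12)),
                            class_patterns = cbind(c(1, rep(0, 21)),
                                                   c(1, rep(0, 21)))),
               "differ")
})

test_that("class rhythms land in their configured bands", {
  ds <- small_dataset()  # snr = 2
  cfg <- small_config()
  for (k in 1:4) {
    psd <- mean_psd(ds$data[ds$labels == k, , , drop = FALSE], ds$fs)
    band <- cfg$class_bands[[k]]
    # strongest band-average power in the class band, compared against
    # equally wide neighbours
    inband <- mean(psd$p[psd$f >= band[1] & psd$f <= band[2]])
    below <- mean(psd$p[psd$f >= band[1] - 4 & psd$f < band[1] - 1])
    above <- mean(psd$p[psd$f > band[2] + 1 & psd$f <= band[2] + 4])
    expect_gt(inband, below)
    expect_gt(inband, above)
  }
})

test_that("vanishing snr removes class-discriminative band power", {
  cfg0 <- small_config(snr = 1e-8, seed = 17)
  ds0 <- make_dataset(cfg0)[[1]]
  band <- small_config()$class_bands[[1]]
  bp <- function(i) {
    x <- eegmi:::fft_bandpass_mat(ds0$data[i, , ], band[1], band[2], ds0$fs)
    mean(x^2)
  }
  pw <- vapply(seq_len(dim(ds0$data)[1]), bp, 0)
  p <- stats::wilcox.test(pw[ds0$labels == 1], pw[ds0$labels != 1])$p.value
  expect_gt(p, 0.01)
})

test_that("front-end pipeline recovers classes from high-snr data", {
  # OVR-CSP + LASSO features followed by a linear classifier separate the
  # four classes almost perfectly when patterns are subject-invariant
  accs <- vapply(1:3, function(seed) {
    cfg <- small_config(n_subjects = 1, trials_per_class = 15, snr = 4,
                        shift = 0, seed = 100 + seed)
    es <- make_dataset(cfg)[[1]]
    be <- filter_bank(es, filter_bank_spec(small_bands()), method = "fft")
    stack <- band_filter_stack(be, m = 2)
    fm <- csp_features(be, stack)
    sel <- lasso_select(fm, es$labels, lambda = 0.02)
    X <- fm$F[, sel$selected, drop = FALSE]
    fit <- MASS::lda(X, grouping = factor(es$labels))
    mean(stats::predict(fit, X)$class == factor(es$labels)) * 100
  }, 0)
  expect_gt(mean(accs), 95)
})

test_that("subject perturbation opens a cross-subject generalization gap", {
  cfg <- small_config(n_subjects = 3, trials_per_class = 15, snr = 2,
                      shift = 0.4, seed = 33)
  ds <- make_dataset(cfg)
  pooled <- epochs_bind(ds[1:2])
  # stratified half split over (class, subject) cells
  fit_idx <- sort(unlist(lapply(
    split(seq_len(dim(pooled$data)[1]),
          paste(pooled$labels, pooled$subject)),
    function(ix) ix[seq(1, length(ix), by = 2)])))
  train <- epochs_subset(pooled, fit_idx)
  heldout_seen <- epochs_subset(pooled, setdiff(seq_len(dim(pooled$data)[1]), fit_idx))
  test_new <- ds[[3]]
  be_tr <- filter_bank(train, filter_bank_spec(small_bands()), method = "fft")
  stack <- band_filter_stack(be_tr, m = 2)
  fm_tr <- csp_features(be_tr, stack)
  sel <- lasso_select(fm_tr, train$labels, lambda = 0.02)
  fit <- MASS::lda(fm_tr$F[, sel$selected, drop = FALSE],
                   grouping = factor(train$labels))
  score <- function(es) {
    be <- filter_bank(es, filter_bank_spec(small_bands()), method = "fft")
    fm <- csp_features(be, stack)
    mean(as.character(stats::predict(fit, fm$F[, sel$selected, drop = FALSE])$class) ==
           as.character(es$labels))
  }
  # held-out trials of seen subjects vs. trials of an unseen subject
  seen <- score(heldout_seen)
  unseen <- score(test_new)
  expect_gt(seen, unseen)
})

test_that("planted-covariance trials have the requested second-order structure", {
  C <- 6
  # white case
  es_w <- planted_covariance_class(300, diag(C), T = 100, fs = 100, seed = 3)
  R <- matrix(0, C, C)
  for (i in 1:300) R <- R + stats::cov(t(es_w$data[i, , ]))
  R <- R / 300
  expect_lt(max(abs(R - diag(C))), 0.05)

  # dominant direction recovered
  v <- c(3, 2, 1, 0, -1, -2); v <- v / sqrt(sum(v^2))
  Sigma <- diag(C) * 0.3 + 5 * v %o% v
  es_d <- planted_covariance_class(500, Sigma, T = 50, fs = 100, seed = 4)
  R2 <- matrix(0, C, C)
  for (i in 1:500) R2 <- R2 + stats::cov(t(es_d$data[i, , ]))
  lead <- eigen(R2 / 500, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(lead * v)), 0.95)

  # determinism and degenerate input
  expect_identical(planted_covariance_class(3, diag(2), seed = 9)$data,
                   planted_covariance_class(3, diag(2), seed = 9)$data)
  expect_error(planted_covariance_class(3, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(planted_covariance_class(3, matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
})
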