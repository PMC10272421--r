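test_that("mean covariance is the trace-normalized class average", {
  # single 2x2 identity trial: X X' = I, trace 2 -> R = I/2
  bt <- array(0, c(2, 2, 2))
  bt[1, , ] <- diag(2)
  bt[2, , ] <- matrix(rnorm(4), 2)
  R <- mean_covariance(bt, c(1, 2), 1)
  expect_equal(R, diag(2) / 2)

  # unit trace for arbitrary input
  set.seed(1)
  bt2 <- array(rnorm(5 * 4 * 50), c(5, 4, 50))
  R2 <- mean_covariance(bt2, rep(1, 5), 1)
  expect_equal(sum(diag(R2)), 1, tolerance = 1e-10)
  expect_equal(R2, t(R2))

  # two identical trials average to the single-trial value
  bt3 <- array(0, c(2, 3, 20))
  X <- matrix(rnorm(60), 3)
  bt3[1, , ] <- X; bt3[2, , ] <- X
  expect_equal(mean_covariance(bt3, c(1, 1), 1),
               mean_covariance(bt3[1, , , drop = FALSE], 1, 1))

  expect_error(mean_covariance(bt3, c(1, 1), 2), "no trials")
})

test_that("CSP sub-filter solves the generalized eigenproblem", {
  # analytic diagonal case
  sf <- csp_subfilter(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)), m = 2)
  expect_equal(sf$eigenvalues, c(4, 0.25), tolerance = 1e-6)
  lead <- sf$W[, 1] / sqrt(sum(sf$W[, 1]^2))
  expect_equal(abs(lead), c(1, 0), tolerance = 1e-6)

  # identical classes: all eigenvalues 1
  set.seed(2)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  sf2 <- csp_subfilter(A, A, m = 3)
  expect_equal(sf2$eigenvalues, rep(1, 3), tolerance = 1e-6)

  expect_error(csp_subfilter(matrix(NaN, 2, 2), diag(2)), "finite")
})

test_that("the leading CSP column maximizes the Rayleigh quotient", {
  # brute-force oracle: no random unit vector beats the leading eigenvector
  set.seed(7)
  C <- 6
  R_c <- crossprod(matrix(rnorm(C * C), C)) / C + diag(C) * 0.1
  R_r <- crossprod(matrix(rnorm(C * C), C)) / C + diag(C) * 0.1
  sf <- csp_subfilter(R_c, R_r, m = 4)
  rq <- function(w) drop(t(w) %*% R_c %*% w / (t(w) %*% R_r %*% w))
  best <- rq(sf$W[, 1])
  V <- matrix(rnorm(C * 1e5), C)
  V <- V / rep(sqrt(colSums(V^2)), each = C)
  rand_best <- max(colSums(V * (R_c %*% V)) / colSums(V * (R_r %*% V)))
  expect_gte(best + 1e-10, rand_best)

  # eigenvalue equals the generalized Rayleigh quotient of its eigenvector
  expect_equal(rq(sf$W[, 2]), sf$eigenvalues[2], tolerance = 1e-6)
})

test_that("the OVR stack has 4 sub-filters x m columns per band", {
  stack <- small_stack()
  expect_equal(ncol(stack$columns), 5L * 4L * 4L)
  expect_equal(nrow(stack$column_index), ncol(stack$columns))
  per_band <- table(stack$column_index$band)
  expect_true(all(per_band == 16L))
  per_class <- table(stack$column_index$class)
  expect_true(all(per_class == 20L))

  # 2 classes, m = 1, 1 band -> 2 columns
  es <- small_dataset()
  es2 <- epochs_subset(es, which(es$labels %in% c(1, 2)))
  be2 <- filter_bank(es2, filter_bank_spec(list(c(8, 12))), method = "fft")
  st2 <- band_filter_stack(be2, m = 1)
  expect_equal(ncol(st2$columns), 2L)

  # an absent class errors
  es1 <- epochs_subset(es, which(es$labels == 1))
  be1 <- filter_bank(es1, filter_bank_spec(list(c(8, 12))), method = "fft")
  expect_error(band_filter_stack(be1), "2 classes")
})

test_that("eigenvalue equals the projected variance ratio on training covariances", {
  be <- small_band_epochs()
  stack <- small_stack()
  bt <- be$data[[2]]
  sf <- stack$subfilters[[2]][[1]]
  R_c <- mean_covariance(bt, be$labels, 1)
  rest <- lapply(2:4, function(cl) mean_covariance(bt, be$labels, cl))
  R_r <- Reduce(`+`, rest) / 3
  w <- sf$W[, 1]
  ratio <- drop(t(w) %*% R_c %*% w / (t(w) %*% R_r %*% w))
  expect_equal(ratio, sf$eigenvalues[1], tolerance = 1e-6)
})

test_that("CSP features are normalized log variances with full provenance", {
  fm <- small_features()
  expect_equal(ncol(fm$F), 80L)  # 4m x 5 bands at m = 4
  expect_equal(nrow(fm$F), 40L)

  # determinism
  fm2 <- csp_features(small_band_epochs(), small_stack())
  expect_identical(fm$F, fm2$F)

  # equal projected variances within a sub-filter give log(1/m) each:
  # identity sub-filter on channels with equal variance
  stack <- structure(list(
    subfilters = list(list(list(W = diag(4), eigenvalues = rep(1, 4), m = 4L,
                                band_index = 1L, target_class = 1L))),
    columns = diag(4),
    column_index = data.frame(band = 1L, class = 1L, eig = 1:4),
    classes = 1L, m = 4L, spec = filter_bank_spec(list(c(1, 30)))),
    class = "band_filter_stack")
  X <- matrix(rnorm(200), 4, 50)
  X <- X / apply(X, 1, stats::sd)
  be <- structure(list(data = list(array(X, c(1, 4, 50))),
                       spec = stack$spec, labels = 1L, fs = 64),
                  class = "band_epochs")
  f <- csp_features(be, stack)
  # rows were scaled to unit sd, so each feature is exactly log(1/4)
  expect_equal(drop(f$F), rep(log(1 / 4), 4), tolerance = 1e-12)
})

test_that("LASSO matches the closed-form soft threshold on an orthogonal design", {
  # columns centered, mutually orthogonal, scaled to unit sample sd:
  # beta_j = S(x_j'y, N*lambda) / (N - 1), intercept = mean(y)
  set.seed(5)
  N <- 40; p <- 5
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(N * p), N))))[, -1, drop = FALSE]
  X <- Q * sqrt(N - 1)
  beta_true <- c(3, -2, 0, 0.5, 0)
  y <- drop(X %*% beta_true) + 0.1 * rnorm(N)
  lambda <- 0.3
  sel <- lasso_select(X, y, lambda = lambda)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  oracle <- soft(drop(crossprod(X, y)), N * lambda) / (N - 1)
  expect_equal(sel$beta, oracle, tolerance = 1e-6)
  expect_equal(sel$beta0, mean(y), tolerance = 1e-6)
  expect_equal(sel$selected, which(oracle != 0))
})

test_that("LASSO selection satisfies shrinkage limits and KKT conditions", {
  fm <- small_features()
  y <- small_dataset()$labels
  # huge lambda: full shrinkage
  sel_inf <- tryCatch(lasso_select(fm, y, lambda = 1e6),
                      error = function(e) NULL)
  expect_true(is.null(sel_inf) || length(sel_inf$selected) == 0L)
  expect_error(lasso_select(fm, y, lambda = -1), "positive")

  # near-zero lambda on an exact linear relation picks the driving feature
  set.seed(8)
  X <- scale(matrix(rnorm(50 * 4), 50))
  yy <- X[, 1]
  sel1 <- lasso_select(X, yy, lambda = 1e-4)
  expect_true(1L %in% sel1$selected)

  # KKT at the solution of a moderate-lambda fit
  lambda <- 0.05
  sel <- lasso_select(fm, y, lambda = lambda)
  Fs <- scale(fm$F)
  r <- as.numeric(y) - sel$beta0 - drop(Fs %*% sel$beta)
  g <- drop(crossprod(Fs, r)) / nrow(Fs)
  tol <- 1e-4
  expect_true(all(abs(g[sel$beta == 0]) <= lambda + tol))
  nz <- sel$beta != 0
  expect_true(all(abs(g[nz] - lambda * sign(sel$beta[nz])) <= tol))
})

test_that("the sparse spatial filter keeps exactly the selected columns", {
  stack <- small_stack()
  ssf <- sparse_spatial_filter(c(1L, 18L), stack)
  expect_equal(ncol(ssf$W), 2L)
  expect_equal(ssf$provenance$band, c(1L, 2L))
  expect_equal(ssf$W, stack$columns[, c(1, 18)])

  all_sel <- sparse_spatial_filter(seq_len(ncol(stack$columns)), stack)
  expect_equal(all_sel$W, stack$columns)

  sel <- lasso_select(small_features(), small_dataset()$labels, lambda = 0.02)
  ssf2 <- sparse_spatial_filter(sel, stack)
  expect_equal(ncol(ssf2$W), length(sel$selected))

  empty <- sel; empty$selected <- integer()
  expect_error(sparse_spatial_filter(empty, stack), "smaller lambda")
})

test_that("sparse-filter projection is a per-band linear map", {
  C <- 8; T <- 256
  ssf_id <- identity_ssf(C, c(2, 5))
  X <- matrix(rnorm(C * T), C, T)
  # with prefiltered data supplied, identity columns pick channels
  Z <- apply_sparse_filter(ssf_id, X, fs = 64, band_filtered = list(X))
  expect_equal(Z, X[c(2, 5), ])

  # shape contract and linearity on a real fitted filter
  ssf <- small_ssf()
  Z1 <- apply_sparse_filter(ssf, X, fs = 64)
  expect_equal(dim(Z1), c(ncol(ssf$W), T))
  Z2 <- apply_sparse_filter(ssf, 2 * X, fs = 64)
  expect_equal(Z2, 2 * Z1, tolerance = 1e-10)

  expect_error(apply_sparse_filter(ssf, X[1:3, ], fs = 64), "channels")
})

test_that("discriminative band dominates the LASSO selection", {
  # two classes that differ only inside 8-12 Hz: at least half of the
  # selected columns must come from that band
  fs <- 64; T <- 256; C <- 8; n <- 24
  set.seed(13)
  pat <- c(1, 2, 1, 0, 0, 0, 0, 0); pat <- pat / sqrt(sum(pat^2))
  dat <- array(0, c(2 * n, C, T))
  labels <- rep(1:2, each = n)
  for (i in seq_len(2 * n)) {
    bg <- matrix(rnorm(C * T), C, T)
    src <- eegmi:::fft_bandpass_mat(matrix(rnorm(T), 1), 8, 12, fs)[1, ]
    src <- src / stats::sd(src)
    amp <- if (labels[i] == 1) 4 else 0
    dat[i, , ] <- amp * pat %o% src + bg
  }
  es <- epoch_set(dat, labels, fs)
  be <- filter_bank(es, filter_bank_spec(small_bands()), method = "fft")
  stack <- band_filter_stack(be, m = 2)
  sel <- lasso_select(csp_features(be, stack), labels, lambda = 0.05)
  ssf <- sparse_spatial_filter(sel, stack)
  expect_gte(mean(ssf$band_of_column == 2L), 0.5)
})
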