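#' Generator architecture specification
#'
#' With the default 22-channel, 1000-sample, 1600-dimensional-noise setting
#' this builds the reference architecture: a fully connected layer to
#' 256,000 units followed by five transposed-convolution layers (batch
#' normalization on the first four, leaky-rectifier activations, slope
#' 0.2), whose kernels and strides land exactly on a (22, 1000) trial. The
#' fully connected output is laid out as 128 feature maps on a 4 x 500
#' (electrode x time) lattice and the per-layer paddings are part of the
#' spec, so the shape trace is checkable layer by layer.
#'
#' Any other `(channels, samples)` (with `samples` divisible by 4) gives a
#' scaled-down generator of the same design (fully connected layer, then
#' transposed convolutions upsampling time by 4) for small-budget training
#' demonstrations.
#'
#' @param noise_dim length of the normally distributed input noise
#' @param channels,samples output trial shape
#' @param fs sampling rate attached to generated trials
#' @param leaky_slope negative-side slope of the leaky rectifier
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(noise_dim = 1600, channels = 22, samples = 1000,
                           fs = 250, leaky_slope = 0.2) {
  full <- (channels == 22 && samples == 1000)
  if (full) {
    arch <- list(
      list(type = "dense", out = 256000L),
      list(type = "reshape", c = 128L, h = 4L, w = 500L),
      list(type = "convt", out = 128L, kh = 15L, kw = 3L, sh = 3L, sw = 1L, ph = 11L, pw = 2L),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 128L, kh = 15L, kw = 3L, sh = 3L, sw = 1L, ph = 4L, pw = 1L),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 64L, kh = 5L, kw = 3L, sh = 2L, sw = 1L, ph = 2L, pw = 0L),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 32L, kh = 5L, kw = 4L, sh = 1L, sw = 2L, ph = 1L, pw = 1L),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 1L, kh = 2L, kw = 1L, sh = 1L, sw = 1L, ph = 0L, pw = 0L))
  } else {
    if (samples %% 4L != 0L)
      stop("scaled generator requires samples divisible by 4")
    s0 <- samples %/% 4L
    arch <- list(
      list(type = "dense", out = 32L * channels * s0),
      list(type = "reshape", c = 32L, h = channels, w = s0),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 16L, kh = 1L, kw = 4L, sh = 1L, sw = 2L, ph = 0L, pw = 1L),
      list(type = "bn"), list(type = "lrelu", slope = leaky_slope),
      list(type = "convt", out = 1L, kh = 1L, kw = 4L, sh = 1L, sw = 2L, ph = 0L, pw = 1L))
  }
  structure(list(noise_dim = as.integer(noise_dim), channels = as.integer(channels),
                 samples = as.integer(samples), fs = fs, arch = arch,
                 full = full, leaky_slope = leaky_slope),
            class = "generator_spec")
}

#' Build a generator network
#'
#' @param spec a [generator_spec()]
#' @param seed weight-initialisation seed
#' @return an `eegmi_net` mapping `(noise_dim)` vectors to `(1, channels,
#'   samples)` trials; an architecture whose layer arithmetic cannot reach
#'   the requested output shape errors with the offending shape trace
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  net <- new_net(spec$arch, c(spec$noise_dim, 1L, 1L), seed)
  os <- net_out_shape(net_ptr(net))
  if (!identical(os, c(1L, spec$channels, spec$samples))) {
    tr <- net_shape_trace(net_ptr(net))
    stop(sprintf("generator layers end at (%s), expected (1,%d,%d); trace: %s",
                 paste(os, collapse = ","), spec$channels, spec$samples,
                 paste(vapply(tr, function(s) paste(s, collapse = "x"), ""),
                       collapse = " -> ")))
  }
  net$role <- "generator"
  net$spec <- spec
  net
}

#' Discriminator architecture specification
#'
#' `kind = "raw"` consumes whole `(channels, samples)` trials; `kind =
#' "fb"` consumes the `(n_sel, samples)` sparsely spatially filtered trials
#' ("FB data"). In the reference 22 x 1000 setting the layer roster follows
#' the published table: for the raw kind a temporal 1 x 23 convolution, a
#' full-height spatial 22 x 1 convolution, temporal convolutions and
#' poolings down to a 750-unit fully connected scalar score. For the fb
#' kind the spatial reduction is a stride-(4,1) convolution followed by a
#' row-collapsing convolution whose kernel height `Var = floor(n_sel / 4)`
#' adapts to the LASSO-selected dimensionality. Other shapes give a scaled
#' analogue of the same design.
#'
#' @param kind `"raw"` or `"fb"`
#' @param n_sel number of sparse-filter columns (fb kind; must be >= 4)
#' @param channels,samples trial shape judged by the raw kind
#' @param leaky_slope activation slope
#' @return object of class `discriminator_spec`
#' @export
discriminator_spec <- function(kind = c("raw", "fb"), n_sel = NULL,
                               channels = 22, samples = 1000,
                               leaky_slope = 0.2) {
  kind <- match.arg(kind)
  full <- (channels == 22 && samples == 1000)
  if (kind == "fb") {
    if (is.null(n_sel)) stop("fb discriminator needs n_sel")
    if (n_sel < 4) stop("fb discriminator requires n_sel >= 4")
    var_k <- n_sel %/% 4L
    height <- as.integer(n_sel)
  } else {
    height <- as.integer(channels)
  }
  sl <- leaky_slope
  if (full) {
    arch <- if (kind == "raw") list(
      list(type = "conv", out = 10L, kh = 1L, kw = 23L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 30L, kh = 22L, kw = 1L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 30L, kh = 1L, kw = 17L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 6L, sh = 1L, sw = 6L),
      list(type = "conv", out = 30L, kh = 1L, kw = 7L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 6L, sh = 1L, sw = 6L),
      list(type = "flatten"), list(type = "dense", out = 1L))
    else list(
      list(type = "conv", out = 10L, kh = 1L, kw = 23L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 30L, kh = 4L, kw = 1L, sh = 4L, sw = 1L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 30L, kh = var_k, kw = 1L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 30L, kh = 1L, kw = 17L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 6L, sh = 1L, sw = 6L),
      list(type = "conv", out = 30L, kh = 1L, kw = 7L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 6L, sh = 1L, sw = 6L),
      list(type = "flatten"), list(type = "dense", out = 1L))
  } else {
    arch <- if (kind == "raw") list(
      list(type = "conv", out = 8L, kh = 1L, kw = 9L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 16L, kh = height, kw = 1L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 4L, sh = 1L, sw = 4L),
      list(type = "conv", out = 16L, kh = 1L, kw = 5L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 4L, sh = 1L, sw = 4L),
      list(type = "flatten"), list(type = "dense", out = 1L))
    else list(
      list(type = "conv", out = 8L, kh = 1L, kw = 9L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 16L, kh = 4L, kw = 1L, sh = 4L, sw = 1L), list(type = "lrelu", slope = sl),
      list(type = "conv", out = 16L, kh = var_k, kw = 1L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 4L, sh = 1L, sw = 4L),
      list(type = "conv", out = 16L, kh = 1L, kw = 5L), list(type = "lrelu", slope = sl),
      list(type = "maxpool", kh = 1L, kw = 4L, sh = 1L, sw = 4L),
      list(type = "flatten"), list(type = "dense", out = 1L))
  }
  structure(list(kind = kind, n_sel = if (kind == "fb") as.integer(n_sel) else NULL,
                 var_kernel = if (kind == "fb") as.integer(n_sel %/% 4L) else NULL,
                 channels = as.integer(channels), samples = as.integer(samples),
                 height = height, arch = arch, full = full),
            class = "discriminator_spec")
}

#' Build a discriminator network
#'
#' @param spec a [discriminator_spec()] (or `kind` string, forwarded)
#' @param seed weight-initialisation seed
#' @param ... forwarded to [discriminator_spec()] when `spec` is a string
#' @return an `eegmi_net` mapping `(1, height, samples)` inputs to a single
#'   score per input
#' @export
build_discriminator <- function(spec = "raw", seed = 1L, ...) {
  if (is.character(spec)) spec <- discriminator_spec(spec, ...)
  net <- new_net(spec$arch, c(1L, spec$height, spec$samples), seed)
  os <- net_out_shape(net_ptr(net))
  if (!identical(os, c(1L, 1L, 1L)))
    stop(sprintf("discriminator must emit a scalar score, got (%s)",
                 paste(os, collapse = ",")))
  net$role <- paste0("discriminator_", spec$kind)
  net$spec <- spec
  net
}

#' GAN training configuration
#'
#' Defaults follow the reference setting: Adam with learning rate 1e-4 and
#' batch size 5; the Adam betas (0.5, 0.999), leaky slope and equal
#' discriminator weights are package choices (the source method fixes only
#' the optimizer, rate and batch).
#'
#' @param lr learning rate
#' @param batch_size trials per update
#' @param n_epochs training epochs
#' @param betas Adam `(beta1, beta2)`
#' @param disc_weights weights `(w_raw, w_fb)` of the two discriminators in
#'   the generator objective
#' @param seed seed for all randomness of a training run
#' @param checkpoint_every snapshot the generator every this many epochs
#' @return object of class `gan_config`
#' @export
gan_config <- function(lr = 1e-4, batch_size = 5, n_epochs = 100,
                       betas = c(0.5, 0.999), disc_weights = c(1, 1),
                       seed = 1L, checkpoint_every = 50L) {
  stopifnot(lr > 0, batch_size >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), betas = betas,
                 disc_weights = disc_weights, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "gan_config")
}

# Project a batch of trials (flattened columns) through the sparse filter.
batch_sparse_project <- function(ssf, batch_mat, channels, samples, fs) {
  n <- ncol(batch_mat)
  out <- matrix(0, ncol(ssf$W) * samples, n)
  for (i in seq_len(n)) {
    X <- matrix(batch_mat[, i], channels, samples)
    out[, i] <- as.vector(apply_sparse_filter(ssf, X, fs))
  }
  out
}

batch_sparse_adjoint <- function(ssf, dZ_mat, channels, samples, fs) {
  n <- ncol(dZ_mat)
  out <- matrix(0, channels * samples, n)
  for (i in seq_len(n)) {
    dZ <- matrix(dZ_mat[, i], ncol(ssf$W), samples)
    out[, i] <- as.vector(sparse_filter_adjoint(ssf, dZ, fs))
  }
  out
}

#' One adversarial update step
#'
#' Performs one discriminator update (binary cross-entropy on real versus
#' generated trials, summed over the raw-trial discriminator and the
#' sparse-filtered discriminator) followed by one generator update with the
#' non-saturating loss against both discriminators, weighted by
#' `disc_weights`. Both discriminators see the same zero-phase band filter
#' operator on real and fake data, so neither can key on filtering
#' artifacts.
#'
#' @param gen,d_raw,d_fb networks from [build_generator()] /
#'   [build_discriminator()]
#' @param real_batch trials x channels x samples array (one class, one
#'   subject)
#' @param ssf the subject's [sparse_spatial_filter()]
#' @param config a [gan_config()]
#' @param z_real optional precomputed sparse projections of `real_batch`
#' @return list of scalar losses (`d_raw`, `d_fb`, `g_raw`, `g_fb`, `g`)
#' @export
gan_step <- function(gen, d_raw, d_fb, real_batch, ssf, config = gan_config(),
                     z_real = NULL) {
  spec <- gen$spec
  B <- dim(real_batch)[1L]
  gptr <- net_ptr(gen); drp <- net_ptr(d_raw); dfp <- net_ptr(d_fb)
  w <- config$disc_weights
  real_m <- as_batch(real_batch)
  z <- matrix(stats::rnorm(spec$noise_dim * B), spec$noise_dim, B)
  fake_m <- net_forward(gptr, z, training = TRUE)
  if (is.null(z_real))
    z_real <- batch_sparse_project(ssf, real_m, spec$channels, spec$samples, spec$fs)
  z_fake <- batch_sparse_project(ssf, fake_m, spec$channels, spec$samples, spec$fs)

  step_d <- function(dp, real_in, fake_in) {
    net_zero_grads(dp)
    lr_ <- net_forward(dp, real_in, training = TRUE)
    loss_real <- bce_with_logits(lr_, 1)
    net_backward(dp, matrix(bce_grad(lr_, 1), nrow = 1L))
    lf <- net_forward(dp, fake_in, training = TRUE)
    loss_fake <- bce_with_logits(lf, 0)
    net_backward(dp, matrix(bce_grad(lf, 0), nrow = 1L))
    net_adam_step(dp, config$lr, config$betas[1L], config$betas[2L], 1e-8)
    loss_real + loss_fake
  }
  loss_d_raw <- step_d(drp, real_m, fake_m)
  loss_d_fb <- step_d(dfp, z_real, z_fake)

  # generator: non-saturating loss against both discriminators
  net_zero_grads(gptr)
  dfake <- matrix(0, nrow(fake_m), B)
  g_raw <- g_fb <- 0
  if (w[1L] != 0) {
    net_zero_grads(drp)
    lg <- net_forward(drp, fake_m, training = TRUE)
    g_raw <- bce_with_logits(lg, 1)
    dfake <- dfake + w[1L] * net_backward(drp, matrix(bce_grad(lg, 1), nrow = 1L))
    net_zero_grads(drp)
  }
  if (w[2L] != 0) {
    net_zero_grads(dfp)
    lg <- net_forward(dfp, z_fake, training = TRUE)
    g_fb <- bce_with_logits(lg, 1)
    dZ <- net_backward(dfp, matrix(bce_grad(lg, 1), nrow = 1L))
    dfake <- dfake + w[2L] * batch_sparse_adjoint(ssf, dZ, spec$channels,
                                                  spec$samples, spec$fs)
    net_zero_grads(dfp)
  }
  net_backward(gptr, dfake)
  net_adam_step(gptr, config$lr, config$betas[1L], config$betas[2L], 1e-8)
  out <- list(d_raw = loss_d_raw, d_fb = loss_d_fb, g_raw = g_raw,
              g_fb = g_fb, g = w[1L] * g_raw + w[2L] * g_fb)
  if (!all(is.finite(unlist(out)))) stop("non-finite GAN loss")
  out
}

#' Train the dual-discriminator GAN on one (subject, class) trial set
#'
#' One unconditional model per subject and class: all trials must share a
#' single subject and class label. Fully seeded: the same config reproduces
#' the same loss history.
#'
#' @param epochs an [epoch_set()] of one class of one subject
#' @param ssf the subject's [sparse_spatial_filter()]
#' @param config a [gan_config()]
#' @param gen_spec a [generator_spec()] matching the trial shape
#' @return list with the trained `generator`, the discriminators, a
#'   per-epoch `history` data frame and parameter `checkpoints`
#' @export
train_fbgan <- function(epochs, ssf, config = gan_config(),
                        gen_spec = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(unique(epochs$labels)) != 1L || length(unique(epochs$subject)) != 1L)
    stop("train_fbgan expects trials of a single (subject, class)")
  n <- n_trials(epochs)
  if (n < config$batch_size)
    stop(sprintf("fewer trials (%d) than batch_size (%d)", n, config$batch_size))
  C <- dim(epochs$data)[2L]; T <- dim(epochs$data)[3L]
  if (is.null(gen_spec))
    gen_spec <- generator_spec(channels = C, samples = T, fs = epochs$fs,
                               noise_dim = if (C == 22 && T == 1000) 1600L else 64L)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3L)
  gen <- build_generator(gen_spec, seed = seeds[1L])
  d_raw <- build_discriminator(
    discriminator_spec("raw", channels = C, samples = T), seed = seeds[2L])
  d_fb <- build_discriminator(
    discriminator_spec("fb", n_sel = ncol(ssf$W), channels = C, samples = T),
    seed = seeds[3L])
  z_real_all <- batch_sparse_project(ssf, as_batch(epochs$data), C, T, epochs$fs)
  hist <- list()
  checkpoints <- list()
  for (ep in seq_len(config$n_epochs)) {
    ord <- sample.int(n)
    sums <- c(d_raw = 0, d_fb = 0, g = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      losses <- gan_step(gen, d_raw, d_fb,
                         epochs$data[idx, , , drop = FALSE], ssf, config,
                         z_real = z_real_all[, idx, drop = FALSE])
      sums <- sums + c(losses$d_raw, losses$d_fb, losses$g)
      nb <- nb + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, d_raw = sums[[1L]] / nb,
                             d_fb = sums[[2L]] / nb, g = sums[[3L]] / nb)
    if (ep %% config$checkpoint_every == 0L || ep == config$n_epochs)
      checkpoints[[as.character(ep)]] <- net_get_params(net_ptr(gen))
  }
  gen <- net_snapshot(gen)
  list(generator = gen, d_raw = net_snapshot(d_raw), d_fb = net_snapshot(d_fb),
       history = do.call(rbind, hist), checkpoints = checkpoints,
       config = config, subject = epochs$subject[1L],
       class_label = epochs$labels[1L])
}

#' Sample trials from a trained generator
#'
#' Deterministic in `seed`: the same seed yields the same trials. Batch
#' normalization uses its running statistics (inference mode).
#'
#' @param generator an `eegmi_net` from [build_generator()] or
#'   [train_fbgan()]
#' @param n number of trials (> 0)
#' @param seed noise seed
#' @param class_label,subject provenance recorded on the output
#' @param checkpoint_id free-form provenance tag
#' @return an [epoch_set()] with `synthetic = TRUE` and provenance
#'   attributes
#' @export
generate_trials <- function(generator, n, seed = 1L, class_label = NA_integer_,
                            subject = "generated", checkpoint_id = "final") {
  if (n <= 0) stop("n must be positive")
  spec <- generator$spec
  gptr <- net_ptr(generator)
  set.seed(seed)
  out <- array(0, c(n, spec$channels, spec$samples))
  done <- 0L
  while (done < n) {
    b <- min(64L, n - done)
    z <- matrix(stats::rnorm(spec$noise_dim * b), spec$noise_dim, b)
    fm <- net_forward(gptr, z, training = FALSE)
    out[done + seq_len(b), , ] <- batch_to_array(fm, spec$channels, spec$samples)
    done <- done + b
  }
  if (!all(is.finite(out))) stop("generator produced non-finite values")
  es <- epoch_set(out, rep(as.integer(class_label), n), spec$fs,
                  subject = subject, session = 0L, synthetic = TRUE)
  attr(es, "seed") <- seed
  attr(es, "checkpoint_id") <- checkpoint_id
  es
}

#' Sample a balanced augmentation set from per-class generators
#'
#' @param generators list of trained generators, one per class (names or
#'   order give the class labels 1..K)
#' @param n total number of trials; must be divisible by the class count
#' @param seed base seed (per-class seeds are derived from it)
#' @param subject provenance subject id
#' @return list of [epoch_set()]s, one per class, `n / K` trials each
#' @export
generate_for_classes <- function(generators, n, seed = 1L, subject = "generated") {
  K <- length(generators)
  if (n %% K != 0L)
    stop(sprintf("n = %d is not divisible by the number of classes (%d)", n, K))
  lapply(seq_len(K), function(k)
    generate_trials(generators[[k]], n %/% K, seed = seed + k,
                    class_label = k, subject = subject))
}
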