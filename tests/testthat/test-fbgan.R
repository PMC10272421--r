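# GAN tests run on the scaled generator/discriminator geometry (8 channels,
# 256 samples); the full-size 22 x 1000 architecture contracts are exercised
# in the acceptance suite.

scaled_gan <- function(seed = 1L) {
  gspec <- generator_spec(noise_dim = 64, channels = 8, samples = 256, fs = 64)
  ssf <- small_ssf()
  list(gen = build_generator(gspec, seed = seed),
       d_raw = build_discriminator(
         discriminator_spec("raw", channels = 8, samples = 256), seed = seed + 1L),
       d_fb = build_discriminator(
         discriminator_spec("fb", n_sel = ncol(ssf$W), channels = 8,
                            samples = 256), seed = seed + 2L),
       ssf = ssf, gspec = gspec)
}

test_that("generator maps noise to trial-shaped output deterministically", {
  s <- scaled_gan()
  p <- eegmi:::net_ptr(s$gen)
  expect_equal(eegmi:::net_out_shape(p), c(1L, 8L, 256L))
  set.seed(1)
  z <- matrix(rnorm(64 * 5), 64, 5)
  y1 <- eegmi:::net_forward(p, z, FALSE)
  y2 <- eegmi:::net_forward(p, z, FALSE)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(8L * 256L, 5L))
  expect_true(all(is.finite(y1)))
  # unreachable layer arithmetic errors with a shape trace
  bad <- generator_spec(noise_dim = 64, channels = 8, samples = 256)
  bad$channels <- 9L
  expect_error(build_generator(bad), "trace")
})

test_that("discriminators emit one score per trial and follow the Var rule", {
  s <- scaled_gan()
  x <- matrix(rnorm(8 * 256 * 3), ncol = 3)
  sc <- eegmi:::net_forward(eegmi:::net_ptr(s$d_raw), x, FALSE)
  expect_equal(dim(sc), c(1L, 3L))

  # Var = floor(n_sel / 4): the row-collapsing kernel height
  expect_equal(discriminator_spec("fb", n_sel = 16)$var_kernel, 4L)
  expect_equal(discriminator_spec("fb", n_sel = 17)$var_kernel, 4L)
  expect_equal(discriminator_spec("fb", n_sel = 20)$var_kernel, 5L)
  expect_error(discriminator_spec("fb", n_sel = 3), "n_sel >= 4")
  expect_error(discriminator_spec("fb"), "n_sel")

  # fb kinds with different selection sizes still yield scalar scores
  for (nsel in c(16L, 17L)) {
    d <- build_discriminator(
      discriminator_spec("fb", n_sel = nsel, channels = 8, samples = 256))
    z <- matrix(rnorm(nsel * 256 * 2), ncol = 2)
    expect_equal(dim(eegmi:::net_forward(eegmi:::net_ptr(d), z, FALSE)),
                 c(1L, 2L))
  }
})

test_that("full-size fb discriminator reduces 16 rows to a 750-unit head", {
  spec <- discriminator_spec("fb", n_sel = 16)
  d <- build_discriminator(spec, seed = 3L)
  tr <- eegmi:::net_shape_trace(eegmi:::net_ptr(d))
  # after the stride-(4,1) conv: 4 rows; after the Var kernel: 1 row
  expect_equal(tr[[3]][2], 4L)
  expect_equal(tr[[5]][2], 1L)
  flat <- tr[[length(tr) - 1L]]
  expect_equal(prod(flat), 750L)
  z <- matrix(rnorm(16 * 1000), ncol = 1)
  expect_length(eegmi:::net_forward(eegmi:::net_ptr(d), z, FALSE), 1L)
})

test_that("discriminator losses start at chance level for a null scorer", {
  s <- scaled_gan()
  # zero the scoring heads: every score is 0.5, so each discriminator's
  # real+fake binary cross-entropy is 2 ln 2 (ln 2 per term)
  for (d in list(s$d_raw, s$d_fb)) {
    p <- eegmi:::net_ptr(d)
    pars <- eegmi:::net_get_params(p)
    k <- length(pars) - 1L
    pars[[k]][] <- 0; pars[[k + 1L]][] <- 0
    eegmi:::net_set_params(p, pars)
  }
  real <- small_dataset()$data[1:5, , ]
  set.seed(1)
  losses <- gan_step(s$gen, s$d_raw, s$d_fb, real, s$ssf,
                     gan_config(lr = 1e-12, batch_size = 5, seed = 1))
  expect_equal(losses$d_raw, 2 * log(2), tolerance = 1e-6)
  expect_equal(losses$d_fb, 2 * log(2), tolerance = 1e-6)
  expect_equal(losses$g, losses$g_raw + losses$g_fb)
})

test_that("discriminator learns to separate distinguishable real and fake", {
  s <- scaled_gan(seed = 7L)
  # real data has a strong planted offset the initial generator lacks
  real_all <- small_dataset()$data[1:20, , ] + 3
  cfg <- gan_config(lr = 2e-3, batch_size = 5, seed = 3,
                    disc_weights = c(0, 0))  # generator frozen
  set.seed(3)
  losses <- numeric(50)
  for (i in 1:50) {
    idx <- ((i - 1) %% 4) * 5 + 1:5
    losses[i] <- gan_step(s$gen, s$d_raw, s$d_fb, real_all[idx, , ],
                          s$ssf, cfg)$d_raw
  }
  expect_lt(mean(losses[41:50]), mean(losses[1:10]) / 2)
})

test_that("discriminator weights gate the generator gradient path", {
  mk <- function() {
    s <- scaled_gan(seed = 5L)
    real <- small_dataset()$data[1:5, , ]
    list(s = s, real = real)
  }
  cfg0 <- gan_config(lr = 1e-3, batch_size = 5, disc_weights = c(0, 0))
  a <- mk()
  g_before <- eegmi:::net_get_params(eegmi:::net_ptr(a$s$gen))
  set.seed(9)
  gan_step(a$s$gen, a$s$d_raw, a$s$d_fb, a$real, a$s$ssf, cfg0)
  g_after <- eegmi:::net_get_params(eegmi:::net_ptr(a$s$gen))
  expect_equal(g_after, g_before, tolerance = 1e-12)  # both paths gated off

  # with weights (1, 0): perturbing the fb discriminator must not change
  # the generator update
  cfg10 <- gan_config(lr = 1e-3, batch_size = 5, disc_weights = c(1, 0))
  b1 <- mk(); b2 <- mk()
  pf <- eegmi:::net_ptr(b2$s$d_fb)
  pp <- eegmi:::net_get_params(pf)
  pp[[1]][] <- pp[[1]][] * 2
  eegmi:::net_set_params(pf, pp)
  set.seed(11); gan_step(b1$s$gen, b1$s$d_raw, b1$s$d_fb, b1$real, b1$s$ssf, cfg10)
  set.seed(11); gan_step(b2$s$gen, b2$s$d_raw, b2$s$d_fb, b2$real, b2$s$ssf, cfg10)
  expect_equal(eegmi:::net_get_params(eegmi:::net_ptr(b1$s$gen)),
               eegmi:::net_get_params(eegmi:::net_ptr(b2$s$gen)),
               tolerance = 1e-12)
})

test_that("per-class training is seeded, bookkept and checkpointed", {
  es <- small_dataset()
  one <- epochs_subset(es, which(es$labels == 1))
  ssf <- small_ssf()
  cfg <- gan_config(n_epochs = 2, batch_size = 5, seed = 21,
                    checkpoint_every = 1L)
  r1 <- train_fbgan(one, ssf, cfg)
  expect_equal(nrow(r1$history), 2L)
  expect_named(r1$checkpoints, c("1", "2"))
  r2 <- train_fbgan(one, ssf, cfg)
  expect_equal(r1$history, r2$history)
  expect_error(train_fbgan(epochs_subset(one, 1:3), ssf, cfg), "batch_size")
  expect_error(train_fbgan(es, ssf, cfg), "single")
})

test_that("generation is seeded with full provenance and balanced class counts", {
  s <- scaled_gan(seed = 2L)
  g1 <- generate_trials(s$gen, 3, seed = 5, class_label = 2L, subject = "A1")
  g2 <- generate_trials(s$gen, 3, seed = 5, class_label = 2L, subject = "A1")
  expect_identical(g1$data, g2$data)
  expect_equal(dim(g1$data), c(3L, 8L, 256L))
  expect_true(all(g1$synthetic))
  expect_true(all(is.finite(g1$data)))
  expect_error(generate_trials(s$gen, 0), "positive")

  gens <- lapply(1:4, function(k) build_generator(s$gspec, seed = k))
  sets <- generate_for_classes(gens, 8, seed = 1)
  expect_length(sets, 4L)
  expect_true(all(vapply(sets, function(x) dim(x$data)[1], 0L) == 2L))
  expect_equal(vapply(sets, function(x) x$labels[1], 0L), 1:4)
  expect_error(generate_for_classes(gens, 6, seed = 1), "divisible")
})
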