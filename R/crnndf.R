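#' Convolutional recurrent classifier architecture
#'
#' The spatial convolution spans all `C` electrode channels with a `C x 45`
#' kernel (stride 1), a `1 x 75` max-pool with stride 10 shortens the
#' sequence, and a two-layer LSTM (hidden state 64, dropout 0.5 between
#' layers) encodes the temporal dynamics; the final hidden state is the
#' 64-d feature vector on which the center-distance loss operates, followed
#' by a linear head to the class logits. The convolution filter count is a
#' package choice (the source figure is unreadable); 64 matches the LSTM
#' input scale and is config-exposed.
#'
#' @param channels,samples input trial shape; requires `samples >= conv_kernel_w + pool_w`
#' @param conv_filters spatial convolution output channels
#' @param conv_kernel_w temporal extent of the spatial convolution kernel
#' @param pool_w,pool_stride max-pool kernel and stride along time
#' @param lstm_layers,hidden recurrent depth and state size
#' @param dropout dropout probability for the pooled features and between
#'   recurrent layers
#' @param n_classes number of classes
#' @return object of class `classifier_spec`
#' @export
classifier_spec <- function(channels = 22, samples = 1000, conv_filters = 64,
                            conv_kernel_w = 45, pool_w = 75, pool_stride = 10,
                            lstm_layers = 2, hidden = 64, dropout = 0.5,
                            n_classes = 4) {
  if (samples < conv_kernel_w + pool_w)
    stop(sprintf("samples (%d) too short: conv kernel %d + pool %d needs at least %d",
                 samples, conv_kernel_w, pool_w, conv_kernel_w + pool_w))
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  conv_t <- samples - conv_kernel_w + 1L
  seq_len_ <- (conv_t - pool_w) %/% pool_stride + 1L
  structure(list(channels = as.integer(channels), samples = as.integer(samples),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel_w = as.integer(conv_kernel_w),
                 pool_w = as.integer(pool_w), pool_stride = as.integer(pool_stride),
                 lstm_layers = as.integer(lstm_layers), hidden = as.integer(hidden),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 conv_time = as.integer(conv_t), seq_len = as.integer(seq_len_)),
            class = "classifier_spec")
}

#' Build the classifier (feature body + linear head)
#'
#' The body maps `(1, C, T)` trials to the 64-d feature vector; the head
#' maps features to class logits. Keeping them separate exposes the
#' feature vector to the center-distance loss and to embedding export.
#'
#' @param spec a [classifier_spec()]
#' @param seed weight-initialisation seed
#' @return object of class `crnn_model` with elements `body`, `head`, `spec`
#' @export
build_crnn <- function(spec = classifier_spec(), seed = 1L) {
  body_arch <- list(
    list(type = "conv", out = spec$conv_filters, kh = spec$channels,
         kw = spec$conv_kernel_w),
    list(type = "lrelu", slope = 0.0),  # plain rectifier
    list(type = "maxpool", kh = 1L, kw = spec$pool_w, sh = 1L,
         sw = spec$pool_stride),
    list(type = "dropout", p = spec$dropout),
    list(type = "reshape", c = spec$conv_filters, h = 1L, w = spec$seq_len),
    list(type = "lstm", layers = spec$lstm_layers, hidden = spec$hidden,
         dropout = spec$dropout))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  body <- new_net(body_arch, c(1L, spec$channels, spec$samples), seeds[1L])
  head <- new_net(list(list(type = "dense", out = spec$n_classes)),
                  c(spec$hidden, 1L, 1L), seeds[2L])
  structure(list(body = body, head = head, spec = spec, seed = seed),
            class = "crnn_model")
}

#' @exportS3Method base::print
print.crnn_model <- function(x, ...) {
  cat(sprintf("<crnn_model> C=%d T=%d conv=%d seq=%d hidden=%d classes=%d\n",
              x$spec$channels, x$spec$samples, x$spec$conv_filters,
              x$spec$seq_len, x$spec$hidden, x$spec$n_classes))
  invisible(x)
}

# Forward pass; returns features (hidden x B) and logits (K x B).
crnn_forward <- function(model, batch_mat, training = FALSE) {
  feats <- net_forward(net_ptr(model$body), batch_mat, training)
  logits <- net_forward(net_ptr(model$head), feats, training)
  list(features = feats, logits = logits)
}

#' Initialize per-class feature centers
#'
#' `cen_j = sum_i [y_i = j] v_i / (1 + sum_i [y_i = j])` -- the printed
#' initialization with its `+1` denominator (a shrunken mean); a class with
#' no samples gets the zero vector. `shrink = FALSE` gives the plain mean.
#'
#' @param features d x N matrix (columns are feature vectors) or N x d
#'   matrix with `byrow = TRUE`
#' @param labels length-N class labels in `1:n_classes`
#' @param n_classes number of classes
#' @param shrink keep the `+1` denominator (default `TRUE`)
#' @param alpha,update_every center-expansion step size and epoch schedule
#'   carried with the bank
#' @return object of class `center_bank`: `centers` (n_classes x d),
#'   `alpha`, `update_every`, `shrink`
#' @export
init_centers <- function(features, labels, n_classes = 4, shrink = TRUE,
                         alpha = 0.02, update_every = 15L) {
  V <- as.matrix(features)
  if (ncol(V) == length(labels) && nrow(V) != length(labels)) V <- t(V)
  stopifnot(nrow(V) == length(labels))
  d <- ncol(V)
  centers <- matrix(0, n_classes, d)
  for (j in seq_len(n_classes)) {
    idx <- which(labels == j)
    s <- if (length(idx)) colSums(V[idx, , drop = FALSE]) else numeric(d)
    centers[j, ] <- s / (length(idx) + if (shrink) 1 else 0)
  }
  structure(list(centers = centers, alpha = alpha,
                 update_every = as.integer(update_every), shrink = shrink),
            class = "center_bank")
}

#' Center-distance loss
#'
#' Mean squared Euclidean distance between each feature vector and its
#' class center: `(1/b) sum_i || v_i - cen_{y_i} ||^2`.
#'
#' @param features d x b matrix (columns are feature vectors)
#' @param labels length-b class labels
#' @param bank a [init_centers()] bank
#' @return scalar loss
#' @export
center_loss <- function(features, labels, bank) {
  V <- as.matrix(features)
  if (nrow(V) != ncol(bank$centers))
    stop(sprintf("feature dimension %d does not match centers (%d)",
                 nrow(V), ncol(bank$centers)))
  diffs <- V - t(bank$centers[labels, , drop = FALSE])
  mean(colSums(diffs^2))
}

#' Expand the class centers away from their common mean
#'
#' If current features are supplied, centers are first re-estimated as the
#' class means (the initialization formula, keeping its shrinkage setting)
#' so they track the drifting feature space; each center is then moved
#' `alpha` along the unit vector pointing from the global mean of the
#' centers toward itself. A center coinciding with the global mean stays
#' put. Inter-center distances never decrease.
#'
#' @param bank a [init_centers()] bank
#' @param features optional d x N feature matrix for re-estimation
#' @param labels labels matching `features`
#' @return the updated bank
#' @export
expand_centers <- function(bank, features = NULL, labels = NULL) {
  if (!is.null(features)) {
    nb <- init_centers(features, labels, n_classes = nrow(bank$centers),
                       shrink = bank$shrink, alpha = bank$alpha,
                       update_every = bank$update_every)
    bank$centers <- nb$centers
  }
  vc <- colMeans(bank$centers)
  for (j in seq_len(nrow(bank$centers))) {
    dir <- bank$centers[j, ] - vc
    nrm <- sqrt(sum(dir^2))
    if (nrm > 0) bank$centers[j, ] <- bank$centers[j, ] + bank$alpha * dir / nrm
  }
  bank
}

#' Joint classification + center-distance objective
#'
#' Cross-entropy of the logits against the true labels plus
#' `lambda_center` times the center loss. With `lambda_center = 0` this is
#' the plain classifier objective.
#'
#' @param logits K x b matrix
#' @param labels length-b true labels
#' @param l_cen scalar center loss
#' @param lambda_center proportion of the center-distance term
#' @return scalar loss
#' @export
total_loss <- function(logits, labels, l_cen = 0, lambda_center = 0.1) {
  ce <- cross_entropy(logits, labels)$loss
  ce + lambda_center * l_cen
}

# softmax cross-entropy; returns loss and gradient wrt logits (K x b)
cross_entropy <- function(logits, labels) {
  K <- nrow(logits); b <- ncol(logits)
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  p <- sweep(e, 2L, colSums(e), `/`)
  picked <- p[cbind(labels, seq_len(b))]
  onehot <- matrix(0, K, b)
  onehot[cbind(labels, seq_len(b))] <- 1
  list(loss = -mean(log(pmax(picked, 1e-300))), grad = (p - onehot) / b, p = p)
}

#' Training configuration for the classifier
#'
#' Defaults follow the reference setting: learning rate 1e-4, batch size
#' 32, center-loss proportion `lambda_center = 0.1`, expansion step `alpha
#' = 0.02` applied every 15 epochs.
#'
#' @param lambda_center proportion of the center-distance loss
#' @param lr,batch_size optimizer settings
#' @param n_epochs training epochs
#' @param alpha center-expansion step size
#' @param update_every epochs between center updates
#' @param shrink use the `+1` shrunken-mean center estimate
#' @param seed training seed
#' @return object of class `loss_config`
#' @export
loss_config <- function(lambda_center = 0.1, lr = 1e-4, batch_size = 32,
                        n_epochs = 200, alpha = 0.02, update_every = 15L,
                        shrink = TRUE, seed = 1L) {
  stopifnot(lambda_center >= 0)
  structure(list(lambda_center = lambda_center, lr = lr,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), alpha = alpha,
                 update_every = as.integer(update_every), shrink = shrink,
                 seed = as.integer(seed)),
            class = "loss_config")
}

#' Train the classifier with the discriminative-feature objective
#'
#' Centers are initialized from the whole training set before the first
#' epoch, the joint loss (cross-entropy + `lambda_center` x center loss)
#' drives Adam updates, and every `update_every` epochs the centers are
#' re-estimated from the current features and expanded by `alpha`. Fully
#' seeded: the same config reproduces the same history.
#'
#' @param train an [epoch_set()]
#' @param config a [loss_config()]
#' @param spec a [classifier_spec()]; inferred from the data when `NULL`
#' @return list with the trained `model`, the final center `bank`,
#'   per-epoch `history` (loss, cross-entropy, center loss, accuracy) and
#'   the `center_trajectory` (bank snapshot at each update epoch)
#' @export
train_crnn_df <- function(train, config = loss_config(), spec = NULL) {
  stopifnot(inherits(train, "epoch_set"))
  n <- n_trials(train)
  if (n < config$batch_size)
    stop(sprintf("fewer trials (%d) than batch_size (%d)", n, config$batch_size))
  C <- dim(train$data)[2L]; T <- dim(train$data)[3L]
  if (is.null(spec)) spec <- classifier_spec(channels = C, samples = T)
  set.seed(config$seed)
  model <- build_crnn(spec, seed = sample.int(.Machine$integer.max, 1L))
  bptr <- net_ptr(model$body); hptr <- net_ptr(model$head)
  all_m <- as_batch(train$data)
  y <- train$labels
  feats0 <- net_forward(bptr, all_m, training = FALSE)
  bank <- init_centers(feats0, y, n_classes = spec$n_classes,
                       shrink = config$shrink, alpha = config$alpha,
                       update_every = config$update_every)
  trajectory <- list()
  hist <- list()
  for (ep in seq_len(config$n_epochs)) {
    ord <- sample.int(n)
    tot <- c(loss = 0, ce = 0, cen = 0)
    correct <- 0L
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      b <- length(idx)
      xb <- all_m[, idx, drop = FALSE]
      yb <- y[idx]
      feats <- net_forward(bptr, xb, training = TRUE)
      logits <- net_forward(hptr, feats, training = TRUE)
      ce <- cross_entropy(logits, yb)
      diffs <- feats - t(bank$centers[yb, , drop = FALSE])
      l_cen <- mean(colSums(diffs^2))
      net_zero_grads(hptr); net_zero_grads(bptr)
      gfeat <- net_backward(hptr, ce$grad)
      gfeat <- gfeat + config$lambda_center * 2 * diffs / b
      net_backward(bptr, gfeat)
      net_adam_step(hptr, config$lr, 0.9, 0.999, 1e-8)
      net_adam_step(bptr, config$lr, 0.9, 0.999, 1e-8)
      tot <- tot + c(ce$loss + config$lambda_center * l_cen, ce$loss, l_cen)
      correct <- correct + sum(apply(logits, 2L, which.max) == yb)
      nb <- nb + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = tot[[1L]] / nb,
                             ce = tot[[2L]] / nb, cen = tot[[3L]] / nb,
                             accuracy = 100 * correct / n)
    if (ep %% config$update_every == 0L && ep < config$n_epochs) {
      feats_all <- net_forward(bptr, all_m, training = FALSE)
      bank <- expand_centers(bank, feats_all, y)
      trajectory[[as.character(ep)]] <- bank$centers
    }
    if (!all(is.finite(tot))) stop(sprintf("non-finite loss at epoch %d", ep))
  }
  model$body <- net_snapshot(model$body)
  model$head <- net_snapshot(model$head)
  list(model = model, bank = bank, history = do.call(rbind, hist),
       center_trajectory = trajectory, config = config, spec = spec)
}

#' Predict classes and export feature vectors
#'
#' @param model a `crnn_model` (trained)
#' @param epochs an [epoch_set()] (or trials x channels x samples array)
#' @return list with `labels` (argmax class per trial) and `features`
#'   (trials x hidden matrix)
#' @export
predict_crnn <- function(model, epochs) {
  dat <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  if (length(dim(dat)) == 2L) dat <- array(dat, c(1L, dim(dat)))
  if (dim(dat)[2L] != model$spec$channels || dim(dat)[3L] != model$spec$samples)
    stop(sprintf("trials are %d x %d, model expects %d x %d",
                 dim(dat)[2L], dim(dat)[3L], model$spec$channels,
                 model$spec$samples))
  fw <- crnn_forward(model, as_batch(dat), training = FALSE)
  list(labels = apply(fw$logits, 2L, which.max), features = t(fw$features))
}

#' Within- over between-class feature distance ratio
#'
#' Diagnostic for feature discriminability: mean pairwise distance within
#' classes divided by mean pairwise distance between classes (smaller is
#' more discriminative).
#'
#' @param features N x d feature matrix
#' @param labels length-N labels
#' @return scalar ratio
#' @export
feature_distance_ratio <- function(features, labels) {
  D <- as.matrix(stats::dist(features))
  same <- outer(labels, labels, `==`) & upper.tri(D)
  diff <- outer(labels, labels, `!=`) & upper.tri(D)
  mean(D[same]) / mean(D[diff])
}
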