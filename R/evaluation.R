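#' Leave-one-subject-out split
#'
#' Pools every trial of every non-target subject (all sessions) into the
#' training set, shuffled with the given seed; all trials of the target
#' subject form the untouched test set. With 9 subjects of 2 x 288 trials
#' this gives 4608 training and 576 test trials.
#'
#' @param dataset list of [epoch_set()]s (one per subject) or a single
#'   pooled [epoch_set()] with per-trial subject ids
#' @param target_subject subject id held out for testing
#' @param seed shuffle seed
#' @return object of class `loso_split` with `train`, `test`, `target_id`
#' @export
loso_split <- function(dataset, target_subject, seed = 1L) {
  pooled <- if (inherits(dataset, "epoch_set")) dataset else epochs_bind(dataset)
  subjects <- unique(pooled$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  if (!target_subject %in% subjects)
    stop(sprintf("unknown subject '%s' (have: %s)", target_subject,
                 paste(subjects, collapse = ", ")))
  test <- epochs_subset(pooled, which(pooled$subject == target_subject))
  train <- epochs_subset(pooled, which(pooled$subject != target_subject))
  set.seed(seed)
  train <- epochs_subset(train, sample.int(n_trials(train)))
  structure(list(train = train, test = test, target_id = target_subject,
                 seed = seed), class = "loso_split")
}

#' @exportS3Method base::print
print.loso_split <- function(x, ...) {
  cat(sprintf("<loso_split> target %s: train %d / test %d trials\n",
              x$target_id, n_trials(x$train), n_trials(x$test)))
  invisible(x)
}

#' Mix generated trials into a training split
#'
#' Appends `n_aug / K` generated trials per class (flagged synthetic, with
#' the target subject's id) to the training set and reshuffles; the test
#' set is untouched. `n_aug = 0` returns the split unchanged.
#'
#' @param split a [loso_split()]
#' @param generated list of [epoch_set()]s of generated trials, one per
#'   class (as from [generate_for_classes()])
#' @param n_aug total number of generated trials to add; must be divisible
#'   by the class count
#' @return the augmented [loso_split()]
#' @export
augment <- function(split, generated, n_aug) {
  stopifnot(inherits(split, "loso_split"))
  if (n_aug == 0) return(split)
  classes <- vapply(generated, function(g) g$labels[1L], integer(1L))
  if (!setequal(classes, sort(unique(split$test$labels))))
    stop("generated sets must cover all classes of the target subject")
  K <- length(generated)
  if (n_aug %% K != 0L)
    stop(sprintf("n_aug = %d is not divisible by the number of classes (%d)",
                 n_aug, K))
  per <- n_aug %/% K
  for (g in generated)
    if (n_trials(g) < per)
      stop(sprintf("insufficient generated trials for class %d: have %d, need %d",
                   g$labels[1L], n_trials(g), per))
  picks <- lapply(generated, function(g) epochs_subset(g, seq_len(per)))
  for (i in seq_along(picks)) {
    picks[[i]]$subject <- rep(split$target_id, per)
    picks[[i]]$synthetic <- rep(TRUE, per)
  }
  train <- epochs_bind(c(list(split$train), picks))
  set.seed(split$seed + 1L)
  split$train <- epochs_subset(train, sample.int(n_trials(train)))
  split
}

#' Classification accuracy in percent
#'
#' @param predicted,true equal-length label vectors
#' @return `100 * correct / total`
#' @export
accuracy <- function(predicted, true) {
  if (!length(true)) stop("empty input")
  if (length(predicted) != length(true)) stop("length mismatch")
  100 * mean(predicted == true)
}

#' Compare real and generated trials in time, frequency and space
#'
#' Produces the three generated-data quality views: class-average traces
#' of named channels (time domain), the spectrogram of the channel-averaged
#' signal in dB (frequency domain), and the trial-averaged channel
#' covariance matrices normalized to unit diagonal (spatial domain),
#' summarized by the Pearson correlation of their upper triangles.
#'
#' @param real,fake [epoch_set()]s with matching class, channel count and
#'   trial length
#' @param channels channel names to trace (default the motor strip C3, Cz,
#'   C4)
#' @param freq_range spectrogram range in Hz
#' @return object of class `quality_report` with `time_avg`, `psd`, `cov`,
#'   `cov_correlation`
#' @export
quality_report <- function(real, fake, channels = c("C3", "Cz", "C4"),
                           freq_range = c(1, 38)) {
  stopifnot(inherits(real, "epoch_set"), inherits(fake, "epoch_set"))
  if (!identical(dim(real$data)[-1L], dim(fake$data)[-1L]))
    stop("real and fake trials must share channel count and length")
  miss <- setdiff(channels, real$channel_names)
  if (length(miss))
    stop(sprintf("channel(s) not found: %s", paste(miss, collapse = ", ")))
  ch_idx <- match(channels, real$channel_names)
  trace_of <- function(es) {
    m <- apply(es$data[, ch_idx, , drop = FALSE], c(2L, 3L), mean)
    rownames(m) <- channels
    m
  }
  spec_of <- function(es) {
    avg <- apply(es$data, 3L, function(s) mean(s))  # channel-mean trace per t
    sg <- signal::specgram(avg, n = min(128L, length(avg)), Fs = es$fs)
    keep <- sg$f >= freq_range[1L] & sg$f <= freq_range[2L]
    list(power_db = 20 * log10(abs(sg$S[keep, , drop = FALSE]) + 1e-12),
         f = sg$f[keep], t = sg$t)
  }
  ncov_of <- function(es) {
    C <- dim(es$data)[2L]
    R <- matrix(0, C, C)
    for (i in seq_len(n_trials(es))) {
      X <- es$data[i, , , drop = TRUE]
      R <- R + stats::cov(t(X))
    }
    stats::cov2cor(R / n_trials(es))
  }
  cov_r <- ncov_of(real); cov_f <- ncov_of(fake)
  ut <- upper.tri(cov_r)
  structure(list(
    time_avg = list(real = trace_of(real), fake = trace_of(fake)),
    psd = list(real = spec_of(real), fake = spec_of(fake)),
    cov = list(real = cov_r, fake = cov_f),
    cov_correlation = stats::cor(cov_r[ut], cov_f[ut])),
    class = "quality_report")
}

#' @exportS3Method base::print
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> covariance correlation %.3f\n",
              x$cov_correlation))
  invisible(x)
}

#' Run one leave-one-subject-out evaluation
#'
#' Splits, optionally augments the training set with generated trials,
#' trains the discriminative-feature classifier and scores the held-out
#' subject. Per-class confusion matrices are kept as extra diagnostics.
#'
#' @param dataset list of per-subject [epoch_set()]s
#' @param target_subject held-out subject id
#' @param config a [loss_config()]
#' @param spec optional [classifier_spec()]
#' @param generated optional per-class generated sets for augmentation
#' @param n_aug generated trials to mix in (0 = none)
#' @param seed split seed
#' @return list with `accuracy`, `confusion`, `train_result`, `split_sizes`
#' @export
run_loso <- function(dataset, target_subject, config = loss_config(),
                     spec = NULL, generated = NULL, n_aug = 0, seed = 1L) {
  split <- loso_split(dataset, target_subject, seed = seed)
  if (n_aug > 0) {
    if (is.null(generated)) stop("n_aug > 0 requires generated trial sets")
    split <- augment(split, generated, n_aug)
  }
  audit_no_leakage(split)
  tr <- train_crnn_df(split$train, config = config, spec = spec)
  pred <- predict_crnn(tr$model, split$test)
  conf <- table(factor(pred$labels, levels = sort(unique(split$test$labels))),
                factor(split$test$labels))
  list(accuracy = accuracy(pred$labels, split$test$labels),
       confusion = conf, train_result = tr,
       split_sizes = c(train = n_trials(split$train), test = n_trials(split$test)),
       manifest = list(target = target_subject, n_aug = n_aug,
                       lambda_center = config$lambda_center,
                       n_epochs = config$n_epochs,
                       batch_size = config$batch_size, lr = config$lr,
                       split_seed = seed, train_seed = config$seed,
                       n_train = n_trials(split$train),
                       n_test = n_trials(split$test),
                       train_checksum = sum(split$train$data),
                       test_checksum = sum(split$test$data)))
}

# every (subject, session, synthetic) test identity must be absent from the
# real portion of the training set; synthetic trials may only carry the
# target id
audit_no_leakage <- function(split) {
  tr <- split$train
  real_ids <- paste(tr$subject[!tr$synthetic], tr$session[!tr$synthetic])
  test_ids <- paste(split$test$subject, split$test$session)
  if (length(intersect(unique(real_ids), unique(test_ids))))
    stop("leakage: target-subject recordings present in the training set")
  if (any(tr$synthetic & tr$subject != split$target_id))
    stop("augmentation added synthetic trials for a non-target subject")
  invisible(TRUE)
}

#' Sweep a pipeline parameter
#'
#' Runs one full seeded evaluation per value of `lambda_center` or
#' `n_aug`, for each requested target subject, and tabulates per-subject
#' accuracies with their mean and population standard deviation.
#'
#' @param dataset list of per-subject [epoch_set()]s
#' @param param `"lambda_center"` or `"n_aug"`
#' @param values values to sweep (non-empty)
#' @param config base [loss_config()]
#' @param spec optional [classifier_spec()]
#' @param generated per-class generated sets (required when sweeping
#'   `n_aug` over positive values)
#' @param targets subject ids to evaluate (default: all)
#' @param seed split seed
#' @return data frame with one row per (value, subject) plus `mean`/`sd`
#'   columns recomputed from the per-subject accuracies
#' @export
sweep_param <- function(dataset, param = c("lambda_center", "n_aug"), values,
                        config = loss_config(), spec = NULL, generated = NULL,
                        targets = NULL, seed = 1L) {
  param <- match.arg(param)
  if (!length(values)) stop("values must be non-empty")
  if (is.null(targets))
    targets <- unique(unlist(lapply(dataset, function(d) d$subject)))
  rows <- list()
  for (v in values) {
    cfg <- config
    n_aug <- 0
    if (param == "lambda_center") cfg$lambda_center <- v else n_aug <- v
    accs <- vapply(targets, function(tg)
      run_loso(dataset, tg, config = cfg, spec = spec, generated = generated,
               n_aug = n_aug, seed = seed)$accuracy, numeric(1L))
    pop_sd <- sqrt(mean((accs - mean(accs))^2))
    rows[[length(rows) + 1L]] <- data.frame(
      param = param, value = v, subject = targets, accuracy = accs,
      mean = mean(accs), sd = pop_sd, row.names = NULL)
  }
  do.call(rbind, rows)
}
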