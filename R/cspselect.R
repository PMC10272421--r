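#' Trace-normalized mean spatial covariance of one class
#'
#' `R_c = mean_i X_i X_i' / tr(X_i X_i')` over the trials of the target
#' class; symmetric with unit trace.
#'
#' @param band_trials trials x channels x samples array (one sub-band)
#' @param labels per-trial class labels
#' @param target_class the class whose covariance is computed
#' @return channels x channels matrix
#' @export
mean_covariance <- function(band_trials, labels, target_class) {
  idx <- which(labels == target_class)
  if (!length(idx)) stop(sprintf("no trials of class %s", target_class))
  C <- dim(band_trials)[2L]
  R <- matrix(0, C, C)
  for (i in idx) {
    X <- band_trials[i, , , drop = TRUE]
    S <- tcrossprod(X)
    R <- R + S / sum(diag(S))
  }
  R <- R / length(idx)
  (R + t(R)) / 2
}

#' One-versus-rest CSP sub-filter
#'
#' Solves the generalized eigenvalue problem `R_c w = lambda R_rest w` by
#' Cholesky whitening of the (regularized) rest covariance and keeps the `m`
#' eigenvectors of largest eigenvalue. Eigenvalues are the variance ratios
#' the filters achieve. The sign convention makes the largest-magnitude
#' entry of each column positive; ties in eigenvalue keep the symmetric
#' eigensolver's stable order.
#'
#' @param R_c target-class mean covariance
#' @param R_rest pooled rest-class mean covariance
#' @param m eigenvectors retained (default 4)
#' @param eps ridge added to `R_rest` as `eps * trace` (conditioning)
#' @return list with `W` (channels x m), `eigenvalues` (descending), `m`
#' @export
csp_subfilter <- function(R_c, R_rest, m = 4, eps = 1e-8) {
  if (!all(is.finite(R_c)) || !all(is.finite(R_rest)))
    stop("covariance matrices must be finite")
  C <- nrow(R_c)
  Rr <- R_rest + diag(eps * sum(diag(R_rest)), C)
  U <- chol(Rr)                       # Rr = U'U
  Uinv <- backsolve(U, diag(C))
  S <- t(Uinv) %*% R_c %*% Uinv
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)     # eigenvalues descending
  m <- min(m, C)
  W <- Uinv %*% e$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, eigenvalues = e$values[seq_len(m)], m = m)
}

#' Per-band one-versus-rest CSP filter stack
#'
#' For every sub-band and every class, fits the OVR CSP sub-filter (class
#' vs. pooled rest) and stacks the retained columns. With 4 classes and
#' `m = 4` each band contributes 16 columns; the default 10-band bank gives
#' 160 columns in total. Column provenance (band, class, eigenvector rank)
#' is recorded for downstream sparsification.
#'
#' @param band_epochs a [filter_bank()] result
#' @param m eigenvectors retained per sub-filter
#' @return object of class `band_filter_stack`
#' @export
band_filter_stack <- function(band_epochs, m = 4) {
  stopifnot(inherits(band_epochs, "band_epochs"))
  classes <- sort(unique(band_epochs$labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_bands <- length(band_epochs$data)
  subfilters <- vector("list", n_bands)
  cols <- list()
  prov <- list()
  for (bi in seq_len(n_bands)) {
    bt <- band_epochs$data[[bi]]
    Rs <- lapply(classes, function(cl) mean_covariance(bt, band_epochs$labels, cl))
    names(Rs) <- classes
    subfilters[[bi]] <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      R_c <- Rs[[ci]]
      R_rest <- Reduce(`+`, Rs[-ci]) / (length(classes) - 1L)
      sf <- csp_subfilter(R_c, R_rest, m)
      sf$band_index <- bi
      sf$target_class <- classes[ci]
      subfilters[[bi]][[ci]] <- sf
      cols[[length(cols) + 1L]] <- sf$W
      prov[[length(prov) + 1L]] <- data.frame(
        band = bi, class = classes[ci], eig = seq_len(sf$m))
    }
  }
  structure(list(subfilters = subfilters,
                 columns = do.call(cbind, cols),
                 column_index = do.call(rbind, prov),
                 classes = classes, m = m,
                 spec = band_epochs$spec),
            class = "band_filter_stack")
}

#' @exportS3Method base::print
print.band_filter_stack <- function(x, ...) {
  cat(sprintf("<band_filter_stack> %d bands x %d classes x m=%d -> %d columns\n",
              length(x$subfilters), length(x$classes), x$m, ncol(x$columns)))
  invisible(x)
}

#' Log-normalized CSP variance features
#'
#' Feature `f[i,j]` is the log of the variance of trial `i` projected on
#' column `j` (in that column's own band), normalized by the summed variance
#' over the `m` columns of the same sub-filter: the standard log-variance
#' CSP feature. With defaults the feature matrix has `4m x 10 = 160`
#' columns.
#'
#' @param band_epochs a [filter_bank()] result (same spec the stack was
#'   built on)
#' @param stack a [band_filter_stack()]
#' @param var_floor variances below this are floored (guards zero-variance
#'   projections)
#' @return object of class `feature_matrix` with fields `F` (trials x D)
#'   and `column_index`
#' @export
csp_features <- function(band_epochs, stack, var_floor = 1e-12) {
  stopifnot(inherits(band_epochs, "band_epochs"),
            inherits(stack, "band_filter_stack"))
  n <- dim(band_epochs$data[[1L]])[1L]
  D <- ncol(stack$columns)
  F <- matrix(0, n, D)
  col_at <- 0L
  for (bi in seq_along(stack$subfilters)) {
    bt <- band_epochs$data[[bi]]
    for (ci in seq_along(stack$subfilters[[bi]])) {
      sf <- stack$subfilters[[bi]][[ci]]
      idx <- col_at + seq_len(sf$m)
      for (i in seq_len(n)) {
        X <- bt[i, , , drop = TRUE]
        P <- crossprod(sf$W, X)             # m x T projections
        v <- pmax(apply(P, 1L, stats::var), var_floor)
        F[i, idx] <- log(v / sum(v))
      }
      col_at <- col_at + sf$m
    }
  }
  structure(list(F = F, column_index = stack$column_index, D = D),
            class = "feature_matrix")
}

#' LASSO feature selection over the stacked CSP features
#'
#' Minimizes `(1/2N) sum_i (y_i - b0 - f_i' b)^2 + lambda * sum_j |b_j|`.
#' Columns are centered and unit-scaled first (L1 penalties are
#' scale-sensitive); the fit itself is delegated to glmnet, whose gaussian
#' objective is exactly this functional. The default treats the multiclass
#' label as a single numeric response; `multiclass = "ovr"` instead fits one
#' binary LASSO per class and unions the supports.
#'
#' @param fm a [csp_features()] result (or a plain numeric matrix)
#' @param labels numeric class labels
#' @param lambda positive penalty, or `"cv"` to pick it by 5-fold
#'   cross-validated prediction error over glmnet's logarithmic grid
#' @param multiclass `"numeric"` (literal single regression, default) or
#'   `"ovr"`
#' @param seed seed for the cross-validation folds
#' @return object of class `lasso_selection`: `beta`, `beta0`, `lambda`,
#'   `selected` (indices of the non-zero support)
#' @export
lasso_select <- function(fm, labels, lambda = "cv",
                         multiclass = c("numeric", "ovr"), seed = 1L) {
  multiclass <- match.arg(multiclass)
  F <- if (inherits(fm, "feature_matrix")) fm$F else as.matrix(fm)
  if (nrow(F) != length(labels)) stop("labels must match feature rows")
  mu <- colMeans(F)
  sdev <- apply(F, 2L, stats::sd)
  sdev[sdev <= 0] <- 1
  Fs <- scale(F, center = mu, scale = sdev)
  y <- as.numeric(labels)
  fit_one <- function(yy) {
    if (identical(lambda, "cv")) {
      set.seed(seed)
      cv <- glmnet::cv.glmnet(Fs, yy, alpha = 1, nfolds = 5,
                              standardize = FALSE)
      lam <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      lam <- as.numeric(lambda)
      if (!is.finite(lam) || lam <= 0) stop("lambda must be positive")
      fit <- glmnet::glmnet(Fs, yy, alpha = 1, lambda = lam,
                            standardize = FALSE, thresh = 1e-12)
    }
    b <- as.numeric(glmnet::coef.glmnet(fit, s = lam))
    list(beta0 = b[1L], beta = b[-1L], lambda = lam)
  }
  if (multiclass == "numeric") {
    r <- fit_one(y)
    sel <- which(r$beta != 0)
    out <- list(beta = r$beta, beta0 = r$beta0, lambda = r$lambda,
                selected = sel)
  } else {
    classes <- sort(unique(y))
    fits <- lapply(classes, function(cl) fit_one(as.numeric(y == cl)))
    betas <- vapply(fits, `[[`, numeric(ncol(Fs)), "beta")
    sel <- which(rowSums(betas != 0) > 0)
    out <- list(beta = rowMeans(betas), beta0 = mean(vapply(fits, `[[`, 0, "beta0")),
                lambda = fits[[1L]]$lambda, selected = sel, per_class_beta = betas)
  }
  out$center <- mu
  out$scale <- sdev
  structure(out, class = "lasso_selection")
}

#' Sparse spatial filter from the LASSO support
#'
#' Keeps exactly the stack columns whose features survived the LASSO,
#' together with their (band, class, eigenvector) provenance. An empty
#' selection is an error (reduce `lambda`).
#'
#' @param selection a [lasso_select()] result
#' @param stack the [band_filter_stack()] the features came from
#' @return object of class `sparse_spatial_filter`: `W` (channels x n_sel),
#'   `provenance`, `band_of_column`, plus the band spec needed to filter
#'   trials before projection
#' @export
sparse_spatial_filter <- function(selection, stack) {
  stopifnot(inherits(stack, "band_filter_stack"))
  sel <- if (inherits(selection, "lasso_selection")) selection$selected
         else as.integer(selection)
  if (!length(sel))
    stop("empty selection: no LASSO-surviving features; use a smaller lambda")
  structure(list(W = stack$columns[, sel, drop = FALSE],
                 provenance = stack$column_index[sel, , drop = FALSE],
                 band_of_column = stack$column_index$band[sel],
                 selected = sel,
                 spec = stack$spec),
            class = "sparse_spatial_filter")
}

#' @exportS3Method base::print
print.sparse_spatial_filter <- function(x, ...) {
  cat(sprintf("<sparse_spatial_filter> %d x %d (bands used: %s)\n",
              nrow(x$W), ncol(x$W),
              paste(sort(unique(x$band_of_column)), collapse = ",")))
  invisible(x)
}

#' Project a trial through the sparse spatial filter
#'
#' `Z = W' X'` where each selected column multiplies the trial filtered in
#' that column's own originating band (the columns are only meaningful in
#' their band). Rows are stacked in selection order, giving an
#' `n_sel x T` matrix. Band filtering uses the self-adjoint Fourier-domain
#' operator so the projection is differentiable for GAN training;
#' pre-filtered trials can be supplied to skip the filtering.
#'
#' @param ssf a [sparse_spatial_filter()]
#' @param trial channels x samples matrix
#' @param fs sampling rate (needed to band-filter)
#' @param band_filtered optional list (band index -> filtered trial)
#' @return `n_sel x T` matrix
#' @export
apply_sparse_filter <- function(ssf, trial, fs, band_filtered = NULL) {
  stopifnot(inherits(ssf, "sparse_spatial_filter"))
  trial <- as.matrix(trial)
  if (nrow(trial) != nrow(ssf$W))
    stop(sprintf("trial has %d channels, filter expects %d",
                 nrow(trial), nrow(ssf$W)))
  bands_used <- sort(unique(ssf$band_of_column))
  if (is.null(band_filtered)) {
    band_filtered <- list()
    for (bi in bands_used) {
      b <- ssf$spec$bands[[bi]]
      band_filtered[[bi]] <- fft_bandpass_mat(trial, b[1L], b[2L], fs,
                                              ssf$spec$order)
    }
  }
  Z <- matrix(0, ncol(ssf$W), ncol(trial))
  for (j in seq_len(ncol(ssf$W)))
    Z[j, ] <- crossprod(ssf$W[, j], band_filtered[[ssf$band_of_column[j]]])
  Z
}

# Adjoint of apply_sparse_filter: maps a gradient on Z back to a gradient on
# the trial.  The band filter is self-adjoint, so each row contributes
# filter_band(w_j %o% dZ_j).
sparse_filter_adjoint <- function(ssf, dZ, fs) {
  C <- nrow(ssf$W)
  out <- matrix(0, C, ncol(dZ))
  for (bi in sort(unique(ssf$band_of_column))) {
    js <- which(ssf$band_of_column == bi)
    M <- ssf$W[, js, drop = FALSE] %*% dZ[js, , drop = FALSE]
    b <- ssf$spec$bands[[bi]]
    out <- out + fft_bandpass_mat(M, b[1L], b[2L], fs, ssf$spec$order)
  }
  out
}
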