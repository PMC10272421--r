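#' Persist an epoch set
#'
#' Single-file container (RDS) holding the trial array, labels, sampling
#' rate and per-trial provenance.
#'
#' @param es an [epoch_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  saveRDS(es, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  es <- readRDS(path)
  if (!inherits(es, "epoch_set")) stop("file does not contain an epoch_set")
  es
}

#' Save / load a trained model or GAN bundle
#'
#' Network handles carry a live engine pointer; saving snapshots their
#' parameters so the object is self-contained, and loading rebuilds the
#' engine lazily on first use.
#'
#' @param x a `crnn_model`, `eegmi_net`, or a [train_fbgan()] /
#'   [train_crnn_df()] result list
#' @param path file path
#' @return `path`, invisibly
#' @export
save_model <- function(x, path) {
  snap <- function(o) {
    if (inherits(o, "eegmi_net")) return(net_snapshot(o))
    if (is.list(o)) return(lapply(o, snap))
    o
  }
  x <- snap(x)
  # drop live environments; they are rebuilt on demand
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Export feature embeddings as CSV
#'
#' One row per trial: identifier, subject, label and the feature vector,
#' ready for downstream 2-D embedding (e.g. t-SNE) outside the package.
#'
#' @param features trials x d feature matrix (as from [predict_crnn()])
#' @param labels per-trial labels
#' @param subjects per-trial subject ids
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
export_features_csv <- function(features, labels, subjects, path) {
  features <- as.matrix(features)
  df <- data.frame(trial_id = seq_len(nrow(features)), subject = subjects,
                   label = labels)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  utils::write.csv(cbind(df, features), path, row.names = FALSE)
  invisible(path)
}
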