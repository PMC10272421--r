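#' @useDynLib eegmi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a network handle
#'
#' Wraps the compiled sequential-network engine. A network is described by a
#' list of layer specs (type plus dimensions) and an input shape
#' `c(channels, height, width)`; the handle keeps the live engine pointer in
#' an environment so that models survive serialization: after `readRDS()`
#' the engine object is rebuilt from the stored architecture, seed and
#' parameter snapshot on first use.
#'
#' @param arch list of layer specs
#' @param in_shape integer vector `c(C, H, W)`
#' @param seed integer seed for weight initialisation and dropout
#' @return an object of class `eegmi_net`
#' @keywords internal
new_net <- function(arch, in_shape, seed) {
  live <- new.env(parent = emptyenv())
  live$ptr <- net_create(arch, as.integer(in_shape), as.integer(seed))
  structure(
    list(arch = arch, in_shape = as.integer(in_shape), seed = as.integer(seed),
         params = NULL, live = live),
    class = "eegmi_net")
}

# Live engine pointer, rebuilding the C++ object if the handle was
# deserialized (external pointers do not survive saveRDS).
net_ptr <- function(net) {
  if (!xptr_valid(net$live$ptr)) {
    net$live$ptr <- net_create(net$arch, net$in_shape, net$seed)
    if (!is.null(net$params)) net_set_params(net$live$ptr, net$params)
  }
  net$live$ptr
}

# Copy current engine parameters into the R object so it can be serialized.
net_snapshot <- function(net) {
  net$params <- net_get_params(net_ptr(net))
  net
}

#' @exportS3Method base::print
print.eegmi_net <- function(x, ...) {
  os <- net_out_shape(net_ptr(x))
  cat(sprintf("<eegmi_net> %d layers, input (%s), output (%s), %s parameters\n",
              length(x$arch), paste(x$in_shape, collapse = ","),
              paste(os, collapse = ","),
              format(net_n_params(net_ptr(x)), big.mark = ",")))
  invisible(x)
}

# Flatten a batch of trials into the engine's column layout.
# x: array (N, C, T) or a single C x T matrix -> (C*T) x N matrix,
# interpreted by the engine as images of shape (1, C, T).
as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1L]
  matrix(aperm(x, c(2L, 3L, 1L)), ncol = n)
}

batch_to_array <- function(m, channels, samples) {
  n <- ncol(m)
  aperm(array(m, c(channels, samples, n)), c(3L, 1L, 2L))
}

# Numerically safe binary cross-entropy with logits; target in {0,1}.
bce_with_logits <- function(logits, target) {
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

bce_grad <- function(logits, target) {
  (stats::plogis(logits) - target) / length(logits)
}
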