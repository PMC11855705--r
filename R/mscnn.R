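#' Multi-scale CNN configuration
#'
#' Parallel 1-D convolutions with odd kernel widths (default 3, 5 and 7 —
#' three scales, the optimum of the layer-count sweep), each with
#' `filters_per_scale` output channels, stride 1 and "same" zero padding, so
#' every scale preserves the input length. Channel outputs are concatenated
#' and compressed by a fully connected layer of width `fc_dim`.
#'
#' @param kernel_sizes distinct odd positive integers.
#' @param filters_per_scale output channels per scale.
#' @param fc_dim width of the per-entity fully connected output.
#' @param activation elementwise nonlinearity (`"relu"` or `"linear"`).
#' @return An object of class `mscnn_config`.
#' @export
mscnn_config <- function(kernel_sizes = c(3L, 5L, 7L), filters_per_scale = 16L,
                         fc_dim = 128L, activation = "relu") {
  kernel_sizes <- as.integer(kernel_sizes)
  if (any(kernel_sizes %% 2L == 0L) || any(kernel_sizes < 1L)) {
    stop("kernel sizes must be odd positive integers")
  }
  if (anyDuplicated(kernel_sizes)) stop("kernel sizes must be distinct")
  stopifnot(filters_per_scale >= 1L, fc_dim >= 1L)
  structure(
    list(
      kernel_sizes = kernel_sizes,
      filters_per_scale = as.integer(filters_per_scale),
      fc_dim = as.integer(fc_dim),
      activation = activation
    ),
    class = "mscnn_config"
  )
}

# Xavier-initialized parameters for both entity branches. Branches are
# unshared: circRNA inputs have length M, drug inputs length N.
mscnn_init <- function(M, N, cfg) {
  branch <- function(len) {
    conv <- lapply(cfg$kernel_sizes, function(k) {
      list(W = xavier_matrix(k, cfg$filters_per_scale), b = rep(0, cfg$filters_per_scale))
    })
    width <- length(cfg$kernel_sizes) * cfg$filters_per_scale * len
    list(conv = conv, fc = list(W = xavier_matrix(width, cfg$fc_dim), b = rep(0, cfg$fc_dim)))
  }
  list(circ = branch(M), drug = branch(N), M = M, N = N)
}

#' Single-scale 1-D convolution of similarity vectors
#'
#' One parallel branch of the multi-scale extractor: a stride-1, "same"
#' zero-padded 1-D convolution with `filters` output channels followed by an
#' elementwise nonlinearity. Accepts a single vector or a batch matrix (one
#' input per row).
#'
#' @param v numeric vector of length L, or a batch x L matrix.
#' @param kernel_size odd kernel width (must not exceed L).
#' @param filters number of output channels.
#' @param params optional `list(W = k x filters, b = filters)`; freshly
#'   Xavier-initialized when omitted.
#' @param activation nonlinearity applied to the feature map.
#' @return Feature map as a `filters x L` matrix for vector input, or a
#'   batch x (filters*L) flattened matrix for batch input, with attribute
#'   `"params"` carrying the parameters used.
#' @export
conv_scale <- function(v, kernel_size, filters, params = NULL, activation = "relu") {
  single <- is.null(dim(v))
  X <- if (single) matrix(v, 1L) else as.matrix(v)
  if (ncol(X) < kernel_size) {
    stop("input length ", ncol(X), " is shorter than the kernel (", kernel_size, ")")
  }
  if (is.null(params)) {
    params <- list(W = xavier_matrix(kernel_size, filters), b = rep(0, filters))
  }
  stopifnot(nrow(params$W) == kernel_size, ncol(params$W) == filters)
  fwd <- conv1d_forward(X, params$W, params$b)
  out <- act_forward(fwd$out, activation)
  res <- if (single) {
    matrix(out, filters, ncol(X), byrow = TRUE) # rows = channels
  } else {
    out
  }
  attr(res, "params") <- params
  res
}

# Forward pass of one branch; returns activation + caches for backprop.
mscnn_branch_forward <- function(X, branch, cfg) {
  conv_caches <- vector("list", length(cfg$kernel_sizes))
  maps <- vector("list", length(cfg$kernel_sizes))
  for (s in seq_along(cfg$kernel_sizes)) {
    fwd <- conv1d_forward(X, branch$conv[[s]]$W, branch$conv[[s]]$b)
    act <- act_forward(fwd$out, cfg$activation)
    conv_caches[[s]] <- list(Xcol = fwd$Xcol, dims = fwd$dims, act = act)
    maps[[s]] <- act
  }
  H <- do.call(cbind, maps) # batch x (S*F*L), the merged multi-scale map
  lin <- dense_forward(H, branch$fc$W, branch$fc$b)
  out <- act_forward(lin, cfg$activation)
  list(out = out, H = H, fc_out = out, conv_caches = conv_caches)
}

mscnn_branch_backward <- function(dOut, cache, branch, cfg) {
  dlin <- act_backward(dOut, cache$fc_out, cfg$activation)
  fc_bk <- dense_backward(dlin, cache$H, branch$fc$W)
  dH <- fc_bk$dX
  widths <- vapply(cache$conv_caches, function(cc) cc$dims[2L] * cc$dims[4L], numeric(1))
  offsets <- cumsum(c(0, widths))
  conv_grads <- vector("list", length(cache$conv_caches))
  dX <- NULL
  for (s in seq_along(cache$conv_caches)) {
    cc <- cache$conv_caches[[s]]
    dmap <- dH[, (offsets[s] + 1L):offsets[s + 1L], drop = FALSE]
    dpre <- act_backward(dmap, cc$act, cfg$activation)
    bk <- conv1d_backward(dpre, cc$Xcol, branch$conv[[s]]$W, cc$dims)
    conv_grads[[s]] <- list(W = bk$dW, b = bk$db)
    dX <- if (is.null(dX)) bk$dX else dX + bk$dX
  }
  list(
    dX = dX,
    grads = list(conv = conv_grads, fc = list(W = fc_bk$dW, b = fc_bk$db))
  )
}

#' Multi-scale convolutional feature extraction for circRNA-drug pairs
#'
#' Runs every kernel size over the circRNA similarity vector and the drug
#' similarity vector (separate, unshared parameters per entity), concatenates
#' the channel outputs, compresses each entity with a fully connected layer,
#' and concatenates the two compressed representations:
#' \eqn{x = [x_c \| x_d]} of length `2 * fc_dim`.
#'
#' @param c_vec circRNA features: length-M vector or batch x M matrix.
#' @param d_vec drug features: length-N vector or batch x N matrix (same
#'   batch size).
#' @param cfg an [mscnn_config()].
#' @param params parameters from `mscnn_init` (internal); freshly
#'   initialized for the given dimensions when omitted.
#' @return batch x (2*fc_dim) matrix of integrated features, with attribute
#'   `"params"`.
#' @export
mscnn_forward <- function(c_vec, d_vec, cfg = mscnn_config(), params = NULL) {
  C <- if (is.null(dim(c_vec))) matrix(c_vec, 1L) else as.matrix(c_vec)
  D <- if (is.null(dim(d_vec))) matrix(d_vec, 1L) else as.matrix(d_vec)
  stopifnot(nrow(C) == nrow(D))
  if (is.null(params)) params <- mscnn_init(ncol(C), ncol(D), cfg)
  if (params$M != ncol(C) || params$N != ncol(D)) {
    stop("parameter shapes do not match input dimensions")
  }
  fc <- mscnn_branch_forward(C, params$circ, cfg)
  fd <- mscnn_branch_forward(D, params$drug, cfg)
  out <- cbind(fc$out, fd$out)
  attr(out, "params") <- params
  out
}

# Full forward with caches (internal, used by the training loop).
mscnn_forward_cached <- function(C, D, params, cfg) {
  fc <- mscnn_branch_forward(C, params$circ, cfg)
  fd <- mscnn_branch_forward(D, params$drug, cfg)
  list(out = cbind(fc$out, fd$out), circ = fc, drug = fd)
}

mscnn_backward <- function(dOut, cache, params, cfg) {
  fc_dim <- ncol(cache$circ$out)
  bc <- mscnn_branch_backward(dOut[, seq_len(fc_dim), drop = FALSE], cache$circ, params$circ, cfg)
  bd <- mscnn_branch_backward(dOut[, fc_dim + seq_len(ncol(cache$drug$out)), drop = FALSE],
                              cache$drug, params$drug, cfg)
  list(grads = list(circ = bc$grads, drug = bd$grads), dC = bc$dX, dD = bd$dX)
}

#' Ablation bypass: raw concatenation of the similarity vectors
#'
#' Used by the no-MSCNN model variant: the per-pair feature is simply
#' `[c_vec, d_vec]` of length M + N, with no learned extraction.
#'
#' @param c_vec,d_vec vectors or batch matrices as in [mscnn_forward()].
#' @return batch x (M+N) matrix.
#' @export
mscnn_bypass <- function(c_vec, d_vec) {
  C <- if (is.null(dim(c_vec))) matrix(c_vec, 1L) else as.matrix(c_vec)
  D <- if (is.null(dim(d_vec))) matrix(d_vec, 1L) else as.matrix(d_vec)
  stopifnot(nrow(C) == nrow(D))
  cbind(C, D)
}
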