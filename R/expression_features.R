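# Expression feature block: log2(RPKM+1) transform, min-max scaling, and the
# single-layer ReLU autoencoder that compresses per-gene expression profiles
# into a low-dimensional code.

#' log2(RPKM + 1) transform of an expression matrix
#'
#' @param m An [expression_matrix()] in state `"rpkm"` (all values >= 0).
#' @return The matrix with every value v replaced by log2(v + 1), state
#'   `"log2"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$transform_state != "rpkm")
    stop("log_transform expects transform_state 'rpkm', got '",
         m$transform_state, "'")
  if (any(m$values < 0)) stop("negative expression values cannot be log-transformed")
  expression_matrix(log2(m$values + 1), "log2")
}

#' Min-max normalize the columns of a feature matrix
#'
#' Each column is scaled as (v - min) / (max - min). When `fit_stats` is
#' supplied (e.g. statistics from training folds), those minima/maxima are
#' used, so held-out values may fall outside \[0, 1\]. Constant columns
#' (max = min) map to 0.
#'
#' @param m Numeric matrix (rows = genes, columns = features).
#' @param fit_stats Optional list with numeric vectors `min` and `max`, one
#'   entry per column, as returned by a previous call.
#' @return List with `values` (the scaled matrix) and `stats` (the min/max
#'   actually used).
#' @export
minmax_normalize <- function(m, fit_stats = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(fit_stats)) {
    fit_stats <- list(min = apply(m, 2L, min), max = apply(m, 2L, max))
  } else {
    if (length(fit_stats$min) != ncol(m) || length(fit_stats$max) != ncol(m))
      stop("fit_stats dimension (", length(fit_stats$min),
           ") does not match feature count (", ncol(m), ")")
  }
  rng <- fit_stats$max - fit_stats$min
  scaled <- sweep(m, 2L, fit_stats$min, "-")
  safe <- ifelse(rng == 0, 1, rng)
  scaled <- sweep(scaled, 2L, safe, "/")
  scaled[, rng == 0] <- 0
  list(values = scaled, stats = fit_stats)
}

#' Specify the autoencoder architecture and training protocol
#'
#' One fully connected encoder layer (input_dim -> code_dim, ReLU) and one
#' decoder layer (code_dim -> input_dim, ReLU), mean-squared-error loss,
#' RMSprop optimizer, 100 epochs with mini-batches of 64 by default.
#'
#' @param input_dim Number of input features (expression samples).
#' @param code_dim Code size; must satisfy 1 <= code_dim < input_dim.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSprop learning rate (the optimizer's conventional
#'   default).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A list of class `ae_spec`.
#' @export
autoencoder_spec <- function(input_dim, code_dim, epochs = 100L,
                             batch_size = 64L, learning_rate = 1e-3,
                             seed = 1L) {
  if (code_dim < 1L || code_dim >= input_dim)
    stop("code_dim must satisfy 1 <= code_dim < input_dim (got ",
         code_dim, " vs input_dim ", input_dim, ")")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 code_dim = as.integer(code_dim),
                 activation = "ReLU", loss = "MSE", optimizer = "RMSprop",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ae_spec")
}

relu <- function(x) pmax(x, 0)

ae_input_matrix <- function(m) {
  if (inherits(m, "expr_matrix")) {
    if (m$transform_state == "rpkm")
      stop("autoencoder input must be log2-transformed (or min-max scaled)")
    m$values
  } else if (is.matrix(m)) m
  else stop("expected an expr_matrix or a numeric matrix")
}

#' Train the expression autoencoder
#'
#' Rows of the input matrix are genes (training examples), columns the
#' expression samples. Training uses hand-written RMSprop (decay 0.9,
#' epsilon 1e-8) on shuffled mini-batches with analytic gradients of the MSE
#' reconstruction loss; weights are initialized uniformly with fan-in
#' scaling, the decoder bias at the per-sample means so the reconstruction
#' starts centered, and the encoder bias shifted so every code unit is
#' active at the mean input (a dead-ReLU guard on non-negative data).
#' Deterministic given `spec$seed`.
#'
#' @param m Log2-transformed [expression_matrix()] (or a plain numeric
#'   matrix, e.g. after min-max scaling).
#' @param spec An [autoencoder_spec()].
#' @return An object of class `autoencoder` holding the weights, the spec and
#'   the per-epoch mean training-loss trace.
#' @export
train_autoencoder <- function(m, spec) {
  stopifnot(inherits(spec, "ae_spec"))
  X <- ae_input_matrix(m)
  if (ncol(X) != spec$input_dim)
    stop("matrix has ", ncol(X), " columns but spec$input_dim is ",
         spec$input_dim)
  n <- nrow(X)
  d <- spec$input_dim
  c_ <- spec$code_dim
  set.seed(spec$seed)
  W1 <- matrix(stats::runif(d * c_, -sqrt(1 / d), sqrt(1 / d)), d, c_)
  # bias init keeps every encoder unit active at the mean input, guarding
  # against dead ReLU units on non-negative data
  b1 <- pmax(0, -as.numeric(colMeans(X) %*% W1)) + 0.01
  W2 <- matrix(stats::runif(c_ * d, -sqrt(1 / c_), sqrt(1 / c_)), c_, d)
  b2 <- colMeans(X)  # start the reconstruction at the per-sample mean
  rho <- 0.9; eps <- 1e-8; lr <- spec$learning_rate
  cache <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  loss_trace <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    batch_starts <- seq(1L, n, by = spec$batch_size)
    batch_losses <- numeric(length(batch_starts))
    for (bi in seq_along(batch_starts)) {
      rows <- idx[batch_starts[bi]:min(batch_starts[bi] + spec$batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      nb <- nrow(Xb)
      Z1 <- sweep(Xb %*% W1, 2L, b1, "+")
      H <- relu(Z1)
      Z2 <- sweep(H %*% W2, 2L, b2, "+")
      Y <- relu(Z2)
      err <- Y - Xb
      batch_losses[bi] <- mean(err^2)
      dY <- 2 * err / (nb * d)
      dZ2 <- dY * (Z2 > 0)
      gW2 <- crossprod(H, dZ2)
      gb2 <- colSums(dZ2)
      dH <- dZ2 %*% t(W2)
      dZ1 <- dH * (Z1 > 0)
      gW1 <- crossprod(Xb, dZ1)
      gb1 <- colSums(dZ1)
      cache$W1 <- rho * cache$W1 + (1 - rho) * gW1^2
      cache$b1 <- rho * cache$b1 + (1 - rho) * gb1^2
      cache$W2 <- rho * cache$W2 + (1 - rho) * gW2^2
      cache$b2 <- rho * cache$b2 + (1 - rho) * gb2^2
      W1 <- W1 - lr * gW1 / (sqrt(cache$W1) + eps)
      b1 <- b1 - lr * gb1 / (sqrt(cache$b1) + eps)
      W2 <- W2 - lr * gW2 / (sqrt(cache$W2) + eps)
      b2 <- b2 - lr * gb2 / (sqrt(cache$b2) + eps)
    }
    loss_trace[epoch] <- mean(batch_losses)
  }
  structure(list(W_enc = W1, b_enc = b1, W_dec = W2, b_dec = b2,
                 spec = spec, loss_trace = loss_trace),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder: %d -> %d -> %d (ReLU/ReLU), final MSE %.4g\n",
              x$spec$input_dim, x$spec$code_dim, x$spec$input_dim,
              utils::tail(x$loss_trace, 1L)))
  invisible(x)
}

#' Encode expression profiles into the learned code space
#'
#' Computes `ReLU(x W_enc + b_enc)` per gene; all outputs are >= 0.
#'
#' @param model A trained [train_autoencoder()] object.
#' @param m Matrix (or `expr_matrix`) with `input_dim` columns.
#' @return Gene x code_dim numeric matrix (rownames = gene ids, colnames
#'   `code001`, ...).
#' @export
encode <- function(model, m) {
  stopifnot(inherits(model, "autoencoder"))
  X <- ae_input_matrix(m)
  if (ncol(X) != model$spec$input_dim)
    stop("matrix has ", ncol(X), " columns but the model expects ",
         model$spec$input_dim)
  codes <- relu(sweep(X %*% model$W_enc, 2L, model$b_enc, "+"))
  colnames(codes) <- sprintf("code%03d", seq_len(ncol(codes)))
  codes
}

#' Reconstruct inputs through the decoder (ReLU output layer)
#'
#' @param model A trained autoencoder.
#' @param codes Matrix of codes (code_dim columns).
#' @return Reconstructed matrix with `input_dim` columns.
#' @export
decode <- function(model, codes) {
  stopifnot(inherits(model, "autoencoder"))
  relu(sweep(codes %*% model$W_dec, 2L, model$b_dec, "+"))
}

#' Choose the autoencoder code dimension by repeated cross-validation
#'
#' For each candidate size the autoencoder is trained on the full gene set,
#' the labeled genes are encoded, and class-weighted repeated stratified
#' cross-validation records the mean ROC AUC; the size with the best mean AUC
#' is returned (ties broken toward the smaller code).
#'
#' @param m Log2-transformed [expression_matrix()] (all genes, labeled and
#'   unlabeled).
#' @param labels Label set.
#' @param grid Integer vector of candidate code sizes (< input_dim).
#' @param folds,repetitions Cross-validation geometry (the full-scale
#'   protocol uses 10 folds and 50 repetitions).
#' @param model_config Classifier used for scoring (default class-weighted
#'   logistic regression).
#' @param ae_epochs,ae_batch_size Autoencoder training protocol.
#' @param seed Seed for training and cross-validation.
#' @return List with `code_dim` (the chosen size) and `auc_table`
#'   (data.frame of per-size mean ROC AUC).
#' @export
select_code_dimension <- function(m, labels, grid, folds = 10L,
                                  repetitions = 3L, model_config = NULL,
                                  ae_epochs = 100L, ae_batch_size = 64L,
                                  seed = 1L) {
  if (length(grid) == 0L) stop("empty code-dimension grid")
  X <- ae_input_matrix(m)
  if (any(grid >= ncol(X)) || any(grid < 1L))
    stop("grid values must satisfy 1 <= code_dim < input_dim")
  assert_label_set(labels)
  if (is.null(model_config))
    model_config <- model_config("LR", seed = derive_seed(seed, 101L))
  aucs <- vapply(grid, function(d) {
    spec <- autoencoder_spec(ncol(X), d, epochs = ae_epochs,
                             batch_size = ae_batch_size,
                             seed = derive_seed(seed, d))
    model <- train_autoencoder(m, spec)
    codes <- encode(model, m)
    labeled <- codes[rownames(codes) %in% c(labels$positives, labels$negatives), ,
                     drop = FALSE]
    rep <- repeated_cv(labeled, labels, model_config, k = folds,
                       repetitions = repetitions,
                       seed = derive_seed(seed, 1000L + d))
    rep$aggregate["roc_auc", "mean"]
  }, numeric(1))
  ord <- order(-aucs, grid)
  list(code_dim = grid[ord[1L]],
       auc_table = data.frame(code_dim = grid, mean_roc_auc = aucs))
}
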