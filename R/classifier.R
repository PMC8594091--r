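#' Classifier configuration
#'
#' Hyperparameters of the six-class window classifier: a single LSTM hidden
#' layer, a dropout layer to limit overfitting, and a dense fully connected
#' layer feeding a softmax over the six fall types.
#'
#' @param hidden_units LSTM hidden state size (>= 1).
#' @param dropout_rate dropout probability on the pooled hidden state, in
#'   \[0, 1).
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed integer seed; training is fully deterministic given the seed.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(hidden_units = 32L, dropout_rate = 0.5,
                              epochs = 50L, learning_rate = 1e-3,
                              batch_size = 16L, seed = 1L) {
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Assemble labelled feature windows into a training dataset
#'
#' Stacks equal-length [feature_window()]s into the array consumed by
#' [train_classifier()]. Channels are the six raw axes plus the per-sample
#' SVM.
#'
#' @param windows list of labelled [feature_window()] objects of identical
#'   length.
#' @return a `window_dataset` with elements `x` (array `n x len x 7`) and
#'   `labels` (character).
#' @export
window_dataset <- function(windows) {
  if (length(windows) == 0L)
    return(structure(list(x = array(0, c(0L, 0L, 7L)), labels = character()),
                     class = "window_dataset"))
  lens <- vapply(windows, function(w) nrow(w$data), integer(1L))
  if (length(unique(lens)) != 1L)
    stop("all windows must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  n <- length(windows); len <- lens[1L]
  x <- array(0, c(n, len, 7L),
             dimnames = list(NULL, NULL, colnames(windows[[1L]]$data)))
  for (i in seq_len(n)) x[i, , ] <- windows[[i]]$data
  structure(list(x = x,
                 labels = vapply(windows, function(w) w$label, character(1L))),
            class = "window_dataset")
}

#' Train the six-class LSTM window classifier
#'
#' Architecture: single LSTM hidden layer over the 7-channel window
#' sequence, dropout on the temporally mean-pooled hidden state, dense layer, softmax over
#' the six fall types (fixed class order, see [activity_labels()]).
#' Channels are standardised with training-set statistics stored in the
#' model. Optimisation is mini-batch Adam with gradient-norm clipping;
#' given the seed, training is deterministic and two runs produce identical
#' predictions.
#'
#' @param dataset a non-empty [window_dataset()] whose labels are all fall
#'   types.
#' @param config a [classifier_config()].
#' @return a `trained_classifier` carrying the weights, the configuration,
#'   the class order and the final training loss.
#' @export
train_classifier <- function(dataset, config = classifier_config()) {
  stopifnot(inherits(dataset, "window_dataset"),
            inherits(config, "classifier_config"))
  n <- dim(dataset$x)[1L]
  if (n == 0L) stop("cannot train on an empty dataset")
  bad <- setdiff(unique(dataset$labels), FALL_LABELS)
  if (length(bad))
    stop("training labels must be the six fall classes; found: ",
         paste(bad, collapse = ", "))
  len <- dim(dataset$x)[2L]; p <- dim(dataset$x)[3L]
  classes <- FALL_LABELS
  y <- match(dataset$labels, classes)
  y_onehot <- matrix(0, n, length(classes))
  y_onehot[cbind(seq_len(n), y)] <- 1

  # per-channel standardisation (constant channels left unscaled)
  mu <- apply(dataset$x, 3L, mean)
  sd_ <- apply(dataset$x, 3L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  x <- dataset$x
  for (ch in seq_len(p)) x[, , ch] <- (x[, , ch] - mu[ch]) / sd_[ch]

  model <- with_seed(config$seed, {
    par <- lstm_init(p, config$hidden_units, length(classes))
    st <- adam_state(par)
    step <- 0L
    loss <- NA_real_
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in batches) {
        xb <- x[bi, , , drop = FALSE]
        yb <- y_onehot[bi, , drop = FALSE]
        mask <- if (config$dropout_rate > 0) {
          keep <- 1 - config$dropout_rate
          matrix(stats::rbinom(length(bi) * config$hidden_units, 1L, keep),
                 length(bi), config$hidden_units) / keep
        } else NULL
        lg <- lstm_loss_grad(par, xb, yb, mask)
        step <- step + 1L
        upd <- adam_update(par, lg$grads, st, config$learning_rate, step)
        par <- upd$par; st <- upd$st
        loss <- lg$loss
      }
    }
    list(par = par, final_loss = loss)
  })

  structure(list(par = model$par, config = config, class_order = classes,
                 norm = list(mean = mu, sd = sd_), window_len = len,
                 input_dim = p, final_loss = model$final_loss),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(paste0("<trained_classifier> LSTM(%d) + dropout(%.2f) + ",
                     "dense -> softmax(%d classes), window %d x %d, ",
                     "final loss %.4f\n"),
              x$config$hidden_units, x$config$dropout_rate,
              length(x$class_order), x$window_len, x$input_dim, x$final_loss))
  invisible(x)
}

classifier_input <- function(model, windows) {
  if (inherits(windows, "feature_window")) windows <- list(windows)
  n <- length(windows)
  x <- array(0, c(n, model$window_len, model$input_dim))
  for (i in seq_len(n)) {
    d <- windows[[i]]$data
    if (nrow(d) != model$window_len)
      stop("window length ", nrow(d), " does not match the training length ",
           model$window_len)
    x[i, , ] <- d
  }
  for (ch in seq_len(model$input_dim))
    x[, , ch] <- (x[, , ch] - model$norm$mean[ch]) / model$norm$sd[ch]
  x
}

#' Class probabilities for feature windows
#'
#' Forward pass (no dropout) producing a six-element probability vector per
#' window: non-negative components summing to 1, in the fixed class order of
#' the six fall situations.
#'
#' @param model a [train_classifier()] model.
#' @param windows a [feature_window()] or list of them, each of the
#'   training window length.
#' @return named numeric vector (single window) or matrix with one row per
#'   window.
#' @export
predict_proba <- function(model, windows) {
  stopifnot(inherits(model, "trained_classifier"))
  single <- inherits(windows, "feature_window")
  x <- classifier_input(model, windows)
  h <- lstm_forward(model$par, x)$h
  logits <- sweep(h %*% model$par$W_out, 2L, model$par$b_out, "+")
  probs <- softmax_rows(logits)
  colnames(probs) <- model$class_order
  if (single) probs[1L, ] else probs
}

#' Hard class predictions for feature windows
#' @inheritParams predict_proba
#' @return character vector of fall-type labels.
#' @export
predict_class <- function(model, windows) {
  p <- predict_proba(model, windows)
  if (is.null(dim(p))) names(p)[which.max(p)]
  else colnames(p)[max.col(p, ties.method = "first")]
}

#' Save and load a trained classifier
#'
#' Single-file JSON checkpoint (format version 1) containing the weights,
#' the configuration, the normalisation statistics and the class order.
#'
#' @param model a [train_classifier()] model.
#' @param path file path.
#' @return `load_classifier` returns the restored model; predictions from
#'   the restored model are bit-identical to the original's.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  x <- list(format_version = 1L,
            config = unclass(model$config),
            class_order = model$class_order,
            window_len = model$window_len, input_dim = model$input_dim,
            final_loss = model$final_loss,
            norm = model$norm,
            dims = list(W = dim(model$par$W), W_out = dim(model$par$W_out),
                        p = model$par$p, H = model$par$H, C = model$par$C),
            weights = list(W = as.vector(model$par$W), b = model$par$b,
                           W_out = as.vector(model$par$W_out),
                           b_out = model$par$b_out))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(as.integer(x$format_version), 1L))
    stop("unsupported checkpoint format version: ", x$format_version)
  par <- list(W = matrix(x$weights$W, x$dims$W[1L], x$dims$W[2L]),
              b = x$weights$b,
              W_out = matrix(x$weights$W_out, x$dims$W_out[1L],
                             x$dims$W_out[2L]),
              b_out = x$weights$b_out,
              p = x$dims$p, H = x$dims$H, C = x$dims$C)
  structure(list(par = par, config = do.call(classifier_config,
                                             as.list(x$config)),
                 class_order = x$class_order,
                 norm = list(mean = x$norm$mean, sd = x$norm$sd),
                 window_len = x$window_len, input_dim = x$input_dim,
                 final_loss = x$final_loss),
            class = "trained_classifier")
}
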