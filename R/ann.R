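# Feedforward workload classifier: multilayer perceptron with tanh hidden
# units and a 2-unit softmax output, trained by scaled conjugate gradient
# on cross-entropy with an early-stopping train/validation split and
# random restarts.

NET_CLASSES <- c("high", "low")

#' Network and training configuration
#'
#' Defaults follow the reference workload classifier: five hidden layers,
#' scaled-conjugate-gradient training, early stopping, 50% of the training
#' vectors used directly for weight updates (the rest form the validation
#' set), and 10 random restarts of which the best by validation loss is
#' kept.  The width of the hidden layers is configurable (a five-unit
#' single hidden layer is expressible as `hidden_layers = 5`).
#'
#' @param hidden_layers integer vector of hidden-layer widths.
#' @param max_iters maximum optimizer iterations per restart.
#' @param early_stop_patience accepted steps without validation
#'   improvement before training stops.
#' @param train_fraction fraction of training vectors used directly for
#'   weight updates; the remainder is the early-stopping validation set.
#' @param n_restarts number of random restarts.
#' @param seed training seed; (features, config) fully determine the net.
#' @return object of class `net_config`.
#' @export
net_config <- function(hidden_layers = rep(10L, 5), max_iters = 200L,
                       early_stop_patience = 6L, train_fraction = 0.5,
                       n_restarts = 10L, seed = 1L) {
  if (length(hidden_layers) < 1 || any(hidden_layers < 1)) {
    abort_invalid("at least one hidden layer of width >= 1 is required")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_invalid("train_fraction must be in (0, 1)")
  }
  if (n_restarts < 1) abort_invalid("n_restarts must be >= 1")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 max_iters = as.integer(max_iters),
                 early_stop_patience = as.integer(early_stop_patience),
                 train_fraction = train_fraction,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "net_config")
}

layer_dims <- function(n_in, config) {
  c(n_in, config$hidden_layers, length(NET_CLASSES))
}

init_weights <- function(dims) {
  # Scaled Gaussian init: SD 1/sqrt(fan_in) per layer.
  lapply(seq_len(length(dims) - 1), function(l) {
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                 1 / sqrt(dims[l])),
                    nrow = dims[l], ncol = dims[l + 1]),
         b = stats::rnorm(dims[l + 1], 0, 0.01))
  })
}

pack_weights <- function(wl) {
  unlist(lapply(wl, function(l) c(as.numeric(l$W), l$b)))
}

unpack_weights <- function(v, dims) {
  out <- vector("list", length(dims) - 1)
  pos <- 0L
  for (l in seq_len(length(dims) - 1)) {
    nw <- dims[l] * dims[l + 1]
    out[[l]] <- list(
      W = matrix(v[pos + seq_len(nw)], nrow = dims[l], ncol = dims[l + 1]),
      b = v[pos + nw + seq_len(dims[l + 1])])
    pos <- pos + nw + dims[l + 1]
  }
  out
}

forward_pass <- function(wl, x, keep_activations = FALSE) {
  nl <- length(wl)
  acts <- if (keep_activations) vector("list", nl + 1) else NULL
  a <- x
  if (keep_activations) acts[[1]] <- a
  for (l in seq_len(nl - 1)) {
    a <- tanh(sweep(a %*% wl[[l]]$W, 2, wl[[l]]$b, "+"))
    if (keep_activations) acts[[l + 1]] <- a
  }
  z <- sweep(a %*% wl[[nl]]$W, 2, wl[[nl]]$b, "+")
  z <- z - apply(z, 1, max)                    # numerically stable softmax
  p <- exp(z)
  p <- p / rowSums(p)
  if (keep_activations) list(p = p, acts = acts) else p
}

cross_entropy <- function(p, y) {
  -mean(log(pmax(rowSums(p * y), 1e-12)))
}

ce_gradient <- function(wl, x, y) {
  nl <- length(wl)
  fw <- forward_pass(wl, x, keep_activations = TRUE)
  n <- nrow(x)
  delta <- (fw$p - y) / n
  grads <- vector("list", nl)
  for (l in nl:1) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(wl[[l]]$W)) * (1 - fw$acts[[l]]^2)
    }
  }
  grads
}

one_hot <- function(labels) {
  if (!all(labels %in% NET_CLASSES)) {
    abort_invalid("labels must be 'high' or 'low'")
  }
  y <- matrix(0, nrow = length(labels), ncol = length(NET_CLASSES),
              dimnames = list(NULL, NET_CLASSES))
  y[cbind(seq_along(labels), match(labels, NET_CLASSES))] <- 1
  y
}

#' Train the workload classifier
#'
#' Fits the feature normalizer on the supplied rows, then for each random
#' restart draws a class-stratified train/validation split of the
#' training vectors, optimizes the network weights on cross-entropy by
#' scaled conjugate gradient with early stopping on the validation loss,
#' and returns the restart with the best validation loss.  Fully
#' deterministic given `config$seed`.
#'
#' @param features [extract_features()] output containing both classes.
#' @param config [net_config()].
#' @param min_per_class minimum training vectors required per class.
#' @param inits optional list (one element per restart) of layer weight
#'   lists overriding the random initialization; intended for
#'   equivariance testing.
#' @return object of class `workload_net` with elements `weights`
#'   (per-layer `W`, `b`), `normalizer`, `config`, `dims` and
#'   `training_meta` (chosen restart, validation loss, iterations).
#' @export
train_workload_net <- function(features, config = net_config(),
                               min_per_class = 10L, inits = NULL) {
  x_raw <- features$matrix
  labels <- features$labels
  counts <- table(factor(labels, levels = NET_CLASSES))
  if (any(counts == 0)) {
    abort_invalid("training data must contain both workload classes")
  }
  if (any(counts < min_per_class)) {
    abort_invalid("need at least %d training vectors per class (have %s)",
                  min_per_class,
                  paste(sprintf("%s: %d", names(counts), counts),
                        collapse = ", "))
  }
  normalizer <- fit_normalizer(features)
  x <- apply_normalizer(normalizer, features)$matrix
  y <- one_hot(labels)
  dims <- layer_dims(ncol(x), config)

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    # Stratified split drawn before the weights so the selected rows
    # depend only on the labels and the restart seed.
    split <- with_seed(derive_seed(config$seed, r, 1), {
      tr <- integer(0)
      for (cl in NET_CLASSES) {
        idx <- which(labels == cl)
        n_tr <- max(1L, round(length(idx) * config$train_fraction))
        tr <- c(tr, sample(idx, n_tr))
      }
      sort(tr)
    })
    val <- setdiff(seq_len(nrow(x)), split)
    if (length(val) == 0) val <- split
    wl0 <- if (!is.null(inits)) {
      inits[[r]]
    } else {
      with_seed(derive_seed(config$seed, r, 2), init_weights(dims))
    }
    x_tr <- x[split, , drop = FALSE]; y_tr <- y[split, , drop = FALSE]
    x_va <- x[val, , drop = FALSE];   y_va <- y[val, , drop = FALSE]
    fn <- function(w) cross_entropy(forward_pass(unpack_weights(w, dims),
                                                 x_tr), y_tr)
    gr <- function(w) pack_weights(ce_gradient(unpack_weights(w, dims),
                                               x_tr, y_tr))
    mon <- function(w, k) cross_entropy(forward_pass(unpack_weights(w, dims),
                                                     x_va), y_va)
    res <- scg_minimize(pack_weights(wl0), fn, gr,
                        max_iters = config$max_iters, monitor = mon,
                        patience = config$early_stop_patience)
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- r
    }
  }
  structure(list(weights = unpack_weights(best$w, dims),
                 normalizer = normalizer,
                 config = config,
                 dims = dims,
                 training_meta = list(restart = best$restart,
                                      validation_loss = best$value,
                                      iterations = best$iters)),
            class = "workload_net")
}

#' @export
print.workload_net <- function(x, ...) {
  cat(sprintf(
    "<workload_net> %s; restart %d, validation loss %.4g (%d iters)\n",
    paste(x$dims, collapse = "-"), x$training_meta$restart,
    x$training_meta$validation_loss, x$training_meta$iterations))
  invisible(x)
}

#' Classify epochs with a trained workload net
#'
#' Applies the net's stored normalizer, runs the forward pass and assigns
#' each epoch to the class with the maximum output; an exact output tie
#' goes to "high" (consistent with the ensemble's tie rule).
#'
#' @param object [train_workload_net()] output.
#' @param features feature set whose columns match the net input width.
#' @param ... unused.
#' @return character vector of "high"/"low", one per epoch.
#' @export
predict.workload_net <- function(object, features, ...) {
  x <- features$matrix
  if (ncol(x) != object$dims[1]) {
    abort_invalid("feature count %d does not match network input width %d",
                  ncol(x), object$dims[1])
  }
  xn <- apply_normalizer(object$normalizer, features)$matrix
  p <- forward_pass(object$weights, xn)
  # Output columns follow NET_CLASSES order: 1 = high, 2 = low.
  ifelse(p[, 1] >= p[, 2], "high", "low")
}

#' Classification accuracy
#'
#' Fraction of epochs whose predicted class matches the true class.
#'
#' @param predicted,truth equal-length class vectors.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    abort_invalid("predicted and truth must be non-empty and equal length")
  }
  mean(predicted == truth)
}
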