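#' Configuration of the portrait convolutional classifier
#'
#' Two valid-padding convolutional layers (32 filters of 3x3, then 16
#' filters of 2x2, both ReLU), a 2x2 max-pooling layer (floor semantics; a
#' dimension shorter than the window is pooled as a single region), a
#' flatten, a ReLU dense layer and a sigmoid output unit, trained full-batch
#' with Adam on binary cross-entropy.
#'
#' @param conv1_filters,conv1_kernel First convolution: filters and kernel.
#' @param conv2_filters,conv2_kernel Second convolution: filters and kernel.
#' @param pool Max-pooling window.
#' @param hidden_units Width of the dense hidden layer.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (full-batch updates).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(conv1_filters = 32, conv1_kernel = c(3, 3),
                       conv2_filters = 16, conv2_kernel = c(2, 2),
                       pool = c(2, 2), hidden_units = 16,
                       learning_rate = 1e-3, epochs = 500, seed = 1) {
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (any(c(conv1_kernel, conv2_kernel, pool) < 1)) abort("Kernel and pool sizes must be >= 1.")
  if (conv1_filters < 1 || conv2_filters < 1 || hidden_units < 1) {
    abort("Layer widths must be >= 1.")
  }
  structure(
    list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
         conv2_filters = conv2_filters, conv2_kernel = conv2_kernel,
         pool = pool, hidden_units = hidden_units,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

# Layer output shapes under valid padding; pooling floors, but a dimension
# shorter than the window is kept as one region.
cnn_shapes <- function(config, input_shape) {
  h0 <- input_shape[1]; w0 <- input_shape[2]
  h1 <- h0 - config$conv1_kernel[1] + 1; w1 <- w0 - config$conv1_kernel[2] + 1
  h2 <- h1 - config$conv2_kernel[1] + 1; w2 <- w1 - config$conv2_kernel[2] + 1
  ph <- if (h2 >= config$pool[1]) h2 %/% config$pool[1] else if (h2 >= 1) 1L else 0L
  pw <- if (w2 >= config$pool[2]) w2 %/% config$pool[2] else if (w2 >= 1) 1L else 0L
  list(input = c(h0, w0), conv1 = c(h1, w1), conv2 = c(h2, w2),
       pool = c(ph, pw), flatten = ph * pw * config$conv2_filters)
}

shape_trace <- function(shapes) {
  paste(sprintf("%s: %s", names(shapes)[1:4],
                vapply(shapes[1:4], function(s) paste(s, collapse = "x"), character(1))),
        collapse = " -> ")
}

# Thin wrappers over the compiled forward/backward core (src/cnn_core.cpp).
# One full-batch gradient step: returns predicted probabilities and the
# gradient of the mean binary cross-entropy w.r.t. every parameter.
cnn_step <- function(params, X, y, config, shapes) {
  n <- dim(X)[1]
  x_mat <- X
  dim(x_mat) <- c(n, prod(shapes$input))
  out <- cnn_step_cpp(params$W1, params$b1, params$W2, params$b2,
                      params$W3, params$b3, params$W4, params$b4,
                      x_mat, y, n, shapes$input[1], shapes$input[2],
                      config$conv1_kernel[1], config$conv1_kernel[2],
                      config$conv2_kernel[1], config$conv2_kernel[2],
                      config$pool[1], config$pool[2])
  grads <- list(W1 = out$W1, b1 = as.numeric(out$b1),
                W2 = out$W2, b2 = as.numeric(out$b2),
                W3 = out$W3, b3 = as.numeric(out$b3),
                W4 = out$W4, b4 = as.numeric(out$b4))
  list(p = as.numeric(out$p), grads = grads)
}

cnn_infer <- function(params, X, config, shapes) {
  n <- dim(X)[1]
  x_mat <- X
  dim(x_mat) <- c(n, prod(shapes$input))
  as.numeric(cnn_infer_cpp(params$W1, params$b1, params$W2, params$b2,
                           params$W3, params$b3, params$W4, params$b4,
                           x_mat, n, shapes$input[1], shapes$input[2],
                           config$conv1_kernel[1], config$conv1_kernel[2],
                           config$conv2_kernel[1], config$conv2_kernel[2],
                           config$pool[1], config$pool[2])$p)
}

cnn_loss <- function(p, y) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_cnn_params <- function(config, input_shape) {
  shp <- cnn_shapes(config, input_shape)
  if (any(unlist(shp[c("conv1", "conv2", "pool")]) < 1)) {
    abort(sprintf("Input %s is too small for the layer stack (%s).",
                  paste(input_shape, collapse = "x"), shape_trace(shp)))
  }
  k1 <- prod(config$conv1_kernel)
  k2 <- prod(config$conv2_kernel) * config$conv1_filters
  he <- function(n_in, n_out) {
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  }
  with_seed(substream_seed(config$seed, "cnn_init"), list(
    W1 = he(k1, config$conv1_filters), b1 = rep(0, config$conv1_filters),
    W2 = he(k2, config$conv2_filters), b2 = rep(0, config$conv2_filters),
    W3 = he(shp$flatten, config$hidden_units), b3 = rep(0, config$hidden_units),
    W4 = he(config$hidden_units, 1), b4 = 0
  ))
}

#' Build an untrained portrait CNN
#'
#' Validates that the layer stack fits the input (valid padding throughout)
#' and initialises the weights. An 8x10 portrait flows
#' 8x10 -> 6x8 -> 5x7 -> 2x3, flattening to 96 features.
#'
#' @param config A [cnn_config()].
#' @param input_shape Portrait dimensions, `c(rows, cols)`.
#' @return Object of class `cnn_model` with `params`, `config`, `shapes`.
#' @export
build_cnn <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"))
  shapes <- cnn_shapes(config, input_shape)
  if (any(unlist(shapes[c("conv1", "conv2", "pool")]) < 1)) {
    abort(sprintf("Input %s too small for the layer stack: %s.",
                  paste(input_shape, collapse = "x"), shape_trace(shapes)))
  }
  params <- init_cnn_params(config, input_shape)
  structure(list(params = params, config = config, shapes = shapes),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model>", shape_trace(x$shapes), "| flatten", x$shapes$flatten,
      "-> dense", x$config$hidden_units, "-> sigmoid\n")
  invisible(x)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the portrait CNN
#'
#' Full-batch Adam minimisation of binary cross-entropy for exactly
#' `config$epochs` epochs; the loss and training-accuracy traces are
#' recorded per epoch. Pure-R implementation, deterministic under the
#' configuration seed.
#'
#' @param portraits A `portrait_stack` (`[sample, gene, population]`) or a
#'   plain 3-d array.
#' @param labels Binary class labels (advanced = positive), one per sample.
#' @param config A [cnn_config()].
#' @return Object of class `cnn_fit`: `params`, `config`, `shapes`,
#'   `loss_trace`, `accuracy_trace`.
#' @export
train_cnn <- function(portraits, labels, config = cnn_config()) {
  dims <- dim(portraits)
  if (length(dims) != 3) abort("`portraits` must be a 3-d array [sample, row, col].")
  assert_binary_labels(labels, dims[1])
  y <- label_to_binary(labels)
  if (min(table(y)) < 2) abort("Need at least 2 samples per class.")
  model <- build_cnn(config, dims[2:3])
  params <- model$params
  shapes <- model$shapes
  X <- array(as.numeric(portraits), dims)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  loss_trace <- accuracy_trace <- numeric(config$epochs)
  for (t in seq_len(config$epochs)) {
    step <- cnn_step(params, X, y, config, shapes)
    loss <- cnn_loss(step$p, y)
    if (!is.finite(loss)) {
      abort(sprintf("Training diverged (non-finite loss at epoch %d); try a smaller learning rate than %g.",
                    t, config$learning_rate))
    }
    loss_trace[t] <- loss
    accuracy_trace[t] <- mean((step$p >= 0.5) == y)
    upd <- adam_step(params, step$grads, state, config$learning_rate, t)
    params <- upd$params
    state <- upd$state
  }
  structure(list(params = params, config = config, shapes = shapes,
                 loss_trace = loss_trace,
                 accuracy_trace = accuracy_trace,
                 input_shape = dims[2:3]),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  ep <- x$config$epochs
  cat(sprintf("<cnn_fit> %d epochs | final loss %.4f | training accuracy %.3f\n",
              ep, x$loss_trace[ep], x$accuracy_trace[ep]))
  invisible(x)
}

#' @rdname train_cnn
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @method glance cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  ep <- x$config$epochs
  tibble(epochs = ep, final_loss = x$loss_trace[ep],
         final_accuracy = x$accuracy_trace[ep],
         flatten_length = x$shapes$flatten)
}

#' Predict advanced-class probabilities from portraits
#'
#' @param object A `cnn_fit`.
#' @param portraits Portrait array with the training input shape.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.cnn_fit <- function(object, portraits, ...) {
  dims <- dim(portraits)
  if (length(dims) != 3 || !all(dims[2:3] == object$input_shape)) {
    abort(sprintf("Portrait shape %s does not match the training shape %s.",
                  paste(dims[-1], collapse = "x"),
                  paste(object$input_shape, collapse = "x")))
  }
  X <- array(as.numeric(portraits), dims)
  p <- cnn_infer(object$params, X, object$config, object$shapes)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
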