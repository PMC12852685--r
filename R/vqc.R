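#' Quantum dropout configuration
#'
#' Per optimization step, each ansatz layer is independently selected for
#' dropout with probability `p_layer`; within a selected layer each trainable
#' rotation is independently removed with probability `p_gate`, so the
#' marginal probability of any given rotation being dropped is
#' `p_layer * p_gate` (0.01 at the defaults). The mask is resampled at every
#' step and dropout is disabled at evaluation.
#'
#' @param p_layer Layer selection probability (default 0.1).
#' @param p_gate Within-layer gate removal probability (default 0.1).
#' @return A `dropout_config` object.
#' @export
dropout_config <- function(p_layer = 0.1, p_gate = 0.1) {
  stopifnot(p_layer >= 0, p_layer <= 1, p_gate >= 0, p_gate <= 1)
  structure(list(p_layer = p_layer, p_gate = p_gate),
            class = "dropout_config")
}

#' Sample a quantum-dropout mask
#'
#' Uses the current RNG stream (seed it with `set.seed()` or let the training
#' loop manage it).
#'
#' @param dropout A [dropout_config()].
#' @param config The [ansatz_config()] whose slot layout the mask addresses.
#' @return A tibble with columns `layer` (1-based) and `slot` (0-based
#'   trainable slot index); zero rows when nothing is dropped.
#' @export
sample_dropout_mask <- function(dropout, config) {
  per <- slots_per_layer(config$n_qubits, config$second_row)
  selected <- which(runif(config$layers) < dropout$p_layer)
  layers <- integer(0)
  slots <- integer(0)
  for (l in selected) {
    dropped <- which(runif(per) < dropout$p_gate) - 1L
    if (length(dropped) > 0) {
      layers <- c(layers, rep(l, length(dropped)))
      slots <- c(slots, (l - 1L) * per + dropped)
    }
  }
  tibble::new_tibble(list(layer = layers, slot = slots),
                     nrow = length(slots))
}

# remove the masked rotations from a model circuit
mask_circuit <- function(circuit, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(circuit)
  keep <- is.na(circuit$gates$param) | !(circuit$gates$param %in% mask$slot)
  qcircuit(circuit$n_qubits, circuit$gates[keep, ], circuit$n_slots)
}

# Batched raw circuit output: sum over qubits of <Z_q> for each record.
# X feeds feature-bound gates (angle encoding); `inits` is a 2^n x B complex
# matrix of pre-encoded initial states (hybrid encoding), or NULL.
vqc_sumz <- function(circuit, theta, X, inits = NULL) {
  feats <- circuit$gates$feature
  if (any(!is.na(feats)) && max(feats, na.rm = TRUE) >= ncol(X)) {
    abort("design matrix has fewer columns than the circuit's bound features")
  }
  cpp_batch_sumz(circuit$n_qubits, circuit_matrix(circuit),
                 as.double(theta), X, inits)
}

#' Predicted disease probability of a VQC
#'
#' The forward pass measures every qubit's Pauli-Z expectation, sums them,
#' adds the classical bias and applies the sigmoid:
#' `p = sigmoid(sum_i <Z_i> + bias)`.
#'
#' @param config An [ansatz_config()].
#' @param params A `vqc_params` list from [init_params()].
#' @param x A single record: for angle encoding a length-`N` vector in
#'   `[0, 2*pi]`; for the hybrid encoding a length-15 vector (5 standardized
#'   continuous values followed by 10 categorical bits).
#' @param mask Optional dropout mask from [sample_dropout_mask()]; masked
#'   rotations are omitted from the circuit.
#' @return Probability in (0, 1).
#' @export
predict_proba <- function(config, params, x, mask = NULL) {
  if (length(params$theta) != n_circuit_params(config)) {
    abort("params length does not match the configuration")
  }
  circuit <- mask_circuit(build_model_circuit(config), mask)
  if (config$encoding == "angle") {
    if (length(x) != config$n_qubits) {
      abort("angle encoding needs one feature per qubit")
    }
    z <- vqc_sumz(circuit, params$theta, matrix(x, nrow = 1))
  } else {
    st <- hybrid_encode(x[1:5], x[6:15])
    z <- vqc_sumz(circuit, params$theta, matrix(0, 1, 0),
                  matrix(as.complex(st), ncol = 1))
  }
  as.numeric(sigmoid(z + params$bias))
}

#' Assign a class label from a probability
#'
#' Labels follow the `{-1, 1}` convention: `p > 0.5` maps to `1`, anything
#' else (including the `p = 0.5` tie) to `-1`.
#'
#' @param p Probability vector.
#' @return Vector in `{-1, 1}`.
#' @export
classify <- function(p) ifelse(p > 0.5, 1, -1)

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over the batch, with probabilities
#' clipped to `[eps, 1-eps]` so the loss stays finite.
#'
#' @param y01 Targets in `{0, 1}`.
#' @param p Predicted probabilities.
#' @param eps Clipping constant (default 1e-12).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(y01, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y01 * log(p) + (1 - y01) * log(1 - p))
}

#' Parameter-shift gradient of the batch loss
#'
#' Each circuit parameter's partial derivative of `sum_i <Z_i>` is obtained
#' from two exact circuit evaluations at `theta_k +/- pi/2` combined as half
#' their difference (the parameter-shift rule for Pauli rotations), then
#' chained analytically through the sigmoid and the binary cross-entropy
#' (whose derivative in the pre-sigmoid output is `p - y`). The bias partial
#' is analytic. Masked (dropped) rotations receive zero gradient.
#'
#' @param config An [ansatz_config()].
#' @param params A `vqc_params` list.
#' @param X Batch design matrix (one row per record; angle features, or a
#'   zero-column matrix when `inits` carries hybrid-encoded states).
#' @param y01 Batch targets in `{0, 1}`.
#' @param mask Optional dropout mask.
#' @param inits Optional `2^N x B` complex matrix of initial states.
#' @return List with `theta` (gradient vector), `bias` (scalar) and `loss`.
#' @export
parameter_shift_gradient <- function(config, params, X, y01, mask = NULL,
                                     inits = NULL) {
  circuit <- mask_circuit(build_model_circuit(config), mask)
  z <- vqc_sumz(circuit, params$theta, X, inits)
  p <- sigmoid(z + params$bias)
  resid <- (p - y01) / length(y01)
  g <- cpp_batch_grad(circuit$n_qubits, circuit_matrix(circuit),
                      as.double(params$theta), X, inits, resid)
  list(theta = as.numeric(g), bias = sum(resid), loss = bce_loss(y01, p))
}

#' Training schedule for variational quantum classifiers
#'
#' Adam with a decaying learning rate: the rate starts at `lr0` and is
#' multiplied by `lr_factor` whenever the monitored training cost has not
#' decreased (by more than `tol`) for `lr_patience` epochs; training stops
#' after `stop_patience` non-improving epochs (or at `max_epochs`). Each
#' epoch draws `batches` batches of `batch_size` records.
#'
#' @param lr0 Initial learning rate.
#' @param lr_factor Multiplicative decay factor.
#' @param lr_patience Epochs without improvement before decaying.
#' @param stop_patience Epochs without improvement before stopping.
#' @param batches,batch_size Batching scheme (default 10 x 64).
#' @param max_epochs Hard epoch cap.
#' @param tol Minimum decrease counted as improvement.
#' @param seed Seed for initialization, batching and dropout masks.
#' @return A `qtrain_config` list.
#' @export
qtrain_config <- function(lr0 = 0.01, lr_factor = 0.5, lr_patience = 50,
                          stop_patience = 100, batches = 10, batch_size = 64,
                          max_epochs = 1000, tol = 1e-8, seed = 1L) {
  stopifnot(lr_patience > 0, stop_patience > 0, batch_size > 0, batches > 0,
            max_epochs > 0)
  structure(
    list(lr0 = lr0, lr_factor = lr_factor, lr_patience = lr_patience,
         stop_patience = stop_patience, batches = batches,
         batch_size = batch_size, max_epochs = max_epochs, tol = tol,
         seed = as.integer(seed)),
    class = "qtrain_config"
  )
}

# materialize hybrid-encoded initial states as a 2^13 x B complex matrix
hybrid_init_states <- function(data, rows) {
  vapply(rows, function(i) {
    as.complex(hybrid_encode(data$amplitude_block[i, ],
                             data$basis_block[i, ]))
  }, complex(2^13))
}

#' Train a variational quantum classifier
#'
#' Runs the full protocol: small-angle initialization, per-epoch minibatch
#' Adam updates from parameter-shift gradients, learning-rate decay and
#' early stopping on the training cost, optional quantum dropout (mask
#' resampled every optimization step, disabled at evaluation), and
#' best-so-far parameter tracking. The monitored cost is the full
#' training-set binary cross-entropy evaluated with dropout off.
#'
#' @param config An [ansatz_config()].
#' @param data An `encoded_cohort` from [encode_cohort()].
#' @param tcfg A [qtrain_config()].
#' @param dropout Optional [dropout_config()].
#' @param train_rows Optional subset of `data$train_index` to train on (used
#'   by the sample-complexity study); defaults to the full training
#'   partition.
#' @param params0 Optional explicit initial `vqc_params`.
#' @return A `vqc_fit` with the best parameters, the per-epoch `history`
#'   tibble (`epoch`, `train_loss`, `test_accuracy`, `lr`), and bookkeeping
#'   fields.
#' @export
train_vqc <- function(config, data, tcfg = qtrain_config(), dropout = NULL,
                      train_rows = NULL, params0 = NULL) {
  train_rows <- train_rows %||% data$train_index
  if (length(train_rows) == 0) abort("empty training set")
  test_rows <- data$test_index

  if (config$encoding == "angle") {
    X_train <- data$angle_matrix[train_rows, , drop = FALSE]
    X_test <- data$angle_matrix[test_rows, , drop = FALSE]
    I_train <- I_test <- NULL
  } else {
    X_train <- matrix(0, length(train_rows), 0)
    X_test <- matrix(0, length(test_rows), 0)
    I_train <- hybrid_init_states(data, train_rows)
    I_test <- hybrid_init_states(data, test_rows)
  }
  y_train <- data$labels01[train_rows]
  y_test_pm <- data$labels_pm[test_rows]

  params <- params0 %||% init_params(config, seed = tcfg$seed)
  circuit <- build_model_circuit(config)
  n_par <- circuit$n_slots

  withr::local_seed(tcfg$seed + 1L)
  opt_t <- adam_init(n_par)
  opt_b <- adam_init(1L)
  lr <- tcfg$lr0
  best <- list(loss = Inf, params = params)
  since_improve <- 0L
  since_lr <- 0L
  hist <- vector("list", tcfg$max_epochs)
  epochs_run <- 0L

  eval_loss <- function(params) {
    z <- vqc_sumz(circuit, params$theta, X_train, I_train)
    bce_loss(y_train, sigmoid(z + params$bias))
  }
  eval_test_acc <- function(params) {
    if (length(test_rows) == 0) return(NA_real_)
    z <- vqc_sumz(circuit, params$theta, X_test, I_test)
    mean(classify(sigmoid(z + params$bias)) == y_test_pm)
  }

  for (epoch in seq_len(tcfg$max_epochs)) {
    batches <- make_batches(length(train_rows), tcfg$batches, tcfg$batch_size)
    for (b in batches) {
      mask <- if (!is.null(dropout)) sample_dropout_mask(dropout, config)
      g <- parameter_shift_gradient(
        config, params,
        X_train[b, , drop = FALSE], y_train[b], mask = mask,
        inits = if (is.null(I_train)) NULL else I_train[, b, drop = FALSE]
      )
      opt_t <- adam_step(opt_t, g$theta, lr)
      params$theta <- params$theta + opt_t$delta
      opt_b <- adam_step(opt_b, g$bias, lr)
      params$bias <- params$bias + opt_b$delta
    }
    loss <- eval_loss(params)
    acc <- eval_test_acc(params)
    epochs_run <- epoch
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = loss,
                            test_accuracy = acc, lr = lr)
    if (best$loss - loss > tcfg$tol) {
      best <- list(loss = loss, params = params)
      since_improve <- 0L
      since_lr <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= tcfg$lr_patience) {
        lr <- lr * tcfg$lr_factor
        since_lr <- 0L
      }
      if (since_improve >= tcfg$stop_patience) break
    }
  }

  history <- dplyr::bind_rows(hist[seq_len(epochs_run)])
  structure(
    list(config = config, params = best$params, train_loss = best$loss,
         test_accuracy = eval_test_acc(best$params), history = history,
         epochs = epochs_run, dropout = dropout, tcfg = tcfg,
         n_train = length(train_rows)),
    class = "vqc_fit"
  )
}

#' @export
print.vqc_fit <- function(x, ...) {
  cat(sprintf(
    "<vqc_fit: %s encoding, %d layer%s%s | %d epochs, train loss %.4f, test accuracy %s>\n",
    x$config$encoding, x$config$layers, if (x$config$layers > 1) "s" else "",
    if (x$config$reuploading) " (re-uploading)" else "",
    x$epochs, x$train_loss,
    if (is.na(x$test_accuracy)) "NA" else sprintf("%.3f", x$test_accuracy)
  ))
  invisible(x)
}

#' Gradient-magnitude diagnostic at initialization
#'
#' Trains nothing: draws `n_inits` random initializations, computes the
#' first-epoch parameter-shift gradient of the training loss for each, and
#' reports magnitude statistics. Useful as a barren-plateau check — a mean
#' absolute gradient well above numerical noise indicates a trainable
#' landscape.
#'
#' @param config An [ansatz_config()].
#' @param data An `encoded_cohort`.
#' @param n_inits Number of random initializations.
#' @param seed Integer seed.
#' @param batch_size Records used per gradient evaluation.
#' @return List with `mean_abs_grad`, `var_abs_grad` and the per-init tibble
#'   `per_init`.
#' @export
gradient_statistics <- function(config, data, n_inits = 10, seed = 1L,
                                batch_size = 64) {
  withr::local_seed(seed)
  rows <- data$train_index[seq_len(min(batch_size, length(data$train_index)))]
  X <- if (config$encoding == "angle") {
    data$angle_matrix[rows, , drop = FALSE]
  } else {
    matrix(0, length(rows), 0)
  }
  inits <- if (config$encoding == "angle") NULL else hybrid_init_states(data, rows)
  y <- data$labels01[rows]
  per <- purrr::map_dfr(seq_len(n_inits), function(i) {
    params <- init_params(config, seed = seed + i)
    g <- parameter_shift_gradient(config, params, X, y, inits = inits)
    tibble(init = i, mean_abs = mean(abs(g$theta)), max_abs = max(abs(g$theta)))
  })
  list(mean_abs_grad = mean(per$mean_abs), var_abs_grad = stats::var(per$mean_abs),
       per_init = per)
}

#' @export
tidy.vqc_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = paste0("theta[", seq_along(x$params$theta) - 1, "]"),
           estimate = x$params$theta),
    tibble(term = "bias", estimate = x$params$bias)
  )
}

#' @export
glance.vqc_fit <- function(x, ...) {
  tibble(
    encoding = x$config$encoding, layers = x$config$layers,
    reuploading = x$config$reuploading,
    dropout = !is.null(x$dropout),
    n_params = length(x$params$theta) + 1L,
    n_train = x$n_train, epochs = x$epochs,
    train_loss = x$train_loss, test_accuracy = x$test_accuracy
  )
}

#' Plot a training history
#'
#' Training loss and test accuracy against the epoch.
#'
#' @param object A `vqc_fit` or `nn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vqc_fit <- function(object, ...) plot_history(object$history)

plot_history <- function(history) {
  long <- tidyr::pivot_longer(
    history, c("train_loss", "test_accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
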