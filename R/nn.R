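#' Classical feedforward network configuration
#'
#' The baseline family: a perceptron (no hidden layers, a single affine map
#' into a sigmoid) or a feedforward network with leaky-ReLU hidden layers and
#' a sigmoid output. The benchmark grid restricts hidden widths to multiples
#' of 4 between 4 and 64 with non-increasing widths; `nn_config` itself
#' accepts any positive widths so that toy networks can be built in examples
#' and tests.
#'
#' @param hidden Integer vector of hidden-layer widths (empty = perceptron).
#' @param dropout Use dropout on hidden activations.
#' @param dropout_rate Drop probability (default 0.2).
#' @param leaky_alpha Negative-slope coefficient of the leaky ReLU.
#' @return An `nn_config` object.
#' @export
nn_config <- function(hidden = integer(0), dropout = FALSE,
                      dropout_rate = 0.2, leaky_alpha = 0.1) {
  hidden <- as.integer(hidden)
  if (length(hidden) > 0 && any(hidden < 1)) abort("widths must be positive")
  structure(
    list(hidden = hidden, dropout = dropout, dropout_rate = dropout_rate,
         leaky_alpha = leaky_alpha),
    class = "nn_config"
  )
}

#' @export
print.nn_config <- function(x, ...) {
  arch <- if (length(x$hidden) == 0) "perceptron" else
    paste(x$hidden, collapse = "-")
  cat(sprintf("<nn_config: %s%s>\n", arch,
              if (x$dropout) sprintf(", dropout %.2g", x$dropout_rate) else ""))
  invisible(x)
}

#' Leaky rectified linear unit
#'
#' `z` for `z >= 0`, `alpha * z` otherwise.
#'
#' @param z Numeric input.
#' @param alpha Negative slope (default 0.1).
#' @return Numeric of the same shape.
#' @export
leaky_relu <- function(z, alpha = 0.1) ifelse(z >= 0, z, alpha * z)

#' Initialize network parameters
#'
#' Networks with hidden layers draw weights from the He normal distribution
#' (`sd = sqrt(2 / fan_in)`) and biases from Xavier-uniform bounds
#' (`+/- sqrt(6 / (fan_in + fan_out))`). The perceptron draws weights from
#' the He uniform distribution (`+/- sqrt(6 / fan_in)`) with all biases 0.
#'
#' @param config An [nn_config()].
#' @param input_width Number of input features.
#' @param seed Integer seed.
#' @return An `nn_params` list with weight matrices `W` (fan_in x fan_out),
#'   bias vectors `b`, and the config.
#' @export
init_nn <- function(config, input_width, seed = 1L) {
  withr::local_seed(seed)
  widths <- c(input_width, config$hidden, 1L)
  L <- length(widths) - 1L
  perceptron <- length(config$hidden) == 0
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    fan_out <- widths[l + 1]
    if (perceptron) {
      lim <- sqrt(6 / fan_in)
      W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[l]] <- numeric(fan_out)
    } else {
      W[[l]] <- matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                       fan_in, fan_out)
      lim <- sqrt(6 / (fan_in + fan_out))
      b[[l]] <- runif(fan_out, -lim, lim)
    }
  }
  structure(list(W = W, b = b, config = config,
                 input_width = as.integer(input_width)),
            class = "nn_params")
}

# Forward pass keeping intermediates for backpropagation. Dropout (inverted
# scaling, so activations keep their expectation) applies to hidden
# activations only, and only when active; masks are drawn from the current
# RNG stream.
nn_forward_full <- function(params, X, dropout_active = FALSE) {
  cfg <- params$config
  L <- length(params$W)
  A <- list(X)
  Z <- vector("list", L)
  M <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
    Z[[l]] <- z
    if (l < L) {
      a <- leaky_relu(z, cfg$leaky_alpha)
      if (dropout_active && cfg$dropout && cfg$dropout_rate > 0) {
        keep <- matrix(rbinom(length(a), 1, 1 - cfg$dropout_rate),
                       nrow(a), ncol(a))
        M[[l]] <- keep / (1 - cfg$dropout_rate)
        a <- a * M[[l]]
      }
      A[[l + 1]] <- a
    }
  }
  p <- sigmoid(Z[[L]][, 1])
  list(p = p, A = A, Z = Z, M = M)
}

#' Network forward pass
#'
#' Affine map and leaky ReLU per hidden layer (with inverted dropout when
#' `dropout_active` and the config enables it), then an affine map into the
#' sigmoid.
#'
#' @param params An `nn_params` from [init_nn()].
#' @param x A feature vector or a design matrix (records in rows).
#' @param dropout_active Draw and apply dropout masks (training mode).
#' @return Probability vector in (0, 1).
#' @export
forward_nn <- function(params, x, dropout_active = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  nn_forward_full(params, X, dropout_active)$p
}

# Backpropagated gradient of the batch BCE loss; reuses the dropout masks
# drawn in the forward pass.
nn_gradient <- function(params, X, y01, dropout_active = FALSE) {
  cfg <- params$config
  fw <- nn_forward_full(params, X, dropout_active)
  L <- length(params$W)
  B <- nrow(X)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix((fw$p - y01) / B, ncol = 1)
  for (l in L:1) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      dact <- ifelse(fw$Z[[l - 1]] >= 0, 1, cfg$leaky_alpha)
      delta <- delta * dact
      if (!is.null(fw$M[[l - 1]])) delta <- delta * fw$M[[l - 1]]
    }
  }
  list(W = gW, b = gb, loss = bce_loss(y01, fw$p), p = fw$p)
}

#' Training schedule for the classical networks
#'
#' Mirrors [qtrain_config()] with the baseline protocol: Adam starting at
#' `lr0 = 0.001`, learning rate halved after 100 non-improving epochs, early
#' stop after 500, 10 batches of 64. The monitored cost defaults to the test
#' cross-entropy, exactly as the protocol states; note that stopping on test
#' cost leaks test information into model selection — a held-out validation
#' split (`monitor = "validation"`) or the training cost are available
#' alternatives.
#'
#' @inheritParams qtrain_config
#' @param monitor Which cost drives patience counters: `"test"`,
#'   `"train"` or `"validation"`.
#' @param val_fraction Fraction of the training rows held out when
#'   `monitor = "validation"`.
#' @return An `ntrain_config` list.
#' @export
ntrain_config <- function(lr0 = 0.001, lr_factor = 0.5, lr_patience = 100,
                          stop_patience = 500, batches = 10, batch_size = 64,
                          max_epochs = 5000, tol = 1e-8, seed = 1L,
                          monitor = c("test", "train", "validation"),
                          val_fraction = 0.2) {
  monitor <- match.arg(monitor)
  stopifnot(lr_patience > 0, stop_patience > 0, batch_size > 0, batches > 0)
  structure(
    list(lr0 = lr0, lr_factor = lr_factor, lr_patience = lr_patience,
         stop_patience = stop_patience, batches = batches,
         batch_size = batch_size, max_epochs = max_epochs, tol = tol,
         seed = as.integer(seed), monitor = monitor,
         val_fraction = val_fraction),
    class = "ntrain_config"
  )
}

#' Train a classical feedforward network
#'
#' Minibatch Adam on the binary cross-entropy with the baseline schedule
#' (see [ntrain_config()]); dropout masks are resampled per batch and
#' disabled at evaluation; the best parameters under the monitored cost are
#' returned.
#'
#' @param config An [nn_config()].
#' @param data An `encoded_cohort` from [encode_cohort()].
#' @param tcfg An [ntrain_config()].
#' @param train_rows Optional subset of `data$train_index`.
#' @param params0 Optional explicit initial `nn_params`.
#' @return An `nn_fit` with best parameters and the per-epoch `history`.
#' @export
train_nn <- function(config, data, tcfg = ntrain_config(), train_rows = NULL,
                     params0 = NULL) {
  train_rows <- train_rows %||% data$train_index
  if (length(train_rows) == 0) abort("empty training set")
  test_rows <- data$test_index

  monitor <- tcfg$monitor
  val_rows <- integer(0)
  if (monitor == "validation") {
    withr::local_seed(tcfg$seed + 2L)
    n_val <- max(1L, floor(tcfg$val_fraction * length(train_rows)))
    val_rows <- sort(sample(train_rows, n_val))
    train_rows <- setdiff(train_rows, val_rows)
  }
  X_train <- data$nn_matrix[train_rows, , drop = FALSE]
  y_train <- data$labels01[train_rows]
  X_test <- data$nn_matrix[test_rows, , drop = FALSE]
  y_test <- data$labels01[test_rows]
  X_val <- data$nn_matrix[val_rows, , drop = FALSE]
  y_val <- data$labels01[val_rows]

  params <- params0 %||% init_nn(config, ncol(X_train), seed = tcfg$seed)
  withr::local_seed(tcfg$seed + 1L)
  flat_len <- function(g) sum(vapply(g, length, integer(1)))
  n_w <- flat_len(params$W)
  n_b <- flat_len(params$b)
  opt_w <- adam_init(n_w)
  opt_b <- adam_init(n_b)
  lr <- tcfg$lr0
  best <- list(cost = Inf, params = params)
  since_improve <- 0L
  since_lr <- 0L
  hist <- vector("list", tcfg$max_epochs)
  epochs_run <- 0L

  eval_cost <- function(params, X, y) {
    if (length(y) == 0) return(NA_real_)
    bce_loss(y, forward_nn(params, X))
  }
  monitored <- function(params, train_loss) {
    switch(monitor,
           test = eval_cost(params, X_test, y_test),
           train = train_loss,
           validation = eval_cost(params, X_val, y_val))
  }

  relist_like <- function(flat, template) {
    out <- template
    pos <- 0L
    for (l in seq_along(template)) {
      k <- length(template[[l]])
      out[[l]][] <- flat[pos + seq_len(k)]
      pos <- pos + k
    }
    out
  }
  flatten <- function(g) unlist(g, use.names = FALSE)

  for (epoch in seq_len(tcfg$max_epochs)) {
    batches <- make_batches(length(train_rows), tcfg$batches, tcfg$batch_size)
    for (b in batches) {
      g <- nn_gradient(params, X_train[b, , drop = FALSE], y_train[b],
                       dropout_active = TRUE)
      opt_w <- adam_step(opt_w, flatten(g$W), lr)
      opt_b <- adam_step(opt_b, flatten(g$b), lr)
      dW <- relist_like(flatten(params$W) + opt_w$delta, params$W)
      db <- relist_like(flatten(params$b) + opt_b$delta, params$b)
      params$W <- dW
      params$b <- db
    }
    train_loss <- eval_cost(params, X_train, y_train)
    cost <- monitored(params, train_loss)
    acc <- if (length(y_test) > 0) {
      mean(classify(forward_nn(params, X_test)) == encode_labels(y_test))
    } else NA_real_
    epochs_run <- epoch
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                            monitored_cost = cost, test_accuracy = acc,
                            lr = lr)
    if (best$cost - cost > tcfg$tol) {
      best <- list(cost = cost, params = params)
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
  params <- best$params
  final_acc <- if (length(y_test) > 0) {
    mean(classify(forward_nn(params, X_test)) == encode_labels(y_test))
  } else NA_real_
  structure(
    list(config = config, params = params, monitored_cost = best$cost,
         train_loss = eval_cost(params, X_train, y_train),
         test_accuracy = final_acc, history = history, epochs = epochs_run,
         tcfg = tcfg, n_train = length(train_rows)),
    class = "nn_fit"
  )
}

#' @export
print.nn_fit <- function(x, ...) {
  arch <- if (length(x$config$hidden) == 0) "perceptron" else
    paste(x$config$hidden, collapse = "-")
  cat(sprintf(
    "<nn_fit: %s | %d epochs, train loss %.4f, test accuracy %s>\n",
    arch, x$epochs, x$train_loss,
    if (is.na(x$test_accuracy)) "NA" else sprintf("%.3f", x$test_accuracy)
  ))
  invisible(x)
}

#' @export
glance.nn_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params$W, length, integer(1))) +
    sum(vapply(x$params$b, length, integer(1)))
  tibble(
    architecture = if (length(x$config$hidden) == 0) "perceptron" else
      paste(x$config$hidden, collapse = "-"),
    dropout = x$config$dropout, n_params = n_par, n_train = x$n_train,
    epochs = x$epochs, train_loss = x$train_loss,
    test_accuracy = x$test_accuracy
  )
}

#' @export
tidy.nn_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$params$W), function(l) {
    dplyr::bind_rows(
      tibble(term = sprintf("W%d[%d]", l, seq_along(x$params$W[[l]])),
             estimate = as.numeric(x$params$W[[l]])),
      tibble(term = sprintf("b%d[%d]", l, seq_along(x$params$b[[l]])),
             estimate = as.numeric(x$params$b[[l]]))
    )
  })
}

#' @export
autoplot.nn_fit <- function(object, ...) {
  plot_history(object$history[, c("epoch", "train_loss", "test_accuracy")])
}

#' Enumerate the constrained network grid
#'
#' All hidden-layer shapes with depth 1 to `max_depth`, widths drawn from
#' `widths` (multiples of 4 from 4 to 64 by default) and non-increasing from
#' layer to layer, each emitted with and without dropout. The constraint set
#' is much larger than a desk can train, so `cap` deterministically thins the
#' list (evenly spaced in enumeration order) to at most `cap` shapes before
#' the dropout doubling.
#'
#' @param max_depth Maximum number of hidden layers.
#' @param widths Allowed layer widths.
#' @param cap Optional ceiling on the number of shapes.
#' @param include_perceptron Also emit the zero-hidden-layer model.
#' @return A tibble with columns `id`, `hidden` (list-column) and `dropout`.
#' @export
enumerate_nn_grid <- function(max_depth = 5, widths = seq(4L, 64L, by = 4L),
                              cap = NULL, include_perceptron = FALSE) {
  shapes <- list()
  grow <- function(prefix, depth_left, max_w) {
    if (length(prefix) > 0) shapes[[length(shapes) + 1]] <<- prefix
    if (depth_left == 0) return()
    for (w in widths[widths <= max_w]) {
      grow(c(prefix, w), depth_left - 1, w)
    }
  }
  grow(integer(0), max_depth, max(widths))
  if (include_perceptron) shapes <- c(list(integer(0)), shapes)
  if (!is.null(cap) && length(shapes) > cap) {
    keep <- unique(round(seq(1, length(shapes), length.out = cap)))
    shapes <- shapes[keep]
  }
  purrr::map_dfr(seq_along(shapes), function(i) {
    h <- shapes[[i]]
    lab <- if (length(h) == 0) "perceptron" else paste(h, collapse = "-")
    tibble(
      id = paste0("nn_", lab, c("", "_dropout")),
      hidden = list(h, h),
      dropout = c(FALSE, TRUE)
    )
  })
}

#' The best classical architecture of the benchmark
#'
#' Three hidden layers of 52 nodes, no dropout.
#'
#' @return An [nn_config()].
#' @export
reference_best_nn <- function() nn_config(c(52L, 52L, 52L), dropout = FALSE)
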