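# Forward pass, loss, parameter-shift gradients, dropout, training.

test_that("predict_proba matches closed forms and the dense oracle", {
  # all-zero angles and parameters: every qubit stays |0>, sum <Z> = N
  cfg <- ansatz_config(4, 1, "angle")
  params <- list(theta = rep(0, n_circuit_params(cfg)), bias = 0)
  p <- predict_proba(cfg, params, rep(0, 4))
  expect_equal(p, 1 / (1 + exp(-4)), tolerance = 1e-12)

  # a bias shifts the logit; engineered sum <Z> = 0 gives p = 0.5
  cfg1 <- ansatz_config(3, 1, "angle")
  th <- rep(0, n_circuit_params(cfg1))
  # RY(pi/2) on every qubit in the encoding zeroes each <Z>
  p0 <- predict_proba(cfg1, list(theta = th, bias = 0), rep(pi / 2, 3))
  expect_equal(p0, 0.5, tolerance = 1e-12)

  # against the dense-matrix oracle on a random 3-qubit model
  withr::with_seed(41, {
    for (i in 1:5) {
      cfg3 <- ansatz_config(3, 2, "angle", reuploading = i %% 2 == 0)
      params3 <- init_params(cfg3, seed = i, scale = 0.7)
      x <- runif(3, 0, 2 * pi)
      circ <- build_model_circuit(cfg3)
      psi <- dense_run(circ, theta = params3$theta, x = x)
      want <- sum(vapply(0:2, function(q) dense_expz(psi, q, 3), numeric(1)))
      got <- predict_proba(cfg3, params3, x)
      expect_equal(got, as.numeric(1 / (1 + exp(-want - params3$bias))),
                   tolerance = 1e-10)
    }
  })
  expect_error(predict_proba(cfg, list(theta = 1, bias = 0), rep(0, 4)),
               "length")
})

test_that("classify follows the sign convention with the documented tie rule", {
  expect_equal(classify(c(0.9, 0.1, 0.5)), c(1, -1, -1))
})

test_that("binary cross-entropy matches hand evaluation and stays finite", {
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.3)),
               -mean(c(log(0.8), log(0.7))))
  # clipping keeps the worst case near -log(eps)
  expect_lt(bce_loss(1, 0), 28)
  expect_gt(bce_loss(1, 0), 27)
})

test_that("parameter-shift gradients agree with finite differences", {
  withr::with_seed(53, {
    for (i in 1:6) {
      cfg <- ansatz_config(4, 2, "angle", reuploading = i > 3)
      params <- init_params(cfg, seed = i, scale = 0.5)
      X <- matrix(runif(8, 0, 2 * pi), 2, 4)
      y <- c(1, 0)
      g <- parameter_shift_gradient(cfg, params, X, y)
      loss_at <- function(th) {
        p <- vapply(1:2, function(r) {
          predict_proba(cfg, list(theta = th, bias = params$bias), X[r, ])
        }, numeric(1))
        bce_loss(y, p)
      }
      fd <- finite_diff(loss_at, params$theta)
      expect_equal(g$theta, fd, tolerance = 1e-5)
      # bias partial
      fb <- finite_diff(function(b) {
        p <- vapply(1:2, function(r) {
          predict_proba(cfg, list(theta = params$theta, bias = b), X[r, ])
        }, numeric(1))
        bce_loss(y, p)
      }, params$bias)
      expect_equal(g$bias, fb, tolerance = 1e-5)
    }
  })
})

test_that("the single-qubit shift rule recovers -sin(theta) exactly", {
  # f(theta) = <Z> after RY(theta)|0> = cos(theta); d/dtheta = -sin(theta)
  shift_grad <- function(th) {
    f <- function(t) {
      expectation_z(apply_rotation(qstate(n_qubits = 1), "Y", 0, t), 0)
    }
    (f(th + pi / 2) - f(th - pi / 2)) / 2
  }
  for (th in c(0.3, 1.1, pi, 4.9)) {
    expect_equal(shift_grad(th), -sin(th), tolerance = 1e-12)
  }
  # stationary points where sin(theta) = 0
  expect_equal(shift_grad(0), 0, tolerance = 1e-12)
  expect_equal(shift_grad(pi), 0, tolerance = 1e-12)
})

test_that("dropout masks have the p_L * p_G marginal", {
  cfg <- ansatz_config(5, 4)
  per <- n_circuit_params(cfg)  # 36 slots over 4 layers
  cases <- list(c(0.1, 0.1), c(0.5, 0.2), c(1, 0.3))
  withr::with_seed(61, {
    for (cs in cases) {
      dc <- dropout_config(p_layer = cs[1], p_gate = cs[2])
      n_draws <- 4000
      dropped <- numeric(n_draws)
      for (i in seq_len(n_draws)) {
        dropped[i] <- nrow(sample_dropout_mask(dc, cfg))
      }
      p_hat <- sum(dropped) / (n_draws * per)
      p_true <- cs[1] * cs[2]
      se <- sqrt(p_true * (1 - p_true) / (n_draws * per))
      expect_lt(abs(p_hat - p_true), 3 * se)
    }
    # degenerate settings
    expect_equal(nrow(sample_dropout_mask(dropout_config(0.5, 0), cfg)), 0L)
    full <- sample_dropout_mask(dropout_config(1, 1), cfg)
    expect_equal(sort(full$slot), 0:(per - 1))
  })
})

test_that("masked rotations are omitted and receive zero gradient", {
  cfg <- ansatz_config(4, 2)
  params <- init_params(cfg, seed = 2, scale = 0.5)
  mask <- tibble::tibble(layer = 1L, slot = c(0L, 3L))
  X <- matrix(runif(4, 0, 2 * pi), 1, 4)
  g <- parameter_shift_gradient(cfg, params, X, 1, mask = mask)
  expect_equal(g$theta[c(1, 4)], c(0, 0))
  expect_false(all(g$theta == 0))
  # the masked forward differs from the unmasked one
  p_masked <- predict_proba(cfg, params, X[1, ], mask = mask)
  p_full <- predict_proba(cfg, params, X[1, ])
  expect_false(isTRUE(all.equal(p_masked, p_full)))
})

test_that("training learns a separable task and is reproducible", {
  data <- toy_separable(n = 80, seed = 42)
  cfg <- ansatz_config(3, 2, "angle")
  tc <- qtrain_config(batches = 2, batch_size = 40, max_epochs = 150,
                      lr_patience = 30, stop_patience = 60, seed = 1)
  accs <- vapply(1:5, function(s) {
    tc$seed <- s
    fit <- train_vqc(cfg, data, tc)
    z <- vqcbench:::vqc_sumz(build_model_circuit(cfg), fit$params$theta,
                             data$angle_matrix)
    mean(classify(vqcbench:::sigmoid(z + fit$params$bias)) == data$labels_pm)
  }, numeric(1))
  expect_gte(sum(accs >= 0.95), 4)

  # bitwise-reproducible histories under a fixed seed
  tc$seed <- 3
  tc$max_epochs <- 10
  f1 <- train_vqc(cfg, data, tc)
  f2 <- train_vqc(cfg, data, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  # the best-so-far training loss trace is non-increasing
  expect_true(all(diff(cummin(f1$history$train_loss)) <= 0))
  expect_error(train_vqc(cfg, data, tc, train_rows = integer(0)), "empty")
})

test_that("quantum dropout trains and evaluation is mask-free", {
  data <- toy_separable(n = 40, seed = 9)
  cfg <- ansatz_config(3, 2, "angle")
  tc <- qtrain_config(batches = 1, batch_size = 40, max_epochs = 15,
                      lr_patience = 5, stop_patience = 10, seed = 4)
  fit <- train_vqc(cfg, data, tc, dropout = dropout_config(0.5, 0.5))
  expect_s3_class(fit, "vqc_fit")
  # the reported training loss is the dropout-free evaluation
  z <- vqcbench:::vqc_sumz(build_model_circuit(cfg), fit$params$theta,
                           data$angle_matrix)
  loss <- bce_loss(data$labels01,
                   vqcbench:::sigmoid(z + fit$params$bias))
  expect_equal(fit$train_loss, loss, tolerance = 1e-12)
})

test_that("gradient statistics are deterministic and match recomputation", {
  tbl <- generate_cohort(cohort_spec(n_records = 120), seed = 31)
  data <- encode_cohort(tbl, seed = 31)
  cfg <- ansatz_config(4, 1, "angle")
  # 4-qubit diagnostic on the first 4 angle features
  data4 <- data
  data4$angle_matrix <- data$angle_matrix[, 1:4]
  gs1 <- gradient_statistics(cfg, data4, n_inits = 3, seed = 2,
                             batch_size = 16)
  gs2 <- gradient_statistics(cfg, data4, n_inits = 3, seed = 2,
                             batch_size = 16)
  expect_identical(gs1, gs2)
  expect_gte(gs1$var_abs_grad, 0)
  # cross-check one init against finite differences
  params <- init_params(cfg, seed = 3)
  rows <- data4$train_index[1:16]
  X <- data4$angle_matrix[rows, ]
  y <- data4$labels01[rows]
  g <- parameter_shift_gradient(cfg, params, X, y)
  fd <- finite_diff(function(th) {
    p <- vapply(seq_len(nrow(X)), function(r) {
      predict_proba(cfg, list(theta = th, bias = 0), X[r, ])
    }, numeric(1))
    bce_loss(y, p)
  }, params$theta)
  expect_equal(g$theta, fd, tolerance = 1e-5)
})

test_that("tidy, glance and autoplot work on a fit", {
  data <- toy_separable(n = 30, seed = 5)
  cfg <- ansatz_config(3, 1, "angle")
  tc <- qtrain_config(batches = 1, batch_size = 30, max_epochs = 5,
                      lr_patience = 2, stop_patience = 4, seed = 1)
  fit <- train_vqc(cfg, data, tc)
  td <- tidy(fit)
  expect_equal(nrow(td), n_circuit_params(cfg) + 1L)
  gl <- glance(fit)
  expect_equal(gl$layers, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})
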