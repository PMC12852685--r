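# Classical baselines: activation, initialization, backprop, grid, training.

test_that("leaky ReLU follows its definition", {
  expect_equal(leaky_relu(1), 1)
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(-2), -0.2)
  expect_equal(leaky_relu(c(-1, 2), alpha = 0.3), c(-0.3, 2))
})

test_that("initialization matches He/Xavier conventions", {
  # He normal weights: sample SD within 5% of sqrt(2/fan_in) at ~1e5 draws
  cfg <- nn_config(c(64, 64))
  draws <- unlist(lapply(1:30, function(s) {
    as.numeric(init_nn(cfg, input_width = 64, seed = s)$W[[1]])
  }))
  expect_gt(length(draws), 1e5)
  expect_equal(sd(draws), sqrt(2 / 64), tolerance = 0.05)
  # Xavier-uniform biases stay inside their bounds
  p <- init_nn(cfg, 64, seed = 1)
  lim <- sqrt(6 / (64 + 64))
  expect_true(all(abs(p$b[[1]]) <= lim))
  # perceptron: He-uniform weights, zero biases
  pc <- init_nn(nn_config(), input_width = 13, seed = 2)
  expect_equal(pc$b[[1]], 0)
  expect_true(all(abs(pc$W[[1]]) <= sqrt(6 / 13)))
  expect_identical(init_nn(cfg, 64, seed = 7), init_nn(cfg, 64, seed = 7))
})

test_that("the forward pass matches hand arithmetic", {
  # one hidden unit: p = sigmoid(w2 * leaky(w1 x + b1) + b2)
  params <- structure(list(
    W = list(matrix(0.5, 1, 1), matrix(-2, 1, 1)),
    b = list(0.1, 0.3),
    config = nn_config(1), input_width = 1L
  ), class = "nn_params")
  x <- -1.4
  h <- leaky_relu(0.5 * x + 0.1, 0.1)
  expect_equal(forward_nn(params, x), 1 / (1 + exp(-(-2 * h + 0.3))))
  # zero weights and biases give p = 0.5
  z <- structure(list(
    W = list(matrix(0, 3, 2), matrix(0, 2, 1)),
    b = list(rep(0, 2), 0), config = nn_config(2), input_width = 3L
  ), class = "nn_params")
  expect_equal(forward_nn(z, c(1, 2, 3)), 0.5)
  # without dropout the pass is deterministic
  p1 <- forward_nn(params, x, dropout_active = FALSE)
  p2 <- forward_nn(params, x, dropout_active = FALSE)
  expect_identical(p1, p2)
})

test_that("backpropagation agrees with finite differences", {
  withr::with_seed(71, {
    for (i in 1:4) {
      cfg <- nn_config(c(6, 4))
      params <- init_nn(cfg, 5, seed = i)
      # keep pre-activations away from the leaky-ReLU kink
      X <- matrix(rnorm(20, sd = 2), 4, 5)
      y <- rbinom(4, 1, 0.5)
      g <- vqcbench:::nn_gradient(params, X, y)
      for (l in 1:3) {
        fd_w <- finite_diff(function(w) {
          p2 <- params
          p2$W[[l]][] <- w
          bce_loss(y, forward_nn(p2, X))
        }, as.numeric(params$W[[l]]))
        expect_equal(as.numeric(g$W[[l]]), fd_w, tolerance = 1e-5)
        fd_b <- finite_diff(function(b) {
          p2 <- params
          p2$b[[l]][] <- b
          bce_loss(y, forward_nn(p2, X))
        }, as.numeric(params$b[[l]]))
        expect_equal(as.numeric(g$b[[l]]), fd_b, tolerance = 1e-5)
      }
    }
  })
})

test_that("inverted dropout preserves the activation expectation", {
  cfg <- nn_config(c(8), dropout = TRUE, dropout_rate = 0.2)
  params <- init_nn(cfg, 4, seed = 3)
  x <- matrix(rnorm(4), 1, 4)
  h_clean <- leaky_relu(sweep(x %*% params$W[[1]], 2, params$b[[1]], "+"),
                        cfg$leaky_alpha)
  withr::with_seed(5, {
    acc <- matrix(0, 1, 8)
    n <- 20000
    for (i in seq_len(n)) {
      fw <- vqcbench:::nn_forward_full(params, x, dropout_active = TRUE)
      acc <- acc + fw$A[[2]]
    }
    mc <- acc / n
  })
  se <- abs(h_clean) * sqrt(0.2 / 0.8 / 20000)
  expect_true(all(abs(mc - h_clean) <= 4 * se + 1e-8))
})

test_that("training learns a separable task and stops on the monitored cost", {
  data <- toy_separable(n = 80, seed = 10)
  # the toy nn_matrix equals the angle matrix; a small net separates it
  tc <- ntrain_config(lr0 = 0.01, batches = 2, batch_size = 40,
                      max_epochs = 300, lr_patience = 50,
                      stop_patience = 100, seed = 1, monitor = "train")
  ok <- vapply(1:5, function(s) {
    tc$seed <- s
    fit <- train_nn(nn_config(c(8)), data, tc)
    acc <- mean(classify(forward_nn(fit$params, data$nn_matrix)) ==
                  data$labels_pm)
    acc >= 0.98
  }, logical(1))
  expect_gte(sum(ok), 4)
  tc$seed <- 2
  tc$max_epochs <- 12
  f1 <- train_nn(nn_config(c(8)), data, tc)
  f2 <- train_nn(nn_config(c(8)), data, tc)
  expect_identical(f1$history, f2$history)
})

test_that("monitoring variants and the validation split work", {
  tbl <- generate_cohort(cohort_spec(n_records = 200), seed = 21)
  data <- encode_cohort(tbl, seed = 21)
  for (mon in c("test", "validation")) {
    tc <- ntrain_config(max_epochs = 8, lr_patience = 3, stop_patience = 6,
                        seed = 2, monitor = mon)
    fit <- train_nn(nn_config(c(8)), data, tc)
    expect_equal(fit$epochs, nrow(fit$history))
    expect_true(all(is.finite(fit$history$monitored_cost)))
  }
})

test_that("the architecture grid honors both constraints", {
  grid <- enumerate_nn_grid(max_depth = 2)
  shapes <- grid$hidden[!grid$dropout]
  # depth 1: 16 width choices
  expect_equal(sum(lengths(shapes) == 1), 16L)
  # every width a multiple of 4 within 4..64, non-increasing across layers
  for (h in shapes) {
    expect_true(all(h %% 4 == 0 & h >= 4 & h <= 64))
    if (length(h) > 1) expect_true(all(diff(h) <= 0))
  }
  # increasing shapes such as (32, 48) never appear
  expect_false(any(vapply(shapes, function(h) {
    length(h) == 2 && h[1] == 32 && h[2] == 48
  }, logical(1))))
  # each shape appears with and without dropout
  expect_equal(sum(grid$dropout), sum(!grid$dropout))
  # the cap thins deterministically
  capped <- enumerate_nn_grid(max_depth = 3, cap = 40)
  expect_lte(nrow(capped), 80L)
  expect_identical(capped, enumerate_nn_grid(max_depth = 3, cap = 40))
})

test_that("the reference network is the 52-52-52 design without dropout", {
  ref <- reference_best_nn()
  expect_equal(ref$hidden, c(52L, 52L, 52L))
  expect_false(ref$dropout)
  # it satisfies the grid constraints
  expect_true(all(ref$hidden %% 4 == 0) && all(diff(ref$hidden) <= 0))
  expect_equal(length(ref$hidden), 3L)
})

test_that("a sample of grid configurations trains without shape errors", {
  tbl <- generate_cohort(cohort_spec(n_records = 50), seed = 77)
  data <- encode_cohort(tbl, seed = 77)
  grid <- enumerate_nn_grid(max_depth = 5, cap = 15)
  withr::with_seed(8, picks <- sample(nrow(grid), 8))
  tc <- ntrain_config(max_epochs = 2, lr_patience = 1, stop_patience = 2,
                      seed = 1, monitor = "train")
  for (i in picks) {
    cfg <- nn_config(grid$hidden[[i]], dropout = grid$dropout[i])
    fit <- train_nn(cfg, data, tc)
    expect_true(is.finite(fit$train_loss))
  }
})
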