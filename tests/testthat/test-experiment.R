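# Grid enumeration, repeated runs, aggregation, selection, study mechanics.

test_that("the QNN grid expands to 54 rows, 46 without DR+dropout", {
  grid <- enumerate_qnn_grid()
  expect_equal(nrow(grid), 54L)
  expect_equal(sum(grid$row == "amplitude_rep"), 10L)
  expect_equal(sum(grid$row == "angle_dr_dropout"), 8L)
  # layer ranges per row: 1-10 plain, 1-8 with dropout
  expect_true(all(grid$layers[grid$dropout] <= 8))
  expect_true(all(!grid$reuploading[grid$encoding == "amplitude_hybrid"]))
  g46 <- enumerate_qnn_grid(exclude = "angle_dr_dropout")
  expect_equal(nrow(g46), 46L)
  expect_equal(nrow(enumerate_qnn_grid(exclude = c(
    "amplitude_rep", "amplitude_rep_dropout", "angle_rep",
    "angle_rep_dropout", "angle_dr", "angle_dr_dropout"
  ))), 0L)
  expect_error(enumerate_qnn_grid(exclude = "nope"), "unknown")
  # ids are unique and models match their rows
  expect_equal(anyDuplicated(grid$id), 0L)
  expect_equal(grid$model[[12]]$config$layers, grid$layers[12])
})

test_that("run_repeated derives distinct deterministic seeds and records failures", {
  data <- toy_separable(n = 40, seed = 2)
  model <- qnn_model(1, n_qubits = 3)
  tc <- qtrain_config(batches = 1, batch_size = 40, max_epochs = 3,
                      lr_patience = 2, stop_patience = 3)
  recs <- run_repeated(model, data, k = 3, seed_base = 5, tcfg = tc)
  expect_equal(nrow(recs), 3L)
  expect_equal(anyDuplicated(recs$seed), 0L)
  expect_true(all(recs$seed > 0 & recs$seed < 2^31))
  recs2 <- run_repeated(model, data, k = 3, seed_base = 5, tcfg = tc)
  expect_identical(recs, recs2)
  # k = 1 gives a single record
  expect_equal(nrow(run_repeated(model, data, k = 1, seed_base = 1,
                                 tcfg = tc)), 1L)
  # a failing model is recorded, not dropped
  bad <- qnn_model(1, n_qubits = 5)   # 5 qubits vs 3 toy features
  recs3 <- run_repeated(bad, data, k = 2, seed_base = 1, tcfg = tc)
  expect_equal(nrow(recs3), 2L)
  expect_true(all(!is.na(recs3$error)))
  expect_true(all(is.na(recs3$accuracy)))
})

test_that("aggregation matches hand computation and an independent oracle", {
  recs <- tibble::tibble(id = "a", rep = 1:10, seed = 1:10,
                         accuracy = rep(0.8, 10), epochs = 1L,
                         train_loss = 0.1, error = NA_character_)
  st <- aggregate_runs(recs)
  expect_equal(st$mean_accuracy, 0.8)
  expect_equal(st$ci_half, 0)
  expect_equal(st$k, 10L)

  two <- tibble::tibble(id = "b", rep = 1:2, seed = 1:2,
                        accuracy = c(0.8, 0.9), epochs = 1L,
                        train_loss = 0.1, error = NA_character_)
  st2 <- aggregate_runs(two)
  expect_equal(st2$mean_accuracy, 0.85)
  expect_equal(st2$ci_half, qt(0.975, 1) * sd(c(0.8, 0.9)) / sqrt(2))

  expect_error(aggregate_runs(recs[0, ]), "no successful runs")

  # randomized fixture against a straightforward recomputation
  withr::with_seed(90, {
    rand <- tibble::tibble(
      id = sample(letters[1:4], 40, replace = TRUE),
      accuracy = runif(40), rep = 1:40, seed = 1:40, epochs = 1L,
      train_loss = 0, error = NA_character_
    )
    st3 <- aggregate_runs(rand)
    for (g in unique(rand$id)) {
      v <- rand$accuracy[rand$id == g]
      row <- st3[st3$id == g, ]
      expect_equal(row$mean_accuracy, sum(v) / length(v))
      expect_equal(row$sd_accuracy, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
      expect_equal(row$ci_half, qt(0.975, length(v) - 1) *
                     row$sd_accuracy / sqrt(length(v)))
    }
  })
})

test_that("accuracy_score counts matches", {
  expect_equal(accuracy_score(c(1, 1, -1), c(1, 1, -1)), 1)
  expect_equal(accuracy_score(c(1, 1), c(-1, -1)), 0)
  expect_equal(accuracy_score(c(1, -1, 1, 1), c(1, -1, -1, 1)), 0.75)
  expect_error(accuracy_score(1, c(1, 2)), "mismatch")
  expect_error(accuracy_score(numeric(0), numeric(0)), "empty")
})

test_that("select_best prefers mean accuracy, then tighter CIs", {
  one <- tibble::tibble(id = "only", mean_accuracy = 0.8, ci_half = 0.1)
  expect_equal(select_best(one), "only")
  st <- tibble::tibble(
    id = c("worse", "better"),
    mean_accuracy = c(0.7, 0.9), ci_half = c(0.01, 0.2)
  )
  expect_equal(select_best(st), "better")
  tie <- tibble::tibble(
    id = c("wide", "tight"),
    mean_accuracy = c(0.85, 0.85), ci_half = c(0.1, 0.02)
  )
  expect_equal(select_best(tie), "tight")
  expect_error(select_best(tie[0, ]), "empty")
})

test_that("the sample-complexity study fixes the test set and varies subsets", {
  tbl <- generate_cohort(cohort_spec(n_records = 150), seed = 44)
  data <- encode_cohort(tbl, seed = 44)
  models <- list(nn_model(c(4), id = "tiny"))
  tc <- ntrain_config(max_epochs = 4, lr_patience = 2, stop_patience = 3,
                      monitor = "train")
  study <- sample_complexity_study(
    models, data, fractions = c(0.3, 1.0), repeats = 2, seed_base = 3,
    tcfg_for = function(m) tc
  )
  expect_equal(nrow(study$records), 4L)
  expect_equal(nrow(study$report), 2L)
  expect_true(all(c(0.3, 1.0) %in% study$report$fraction))
  # subset sizes follow the round-half-up contract
  n_tr <- length(data$train_index)
  expect_true(all(study$records$n_train[study$records$fraction == 0.3] ==
                    floor(0.3 * n_tr + 0.5)))
  expect_true(all(study$records$n_train[study$records$fraction == 1.0] ==
                    n_tr))
  # repeats draw different subsets at f < 1 (different seeds)
  seeds03 <- study$records$seed[study$records$fraction == 0.3]
  expect_equal(anyDuplicated(seeds03), 0L)
  # deterministic end to end
  study2 <- sample_complexity_study(
    models, data, fractions = c(0.3, 1.0), repeats = 2, seed_base = 3,
    tcfg_for = function(m) tc
  )
  expect_identical(study$records, study2$records)
  # the default roster matches the published architecture list
  roster <- default_study_roster()
  expect_length(roster, 7L)
  expect_equal(sum(vapply(roster, function(m) m$kind == "nn", logical(1))),
               2L)
})
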