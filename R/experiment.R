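#' Model specifications for the experiment suite
#'
#' Lightweight descriptors pairing an architecture with an id, consumed by
#' [run_repeated()] and [sample_complexity_study()].
#'
#' @param layers Number of ansatz layers.
#' @param encoding `"angle"` or `"amplitude_hybrid"` (11 and 13 qubits).
#' @param reuploading Use data re-uploading (angle encoding only).
#' @param dropout Attach the default quantum [dropout_config()] (QNN) or
#'   enable classical dropout (NN).
#' @param n_qubits Qubit count; defaults to 11 (angle) or 13 (hybrid).
#' @param id Optional identifier; a descriptive one is derived if missing.
#' @return A `model_spec` list with fields `id`, `kind`, `config` and (for
#'   QNNs) `dropout`.
#' @export
qnn_model <- function(layers, encoding = c("angle", "amplitude_hybrid"),
                      reuploading = FALSE, dropout = FALSE, n_qubits = NULL,
                      id = NULL) {
  encoding <- match.arg(encoding)
  n_qubits <- n_qubits %||% if (encoding == "angle") 11L else 13L
  id <- id %||% paste0(
    "qnn_", if (encoding == "angle") "angle" else "amplitude",
    if (reuploading) "_dr" else "", "_L", layers,
    if (dropout) "_dropout" else ""
  )
  structure(
    list(id = id, kind = "vqc",
         config = ansatz_config(n_qubits, layers, encoding, reuploading),
         dropout = if (dropout) dropout_config() else NULL),
    class = "model_spec"
  )
}

#' @rdname qnn_model
#' @param hidden Hidden widths for the classical network (empty =
#'   perceptron).
#' @export
nn_model <- function(hidden = integer(0), dropout = FALSE, id = NULL) {
  id <- id %||% paste0(
    "nn_", if (length(hidden) == 0) "perceptron" else
      paste(hidden, collapse = "-"),
    if (dropout) "_dropout" else ""
  )
  structure(
    list(id = id, kind = "nn", config = nn_config(hidden, dropout = dropout)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s (%s)>\n", x$id, x$kind))
  invisible(x)
}

#' Train one model specification
#'
#' @param model A `model_spec`.
#' @param data An `encoded_cohort`.
#' @param tcfg Optional training schedule ([qtrain_config()] or
#'   [ntrain_config()] to match the model kind).
#' @param train_rows Optional training-row subset.
#' @return A `vqc_fit` or `nn_fit`.
#' @export
train_model <- function(model, data, tcfg = NULL, train_rows = NULL) {
  if (model$kind == "vqc") {
    train_vqc(model$config, data, tcfg %||% qtrain_config(),
              dropout = model$dropout, train_rows = train_rows)
  } else {
    train_nn(model$config, data, tcfg %||% ntrain_config(),
             train_rows = train_rows)
  }
}

#' Enumerate the QNN benchmark grid
#'
#' Six architecture rows expanded over their layer ranges: amplitude and
#' angle encoding with plain ansatz repetition (layers 1-10) or with dropout
#' (layers 1-8), plus data re-uploading for angle encoding (1-10, and 1-8
#' with dropout). The full expansion holds 54 configurations; excluding the
#' re-uploading-with-dropout row leaves 46, one reading consistent with the
#' benchmark's stated architecture count.
#'
#' @param exclude Character vector of row keys to drop, among
#'   `"amplitude_rep"`, `"amplitude_rep_dropout"`, `"angle_rep"`,
#'   `"angle_rep_dropout"`, `"angle_dr"`, `"angle_dr_dropout"`.
#' @return A tibble with one row per configuration (`id`, `encoding`,
#'   `reuploading`, `dropout`, `layers`, `row`) and a list-column `model` of
#'   `model_spec` objects.
#' @export
enumerate_qnn_grid <- function(exclude = character()) {
  rows <- tibble(
    row = c("amplitude_rep", "amplitude_rep_dropout", "angle_rep",
            "angle_rep_dropout", "angle_dr", "angle_dr_dropout"),
    encoding = c("amplitude_hybrid", "amplitude_hybrid", "angle", "angle",
                 "angle", "angle"),
    reuploading = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    dropout = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    max_layers = c(10L, 8L, 10L, 8L, 10L, 8L)
  )
  bad <- setdiff(exclude, rows$row)
  if (length(bad) > 0) {
    abort(paste("unknown grid row(s):", paste(bad, collapse = ", ")))
  }
  rows <- rows[!rows$row %in% exclude, ]
  out <- tidyr::uncount(rows, weights = rows$max_layers, .id = "layers")
  out$layers <- as.integer(out$layers)
  out$model <- purrr::pmap(
    list(out$layers, out$encoding, out$reuploading, out$dropout),
    function(L, enc, dr, dp) qnn_model(L, enc, reuploading = dr, dropout = dp)
  )
  out$id <- purrr::map_chr(out$model, "id")
  out[, c("id", "row", "encoding", "reuploading", "dropout", "layers",
          "model")]
}

# stable small-integer seed from (config id, repeat index, base seed)
stable_seed <- function(id, rep, base) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 1000003
  as.integer((h * 2017 + rep * 7919 + base * 104729) %% 2147483629)
}

#' Repeated-seed training of one configuration
#'
#' Trains the model `k` times with distinct derived seeds (different
#' parameter initializations, batch orders and dropout masks) and records
#' each run's final test accuracy. Failures are recorded in the `error`
#' column rather than silently dropped.
#'
#' @param model A `model_spec`.
#' @param data An `encoded_cohort`.
#' @param k Number of repeats (the benchmark protocol uses 10).
#' @param seed_base Base seed combined with the config id and repeat index.
#' @param tcfg Training-schedule template; its seed is overridden per run.
#' @param train_rows Optional training-row subset.
#' @return A tibble of run records: `id`, `repeat`, `seed`, `accuracy`,
#'   `epochs`, `train_loss`, `error`.
#' @export
run_repeated <- function(model, data, k = 10, seed_base = 1L, tcfg = NULL,
                         train_rows = NULL) {
  purrr::map_dfr(seq_len(k), function(r) {
    s <- stable_seed(model$id, r, seed_base)
    run_tcfg <- tcfg %||% if (model$kind == "vqc") qtrain_config() else
      ntrain_config()
    run_tcfg$seed <- s
    rec <- tibble(id = model$id, rep = r, seed = s, accuracy = NA_real_,
                  epochs = NA_integer_, train_loss = NA_real_,
                  error = NA_character_)
    fit <- tryCatch(train_model(model, data, run_tcfg, train_rows),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rec$error <- conditionMessage(fit)
    } else {
      rec$accuracy <- fit$test_accuracy
      rec$epochs <- fit$epochs
      rec$train_loss <- fit$train_loss
    }
    rec
  })
}

#' Aggregate run records into mean and 95% confidence interval
#'
#' Groups by `id` and reports the repeat count, mean accuracy, SD and the
#' 95% CI half-width computed from the Student-t distribution with `k - 1`
#' degrees of freedom on the mean.
#'
#' @param records Run-record tibble from [run_repeated()] (rows with a
#'   non-missing accuracy are used).
#' @return A tibble with columns `id`, `k`, `mean_accuracy`, `sd_accuracy`,
#'   `ci_half`.
#' @export
aggregate_runs <- function(records) {
  ok <- records[!is.na(records$accuracy), ]
  if (nrow(ok) == 0) abort("no successful runs to aggregate")
  dplyr::summarise(
    dplyr::group_by(ok, .data$id),
    k = dplyr::n(),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = ifelse(dplyr::n() > 1, sd(.data$accuracy), 0),
    ci_half = ifelse(
      dplyr::n() > 1,
      qt(0.975, dplyr::n() - 1) * sd(.data$accuracy) / sqrt(dplyr::n()),
      0
    ),
    .groups = "drop"
  )
}

#' Classification accuracy
#'
#' @param predictions,labels Equal-length vectors on the same label scale.
#' @return Fraction of matches in `[0, 1]`.
#' @export
accuracy_score <- function(predictions, labels) {
  if (length(predictions) != length(labels)) abort("length mismatch")
  if (length(labels) == 0) abort("empty label vector")
  mean(predictions == labels)
}

#' Select the best configuration from aggregate statistics
#'
#' Highest mean accuracy; ties broken by smaller CI half-width, then by
#' fewer parameters when an `n_params` column is present, then by id.
#'
#' @param stats Aggregate tibble from [aggregate_runs()].
#' @return The winning `id`.
#' @export
select_best <- function(stats) {
  if (nrow(stats) == 0) abort("empty statistics table")
  ord <- order(-stats$mean_accuracy, stats$ci_half,
               if ("n_params" %in% names(stats)) stats$n_params else
                 rep(0, nrow(stats)),
               stats$id)
  stats$id[ord[1]]
}

#' The sample-complexity roster of the benchmark
#'
#' Seven architectures: the perceptron, the best classical network
#' (52-52-52), re-uploading QNNs with 1, 4 and 9 layers, and dropout QNNs
#' with 1 and 6 layers.
#'
#' @return A list of `model_spec` objects.
#' @export
default_study_roster <- function() {
  list(
    nn_model(id = "perceptron"),
    nn_model(c(52L, 52L, 52L), id = "nn_52-52-52"),
    qnn_model(1, reuploading = TRUE),
    qnn_model(4, reuploading = TRUE),
    qnn_model(9, reuploading = TRUE),
    qnn_model(1, dropout = TRUE),
    qnn_model(6, dropout = TRUE)
  )
}

#' Sample-complexity study
#'
#' For each architecture and each training fraction, trains `repeats` times,
#' each repeat on a different random subset of the training partition (drawn
#' without replacement by [subsample_fraction()]); the test partition stays
#' fixed across fractions. Aggregates to the architecture-by-fraction table
#' of mean accuracy with 95% CIs.
#'
#' @param models List of `model_spec`s (defaults to [default_study_roster()]).
#' @param data An `encoded_cohort`.
#' @param fractions Training fractions (default 0.1, 0.3, 0.5, 0.7, 1.0).
#' @param repeats Repeats per (architecture, fraction) cell.
#' @param seed_base Base seed.
#' @param tcfg_for Function `model_spec -> training config` supplying the
#'   per-kind schedule (budget knob for desk-scale runs); `NULL` uses the
#'   full-protocol defaults.
#' @return List with `records` (one row per run) and `report` (one row per
#'   architecture x fraction), of class `sample_complexity_report`.
#' @export
sample_complexity_study <- function(models = default_study_roster(), data,
                                    fractions = c(0.1, 0.3, 0.5, 0.7, 1.0),
                                    repeats = 10, seed_base = 1L,
                                    tcfg_for = NULL) {
  records <- purrr::map_dfr(models, function(model) {
    tcfg <- if (is.null(tcfg_for)) NULL else tcfg_for(model)
    purrr::map_dfr(fractions, function(f) {
      recs <- purrr::map_dfr(seq_len(repeats), function(r) {
        sub_seed <- stable_seed(paste0(model$id, "@", f), r, seed_base)
        rows <- subsample_fraction(data$train_index, f, seed = sub_seed)
        run_tcfg <- tcfg %||% if (model$kind == "vqc") qtrain_config() else
          ntrain_config()
        run_tcfg$seed <- sub_seed
        rec <- tibble(id = model$id, fraction = f, rep = r, seed = sub_seed,
                      n_train = length(rows), accuracy = NA_real_,
                      epochs = NA_integer_, error = NA_character_)
        fit <- tryCatch(train_model(model, data, run_tcfg, train_rows = rows),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          rec$error <- conditionMessage(fit)
        } else {
          rec$accuracy <- fit$test_accuracy
          rec$epochs <- fit$epochs
        }
        rec
      })
      recs
    })
  })
  ok <- records[!is.na(records$accuracy), ]
  report <- dplyr::summarise(
    dplyr::group_by(ok, .data$id, .data$fraction),
    k = dplyr::n(),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = ifelse(dplyr::n() > 1, sd(.data$accuracy), 0),
    ci_half = ifelse(
      dplyr::n() > 1,
      qt(0.975, dplyr::n() - 1) * sd(.data$accuracy) / sqrt(dplyr::n()),
      0
    ),
    .groups = "drop"
  )
  structure(list(records = records, report = report),
            class = "sample_complexity_report")
}

#' @export
print.sample_complexity_report <- function(x, ...) {
  cat("<sample_complexity_report>\n")
  print(tidyr::pivot_wider(
    x$report[, c("id", "fraction", "mean_accuracy")],
    names_from = "fraction", values_from = "mean_accuracy"
  ))
  invisible(x)
}

#' @export
autoplot.sample_complexity_report <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$fraction, y = .data$mean_accuracy,
                               color = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$ci_half,
                   ymax = .data$mean_accuracy + .data$ci_half),
      width = 0.02
    ) +
    ggplot2::labs(x = "training fraction", y = "mean test accuracy",
                  color = "architecture") +
    ggplot2::theme_minimal()
}
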