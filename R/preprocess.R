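#' Standardize a numeric column
#'
#' Computes `z_i = (x_i - mean) / sd`. When `fit` is supplied (a list with
#' `mean` and `sd`, typically estimated on the training partition), those
#' statistics are reused instead of refitting — this is how test data is
#' transformed without leakage.
#'
#' @param x Numeric vector.
#' @param fit Optional `list(mean =, sd =)` from a previous fit.
#' @return Standardized vector with the fit statistics attached as attribute
#'   `"fit"`.
#' @export
standardize <- function(x, fit = NULL) {
  if (is.null(fit)) {
    fit <- list(mean = mean(x), sd = sd(x))
  }
  if (!is.finite(fit$sd) || fit$sd <= 0) {
    abort("zero-variance column cannot be standardized")
  }
  structure((x - fit$mean) / fit$sd, fit = fit)
}

#' Min-max scale a numeric column onto [0, 2*pi]
#'
#' Affine map sending the fitted minimum to 0 and maximum to `2*pi`, as
#' required by angle encoding. Values outside the fitted range (e.g. test
#' records beyond the training range) are clipped to the endpoints.
#'
#' @param x Numeric vector.
#' @param fit Optional `list(min =, max =)` from a previous fit.
#' @return Vector in `[0, 2*pi]` with attribute `"fit"`.
#' @export
scale_to_angle <- function(x, fit = NULL) {
  if (is.null(fit)) {
    fit <- list(min = min(x), max = max(x))
  }
  if (fit$max <= fit$min) {
    abort("constant column cannot be scaled to an angle range")
  }
  out <- 2 * pi * (x - fit$min) / (fit$max - fit$min)
  structure(pmin(pmax(out, 0), 2 * pi), fit = fit)
}

#' One-hot encode a categorical column
#'
#' @param x Factor (or character) vector.
#' @param levels Level set; defaults to the factor's levels. Values outside
#'   it are an error.
#' @param scheme `"full"` (one column per level, rows sum to 1) or
#'   `"drop_first"` (reference level dropped, rows sum to 0 or 1).
#' @return Integer 0/1 matrix with `Feature=Level`-style column names taken
#'   from `x`'s name when available.
#' @export
one_hot <- function(x, levels = NULL, scheme = c("full", "drop_first")) {
  scheme <- match.arg(scheme)
  levels <- levels %||% base::levels(factor(x))
  x <- as.character(x)
  if (!all(x %in% levels)) {
    abort(paste("unseen level(s):",
                paste(unique(setdiff(x, levels)), collapse = ", ")))
  }
  keep <- if (scheme == "drop_first") levels[-1] else levels
  out <- vapply(keep, function(l) as.integer(x == l),
                integer(length(x)))
  out <- matrix(out, nrow = length(x),
                dimnames = list(NULL, keep))
  out
}

#' Map binary labels between {0, 1} and {-1, 1}
#'
#' Quantum classifiers in this package assign classes by the sign convention
#' `{-1, 1}`; the loss is computed on `{0, 1}`. `encode_labels` maps 0 to -1
#' and 1 to 1; `decode_labels` is its exact inverse.
#'
#' @param y01 Vector in `{0, 1}`.
#' @param ypm Vector in `{-1, 1}`.
#' @return Numeric vector.
#' @export
encode_labels <- function(y01) {
  if (!all(y01 %in% c(0, 1))) abort("labels must be 0 or 1")
  2 * as.numeric(y01) - 1
}

#' @rdname encode_labels
#' @export
decode_labels <- function(ypm) {
  if (!all(ypm %in% c(-1, 1))) abort("labels must be -1 or 1")
  (as.numeric(ypm) + 1) / 2
}

#' Random 70/30-style train/test split
#'
#' The training partition takes `ceiling(train_fraction * n)` rows; the split
#' is disjoint, exhaustive and deterministic under the seed.
#'
#' @param table A cohort tibble.
#' @param train_fraction Fraction of rows assigned to training.
#' @param seed Integer seed.
#' @return List with `train`, `test` (tibbles) and the integer
#'   `train_index` / `test_index` vectors.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("train_fraction must be in (0, 1]")
  }
  n <- nrow(table)
  n_train <- ceiling(train_fraction * n)
  withr::local_seed(seed)
  train_index <- sort(sample.int(n, n_train))
  test_index <- setdiff(seq_len(n), train_index)
  list(
    train = table[train_index, ], test = table[test_index, ],
    train_index = train_index, test_index = test_index
  )
}

#' Subsample a fraction of a training index set
#'
#' Draws `round(f * length(index))` indices (round half up) without
#' replacement; `f = 1` returns the full set. Used by the sample-complexity
#' study, where each repeat draws a different random subset.
#'
#' @param index Integer vector of training row indices.
#' @param f Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of sampled indices.
#' @export
subsample_fraction <- function(index, f, seed = 1L) {
  if (f <= 0 || f > 1) abort("fraction must be in (0, 1]")
  if (f == 1) return(index)
  size <- floor(f * length(index) + 0.5)
  withr::local_seed(seed)
  sort(sample(index, size))
}

nn_input_schemes <- c("compact", "drop_first", "full")

#' Encode a cohort for every model family
#'
#' Produces all the design matrices the classifiers consume, with every fit
#' statistic (means, SDs, ranges) estimated on the training partition only
#' and then applied to the test partition (leakage-free by construction):
#'
#' * `angle_matrix` — the 11 predictors with categoricals integer-coded, each
#'   column min-max scaled to `[0, 2*pi]` (11-qubit angle encoding);
#' * `amplitude_block` — the 5 continuous features standardized (amplitude
#'   register of the 13-qubit hybrid encoder);
#' * `basis_block` — drop-first one-hot bits of the 6 categoricals (10 bits,
#'   basis register);
#' * `nn_matrix` — the classical-network design matrix under `nn_scheme`:
#'   `"compact"` (13 columns: standardized continuous, binary indicators,
#'   drop-first chest-pain indicators, integer-coded ECG and slope),
#'   `"drop_first"` (15 columns) or `"full"` (21 columns);
#' * `labels01` / `labels_pm` — outcomes in `{0,1}` and `{-1,1}`.
#'
#' @param table Cohort tibble from [generate_cohort()] or [read_cohort_csv()].
#' @param train_fraction Passed to [split_train_test()].
#' @param seed Split seed.
#' @param nn_scheme Input design for the classical networks.
#' @return An `encoded_cohort` object (list of matrices, labels and index
#'   vectors).
#' @export
encode_cohort <- function(table, train_fraction = 0.7, seed = 1L,
                          nn_scheme = c("compact", "drop_first", "full")) {
  nn_scheme <- match.arg(nn_scheme)
  sp <- split_train_test(table, train_fraction, seed)
  tr <- sp$train_index
  cont <- c("Age", "RestingBP", "Cholesterol", "MaxHR", "Oldpeak")
  cats <- c("Sex", "ChestPainType", "FastingBS", "RestingECG",
            "ExerciseAngina", "ST_Slope")

  # 11-qubit angle design: raw predictors, categoricals integer-coded, then
  # train-fitted min-max onto [0, 2*pi]
  raw11 <- vapply(
    c("Age", "Sex", "ChestPainType", "RestingBP", "Cholesterol", "FastingBS",
      "RestingECG", "MaxHR", "ExerciseAngina", "Oldpeak", "ST_Slope"),
    function(cl) as.numeric(table[[cl]]),
    numeric(nrow(table))
  )
  angle_matrix <- apply_cols_fitted(raw11, tr, scale_to_angle)

  amplitude_block <- apply_cols_fitted(
    vapply(cont, function(cl) as.numeric(table[[cl]]), numeric(nrow(table))),
    tr, standardize
  )

  basis_block <- do.call(cbind, lapply(cats, function(cl) {
    m <- one_hot(table[[cl]], scheme = "drop_first")
    colnames(m) <- paste0(cl, "=", colnames(m))
    m
  }))

  std_cont <- amplitude_block
  bin3 <- cbind(
    "Sex=M" = as.integer(table$Sex == "M"),
    "FastingBS=1" = as.integer(table$FastingBS == "1"),
    "ExerciseAngina=Y" = as.integer(table$ExerciseAngina == "Y")
  )
  nn_matrix <- switch(
    nn_scheme,
    compact = {
      cp <- one_hot(table$ChestPainType, scheme = "drop_first")
      colnames(cp) <- paste0("ChestPainType=", colnames(cp))
      cbind(std_cont, bin3, cp,
            RestingECG = as.numeric(table$RestingECG),
            ST_Slope = as.numeric(table$ST_Slope))
    },
    drop_first = cbind(std_cont, basis_block),
    full = {
      m <- do.call(cbind, lapply(cats, function(cl) {
        h <- one_hot(table[[cl]], scheme = "full")
        colnames(h) <- paste0(cl, "=", colnames(h))
        h
      }))
      cbind(std_cont, m)
    }
  )

  y01 <- as.numeric(table$HeartDisease)
  structure(
    list(
      angle_matrix = angle_matrix,
      amplitude_block = amplitude_block,
      basis_block = basis_block,
      nn_matrix = nn_matrix,
      labels01 = y01,
      labels_pm = encode_labels(y01),
      train_index = sp$train_index,
      test_index = sp$test_index,
      nn_scheme = nn_scheme
    ),
    class = "encoded_cohort"
  )
}

# fit a column-wise transform on the training rows, apply to all rows
apply_cols_fitted <- function(mat, train_index, f) {
  out <- vapply(seq_len(ncol(mat)), function(j) {
    fit <- attr(f(mat[train_index, j]), "fit")
    as.numeric(f(mat[, j], fit = fit))
  }, numeric(nrow(mat)))
  colnames(out) <- colnames(mat)
  out
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat(sprintf(
    "<encoded_cohort: %d records (%d train / %d test), nn design '%s' (%d cols)>\n",
    length(x$labels01), length(x$train_index), length(x$test_index),
    x$nn_scheme, ncol(x$nn_matrix)
  ))
  invisible(x)
}
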