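#' Specification of a synthetic heart-disease-like cohort
#'
#' Bundles everything [generate_cohort()] needs: sample size, the continuous
#' feature marginals (mean, SD, clipping range), the signed correlation
#' targets for (Age, MaxHR) and (Age, Oldpeak), the categorical level sets
#' with sampling probabilities, and a logistic label model whose intercept is
#' calibrated to a target disease prevalence. Defaults emulate the public
#' Heart Disease (coronary artery disease) tabular benchmark: 918 records,
#' 55% positive class, Age strongly anti-correlated with maximum heart rate
#' and moderately correlated with exercise-induced ST depression.
#'
#' @param n_records Cohort size (default 918).
#' @param target_prevalence Fraction of positive (disease) labels in
#'   expectation, in (0, 1).
#' @param continuous_marginals Tibble with columns `feature`, `mean`, `sd`,
#'   `min`, `max`.
#' @param correlation_targets Named numeric vector of signed correlations for
#'   `"Age:MaxHR"` and `"Age:Oldpeak"` (latent Gaussian scale).
#' @param categorical_levels Named list; each element is
#'   `list(levels = <chr>, probs = <numeric summing to 1>)`.
#' @param label_coefficients Named numeric vector of logistic coefficients on
#'   standardized continuous features and `Feature=Level` indicators.
#' @return A `cohort_spec` object (a validated list).
#' @export
cohort_spec <- function(n_records = 918,
                        target_prevalence = 0.55,
                        continuous_marginals = default_marginals(),
                        correlation_targets = c("Age:MaxHR" = -0.38,
                                                "Age:Oldpeak" = 0.26),
                        categorical_levels = default_categoricals(),
                        label_coefficients = default_label_coefficients()) {
  spec <- structure(
    list(
      n_records = as.integer(n_records),
      target_prevalence = target_prevalence,
      continuous_marginals = continuous_marginals,
      correlation_targets = correlation_targets,
      categorical_levels = categorical_levels,
      label_coefficients = label_coefficients
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n_records < 1) abort("n_records must be positive")
  if (spec$target_prevalence <= 0 || spec$target_prevalence >= 1) {
    abort("target_prevalence must be in (0, 1)")
  }
  m <- spec$continuous_marginals
  need <- c("feature", "mean", "sd", "min", "max")
  if (!all(need %in% names(m))) abort("continuous_marginals is missing columns")
  if (any(m$min >= m$max)) abort("every continuous feature needs min < max")
  if (any(m$sd <= 0)) abort("continuous SDs must be positive")
  for (nm in names(spec$categorical_levels)) {
    lv <- spec$categorical_levels[[nm]]
    if (length(lv$levels) != length(lv$probs)) {
      abort(sprintf("%s: levels and probs differ in length", nm))
    }
    if (abs(sum(lv$probs) - 1) > 1e-12) {
      abort(sprintf("%s: probabilities must sum to 1", nm))
    }
  }
  invisible(spec)
}

# Continuous marginals of the emulated benchmark (units: years, mmHg, mg/dL,
# bpm, ST-depression mm).
default_marginals <- function() {
  tibble(
    feature = c("Age", "RestingBP", "Cholesterol", "MaxHR", "Oldpeak"),
    mean = c(53.51, 132.40, 198.80, 136.80, 0.89),
    sd   = c(9.43, 18.51, 109.38, 25.46, 1.07),
    min  = c(28, 0, 0, 60, -2.6),
    max  = c(77, 200, 603, 202, 6.2)
  )
}

default_categoricals <- function() {
  list(
    Sex = list(levels = c("F", "M"), probs = c(0.21, 0.79)),
    ChestPainType = list(levels = c("TA", "ATA", "NAP", "ASY"),
                         probs = c(0.05, 0.19, 0.22, 0.54)),
    FastingBS = list(levels = c("0", "1"), probs = c(0.77, 0.23)),
    RestingECG = list(levels = c("Normal", "ST", "LVH"),
                      probs = c(0.60, 0.19, 0.21)),
    ExerciseAngina = list(levels = c("N", "Y"), probs = c(0.60, 0.40)),
    ST_Slope = list(levels = c("Up", "Flat", "Down"),
                    probs = c(0.43, 0.50, 0.07))
  )
}

# Logistic label model on standardized continuous features and level
# indicators; signs follow clinical direction (lower peak heart rate, more ST
# depression, exertional angina, asymptomatic presentation => higher risk).
default_label_coefficients <- function() {
  c(
    "Age" = 0.25, "RestingBP" = 0.10, "Cholesterol" = 0.10,
    "MaxHR" = -0.90, "Oldpeak" = 0.80,
    "Sex=M" = 0.70, "FastingBS=1" = 0.40,
    "ChestPainType=ASY" = 1.20, "ChestPainType=NAP" = 0.10,
    "RestingECG=ST" = 0.30, "RestingECG=LVH" = 0.20,
    "ExerciseAngina=Y" = 1.00,
    "ST_Slope=Flat" = 0.90, "ST_Slope=Down" = 0.90
  )
}

# linear predictor (without intercept) of the label model for a cohort table
label_linear_predictor <- function(tbl, spec) {
  m <- spec$continuous_marginals
  lp <- rep(0, nrow(tbl))
  for (cf in names(spec$label_coefficients)) {
    b <- spec$label_coefficients[[cf]]
    if (grepl("=", cf, fixed = TRUE)) {
      parts <- strsplit(cf, "=", fixed = TRUE)[[1]]
      lp <- lp + b * as.numeric(as.character(tbl[[parts[1]]]) == parts[2])
    } else {
      row <- m[m$feature == cf, ]
      lp <- lp + b * (tbl[[cf]] - row$mean) / row$sd
    }
  }
  lp
}

#' Generate a synthetic cohort
#'
#' Draws continuous features from a Gaussian copula with the spec's marginal
#' means/SDs and correlation targets (clipped to the spec's ranges),
#' categorical features multinomially, and the binary `HeartDisease` label
#' from a logistic model whose intercept is calibrated by root finding so the
#' expected prevalence matches `spec$target_prevalence`. Deterministic under
#' a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with the 11 predictor columns (`Age`, `Sex`,
#'   `ChestPainType`, `RestingBP`, `Cholesterol`, `FastingBS`, `RestingECG`,
#'   `MaxHR`, `ExerciseAngina`, `Oldpeak`, `ST_Slope`) and `HeartDisease` in
#'   `{0, 1}`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  withr::local_seed(seed)
  n <- spec$n_records
  m <- spec$continuous_marginals
  p <- nrow(m)

  # latent Gaussian with the target correlation structure
  R <- diag(p)
  dimnames(R) <- list(m$feature, m$feature)
  for (nm in names(spec$correlation_targets)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- spec$correlation_targets[[nm]]
  }
  z <- matrix(rnorm(n * p), n, p) %*% chol(R)
  cont <- purrr::map_dfc(seq_len(p), function(j) {
    x <- m$mean[j] + m$sd[j] * z[, j]
    tibble(!!m$feature[j] := pmin(pmax(x, m$min[j]), m$max[j]))
  })
  # ST depression is recorded to one decimal in the emulated source
  cont$Oldpeak <- round(cont$Oldpeak, 1)

  cats <- purrr::imap_dfc(spec$categorical_levels, function(lv, nm) {
    tibble(!!nm := factor(sample(lv$levels, n, replace = TRUE,
                                 prob = lv$probs), levels = lv$levels))
  })

  tbl <- dplyr::bind_cols(cont, cats)
  lp <- label_linear_predictor(tbl, spec)
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - spec$target_prevalence,
                c(-20, 20), tol = 1e-10)$root
  tbl$HeartDisease <- rbinom(n, 1, plogis(b0 + lp))

  tbl <- tbl[, c("Age", "Sex", "ChestPainType", "RestingBP", "Cholesterol",
                 "FastingBS", "RestingECG", "MaxHR", "ExerciseAngina",
                 "Oldpeak", "ST_Slope", "HeartDisease")]
  if (anyDuplicated(tbl) > 0) {
    abort("duplicate rows generated; this should be measure-zero")
  }
  tbl
}

#' Read or write a cohort CSV
#'
#' Uses the exact column names of the emulated benchmark so the real public
#' dataset can be dropped in unchanged.
#'
#' @param path CSV path.
#' @param table A cohort tibble as returned by [generate_cohort()].
#' @return `read_cohort_csv` returns a typed tibble; `write_cohort_csv`
#'   invisibly returns `path`.
#' @export
read_cohort_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("Age", "Sex", "ChestPainType", "RestingBP", "Cholesterol",
            "FastingBS", "RestingECG", "MaxHR", "ExerciseAngina", "Oldpeak",
            "ST_Slope", "HeartDisease")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste("cohort CSV is missing columns:", paste(missing, collapse = ", ")))
  }
  lv <- default_categoricals()
  for (nm in names(lv)) {
    tbl[[nm]] <- factor(as.character(tbl[[nm]]), levels = lv[[nm]]$levels)
    if (anyNA(tbl[[nm]])) abort(sprintf("unknown level in column %s", nm))
  }
  tbl[, need]
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  out <- dplyr::mutate(table, dplyr::across(dplyr::where(is.factor),
                                            as.character))
  readr::write_csv(out, path)
  invisible(path)
}
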