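#' Ansatz configuration for a variational quantum classifier
#'
#' The circuit family is a hardware-efficient layout: per layer, a row of
#' trainable RY rotations on all qubits, a "double structure" row of CZ gates
#' on pairs (0,1), (2,3), ..., a second RY row on an interior subset of
#' qubits, and a second CZ row on the offset pairs (1,2), (3,4), ... within
#' qubits `1..N-2`. Two conventions are supported for the second RY row:
#'
#' * `"exclude_last_only"` (default) — qubits `0..N-2`, giving `2N-1`
#'   rotations per layer, which matches the parameter-count formula
#'   `(2N-1)L`;
#' * `"exclude_first_and_last"` — qubits `1..N-2`, giving `2N-2` rotations,
#'   the literal reading of the layout prose.
#'
#' @param n_qubits Number of qubits `N` (>= 3); 11 for angle encoding, 13 for
#'   the hybrid amplitude/basis encoding.
#' @param layers Number of ansatz layers `L` (>= 1).
#' @param encoding `"angle"` or `"amplitude_hybrid"`.
#' @param reuploading Repeat the data-encoding block before every layer
#'   (data re-uploading). Only available with angle encoding.
#' @param second_row Second-RY-row convention, see above.
#' @return An `ansatz_config` object.
#' @export
ansatz_config <- function(n_qubits = 11, layers = 1,
                          encoding = c("angle", "amplitude_hybrid"),
                          reuploading = FALSE,
                          second_row = c("exclude_last_only",
                                         "exclude_first_and_last")) {
  encoding <- match.arg(encoding)
  second_row <- match.arg(second_row)
  if (n_qubits < 3) abort("the ansatz needs at least 3 qubits")
  if (layers < 1) abort("layers must be >= 1")
  if (reuploading && encoding != "angle") {
    abort("data re-uploading is only defined for angle encoding")
  }
  structure(
    list(n_qubits = as.integer(n_qubits), layers = as.integer(layers),
         encoding = encoding, reuploading = reuploading,
         second_row = second_row),
    class = "ansatz_config"
  )
}

#' @export
print.ansatz_config <- function(x, ...) {
  cat(sprintf(
    "<ansatz_config: %d qubits, %d layer%s, %s encoding%s, %d trainable params + bias>\n",
    x$n_qubits, x$layers, if (x$layers > 1) "s" else "", x$encoding,
    if (x$reuploading) " with re-uploading" else "", n_circuit_params(x)
  ))
  invisible(x)
}

slots_per_layer <- function(n_qubits, second_row) {
  n_qubits + switch(second_row,
                    exclude_last_only = n_qubits - 1L,
                    exclude_first_and_last = n_qubits - 2L)
}

#' Number of trainable circuit parameters
#'
#' `(2N-1) * L` under the default convention, `(2N-2) * L` under
#' `"exclude_first_and_last"`; the classical bias is not counted.
#'
#' @param config An [ansatz_config()].
#' @return Integer.
#' @export
n_circuit_params <- function(config) {
  as.integer(slots_per_layer(config$n_qubits, config$second_row) *
               config$layers)
}

#' Build one ansatz layer
#'
#' @param n_qubits Number of qubits (>= 3).
#' @param slot_offset First trainable slot index used by this layer.
#' @param second_row Second-RY-row convention (see [ansatz_config()]).
#' @return A gate tibble (RY rows carry consecutive `param` slots).
#' @export
build_ansatz_layer <- function(n_qubits,
                               slot_offset = 0L,
                               second_row = c("exclude_last_only",
                                              "exclude_first_and_last")) {
  second_row <- match.arg(second_row)
  if (n_qubits < 3) abort("the ansatz needs at least 3 qubits")
  n <- as.integer(n_qubits)
  ry_row <- function(qubits, offset) {
    new_gate_tbl("RY", qubits, NA_integer_, NA_real_,
                 offset + seq_along(qubits) - 1L, NA_integer_)
  }
  cz_row <- function(firsts) {
    if (length(firsts) == 0) return(new_gate_tbl())
    new_gate_tbl("CZ", firsts + 1L, firsts, NA_real_, NA_integer_,
                 NA_integer_)
  }
  row1 <- 0:(n - 1)
  row2 <- switch(second_row,
                 exclude_last_only = 0:(n - 2),
                 exclude_first_and_last = 1:(n - 2))
  cz1 <- seq(0L, n - 2L, by = 2L)                   # (0,1), (2,3), ...
  cz2 <- if (n >= 4) seq(1L, n - 3L, by = 2L) else integer(0)  # (1,2), (3,4), ...
  dplyr::bind_rows(
    ry_row(row1, slot_offset),
    cz_row(cz1),
    ry_row(row2, slot_offset + n),
    cz_row(cz2)
  )
}

#' Build the full model circuit for a configuration
#'
#' Without re-uploading: one data-encoding block followed by `L` ansatz
#' layers. With re-uploading: `L` repetitions of (encoding block, ansatz
#' layer). For the hybrid amplitude/basis encoding the data enters as the
#' initial state (prepared by [hybrid_encode()]), so the circuit holds only
#' the ansatz layers.
#'
#' @param config An [ansatz_config()].
#' @return A [qcircuit()] whose RY-angle gates reference input features
#'   (angle encoding) and trainable parameter slots.
#' @export
build_model_circuit <- function(config) {
  n <- config$n_qubits
  per <- slots_per_layer(n, config$second_row)
  layer_at <- function(l) {
    build_ansatz_layer(n, slot_offset = (l - 1L) * per,
                       second_row = config$second_row)
  }
  enc <- if (config$encoding == "angle") {
    angle_encode(n, as_features = TRUE)$gates
  } else {
    new_gate_tbl()
  }
  gates <- if (config$reuploading) {
    purrr::map_dfr(seq_len(config$layers),
                   function(l) dplyr::bind_rows(enc, layer_at(l)))
  } else {
    dplyr::bind_rows(enc,
                     purrr::map_dfr(seq_len(config$layers), layer_at))
  }
  qcircuit(n, gates, n_slots = per * config$layers)
}

#' Initialize VQC parameters
#'
#' Small-angle initialization: every rotation angle is `0.01 * g` with
#' `g ~ Normal(mean = 1, sd = 1)` (so the angles have mean and SD 0.01),
#' which keeps the circuit near identity and mitigates barren plateaus. The
#' classical bias starts at 0. A zero-mean variant (`g ~ Normal(0, 1)`) is
#' available via `centered = TRUE`.
#'
#' @param config An [ansatz_config()].
#' @param seed Integer seed.
#' @param scale Multiplier for the Gaussian draw (default 0.01).
#' @param centered Use mean-zero Gaussians instead of mean-one.
#' @return A `vqc_params` list with elements `theta` and `bias`.
#' @export
init_params <- function(config, seed = 1L, scale = 0.01, centered = FALSE) {
  withr::local_seed(seed)
  p <- n_circuit_params(config)
  mu <- if (centered) 0 else 1
  structure(list(theta = scale * rnorm(p, mean = mu, sd = 1), bias = 0),
            class = "vqc_params")
}
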