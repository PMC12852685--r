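#' Quantum state vectors
#'
#' A pure state on `n` qubits is a unit-norm complex vector of length `2^n`.
#' Qubit `q` (0-based) is the q-th least significant bit of the 0-based
#' amplitude index, so the printed basis label reads `|q0 q1 ...>` with the
#' first character belonging to qubit 0. Under this convention the amplitude
#' vector `(a, b, c, d)` on two qubits is `a|00> + b|10> + c|01> + d|11>`.
#'
#' @param amplitudes Complex (or real) vector whose length is a power of two.
#' @param n_qubits Alternative to `amplitudes`: build `|0...0>` on this many
#'   qubits.
#' @return An object of class `qstate`: a complex vector with attribute
#'   `n_qubits`.
#' @examples
#' qstate(n_qubits = 2)
#' qstate(c(0.4, 0.4, 0.8, 0.2))
#' @export
qstate <- function(amplitudes = NULL, n_qubits = NULL) {
  if (is.null(amplitudes)) {
    if (is.null(n_qubits) || n_qubits < 1) {
      abort("supply `amplitudes` or a positive `n_qubits`")
    }
    amplitudes <- c(1 + 0i, rep(0i, 2^n_qubits - 1))
  }
  amplitudes <- as.complex(amplitudes)
  n <- log2(length(amplitudes))
  if (n %% 1 != 0 || n < 1) {
    abort("amplitude vector length must be a power of two (>= 2)")
  }
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (abs(nrm - 1) > 1e-9) {
    abort(sprintf("state norm is %.3g, must be 1 (within 1e-9)", nrm))
  }
  structure(amplitudes, n_qubits = as.integer(n), class = "qstate")
}

#' @export
print.qstate <- function(x, digits = 4, max_terms = 16, ...) {
  n <- n_qubits(x)
  cat(sprintf("<qstate: %d qubit%s>\n", n, if (n > 1) "s" else ""))
  idx <- which(Mod(x) > 1e-12)
  shown <- head(idx, max_terms)
  for (i in shown) {
    lab <- paste(bit_at(i - 1, 0:(n - 1)), collapse = "")
    amp <- unclass(x)[i]
    amp_str <- if (abs(Im(amp)) < 1e-12) {
      format(Re(amp), digits = digits)
    } else {
      format(amp, digits = digits)
    }
    cat(sprintf("  %s |%s>\n", amp_str, lab))
  }
  if (length(idx) > max_terms) cat(sprintf("  ... %d more terms\n", length(idx) - max_terms))
  invisible(x)
}

n_qubits <- function(x) attr(x, "n_qubits")

bit_at <- function(index, bits) bitwAnd(bitwShiftR(index, bits), 1L)

gate_kinds <- c(RX = 0L, RY = 1L, RZ = 2L, CNOT = 3L, CZ = 4L)

new_gate_tbl <- function(gate = character(), target = integer(),
                         control = integer(), angle = double(),
                         param = integer(), feature = integer()) {
  tibble(
    gate = gate, target = as.integer(target),
    control = as.integer(control), angle = as.double(angle),
    param = as.integer(param), feature = as.integer(feature)
  )
}

#' Parameterized quantum circuits
#'
#' A circuit is an ordered list of gates on `n_qubits` qubits, stored as a
#' tibble with one row per gate. Rotation angles can be fixed (`angle`), bound
#' to a trainable parameter slot (`param`, 0-based), or bound to an input
#' feature (`feature`, 0-based); two-qubit gates carry a `control` qubit.
#'
#' @param n_qubits Number of qubits.
#' @param gates Tibble of gates (columns `gate`, `target`, `control`, `angle`,
#'   `param`, `feature`); defaults to the empty circuit.
#' @param n_slots Number of trainable parameter slots referenced by the
#'   circuit (slots must be dense `0..n_slots-1`).
#' @return A `qcircuit` object.
#' @export
qcircuit <- function(n_qubits, gates = NULL, n_slots = 0L) {
  if (n_qubits < 1) abort("n_qubits must be positive")
  gates <- gates %||% new_gate_tbl()
  stopifnot(all(gates$gate %in% names(gate_kinds)))
  if (nrow(gates) > 0) {
    if (any(gates$target < 0 | gates$target >= n_qubits)) {
      abort("gate target out of range")
    }
    two <- gates$gate %in% c("CNOT", "CZ")
    if (any(two & (is.na(gates$control) | gates$control == gates$target))) {
      abort("CNOT/CZ require a control qubit different from the target")
    }
    if (any(!two & !is.na(gates$control))) {
      abort("rotation gates cannot have a control qubit")
    }
    slots <- gates$param[!is.na(gates$param)]
    # dropout-masked circuits may omit slots, but none may exceed n_slots-1
    if (length(slots) > 0 && (min(slots) < 0 || max(slots) >= n_slots)) {
      abort("parameter slots must lie in 0..n_slots-1")
    }
  }
  structure(
    list(n_qubits = as.integer(n_qubits), gates = gates,
         n_slots = as.integer(n_slots)),
    class = "qcircuit"
  )
}

#' @export
print.qcircuit <- function(x, ...) {
  cat(sprintf("<qcircuit: %d qubits, %d gates, %d trainable slots>\n",
              x$n_qubits, nrow(x$gates), x$n_slots))
  invisible(x)
}

# compile a circuit's gate tibble to the numeric matrix the C++ kernels expect
circuit_matrix <- function(circuit) {
  g <- circuit$gates
  cbind(
    kind = unname(gate_kinds[g$gate]),
    target = g$target,
    control = ifelse(is.na(g$control), -1L, g$control),
    angle = ifelse(is.na(g$angle), 0, g$angle),
    pslot = ifelse(is.na(g$param), -1L, g$param),
    dslot = ifelse(is.na(g$feature), -1L, g$feature)
  )
}

#' Run a circuit on the statevector simulator
#'
#' Applies the gates in order, starting from `|0...0>` unless `init` is given.
#' The simulation is dense, noiseless and exact (the infinite-shot limit).
#'
#' @param circuit A [qcircuit()].
#' @param theta Numeric vector of trainable parameter values (length
#'   `circuit$n_slots`).
#' @param x Numeric feature vector for feature-bound gates.
#' @param init Optional initial [qstate()].
#' @return The final [qstate()].
#' @export
run_circuit <- function(circuit, theta = numeric(circuit$n_slots),
                        x = numeric(0), init = NULL) {
  if (length(theta) != circuit$n_slots) {
    abort(sprintf("theta has length %d, circuit expects %d",
                  length(theta), circuit$n_slots))
  }
  feats <- circuit$gates$feature
  if (length(feats) > 0 && any(!is.na(feats)) &&
      max(feats, na.rm = TRUE) >= length(x)) {
    abort("feature vector `x` shorter than the features the circuit binds")
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "qstate"), n_qubits(init) == circuit$n_qubits)
  }
  amps <- cpp_run_circuit(circuit$n_qubits, circuit_matrix(circuit),
                          as.double(theta), as.double(x),
                          if (is.null(init)) NULL else as.complex(init))
  structure(amps, n_qubits = circuit$n_qubits, class = "qstate")
}

#' Apply a single Pauli rotation to a state
#'
#' Applies the 2x2 rotation matrix `RX`, `RY` or `RZ` (angle `theta`, radians)
#' to one qubit. `RY(theta)` maps `|0>` to `cos(theta/2)|0> + sin(theta/2)|1>`.
#'
#' @param state A [qstate()].
#' @param axis One of `"X"`, `"Y"`, `"Z"`.
#' @param qubit 0-based qubit index.
#' @param theta Rotation angle in radians.
#' @return The rotated [qstate()].
#' @export
apply_rotation <- function(state, axis = c("X", "Y", "Z"), qubit, theta) {
  axis <- match.arg(axis)
  n <- n_qubits(state)
  if (qubit < 0 || qubit >= n) abort("qubit out of range")
  g <- new_gate_tbl(paste0("R", axis), qubit, NA_integer_, theta,
                    NA_integer_, NA_integer_)
  run_circuit(qcircuit(n, g), init = state)
}

#' Apply a CNOT or CZ gate to a state
#'
#' If the control qubit is `|1>`, the target receives an X flip (CNOT) or a Z
#' phase (CZ); nothing happens when the control is `|0>`. `CNOT|10> = |11>`
#' and `CZ|11> = -|11>`.
#'
#' @param state A [qstate()].
#' @param kind `"CNOT"` or `"CZ"`.
#' @param control,target Distinct 0-based qubit indices.
#' @return The transformed [qstate()].
#' @export
apply_two_qubit <- function(state, kind = c("CNOT", "CZ"), control, target) {
  kind <- match.arg(kind)
  n <- n_qubits(state)
  if (control == target) abort("control and target must differ")
  if (min(control, target) < 0 || max(control, target) >= n) {
    abort("qubit out of range")
  }
  g <- new_gate_tbl(kind, target, control, NA_real_, NA_integer_, NA_integer_)
  run_circuit(qcircuit(n, g), init = state)
}

#' Basis-encode a bit string
#'
#' Loads an n-bit string onto n qubits as the computational basis state with
#' that label: bits `c(0, 1, 0)` become `|010>`.
#'
#' @param bits Vector of 0/1 values (or a string such as `"010"`).
#' @return A [qstate()] with a single unit amplitude.
#' @export
basis_encode <- function(bits) {
  if (is.character(bits)) bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  if (length(bits) == 0) abort("empty bit vector")
  if (!all(bits %in% c(0L, 1L))) abort("bits must be 0 or 1")
  n <- length(bits)
  idx <- sum(bits * 2^(seq_len(n) - 1))  # qubit q is bit q of the index
  amps <- rep(0i, 2^n)
  amps[idx + 1] <- 1 + 0i
  qstate(amps)
}

#' Pauli-Z expectation of one qubit
#'
#' Returns `P(qubit = 0) - P(qubit = 1)`, a value in `[-1, 1]`.
#'
#' @param state A [qstate()].
#' @param qubit 0-based qubit index.
#' @return A real scalar.
#' @export
expectation_z <- function(state, qubit) {
  n <- n_qubits(state)
  if (qubit < 0 || qubit >= n) abort("qubit out of range")
  cpp_expz_all(as.complex(state), n)[qubit + 1]
}

#' Pauli-Z expectations of every qubit
#'
#' @param state A [qstate()].
#' @return Numeric vector of length `n_qubits`.
#' @export
expectation_z_all <- function(state) {
  cpp_expz_all(as.complex(state), n_qubits(state))
}

#' Serialize and restore circuits as plain text
#'
#' One gate per line: `kind target control angle param feature` with `.` for
#' unset fields. A header line carries the qubit and slot counts.
#'
#' @param circuit A [qcircuit()].
#' @param path File path.
#' @return `read_circuit` returns a [qcircuit()]; `write_circuit` invisibly
#'   returns `path`.
#' @export
write_circuit <- function(circuit, path) {
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  g <- circuit$gates
  lines <- c(
    sprintf("qcircuit %d %d", circuit$n_qubits, circuit$n_slots),
    sprintf("%s %s %s %s %s %s", g$gate, fmt(g$target), fmt(g$control),
            fmt(g$angle), fmt(g$param), fmt(g$feature))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "qcircuit") abort("not a circuit file")
  body <- lines[-1]
  parse_num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  if (length(body) == 0) {
    return(qcircuit(as.integer(hdr[2]), n_slots = as.integer(hdr[3])))
  }
  parts <- do.call(rbind, strsplit(body, " "))
  g <- new_gate_tbl(parts[, 1], parse_num(parts[, 2]), parse_num(parts[, 3]),
                    parse_num(parts[, 4]), parse_num(parts[, 5]),
                    parse_num(parts[, 6]))
  qcircuit(as.integer(hdr[2]), g, n_slots = as.integer(hdr[3]))
}
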