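#' Angle encoding of a feature vector
#'
#' Loads a length-N feature vector onto N qubits by applying `RY(x_i)` to
#' qubit i. Features are expected on the `[0, 2*pi]` scale produced by
#' [scale_to_angle()].
#'
#' @param x Numeric vector in `[0, 2*pi]` (one qubit per entry), or, with
#'   `as_features = TRUE`, the number of features to bind symbolically.
#' @param as_features If `TRUE`, `x` is an integer count and the returned
#'   circuit binds each rotation to input feature `i` instead of a fixed
#'   angle, so the same circuit serves every record.
#' @return A [qcircuit()] of RY gates on `length(x)` qubits.
#' @export
angle_encode <- function(x, as_features = FALSE) {
  if (as_features) {
    n <- as.integer(x)
    g <- new_gate_tbl("RY", 0:(n - 1), NA_integer_, NA_real_, NA_integer_,
                      0:(n - 1))
    return(qcircuit(n, g))
  }
  if (length(x) == 0) abort("empty feature vector")
  if (any(x < -1e-9 | x > 2 * pi + 1e-9)) {
    abort("angle-encoded features must lie in [0, 2*pi]")
  }
  n <- length(x)
  g <- new_gate_tbl("RY", 0:(n - 1), NA_integer_, as.double(x), NA_integer_,
                    NA_integer_)
  qcircuit(n, g)
}

# Uniformly controlled RY: rotate `target` by beta[j+1] when the control
# qubits (low bit first) read j. Recursive decomposition into RY and CNOT:
#   UC(c + rest, beta) = UC(rest, (b0+b1)/2) CNOT(c) UC(rest, (b0-b1)/2) CNOT(c)
# using X RY(a) X = RY(-a), where c is the highest control.
uc_ry <- function(controls, target, beta) {
  if (length(controls) == 0) {
    return(new_gate_tbl("RY", target, NA_integer_, beta, NA_integer_,
                        NA_integer_))
  }
  m <- length(controls)
  c_hi <- controls[m]
  half <- length(beta) / 2
  b0 <- beta[seq_len(half)]
  b1 <- beta[half + seq_len(half)]
  cnot <- new_gate_tbl("CNOT", target, c_hi, NA_real_, NA_integer_,
                       NA_integer_)
  dplyr::bind_rows(
    uc_ry(controls[-m], target, (b0 + b1) / 2),
    cnot,
    uc_ry(controls[-m], target, (b0 - b1) / 2),
    cnot
  )
}

#' Mottonen state preparation for real amplitude vectors
#'
#' Builds a circuit of uniformly controlled RY rotations (decomposed into RY
#' and CNOT gates) that prepares an arbitrary real unit vector `v` from
#' `|0...0>`: running the circuit yields a state whose amplitudes equal `v`
#' under the package's basis-label convention. Signed entries are reached via
#' the final rotation level; complex phases are not supported (the pipeline
#' only needs real amplitudes), so no RZ stage is emitted.
#'
#' @param v Real unit vector whose length is a power of two (pad with zeros
#'   first if needed).
#' @return A [qcircuit()] on `log2(length(v))` qubits.
#' @examples
#' st <- run_circuit(mottonen_prepare(c(0.4, 0.4, 0.8, 0.2)))
#' Re(st)  # 0.4 0.4 0.8 0.2
#' @export
mottonen_prepare <- function(v) {
  v <- as.double(v)
  k <- log2(length(v))
  if (k %% 1 != 0 || k < 1) abort("length must be a power of two (>= 2)")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9) abort("input must be a unit vector")
  n <- as.integer(k)
  # Subtree norms, computed bottom-up. At step t entries of r are indexed by
  # bits t..n-1 of the amplitude index (bit t is the LSB of the r index), so
  # adjacent pairs differ in bit t; the leaf level (t = 0) uses the signed
  # amplitudes themselves, which is where signs enter (beta/2 = atan2 of the
  # signed pair), all higher levels see nonnegative norms.
  betas <- vector("list", n)
  r <- v
  for (t in 0:(n - 1)) {
    a0 <- r[c(TRUE, FALSE)]
    a1 <- r[c(FALSE, TRUE)]
    betas[[t + 1]] <- 2 * atan2(a1, a0)
    r <- sqrt(a0^2 + a1^2)
  }
  # Emit top-down: rotate qubit n-1 unconditionally, then each lower qubit t
  # as a uniformly controlled rotation on the qubits above it. The angle
  # vector for target t is indexed by the value of bits t+1..n-1, matching
  # uc_ry's low-bit-first control ordering.
  gates <- new_gate_tbl()
  for (t in (n - 1):0) {
    controls <- if (t < n - 1) (t + 1):(n - 1) else integer(0)
    gates <- dplyr::bind_rows(gates, uc_ry(controls, t, betas[[t + 1]]))
  }
  qcircuit(n, gates)
}

#' Adjoint (inverse) of a circuit of rotations and CNOT/CZ gates
#'
#' Reverses the gate order and negates rotation angles; CNOT and CZ are
#' self-inverse. Only fixed-angle circuits can be inverted this way.
#'
#' @param circuit A [qcircuit()] with no parameter- or feature-bound gates.
#' @return The inverse [qcircuit()].
#' @export
adjoint_circuit <- function(circuit) {
  g <- circuit$gates
  if (any(!is.na(g$param)) || any(!is.na(g$feature))) {
    abort("adjoint is only defined for fixed-angle circuits")
  }
  g <- g[rev(seq_len(nrow(g))), ]
  g$angle <- -g$angle
  qcircuit(circuit$n_qubits, g)
}

#' Hybrid amplitude/basis encoding of one clinical record
#'
#' Encodes the five standardized continuous features by amplitude encoding
#' (padded with three zeros to length 8, L2-normalized, Mottonen-prepared on
#' 3 qubits) and the ten drop-first categorical indicator bits by basis
#' encoding on 10 qubits, for 13 qubits in total. The result is the product
#' state with the amplitude register on qubits 0-2 and the basis register on
#' qubits 3-12.
#'
#' @param continuous5 Numeric vector of 5 standardized continuous features.
#' @param categorical_bits 0/1 vector of length 10.
#' @return A 13-qubit [qstate()].
#' @export
hybrid_encode <- function(continuous5, categorical_bits) {
  if (length(continuous5) != 5) abort("expected 5 continuous features")
  if (length(categorical_bits) != 10 ||
      !all(categorical_bits %in% c(0, 1))) {
    abort("expected 10 categorical bits")
  }
  padded <- c(continuous5, 0, 0, 0)
  nrm <- sqrt(sum(padded^2))
  if (nrm == 0) abort("continuous block is all zero; cannot normalize")
  amp_reg <- Re(run_circuit(mottonen_prepare(padded / nrm)))
  basis_reg <- as.complex(basis_encode(categorical_bits))
  # full index bits 0-2 from the amplitude register (fast), 3-12 from the
  # basis register (slow) => kron(basis, amplitude)
  qstate(kronecker(basis_reg, amp_reg))
}
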