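# Independent oracles used across the suite. The dense-matrix simulator
# builds explicit 2^n x 2^n unitaries by Kronecker products and never touches
# the package's statevector kernels.

rx_mat <- function(th) {
  matrix(c(cos(th / 2), -1i * sin(th / 2),
           -1i * sin(th / 2), cos(th / 2)), 2, 2, byrow = TRUE)
}
ry_mat <- function(th) {
  matrix(c(cos(th / 2), -sin(th / 2),
           sin(th / 2), cos(th / 2)), 2, 2, byrow = TRUE)
}
rz_mat <- function(th) diag(c(exp(-1i * th / 2), exp(1i * th / 2)))

# Full-register operator for a single-qubit matrix on qubit q: qubit 0 is the
# least significant bit, so it sits rightmost in the Kronecker chain.
embed_1q <- function(m2, q, n) {
  mats <- rep(list(diag(2)), n)
  mats[[q + 1]] <- m2
  Reduce(kronecker, rev(mats))
}

embed_ctrl <- function(q_ctrl, q_targ, target_2x2, n) {
  p0 <- diag(c(1, 0))
  p1 <- diag(c(0, 1))
  term <- function(proj, act) {
    mats <- rep(list(diag(2)), n)
    mats[[q_ctrl + 1]] <- proj
    if (!is.null(act)) mats[[q_targ + 1]] <- act
    Reduce(kronecker, rev(mats))
  }
  term(p0, NULL) + term(p1, target_2x2)
}

x_mat <- matrix(c(0, 1, 1, 0), 2, 2)
z_mat <- diag(c(1, -1))

dense_gate <- function(row, n, theta, x) {
  angle_of <- function(row) {
    if (!is.na(row$param)) theta[row$param + 1]
    else if (!is.na(row$feature)) x[row$feature + 1]
    else row$angle
  }
  switch(row$gate,
    RX = embed_1q(rx_mat(angle_of(row)), row$target, n),
    RY = embed_1q(ry_mat(angle_of(row)), row$target, n),
    RZ = embed_1q(rz_mat(angle_of(row)), row$target, n),
    CNOT = embed_ctrl(row$control, row$target, x_mat, n),
    CZ = embed_ctrl(row$control, row$target, z_mat, n)
  )
}

# State after a circuit, by explicit matrix products (oracle for run_circuit)
dense_run <- function(circuit, theta = numeric(), x = numeric(),
                      init = NULL) {
  n <- circuit$n_qubits
  psi <- if (is.null(init)) c(1, rep(0, 2^n - 1)) else as.complex(init)
  g <- circuit$gates
  for (k in seq_len(nrow(g))) {
    psi <- dense_gate(g[k, ], n, theta, x) %*% psi
  }
  as.complex(psi)
}

dense_expz <- function(psi, qubit, n) {
  idx <- 0:(2^n - 1)
  sign <- ifelse(bitwAnd(bitwShiftR(idx, qubit), 1L) == 1, -1, 1)
  sum(sign * Mod(psi)^2)
}

random_circuit <- function(n, n_gates, rng_free = FALSE) {
  gates <- purrr::map_dfr(seq_len(n_gates), function(i) {
    kind <- sample(c("RX", "RY", "RZ", "CNOT", "CZ"), 1)
    if (kind %in% c("CNOT", "CZ")) {
      qs <- sample(0:(n - 1), 2)
      tibble::tibble(gate = kind, target = qs[1], control = qs[2],
                     angle = NA_real_, param = NA_integer_,
                     feature = NA_integer_)
    } else {
      tibble::tibble(gate = kind, target = sample(0:(n - 1), 1),
                     control = NA_integer_, angle = runif(1, -2 * pi, 2 * pi),
                     param = NA_integer_, feature = NA_integer_)
    }
  })
  qcircuit(n, gates)
}

# central finite differences of a scalar function
finite_diff <- function(f, at, h = 1e-5) {
  vapply(seq_along(at), function(k) {
    up <- at; up[k] <- up[k] + h
    dn <- at; dn[k] <- dn[k] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# minimal encoded-cohort stand-in for toy training tasks
make_toy_encoded <- function(angle_matrix, y01, train_index,
                             test_index = integer(0)) {
  structure(
    list(
      angle_matrix = angle_matrix,
      amplitude_block = NULL, basis_block = NULL,
      nn_matrix = angle_matrix,
      labels01 = y01, labels_pm = encode_labels(y01),
      train_index = train_index, test_index = test_index,
      nn_scheme = "toy"
    ),
    class = "encoded_cohort"
  )
}

# 3-feature toy task, separable within the model class: the two classes sit
# in well-separated angle clusters, so a sum of per-qubit <Z> values (cosine
# features) splits them cleanly once the bias and rotations settle.
toy_separable <- function(n = 80, seed = 42) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    centre <- ifelse(y == 1, 0.8, pi + 0.6)
    X <- vapply(1:3, function(j) {
      pmin(pmax(rnorm(n, centre, 0.35), 0), 2 * pi)
    }, numeric(n))
    colnames(X) <- paste0("x", 1:3)
    make_toy_encoded(X, y, seq_len(n))
  })
}
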