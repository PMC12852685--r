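# Shared optimizer plumbing for the quantum and classical training loops.

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# Draw the epoch's batches (as lists of positions into the training rows),
# using the current RNG stream. With at least batches*batch_size rows
# available, `batches` batches of exactly `batch_size` are sampled without
# replacement; a smaller (sub)sample is reshuffled and partitioned, keeping
# the final short batch.
make_batches <- function(n_avail, batches, batch_size) {
  want <- batches * batch_size
  if (n_avail >= want) {
    idx <- sample.int(n_avail, want)
    split(idx, rep(seq_len(batches), each = batch_size))
  } else {
    idx <- sample.int(n_avail, n_avail)
    split(idx, ceiling(seq_along(idx) / batch_size))
  }
}

sigmoid <- function(z) 1 / (1 + exp(-z))
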