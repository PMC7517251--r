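# Independent brute-force oracles used to check the package's closed forms
# and samplers. These deliberately re-derive everything from the energy
# definition with plain loops, sharing no code path with the implementation.

# exact joint distribution of an RBM by direct enumeration of all states
oracle_enumerate <- function(W, b_h, b_v, beta = 1) {
  n_h <- nrow(W); n_v <- ncol(W)
  hs <- as.matrix(expand.grid(rep(list(0:1), n_h)))[, n_h:1, drop = FALSE]
  vs <- as.matrix(expand.grid(rep(list(0:1), n_v)))[, n_v:1, drop = FALSE]
  p <- matrix(0, nrow(hs), nrow(vs))
  for (a in seq_len(nrow(hs))) {
    for (b in seq_len(nrow(vs))) {
      h <- hs[a, ]; v <- vs[b, ]
      e <- -(sum(b_v * v) + sum(b_h * h) + sum(h * (W %*% v)))
      p[a, b] <- exp(-beta * e)
    }
  }
  z <- sum(p)
  list(joint = p / z, p_h = rowSums(p) / z, p_v = colSums(p) / z,
       h_states = hs, v_states = vs, log_z = log(z))
}

# exact Boltzmann distribution of an L x L periodic Ising lattice (L small)
oracle_ising_distribution <- function(L, temperature) {
  n <- L * L
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  e <- numeric(nrow(states))
  for (k in seq_len(nrow(states))) {
    s <- matrix(states[k, ], L, L, byrow = TRUE)
    en <- 0
    for (y in seq_len(L)) {
      for (x in seq_len(L)) {
        en <- en - s[y, x] * s[y, x %% L + 1] - s[y, x] * s[y %% L + 1, x]
      }
    }
    e[k] <- en
  }
  w <- exp(-e / temperature)
  list(states = states, prob = w / sum(w), energy = e)
}

# bit-string key of a +/-1 state row, in the package's 0/1 convention
oracle_state_key <- function(srow) paste0(as.integer(srow > 0), collapse = "")

# standard error from batch means (guards against residual autocorrelation)
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  b <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(k) mean(x[((k - 1) * b + 1):(k * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# total-variation distance between an empirical table of keys and exact probs
tv_distance <- function(keys, exact_keys, exact_prob) {
  emp <- table(factor(keys, levels = exact_keys)) / length(keys)
  0.5 * sum(abs(as.numeric(emp) - exact_prob))
}

random_tiny_rbm <- function(n_v, n_h, scale = 1, seed = 1) {
  withr::with_seed(seed, {
    rbm(matrix(stats::runif(n_h * n_v, -scale, scale), n_h, n_v),
        stats::runif(n_h, -scale, scale), stats::runif(n_v, -scale, scale))
  })
}
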