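test_that("conditional entropy is the sum of per-unit binary entropies", {
  m <- rbm(matrix(0, 3, 2))
  expect_equal(conditional_hidden_entropy(m, c(0, 1)), 3)

  # single unit with activation a = 2: check against direct binary entropy
  m1 <- rbm(matrix(c(2), 1, 1))
  p <- 1 / (1 + exp(-2))
  h_bits <- -(p * log2(p) + (1 - p) * log2(1 - p))
  expect_equal(conditional_hidden_entropy(m1, 1), h_bits, tolerance = 1e-12)
  expect_equal(h_bits, 0.5271, tolerance = 1e-4)   # = 0.3653 nats

  # saturated activations do not overflow
  m_sat <- rbm(matrix(700, 4, 1))
  expect_equal(conditional_hidden_entropy(m_sat, 1), 0)
  m_neg <- rbm(matrix(-700, 4, 1))
  expect_equal(conditional_hidden_entropy(m_neg, 1), 0)

  # random activations: oracle = per-unit binary entropy summation
  withr::with_seed(20, {
    for (rep in 1:25) {
      a <- runif(5, -8, 8)
      m_r <- rbm(matrix(a, 5, 1))
      p_r <- 1 / (1 + exp(-a))
      oracle <- sum(-p_r * log2(p_r) - (1 - p_r) * log2(1 - p_r))
      expect_equal(conditional_hidden_entropy(m_r, 1), oracle,
                   tolerance = 1e-10)
    }
  })

  # invariant under permutation of hidden units
  m2 <- random_tiny_rbm(3, 4, seed = 21)
  perm <- c(3, 1, 4, 2)
  m2p <- rbm(m2$W[perm, ], m2$b_h[perm], m2$b_v)
  v <- c(1, 0, 1)
  expect_equal(conditional_hidden_entropy(m2, v),
               conditional_hidden_entropy(m2p, v))
})

test_that("hidden marginal energies reproduce the enumerated marginal", {
  z <- rbm(matrix(0, 2, 3))
  eh <- hidden_marginal_energy(z, enumerate_states(2))
  expect_equal(eh, rep(-3 * log(2), 4))

  m <- random_tiny_rbm(3, 2, seed = 22)
  o <- oracle_enumerate(m$W, m$b_h, m$b_v)
  eh2 <- hidden_marginal_energy(m, o$h_states)
  log_z_h <- logsumexp(-eh2)
  expect_equal(eh2 + log_z_h, -log(o$p_h), tolerance = 1e-10)
})

test_that("visible free energy matches explicit summation and Eq-4 identity", {
  z <- rbm(matrix(0, 3, 2))
  expect_equal(visible_free_energy(z, c(1, 0)), -3 * log(2))

  withr::with_seed(23, {
    for (rep in 1:10) {
      n_v <- sample(2:4, 1); n_h <- sample(2:3, 1)
      m <- rbm(matrix(runif(n_h * n_v, -2, 2), n_h, n_v),
               runif(n_h, -1, 1), runif(n_v, -1, 1))
      vs <- enumerate_states(n_v)
      hs <- enumerate_states(n_h)
      f <- visible_free_energy(m, vs)
      for (i in seq_len(nrow(vs))) {
        # explicit sum over hidden states
        e_joint <- joint_energy(m, hs,
                                matrix(vs[i, ], nrow(hs), n_v, byrow = TRUE))
        expect_equal(f[i], -logsumexp(-e_joint), tolerance = 1e-10)
        # free energy = expected joint energy minus conditional entropy
        q <- exp(-e_joint) / sum(exp(-e_joint))
        h_nats <- conditional_hidden_entropy(m, vs[i, ]) * log(2)
        expect_equal(f[i], sum(q * e_joint) - h_nats, tolerance = 1e-8)
      }
    }
  })
})

test_that("expected conditional energy: enumeration, sampling, point mass", {
  z <- rbm(matrix(0, 2, 3))
  e <- expected_conditional_energy(z, c(1, 0, 1), mode = "enumerate")
  expect_equal(as.numeric(e), hidden_marginal_energy(z, c(1, 1)))

  m <- random_tiny_rbm(3, 3, seed = 24)
  vs <- enumerate_states(3)
  exact <- expected_conditional_energy(m, vs, mode = "enumerate")
  # independent oracle: conditional expectation from enumerated joint
  o <- oracle_enumerate(m$W, m$b_h, m$b_v)
  eh <- hidden_marginal_energy(m, o$h_states)
  for (i in seq_len(nrow(vs))) {
    q <- o$joint[, i] / o$p_v[i]
    expect_equal(exact[i], sum(q * eh), tolerance = 1e-10)
  }
  mc <- expected_conditional_energy(m, vs, mode = "sample",
                                    n_samples = 100000, seed = 25)
  # per-stimulus Monte Carlo error at n = 1e5 (3 sigma with sd <~ 1.5 nats)
  expect_lt(max(abs(as.numeric(mc) - as.numeric(exact))), 0.05)

  # forced (saturated) conditional is a point mass
  m_f <- rbm(matrix(c(50, -50, 50), 3, 1))
  ef <- expected_conditional_energy(m_f, 1, mode = "enumerate")
  expect_equal(as.numeric(ef), hidden_marginal_energy(m_f, c(1, 0, 1)),
               tolerance = 1e-8)
  expect_error(expected_conditional_energy(rbm(matrix(0, 21, 2)), c(0, 1),
                                           mode = "enumerate"), "enumerate")
})

test_that("empirical stimulus energies are negative log2 frequencies", {
  d <- pattern_dataset(matrix(c(0, 1, 0, 1), 4, 1))
  tab <- empirical_stimulus_energy(d)
  expect_equal(tab$energy_bits, c(1, 1))
  d2 <- pattern_dataset(matrix(c(1, 1, 1, 0), 4, 1))
  tab2 <- empirical_stimulus_energy(d2)
  expect_equal(sort(tab2$energy_bits), sort(c(2, log2(4 / 3))))
})

test_that("enumerate_model is exact and consistent across energy routes", {
  z <- rbm(matrix(0, 2, 2))
  o <- enumerate_model(z)
  expect_equal(as.vector(o$joint), rep(1 / 16, 16))
  expect_equal(o$log_z, 4 * log(2))

  m <- random_tiny_rbm(4, 3, seed = 26)
  en <- enumerate_model(m)
  oracle <- oracle_enumerate(m$W, m$b_h, m$b_v)
  expect_equal(en$joint, oracle$joint, tolerance = 1e-12, ignore_attr = TRUE)
  # visible marginal from free energies equals enumerated marginal
  f <- visible_free_energy(m, en$v_states)
  expect_equal(exp(-f) / sum(exp(-f)), en$p_v, tolerance = 1e-10)
  expect_error(enumerate_model(rbm(matrix(0, 20, 10))), "24")
})

test_that("stimulus thermo table reports normalized, anchored energies", {
  m <- random_tiny_rbm(3, 2, seed = 27)
  d <- pattern_dataset(withr::with_seed(28,
    matrix(rbinom(300, 1, 0.5), 100, 3)))
  tab <- stimulus_thermo(m, d, mode = "enumerate")
  expect_true(all(tab$E_code_bits >= 0))
  expect_true(all(tab$F_visible_bits >= 0))
  expect_equal(min(tab$F_visible_bits), 0)
  expect_true(all(tab$H_cond_bits >= 0 & tab$H_cond_bits <= 2))
  expect_equal(sum(tab$frequency), 1)
})
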