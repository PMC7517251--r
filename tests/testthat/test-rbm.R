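test_that("unit activations follow the logistic form", {
  m <- rbm(matrix(0, 3, 2))
  expect_equal(unit_activation(m, c(0, 1)), rep(0.5, 3))
  m2 <- rbm(matrix(c(2, -1), 1, 2), b_h = 0.5)
  expect_equal(unit_activation(m2, c(1, 1)), 1 / (1 + exp(-1.5)))
  expect_equal(unit_activation(m2, c(1, 1)), 0.8176, tolerance = 1e-4)
  # reverse direction uses the transposed weights
  expect_equal(unit_activation(m2, 1, "visible-given-hidden"),
               sigmoid(c(2, -1) + 0))
  # near-zero beta is the uniform high-temperature limit
  hot <- scale_temperature(random_tiny_rbm(3, 2, scale = 1, seed = 2), 1e-9)
  expect_true(all(abs(unit_activation(hot, c(1, 0, 1)) - 0.5) < 1e-6))
  expect_error(unit_activation(m2, c(1, 1, 1)), "length")
})

test_that("joint energy matches the bilinear form and beta scaling", {
  m <- random_tiny_rbm(3, 2, seed = 3)
  expect_identical(joint_energy(m, c(0, 0), c(0, 0, 0)), 0)
  # a single hidden bias of ln 3 makes h=1 three times likelier than h=0
  m3 <- rbm(matrix(0, 1, 2), b_h = log(3))
  e1 <- joint_energy(m3, 1, c(1, 0))
  e0 <- joint_energy(m3, 0, c(1, 0))
  expect_equal(exp(-(e1 - e0)), 3)
  oracle <- oracle_enumerate(m3$W, m3$b_h, m3$b_v)
  expect_equal(oracle$p_h[2] / oracle$p_h[1], 3, tolerance = 1e-12)
  # energy is linear in beta
  m_b2 <- m; m_b2$beta <- 2
  h <- c(1, 0); v <- c(1, 1, 0)
  expect_equal(joint_energy(m_b2, h, v), 2 * joint_energy(m, h, v))
})

test_that("temperature scaling re-expresses the model at beta = 1", {
  m <- random_tiny_rbm(3, 2, seed = 4)
  s1 <- scale_temperature(m, 1)
  expect_equal(s1$W, m$W)
  expect_equal(scale_temperature(scale_temperature(m, 0.5), 0.5)$W,
               scale_temperature(m, 0.25)$W)
  # enumerated distribution equals base probabilities^beta renormalized
  beta <- 3
  sc <- scale_temperature(m, beta)
  base <- oracle_enumerate(m$W, m$b_h, m$b_v)
  scaled <- enumerate_model(sc)
  expected <- base$joint^beta / sum(base$joint^beta)
  expect_equal(scaled$joint, expected, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(scale_temperature(m, 0), "beta")
})

test_that("block Gibbs sampling reaches the enumerated joint distribution", {
  # zero-parameter model: uniform joint
  z <- rbm(matrix(0, 2, 3))
  s <- gibbs_sample(z, n_keep = 50000, n_chains = 100, thin = 1,
                    burn_in = 50, seed = 5)
  expect_true(all(abs(colMeans(s$h) - 0.5) < 0.01))
  expect_true(all(abs(colMeans(s$v) - 0.5) < 0.01))
  keys <- paste(pattern_strings(s$h), pattern_strings(s$v))
  oracle <- oracle_enumerate(z$W, z$b_h, z$b_v)
  exact_keys <- as.vector(outer(
    apply(oracle$h_states, 1, paste0, collapse = ""),
    apply(oracle$v_states, 1, paste0, collapse = ""), paste))
  expect_lt(tv_distance(keys, exact_keys, as.vector(oracle$joint)), 0.02)

  # random tiny model
  m <- random_tiny_rbm(3, 2, seed = 6)
  s2 <- gibbs_sample(m, n_keep = 200000, n_chains = 100, thin = 10,
                     burn_in = 200, seed = 7)
  o2 <- oracle_enumerate(m$W, m$b_h, m$b_v)
  keys2 <- paste(pattern_strings(s2$h), pattern_strings(s2$v))
  expect_lt(tv_distance(keys2, exact_keys, as.vector(o2$joint)), 0.02)

  # near-zero beta looks uniform again
  hot <- scale_temperature(m, 1e-6)
  s3 <- gibbs_sample(hot, n_keep = 50000, n_chains = 100, thin = 1,
                     burn_in = 50, seed = 8)
  keys3 <- paste(pattern_strings(s3$h), pattern_strings(s3$v))
  expect_lt(tv_distance(keys3, exact_keys, rep(1 / 32, 32)), 0.02)
})

test_that("the block-Gibbs kernel has the Boltzmann stationary distribution", {
  m <- random_tiny_rbm(3, 2, seed = 9)
  o <- oracle_enumerate(m$W, m$b_h, m$b_v)
  hs <- o$h_states; vs <- o$v_states
  n_joint <- nrow(hs) * nrow(vs)
  # transition (h,v) -> (h',v'): P(h'|v) * P(v'|h')
  trans <- matrix(0, n_joint, n_joint)
  idx <- function(a, b) (b - 1L) * nrow(hs) + a
  for (b in seq_len(nrow(vs))) {
    ph <- unit_activation(m, vs[b, ])
    for (a2 in seq_len(nrow(hs))) {
      p_h2 <- prod(ifelse(hs[a2, ] == 1, ph, 1 - ph))
      pv <- unit_activation(m, hs[a2, ], "visible-given-hidden")
      for (b2 in seq_len(nrow(vs))) {
        p_v2 <- prod(ifelse(vs[b2, ] == 1, pv, 1 - pv))
        for (a in seq_len(nrow(hs))) {
          trans[idx(a, b), idx(a2, b2)] <- trans[idx(a, b), idx(a2, b2)] +
            p_h2 * p_v2
        }
      }
    }
  }
  pi_vec <- as.vector(o$joint)
  expect_equal(as.vector(pi_vec %*% trans), pi_vec, tolerance = 1e-8)
})

test_that("CD1 learns a degenerate single-pattern distribution", {
  p <- c(1, 0, 1, 0)
  data <- pattern_dataset(matrix(rep(p, 200), ncol = 4, byrow = TRUE))
  fit <- train_cd1(data, 2, schedule = c(0.2, 0.1), epochs_per_stage = 4,
                   seed = 10)
  all_v <- enumerate_states(4)
  fe <- visible_free_energy(fit, all_v)
  expect_equal(unname(which.min(fe)), which(pattern_strings(all_v) == "1010"))
})

test_that("CD1 recovers a tiny ground-truth model in distribution", {
  gt <- withr::with_seed(11, rbm(matrix(rnorm(12, sd = 1.2), 3, 4),
                                 rnorm(3, sd = 0.5), rnorm(4, sd = 0.5)))
  o <- oracle_enumerate(gt$W, gt$b_h, gt$b_v)
  idx <- withr::with_seed(12, sample.int(16, 20000, replace = TRUE,
                                         prob = o$p_v))
  data <- pattern_dataset(o$v_states[idx, ])
  p_dat <- tabulate(idx, 16) / 20000
  kl_to <- function(model) {
    f <- visible_free_energy(model, o$v_states)
    q <- exp(-f) / sum(exp(-f))
    sum(p_dat[p_dat > 0] * log(p_dat[p_dat > 0] / q[p_dat > 0]))
  }
  fit <- train_cd1(data, 3, epochs_per_stage = 4, minibatch = 16, seed = 13)
  kl_init <- kl_to(rbm_random(4, 3, seed = 13))
  expect_lt(kl_to(fit), 0.1)
  expect_lt(kl_to(fit), kl_init)
})

test_that("training is reproducible and rejects bad input", {
  data <- pattern_dataset(matrix(rbinom(80, 1, 0.5), 20, 4))
  a <- train_cd1(data, 2, schedule = 0.1, epochs_per_stage = 1, seed = 14)
  b <- train_cd1(data, 2, schedule = 0.1, epochs_per_stage = 1, seed = 14)
  expect_identical(a$W, b$W)
  expect_error(train_cd1(data, 0), "n_hidden")
})
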