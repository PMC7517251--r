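test_that("model-data KL has its closed-form values", {
  d <- pattern_dataset(matrix(c(0, 1, 0, 1), 4, 1))
  expect_equal(model_data_kl(d, d, pseudocount = 0), 0)
  # held-out uniform over two patterns, model 3/4 on one
  held <- pattern_dataset(matrix(c(0, 1), 2, 1))
  mod <- pattern_dataset(matrix(c(0, 0, 0, 1), 4, 1))
  expect_equal(model_data_kl(mod, held, pseudocount = 0),
               0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25))
  expect_equal(model_data_kl(mod, held, pseudocount = 0), 0.2075,
               tolerance = 1e-4)
  expect_gte(model_data_kl(mod, held), 0)
})

test_that("activity statistics capture sparsity and correlation", {
  z <- rbm(matrix(0, 4, 3))
  s <- gibbs_sample(z, n_keep = 20000, n_chains = 50, thin = 1,
                    burn_in = 20, seed = 40)
  st <- activity_stats(s)
  expect_equal(st$sparsity, 0.5, tolerance = 0.02)
  expect_lt(st$mean_abs_correlation, 0.03)

  # duplicated hidden units correlate perfectly; constant units contribute 0
  fake <- structure(list(h = cbind(s$h[, 1], s$h[, 1], 1L),
                         v = s$v, chain_meta = list()),
                    class = "state_samples")
  st2 <- activity_stats(fake)
  expect_equal(st2$mean_abs_correlation, (1 + 0 + 0) / 3)
})

test_that("stimulus-energy binning is an even partition with closed edges", {
  b <- bin_by_stimulus_energy(c(1, 2, 3, 4), 2)
  expect_equal(as.integer(b), c(1L, 1L, 2L, 2L))
  expect_equal(attr(b, "edges"), c(1, 2.5, 4))
  # degenerate range
  b2 <- bin_by_stimulus_energy(rep(2, 5), 4)
  expect_equal(as.integer(b2), rep(1L, 5))
  # conservation on arbitrary data
  e <- withr::with_seed(41, runif(500, 6, 20))
  b3 <- bin_by_stimulus_energy(e, 10)
  expect_equal(sum(tabulate(b3, 10)), 500)
  expect_true(all(b3 >= 1 & b3 <= 10))
})

test_that("energy-entropy profile matches the enumeration oracle", {
  # zero model: entropy pinned at n_hidden bits, slopes vanish
  z <- rbm(matrix(0, 3, 2))
  d <- pattern_dataset(withr::with_seed(42, matrix(rbinom(400, 1, 0.3),
                                                   200, 2)))
  prof <- energy_entropy_profile(z, d, n_bins = 3, mode = "enumerate")
  expect_true(all(abs(prof$bins$mean_entropy - 3) < 1e-10))
  expect_equal(prof$slopes$entropy_vs_Ev, 0, tolerance = 1e-10)
  expect_equal(prof$I_enc,
               mean_code <- sum(prof$per_stimulus$frequency *
                                  prof$per_stimulus$E_code_bits) - 3,
               tolerance = 1e-10)

  # hand-set tiny model: bin means against a from-scratch oracle
  m <- random_tiny_rbm(2, 2, seed = 43)
  prof2 <- energy_entropy_profile(m, d, n_bins = 2, mode = "enumerate")
  o <- oracle_enumerate(m$W, m$b_h, m$b_v)
  tab <- empirical_stimulus_energy(d)
  eh <- hidden_marginal_energy(m, o$h_states)
  stats <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.integer(strsplit(tab$pattern[i], "")[[1]])
    col <- which(apply(o$v_states, 1, paste0, collapse = "") ==
                   tab$pattern[i])
    q <- o$joint[, col] / o$p_v[col]
    c(H = -sum(q[q > 0] * log2(q[q > 0])),
      E = sum(q * eh) / log(2))
  })
  h_orc <- vapply(stats, `[[`, numeric(1), "H")
  e_orc <- vapply(stats, `[[`, numeric(1), "E") - min(eh) / log(2)
  ord <- match(prof2$per_stimulus$pattern, tab$pattern)
  expect_equal(prof2$per_stimulus$H_cond_bits, h_orc[ord], tolerance = 1e-8)
  expect_equal(prof2$per_stimulus$E_code_bits, e_orc[ord], tolerance = 1e-8)

  # profiles are invariant to input row order
  d_rev <- pattern_dataset(d$x[rev(seq_len(200)), ])
  prof3 <- energy_entropy_profile(m, d_rev, n_bins = 2, mode = "enumerate")
  expect_equal(prof3$bins, prof2$bins, tolerance = 1e-12)
})

test_that("sampled profile converges to the enumerated profile", {
  m <- random_tiny_rbm(3, 3, seed = 44)
  d <- pattern_dataset(withr::with_seed(45, matrix(rbinom(900, 1, 0.5),
                                                   300, 3)))
  exact <- energy_entropy_profile(m, d, n_bins = 3, mode = "enumerate")
  errs <- vapply(c(500, 8000), function(n) {
    p <- energy_entropy_profile(m, d, n_bins = 3, mode = "sample",
                                n_samples = n, seed = 46)
    max(abs(p$bins$mean_code_energy - exact$bins$mean_code_energy))
  }, numeric(1))
  expect_lt(errs[[2]], errs[[1]])           # error shrinks with samples
  expect_lt(errs[[2]], 0.1)
})

test_that("profile slopes satisfy the chain-rule consistency relation", {
  # construct a synthetic profile with an exactly linear bin-mean relation
  ev <- seq(6, 20, length.out = 8)
  h <- 10 - 0.4 * ev
  e <- 3 - 0.3 * ev
  s_h <- coef(lm(h ~ ev))[[2]]
  s_e <- coef(lm(e ~ ev))[[2]]
  s_eh <- coef(lm(e ~ h))[[2]]
  expect_equal(s_e, s_eh * s_h, tolerance = 1e-10)
})

test_that("slope table flags suppression and criticality onsets", {
  mk_prof <- function(n_hidden, s_h, s_eh) {
    structure(list(per_stimulus = tibble::tibble(), bins = tibble::tibble(),
                   slopes = list(entropy_vs_Ev = s_h,
                                 energy_vs_Ev = s_h * s_eh,
                                 energy_vs_entropy = s_eh,
                                 energy_vs_entropy_stimulus = s_eh),
                   I_enc = 1, n_hidden = n_hidden, edges = NULL,
                   n_bins = 10, weighted = TRUE, mode = "enumerate"),
              class = "energy_entropy_profile")
  }
  fam <- list(mk_prof(5, 0.5, 2.0), mk_prof(10, 0.1, 1.5),
              mk_prof(20, -0.2, 1.1), mk_prof(60, -0.5, 0.97))
  tab <- slope_vs_model_size(fam, criticality_tol = 0.2)
  expect_equal(tab$n_hidden, c(5, 10, 20, 60))
  expect_equal(attr(tab, "onset_suppression"), 20)
  expect_equal(attr(tab, "onset_criticality"), 20)
  # single profile: onset possibly not reached
  tab2 <- slope_vs_model_size(list(mk_prof(5, 0.5, 2.0)))
  expect_true(is.na(attr(tab2, "onset_suppression")))
})

test_that("rank-frequency slope identifies uniform and Zipfian ensembles", {
  # uniform over 64 patterns: flat rank plot
  x <- enumerate_states(6)[rep(1:64, each = 50), ]
  rf <- rank_frequency(pattern_dataset(x))
  expect_equal(attr(rf, "slope"), 0, tolerance = 0.02)

  # frequencies proportional to 1/rank: slope -1
  counts <- round(5000 / (1:100))
  x2 <- enumerate_states(7)[rep(1:100, times = counts), ]
  rf2 <- rank_frequency(pattern_dataset(x2))
  expect_equal(attr(rf2, "slope"), -1, tolerance = 0.01)

  # too few distinct patterns: slope missing
  rf3 <- rank_frequency(pattern_dataset(matrix(c(0, 1), 10, 1)))
  expect_true(is.na(attr(rf3, "slope")))
})
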