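#' Stimulus-conditioned hidden-layer entropy, in closed form
#'
#' Because the conditional distribution of the hidden layer given a stimulus
#' is factorial, its entropy is a sum of per-unit binary entropies:
#' `H_{h|v} = sum_j g(a_j) - a_j f(a_j)` with `a = beta * (W v + Bh)`,
#' `f` the logistic sigmoid and `g(x) = log(1 + e^x)`. Computed in nats with
#' overflow-safe softplus evaluation and returned in bits.
#'
#' @param model An [rbm()].
#' @param v Binary stimulus vector, or matrix with one stimulus per row.
#' @return Conditional entropy in bits (vectorized over rows), in `[0, n_hidden]`.
#' @examples
#' m <- rbm(matrix(0, 3, 2))
#' conditional_hidden_entropy(m, c(0, 1))  # 3 fair hidden bits
#' @export
conditional_hidden_entropy <- function(model, v) {
  stopifnot(inherits(model, "rbm"))
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, nrow = 1)
  check_binary(v, "v")
  if (ncol(v) != model$n_visible) abort("`v` length must equal n_visible.")
  p <- scaled_params(model)
  a <- v %*% t(p$W) + matrix(p$b_h, nrow(v), model$n_hidden, byrow = TRUE)
  h_nats <- rowSums(softplus(a) - a * sigmoid(a))
  out <- nats_to_bits(h_nats)
  if (vec_in) out[[1]] else out
}

#' Marginal energy of a hidden codeword
#'
#' The negative log marginal probability of a hidden pattern, up to one
#' additive constant shared by all patterns:
#' `E_h = -Bh.h - sum_i g((W'h)_i + Bv_i)` (beta-scaled parameters), in nats.
#'
#' @param model An [rbm()].
#' @param h Binary hidden vector, or matrix with one pattern per row.
#' @return Unnormalized energy in nats (vectorized over rows).
#' @export
hidden_marginal_energy <- function(model, h) {
  stopifnot(inherits(model, "rbm"))
  vec_in <- is.null(dim(h))
  if (vec_in) h <- matrix(h, nrow = 1)
  check_binary(h, "h")
  if (ncol(h) != model$n_hidden) abort("`h` length must equal n_hidden.")
  p <- scaled_params(model)
  a <- h %*% p$W + matrix(p$b_v, nrow(h), model$n_visible, byrow = TRUE)
  out <- -(h %*% p$b_h)[, 1] - rowSums(softplus(a))
  if (vec_in) out[[1]] else out
}

#' Free energy of a visible pattern
#'
#' The negative log of the hidden-marginalized unnormalized probability of a
#' stimulus: `F(v) = -Bv.v - sum_j g((W v)_j + Bh_j)` (beta-scaled
#' parameters), equal to `-log sum_h exp(-E(h, v))`, in nats. Satisfies the
#' free-energy identity `F(v) = <E(h, v)>_{h|v} - H_{h|v}` exactly.
#'
#' @param model An [rbm()].
#' @param v Binary stimulus vector, or matrix with one stimulus per row.
#' @return Unnormalized free energy in nats (vectorized over rows).
#' @export
visible_free_energy <- function(model, v) {
  stopifnot(inherits(model, "rbm"))
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, nrow = 1)
  check_binary(v, "v")
  if (ncol(v) != model$n_visible) abort("`v` length must equal n_visible.")
  p <- scaled_params(model)
  a <- v %*% t(p$W) + matrix(p$b_h, nrow(v), model$n_hidden, byrow = TRUE)
  out <- -(v %*% p$b_v)[, 1] - rowSums(softplus(a))
  if (vec_in) out[[1]] else out
}

#' Expected codeword energy evoked by a stimulus
#'
#' `<E_h>_{h|v}`: the mean marginal energy of hidden codewords drawn from the
#' factorial conditional given `v`. In `"enumerate"` mode (requires
#' `n_hidden <= 20`) the expectation is exact; in `"sample"` mode codewords
#' are drawn directly from the conditional (no chain needed) and the Monte
#' Carlo mean is returned.
#'
#' @param model An [rbm()].
#' @param v Binary stimulus vector or matrix of stimuli (one per row).
#' @param mode `"enumerate"` or `"sample"`.
#' @param n_samples Conditional samples per stimulus in sample mode.
#' @param seed Integer seed (sample mode).
#' @return Expected codeword energy in nats (unnormalized), vectorized over
#'   rows; the attribute `"min_energy"` carries the lowest single-codeword
#'   energy encountered (the normalization anchor candidate).
#' @export
expected_conditional_energy <- function(model, v,
                                        mode = c("enumerate", "sample"),
                                        n_samples = 10000L, seed = 1L) {
  mode <- arg_match(mode)
  stopifnot(inherits(model, "rbm"))
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, nrow = 1)
  check_binary(v, "v")
  if (ncol(v) != model$n_visible) abort("`v` length must equal n_visible.")
  if (mode == "enumerate") {
    if (model$n_hidden > 20) {
      abort("enumerate mode requires n_hidden <= 20; use mode = \"sample\".")
    }
    hs <- enumerate_states(model$n_hidden)
    eh <- hidden_marginal_energy(model, hs)
    probs <- unit_activation(model, v, "hidden-given-visible")
    # conditional probability of each full hidden state, per stimulus
    logp <- log(pmax(probs, 1e-300))
    log1mp <- log(pmax(1 - probs, 1e-300))
    lq <- logp %*% t(hs) + log1mp %*% t(1 - hs)
    out <- as.numeric(exp(lq) %*% eh)
    attr(out, "min_energy") <- min(eh)
  } else {
    check_count(n_samples, "n_samples")
    probs <- unit_activation(model, v, "hidden-given-visible")
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
    p <- scaled_params(model)
    res <- cpp_expected_hidden_energy(p$W, p$b_h, p$b_v, probs,
                                      as.integer(n_samples), as.integer(seed))
    out <- res$mean_energy
    attr(out, "min_energy") <- res$min_energy
  }
  if (vec_in) {
    a <- attr(out, "min_energy")
    out <- out[[1]]
    attr(out, "min_energy") <- a
  }
  out
}

#' Empirical stimulus energies of a dataset
#'
#' The information content of each observed stimulus under the empirical
#' distribution: `E_v = -log2(frequency)` in bits. Unseen patterns have no
#' entry (no pseudo-counting at this layer).
#'
#' @param data A [pattern_dataset()].
#' @return A tibble with columns `pattern`, `count`, `frequency`,
#'   `energy_bits`, sorted by decreasing frequency.
#' @export
empirical_stimulus_energy <- function(data) {
  freq <- pattern_frequencies(data)
  dplyr::mutate(freq, energy_bits = -log2(.data$frequency))
}

#' Exact enumeration of a small model
#'
#' Enumerates all joint states of an RBM with `n_visible + n_hidden <= 24`
#' and returns exact probabilities, marginals and the log partition function.
#' This is the oracle backing the sampled estimators.
#'
#' @param model An [rbm()].
#' @return A list with `joint` (matrix `2^n_hidden` x `2^n_visible` of joint
#'   probabilities), `p_v`, `p_h` (marginals), `log_z`, and the state
#'   matrices `h_states`, `v_states` (rows in [enumerate_states()] order).
#' @export
enumerate_model <- function(model) {
  stopifnot(inherits(model, "rbm"))
  if (model$n_visible + model$n_hidden > 24) {
    abort("enumerate_model() requires n_visible + n_hidden <= 24.")
  }
  hs <- enumerate_states(model$n_hidden)
  vs <- enumerate_states(model$n_visible)
  p <- scaled_params(model)
  # -E(h, v) for all pairs: rows = hidden states, cols = visible states
  neg_e <- outer(as.numeric(hs %*% p$b_h), as.numeric(vs %*% p$b_v), "+") +
    hs %*% p$W %*% t(vs)
  log_z <- logsumexp(neg_e)
  joint <- exp(neg_e - log_z)
  list(joint = joint, p_v = colSums(joint), p_h = rowSums(joint),
       log_z = log_z, h_states = hs, v_states = vs)
}

#' Per-stimulus thermodynamic table
#'
#' For every distinct pattern in `data`, computes the empirical stimulus
#' energy `E_v` (bits), the closed-form conditional entropy `H_{h|v}` (bits),
#' the expected codeword energy `<E_h>_{h|v}` (bits, normalized so the
#' lowest-energy codeword encountered sits at 0), and the model's visible
#' free energy (bits, normalized to its minimum over the analyzed stimuli).
#'
#' @param model An [rbm()].
#' @param data A [pattern_dataset()] of stimuli.
#' @param mode `"enumerate"` (exact, `n_hidden <= 20`) or `"sample"`.
#' @param n_samples Conditional samples per stimulus in sample mode.
#' @param seed Integer seed (sample mode).
#' @return A tibble with columns `pattern`, `count`, `frequency`,
#'   `E_v_bits`, `H_cond_bits`, `E_code_bits`, `F_visible_bits`. The energy
#'   normalization anchors are stored in attributes `anchor_code_nats` and
#'   `anchor_free_nats`.
#' @export
stimulus_thermo <- function(model, data, mode = c("enumerate", "sample"),
                            n_samples = 10000L, seed = 1L) {
  mode <- arg_match(mode)
  stopifnot(inherits(model, "rbm"), inherits(data, "pattern_dataset"))
  tab <- empirical_stimulus_energy(data)
  vs <- pattern_from_string(tab$pattern)
  h_bits <- conditional_hidden_entropy(model, vs)
  e_code <- expected_conditional_energy(model, vs, mode = mode,
                                        n_samples = n_samples, seed = seed)
  anchor <- attr(e_code, "min_energy")
  f_v <- visible_free_energy(model, vs)
  anchor_f <- min(f_v)
  out <- tibble::tibble(
    pattern = tab$pattern, count = tab$count, frequency = tab$frequency,
    E_v_bits = tab$energy_bits,
    H_cond_bits = h_bits,
    E_code_bits = nats_to_bits(as.numeric(e_code) - anchor),
    F_visible_bits = nats_to_bits(f_v - anchor_f)
  )
  attr(out, "anchor_code_nats") <- anchor
  attr(out, "anchor_free_nats") <- anchor_f
  attr(out, "mode") <- mode
  out
}
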