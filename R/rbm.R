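#' Construct a restricted Boltzmann machine
#'
#' A two-layer stochastic binary network with energy
#' `E(h, v) = -beta * (Bv.v + Bh.h + h'Wv)` (in nats, additive constant fixed
#' at 0), so `P(h, v) propto exp(-E(h, v))`. The inverse temperature `beta`
#' globally scales all parameters; `beta = 1` is the trained model.
#'
#' @param W Weight matrix, `n_hidden` x `n_visible`.
#' @param b_h Hidden bias vector (length `n_hidden`).
#' @param b_v Visible bias vector (length `n_visible`).
#' @param beta Inverse temperature (> 0, default 1).
#' @return An `rbm` object.
#' @examples
#' m <- rbm(matrix(0, 2, 3), b_h = c(0, 0), b_v = c(0, 0, 0))
#' m
#' @export
rbm <- function(W, b_h = NULL, b_v = NULL, beta = 1) {
  W <- as.matrix(W)
  if (is.null(b_h)) b_h <- numeric(nrow(W))
  if (is.null(b_v)) b_v <- numeric(ncol(W))
  if (length(b_h) != nrow(W) || length(b_v) != ncol(W)) {
    abort("Bias lengths must match the weight matrix: length(b_h) = nrow(W), length(b_v) = ncol(W).")
  }
  if (!all(is.finite(W)) || !all(is.finite(b_h)) || !all(is.finite(b_v))) {
    abort("All parameters must be finite.")
  }
  if (!is.finite(beta) || beta <= 0) abort("`beta` must be positive.")
  structure(
    list(W = W, b_h = as.numeric(b_h), b_v = as.numeric(b_v), beta = beta,
         n_hidden = nrow(W), n_visible = ncol(W), meta = list()),
    class = "rbm"
  )
}

#' @rdname rbm
#' @param n_visible,n_hidden Layer sizes.
#' @param sd Standard deviation of the iid Gaussian weight initialization
#'   (default 0.01); biases start at 0.
#' @param seed Integer seed.
#' @export
rbm_random <- function(n_visible, n_hidden, sd = 0.01, seed = 1L) {
  check_count(n_visible, "n_visible")
  check_count(n_hidden, "n_hidden")
  withr::local_seed(as.integer(seed))
  rbm(matrix(stats::rnorm(n_hidden * n_visible, sd = sd), n_hidden, n_visible))
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm> %d visible, %d hidden units; beta = %.4g\n",
              x$n_visible, x$n_hidden, x$beta))
  invisible(x)
}

# effective (beta-scaled) parameters used by all energy/probability formulas
scaled_params <- function(model) {
  list(W = model$beta * model$W, b_h = model$beta * model$b_h,
       b_v = model$beta * model$b_v)
}

#' Conditional firing probabilities of one layer given the other
#'
#' For hidden-given-visible, element j is `sigma(beta * (W_j.v + Bh_j))` with
#' `sigma` the logistic function; visible-given-hidden is the
#' transpose-symmetric form. The conditional distribution of either layer is
#' factorial (a product of independent Bernoulli units).
#'
#' @param model An [rbm()].
#' @param state Binary vector over the conditioning layer, or a matrix with
#'   one state per row.
#' @param direction `"hidden-given-visible"` or `"visible-given-hidden"`.
#' @return A probability vector (or matrix, one row per input state).
#' @examples
#' m <- rbm(matrix(c(2, -1), 1, 2), b_h = 0.5)
#' unit_activation(m, c(1, 1))  # sigma(1.5)
#' @export
unit_activation <- function(model, state,
                            direction = c("hidden-given-visible",
                                          "visible-given-hidden")) {
  direction <- arg_match(direction)
  stopifnot(inherits(model, "rbm"))
  vec_in <- is.null(dim(state))
  if (vec_in) state <- matrix(state, nrow = 1)
  check_binary(state, "state")
  p <- scaled_params(model)
  if (direction == "hidden-given-visible") {
    if (ncol(state) != model$n_visible) abort("`state` length must equal n_visible.")
    a <- state %*% t(p$W) + matrix(p$b_h, nrow(state), model$n_hidden, byrow = TRUE)
  } else {
    if (ncol(state) != model$n_hidden) abort("`state` length must equal n_hidden.")
    a <- state %*% p$W + matrix(p$b_v, nrow(state), model$n_visible, byrow = TRUE)
  }
  out <- sigmoid(a)
  if (vec_in) drop(out) else out
}

#' Joint energy of a hidden/visible state pair
#'
#' `E(h, v) = -beta * (Bv.v + Bh.h + h'Wv)` in nats, with the additive
#' constant fixed at 0, so `exp(-E)` is proportional to the joint probability.
#'
#' @param model An [rbm()].
#' @param h,v Binary state vectors (or matrices with paired rows).
#' @return Energy in nats (vectorized over rows).
#' @export
joint_energy <- function(model, h, v) {
  stopifnot(inherits(model, "rbm"))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  check_binary(h, "h"); check_binary(v, "v")
  if (ncol(h) != model$n_hidden || ncol(v) != model$n_visible ||
      nrow(h) != nrow(v)) {
    abort("`h` and `v` must have matching dimensions for the model.")
  }
  p <- scaled_params(model)
  -(v %*% p$b_v + h %*% p$b_h + rowSums((h %*% p$W) * v))[, 1]
}

#' Rescale a model to a different inverse temperature
#'
#' Returns a model whose weights and biases are the originals multiplied by
#' `beta` and whose `beta` field is 1, so downstream code never double-scales.
#' Its distribution is the original distribution with probabilities raised to
#' the power `beta` and renormalized.
#'
#' @param model An [rbm()].
#' @param beta Inverse temperature (> 0).
#' @return An [rbm()] at the new temperature.
#' @export
scale_temperature <- function(model, beta) {
  stopifnot(inherits(model, "rbm"))
  if (!is.finite(beta) || beta <= 0) abort("`beta` must be positive.")
  eff <- model$beta * beta
  out <- rbm(eff * model$W, eff * model$b_h, eff * model$b_v, beta = 1)
  out$meta <- c(model$meta, list(scaled_beta = eff))
  out
}

#' Block Gibbs sampling from an RBM
#'
#' Runs `n_chains` parallel chains initialized from iid fair bits. One step
#' updates the whole hidden layer given the visible layer, then the whole
#' visible layer given the hidden layer. After `burn_in` steps, every
#' `thin`-th joint state is recorded until `n_keep` states (split evenly over
#' chains) have been collected.
#'
#' @param model An [rbm()].
#' @param n_keep Total number of joint states to keep.
#' @param n_chains Number of parallel chains (default 500).
#' @param thin Steps between kept states (default 150).
#' @param burn_in Discarded initial steps per chain (default 1000).
#' @param seed Integer seed.
#' @return A `state_samples` object: list with binary matrices `h`
#'   (`n_keep` x `n_hidden`) and `v` (`n_keep` x `n_visible`) and `chain_meta`.
#' @export
gibbs_sample <- function(model, n_keep, n_chains = 500L, thin = 150L,
                         burn_in = 1000L, seed = 1L) {
  stopifnot(inherits(model, "rbm"))
  check_count(n_keep, "n_keep")
  check_count(n_chains, "n_chains")
  check_count(thin, "thin")
  check_count(burn_in, "burn_in", min = 0L)
  n_chains <- min(n_chains, n_keep)
  keep_per_chain <- ceiling(n_keep / n_chains)
  p <- scaled_params(model)
  res <- cpp_rbm_gibbs(p$W, p$b_h, p$b_v, as.integer(n_chains),
                       as.integer(keep_per_chain), as.integer(thin),
                       as.integer(burn_in), as.integer(seed))
  keep <- seq_len(n_keep)
  structure(
    list(h = res$h[keep, , drop = FALSE], v = res$v[keep, , drop = FALSE],
         chain_meta = list(n_chains = n_chains,
                           keep_per_chain = keep_per_chain, thin = thin,
                           burn_in = burn_in, seed = as.integer(seed))),
    class = "state_samples"
  )
}

#' @export
print.state_samples <- function(x, ...) {
  cat(sprintf("<state_samples> %d joint states (%d hidden, %d visible units)\n",
              nrow(x$h), ncol(x$h), ncol(x$v)))
  invisible(x)
}

#' Train an RBM with one-step contrastive divergence
#'
#' CD1 with the staged learning-rate schedule: by default rates
#' 0.2, 0.1, 0.05, 0.01, 5e-3, 1e-3 with 8 epochs per stage and minibatch 4.
#' The positive phase uses data-clamped hidden probabilities; the negative
#' phase is one full block Gibbs step from the data (sampled hidden, sampled
#' visible reconstruction, then hidden probabilities). Weights are
#' initialized iid N(0, 0.01^2), biases at 0. No momentum or weight decay.
#'
#' @param data A [pattern_dataset()] (or binary matrix) of training stimuli.
#' @param n_hidden Number of hidden units.
#' @param schedule Numeric vector of stage learning rates.
#' @param epochs_per_stage Epochs per stage (default 8).
#' @param minibatch Minibatch size (default 4).
#' @param seed Integer seed (initialization, shuffling, reconstruction noise).
#' @return A trained [rbm()] at `beta = 1`, with the training configuration
#'   in `$meta`.
#' @export
train_cd1 <- function(data, n_hidden,
                      schedule = c(0.2, 0.1, 0.05, 0.01, 5e-3, 1e-3),
                      epochs_per_stage = 8L, minibatch = 4L, seed = 1L) {
  if (inherits(data, "pattern_dataset")) data <- data$x
  data <- as.matrix(data)
  check_binary(data, "data")
  if (nrow(data) < 1L) abort("`data` must be non-empty.")
  check_count(n_hidden, "n_hidden")
  check_count(epochs_per_stage, "epochs_per_stage")
  check_count(minibatch, "minibatch")
  if (any(!is.finite(schedule)) || any(schedule <= 0)) {
    abort("`schedule` must be positive learning rates.")
  }
  withr::local_seed(as.integer(seed))
  n_visible <- ncol(data)
  n <- nrow(data)
  W <- matrix(stats::rnorm(n_hidden * n_visible, sd = 0.01), n_hidden, n_visible)
  b_h <- numeric(n_hidden)
  b_v <- numeric(n_visible)
  for (rate in schedule) {
    for (ep in seq_len(epochs_per_stage)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = minibatch)
      for (s in starts) {
        idx <- ord[s:min(s + minibatch - 1L, n)]
        v0 <- data[idx, , drop = FALSE]
        m <- nrow(v0)
        ph0 <- sigmoid(v0 %*% t(W) + matrix(b_h, m, n_hidden, byrow = TRUE))
        h0 <- matrix(as.integer(runif(m * n_hidden) < ph0), m, n_hidden)
        pv1 <- sigmoid(h0 %*% W + matrix(b_v, m, n_visible, byrow = TRUE))
        v1 <- matrix(as.integer(runif(m * n_visible) < pv1), m, n_visible)
        ph1 <- sigmoid(v1 %*% t(W) + matrix(b_h, m, n_hidden, byrow = TRUE))
        W <- W + rate * (t(ph0) %*% v0 - t(ph1) %*% v1) / m
        b_h <- b_h + rate * (colMeans(ph0) - colMeans(ph1))
        b_v <- b_v + rate * (colMeans(v0) - colMeans(v1))
        if (!all(is.finite(W))) {
          abort("Non-finite gradient encountered during CD1 training.")
        }
      }
    }
  }
  out <- rbm(W, b_h, b_v, beta = 1)
  out$meta <- list(schedule = schedule, epochs_per_stage = epochs_per_stage,
                   minibatch = minibatch, seed = as.integer(seed),
                   n_train = n)
  out
}
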