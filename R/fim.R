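# Fisher information of the RBM as covariance of the sufficient statistics
# T(v, h) = (v_i h_j for all weights, v_i, h_j). Parameter ordering is the
# fixed public convention: all weights row-major (hidden row j, visible
# column i varying fastest), then visible biases, then hidden biases.

fim_param_names <- function(n_visible, n_hidden) {
  w <- as.vector(t(outer(seq_len(n_hidden), seq_len(n_visible),
                         function(j, i) sprintf("w[%d,%d]", j, i))))
  c(w, sprintf("bv[%d]", seq_len(n_visible)),
    sprintf("bh[%d]", seq_len(n_hidden)))
}

# sufficient-statistic design matrix for binary sample blocks (chunk of rows)
suff_stats <- function(h, v) {
  n_h <- ncol(h); n_v <- ncol(v)
  xw <- h[, rep(seq_len(n_h), each = n_v), drop = FALSE] *
    v[, rep(seq_len(n_v), times = n_h), drop = FALSE]
  cbind(xw, v, h)
}

new_fim_result <- function(F_mat, param_names, beta, meta) {
  F_mat <- (F_mat + t(F_mat)) / 2
  ev <- eigen(F_mat, symmetric = TRUE)
  lead <- ev$vectors[, 1]
  if (lead[which.max(abs(lead))] < 0) lead <- -lead
  structure(
    list(matrix = F_mat,
         eigenvalues = ev$values,
         leading_eigenvector = lead,
         diagonal_sensitivities = sqrt(pmax(diag(F_mat), 0)),
         param_names = param_names, beta = beta, meta = meta),
    class = "fim_result"
  )
}

#' @export
print.fim_result <- function(x, ...) {
  cat(sprintf(
    "<fim_result> %d parameters at beta = %.4g; lambda_max = %.4g\n",
    nrow(x$matrix), x$beta, x$eigenvalues[[1]]))
  invisible(x)
}

#' Fisher Information Matrix from model samples
#'
#' Assembles the FIM from first and second moments of the sufficient
#' statistics of joint samples drawn from the model:
#' `F = Cov(T)` with `T = (v_i h_j, v_i, h_j)`, which reproduces the
#' moment formulas block-by-block (e.g.
#' `F_{w_ij, w_kl} = <v_i h_j v_k h_l> - <v_i h_j><v_k h_l>`).
#'
#' @param model The [rbm()] the samples were drawn from (at its `beta`).
#' @param samples A `state_samples` object from [gibbs_sample()] on the same
#'   model.
#' @return A `fim_result`: symmetric PSD matrix, descending `eigenvalues`,
#'   `leading_eigenvector`, per-parameter `diagonal_sensitivities`
#'   (`sqrt(F_kk)`), `param_names`, `beta`, and sampling metadata.
#' @export
fim_from_samples <- function(model, samples) {
  stopifnot(inherits(model, "rbm"), inherits(samples, "state_samples"))
  h <- samples$h; v <- samples$v
  if (ncol(h) != model$n_hidden || ncol(v) != model$n_visible) {
    abort("Sample dimensions do not match the model.")
  }
  n <- nrow(h)
  p_tot <- model$n_hidden * model$n_visible + model$n_visible + model$n_hidden
  xtx <- matrix(0, p_tot, p_tot)
  xsum <- numeric(p_tot)
  chunk <- max(1L, floor(2e7 / p_tot))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    x <- suff_stats(h[idx, , drop = FALSE] * 1.0, v[idx, , drop = FALSE] * 1.0)
    xtx <- xtx + crossprod(x)
    xsum <- xsum + colSums(x)
  }
  m <- xsum / n
  F_mat <- xtx / n - tcrossprod(m)
  new_fim_result(F_mat, fim_param_names(model$n_visible, model$n_hidden),
                 model$beta,
                 list(n_samples = n, estimator = "sample-moments",
                      chain_meta = samples$chain_meta))
}

#' Exact Fisher Information Matrix by enumeration
#'
#' Computes the same covariance as [fim_from_samples()] from the exact joint
#' distribution of an enumerable model (`n_visible + n_hidden <= 24`).
#'
#' @param model An [rbm()].
#' @return A `fim_result`.
#' @export
fim_from_moments <- function(model) {
  stopifnot(inherits(model, "rbm"))
  enum <- enumerate_model(model)
  n_hs <- nrow(enum$h_states); n_vs <- nrow(enum$v_states)
  # all joint states: hidden index varies slowest to match enum$joint layout
  h_all <- enum$h_states[rep(seq_len(n_hs), times = n_vs), , drop = FALSE]
  v_all <- enum$v_states[rep(seq_len(n_vs), each = n_hs), , drop = FALSE]
  p <- as.vector(enum$joint)   # column-major: h varies fastest within column
  x <- suff_stats(h_all * 1.0, v_all * 1.0)
  m <- colSums(x * p)
  F_mat <- crossprod(x, x * p) - tcrossprod(m)
  new_fim_result(F_mat, fim_param_names(model$n_visible, model$n_hidden),
                 model$beta, list(estimator = "exact-enumeration"))
}

#' Sensitivity of the model along a parameter direction
#'
#' `S(w) = sqrt(w' F w)`; for a unit-norm eigenvector this is the square
#' root of the eigenvalue, and for the k-th coordinate direction it is
#' `sqrt(F_kk)` (matching `diagonal_sensitivities`).
#'
#' @param fim A `fim_result`.
#' @param direction Numeric vector in the parameter ordering of `fim`.
#' @return The scalar sensitivity.
#' @export
parameter_sensitivity <- function(fim, direction) {
  stopifnot(inherits(fim, "fim_result"))
  if (length(direction) != nrow(fim$matrix)) {
    abort("`direction` length must match the number of parameters.")
  }
  sqrt(max(0, drop(crossprod(direction, fim$matrix %*% direction))))
}

#' Eigen-spectrum of the FIM over an inverse-temperature sweep
#'
#' For each `beta` in the grid, rescales the model with [scale_temperature()],
#' draws fresh Gibbs samples from the rescaled model, computes the FIM of the
#' rescaled model with respect to its own parameters, and records its
#' spectrum. The largest eigenvalue is a generalized susceptibility: a local
#' interior peak flags proximity to a phase transition, and trained models
#' above the critical size peak near `beta = 1`.
#'
#' @param model An [rbm()] (typically a trained model at `beta = 1`).
#' @param betas Strictly increasing grid of inverse temperatures (length >= 3).
#' @param n_samples Gibbs samples per grid point (default 100000; 350000 is
#'   the high-accuracy preset).
#' @param n_chains,thin,burn_in Gibbs protocol per grid point.
#' @param truncation_floor Eigenvalues below this are dropped from the stored
#'   spectra (default 1e-5).
#' @param seed Integer seed; each grid point uses an offset stream.
#' @param mode `"sample"` (default) or `"exact"` (enumeration, tiny models).
#' @return A `spectrum_sweep` object: list with `summary` (tibble: `beta`,
#'   `lambda_max`, `n_above_floor`, `trace`, `trace_per_hidden_unit`),
#'   `spectra` (tibble: `beta`, `rank`, `eigenvalue`, floor-truncated) and
#'   `peak_beta` (argmax of `lambda_max` over the grid).
#' @export
spectrum_sweep <- function(model, betas, n_samples = 100000L,
                           n_chains = 500L, thin = 10L, burn_in = 500L,
                           truncation_floor = 1e-5, seed = 1L,
                           mode = c("sample", "exact")) {
  mode <- arg_match(mode)
  stopifnot(inherits(model, "rbm"))
  if (length(betas) < 3) abort("`betas` must have at least 3 grid points.")
  if (any(diff(betas) <= 0)) abort("`betas` must be strictly increasing.")
  res <- purrr::map(seq_along(betas), function(k) {
    mb <- scale_temperature(model, betas[[k]])
    fim <- if (mode == "exact") {
      fim_from_moments(mb)
    } else {
      s <- gibbs_sample(mb, n_keep = n_samples, n_chains = n_chains,
                        thin = thin, burn_in = burn_in,
                        seed = as.integer(seed) + k)
      fim_from_samples(mb, s)
    }
    ev <- fim$eigenvalues
    list(
      summary = tibble::tibble(
        beta = betas[[k]],
        lambda_max = ev[[1]],
        n_above_floor = sum(ev > truncation_floor),
        trace = sum(diag(fim$matrix)),
        trace_per_hidden_unit = sum(diag(fim$matrix)) / model$n_hidden
      ),
      spectra = tibble::tibble(beta = betas[[k]],
                               rank = seq_along(ev[ev > truncation_floor]),
                               eigenvalue = ev[ev > truncation_floor])
    )
  })
  summary <- dplyr::bind_rows(purrr::map(res, "summary"))
  structure(
    list(summary = summary,
         spectra = dplyr::bind_rows(purrr::map(res, "spectra")),
         peak_beta = summary$beta[[which.max(summary$lambda_max)]],
         truncation_floor = truncation_floor, mode = mode,
         seed = as.integer(seed), n_samples = n_samples),
    class = "spectrum_sweep"
  )
}

#' @export
print.spectrum_sweep <- function(x, ...) {
  cat(sprintf(
    "<spectrum_sweep> %d inverse temperatures in [%.3g, %.3g]; lambda_max peak at beta = %.3g\n",
    nrow(x$summary), min(x$summary$beta), max(x$summary$beta), x$peak_beta))
  invisible(x)
}

#' Rank hidden units by parameter sensitivity
#'
#' Scores each hidden unit by the root-mean-square of the diagonal FIM
#' sensitivities over its bias and incident weights, and ranks units from
#' most to least important (ties broken by unit index). Each unit's
#' projective field (its weight row, an image over the visible pixels) is
#' returned alongside.
#'
#' @param fim A `fim_result` for `model`.
#' @param model The matching [rbm()].
#' @return A tibble with columns `unit`, `score`, `rank` and the list-column
#'   `projective_field`, sorted by rank.
#' @export
rank_units <- function(fim, model) {
  stopifnot(inherits(fim, "fim_result"), inherits(model, "rbm"))
  n_h <- model$n_hidden; n_v <- model$n_visible
  d2 <- fim$diagonal_sensitivities^2
  score <- vapply(seq_len(n_h), function(j) {
    w_idx <- (j - 1L) * n_v + seq_len(n_v)
    bh_idx <- n_h * n_v + n_v + j
    sqrt(mean(d2[c(w_idx, bh_idx)]))
  }, numeric(1))
  ord <- order(-score, seq_len(n_h))
  tibble::tibble(
    unit = ord,
    score = score[ord],
    rank = seq_len(n_h),
    projective_field = purrr::map(ord, ~ model$W[.x, ])
  )
}
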