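# broom-style tidiers so every fitted object drops into a pipe

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rbm
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.rbm <- function(x, ...) {
  tibble::tibble(
    term = fim_param_names(x$n_visible, x$n_hidden),
    estimate = c(as.vector(t(x$W)), x$b_v, x$b_h)
  )
}

#' @rdname rbm
#' @export
glance.rbm <- function(x, ...) {
  tibble::tibble(
    n_visible = x$n_visible, n_hidden = x$n_hidden, beta = x$beta,
    n_parameters = x$n_visible * x$n_hidden + x$n_visible + x$n_hidden
  )
}

#' @rdname pattern_dataset
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.pattern_dataset <- function(x, ...) pattern_frequencies(x)

#' @rdname pattern_dataset
#' @export
glance.pattern_dataset <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_units = x$n_units,
                 n_distinct = nrow(pattern_frequencies(x)))
}

#' @rdname sample_ising
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.lattice_samples <- function(x, ...) ising_observables(x)

#' @rdname sample_ising
#' @export
glance.lattice_samples <- function(x, ...) {
  obs <- ising_observables(x)
  tibble::tibble(
    L = x$L, temperature = x$temperature, n_samples = nrow(obs),
    mean_abs_magnetization = mean(obs$abs_magnetization),
    mean_energy_per_site = mean(obs$energy_per_site)
  )
}

#' @rdname energy_entropy_profile
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.energy_entropy_profile <- function(x, ...) x$bins

#' @rdname energy_entropy_profile
#' @export
glance.energy_entropy_profile <- function(x, ...) {
  tibble::tibble(
    n_hidden = x$n_hidden,
    slope_entropy_vs_Ev = x$slopes$entropy_vs_Ev,
    slope_energy_vs_Ev = x$slopes$energy_vs_Ev,
    slope_energy_vs_entropy = x$slopes$energy_vs_entropy,
    slope_energy_vs_entropy_stimulus = x$slopes$energy_vs_entropy_stimulus,
    I_enc = x$I_enc,
    n_stimuli = nrow(x$per_stimulus),
    n_bins_nonempty = nrow(x$bins)
  )
}

#' @rdname fim_from_samples
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.fim_result <- function(x, ...) {
  tibble::tibble(
    term = x$param_names,
    sensitivity = x$diagonal_sensitivities,
    leading_eigenvector = x$leading_eigenvector
  )
}

#' @rdname fim_from_samples
#' @export
glance.fim_result <- function(x, ...) {
  tibble::tibble(
    beta = x$beta,
    lambda_max = x$eigenvalues[[1]],
    trace = sum(diag(x$matrix)),
    n_parameters = nrow(x$matrix)
  )
}

#' @rdname spectrum_sweep
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.spectrum_sweep <- function(x, ...) x$summary

#' @rdname spectrum_sweep
#' @export
glance.spectrum_sweep <- function(x, ...) {
  tibble::tibble(
    peak_beta = x$peak_beta,
    lambda_max_at_peak = max(x$summary$lambda_max),
    n_betas = nrow(x$summary),
    truncation_floor = x$truncation_floor
  )
}

#' @rdname rank_frequency
#' @param x An object to tidy.
#' @param ... Unused.
#' @export
tidy.rank_frequency <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("pattern", "count", "frequency", "rank")])
}

#' @rdname rank_frequency
#' @export
glance.rank_frequency <- function(x, ...) {
  tibble::tibble(slope = attr(x, "slope"), n_distinct = nrow(x),
                 min_count = attr(x, "min_count"))
}
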