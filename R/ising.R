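#' Critical temperature of the two-dimensional Ising model
#'
#' Onsager's exact critical temperature for the square-lattice Ising model
#' with coupling J = 1 and k_B = 1: `Tc = 2 / log(1 + sqrt(2))`, approximately
#' 2.269. This is the reference point for choosing lattice sampling
#' temperatures above or below criticality.
#'
#' @return The critical temperature as a double.
#' @examples
#' onsager_critical_temperature()
#' @export
onsager_critical_temperature <- function() {
  2 / log(1 + sqrt(2))
}

#' Sample configurations of the 2D Ising model
#'
#' Draws spin configurations of the ferromagnetic Ising model on an L-by-L
#' square lattice with periodic boundaries, coupling J = 1 and k_B = 1, at
#' temperature `T`. Spins are sampled from the Boltzmann distribution
#' `P(sigma) propto exp(sum_<ij> sigma_i sigma_j / T)` either with the
#' Swendsen-Wang cluster algorithm (rapid mixing near criticality) or with
#' single-site Metropolis dynamics. Spins are returned as bits via
#' `s = (sigma + 1) / 2`.
#'
#' One Swendsen-Wang step is one full bond-percolation cluster decomposition
#' plus independent cluster flips; one Metropolis step is a sweep of L^2
#' random single-site proposals.
#'
#' @param L Lattice side length (>= 2).
#' @param temperature Temperature T > 0 in units of J/k_B.
#' @param n_samples Number of configurations to return.
#' @param burn_in Steps discarded before recording (default 1000).
#' @param thin Steps between recorded configurations (default 100).
#' @param seed Integer seed; together with the parameters it fully determines
#'   the output.
#' @param method `"swendsen-wang"` (default) or `"metropolis"`.
#' @return A `lattice_samples` object: list with `configurations` (an
#'   `n_samples` x `L^2` 0/1 matrix, sites in row-major lattice order),
#'   `L`, `temperature`, and `sampler_meta`.
#' @examples
#' s <- sample_ising(5, temperature = 3, n_samples = 10, burn_in = 50,
#'                   thin = 5, seed = 1)
#' dim(s$configurations)
#' @export
sample_ising <- function(L, temperature, n_samples, burn_in = 1000L,
                         thin = 100L, seed = 1L,
                         method = c("swendsen-wang", "metropolis")) {
  method <- arg_match(method)
  check_count(L, "L", min = 2L)
  if (!is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be positive.")
  }
  check_count(n_samples, "n_samples")
  check_count(burn_in, "burn_in", min = 0L)
  check_count(thin, "thin", min = 1L)
  configs <- cpp_sample_ising(as.integer(L), temperature,
                              as.integer(n_samples), as.integer(burn_in),
                              as.integer(thin), as.integer(seed), method)
  structure(
    list(
      configurations = configs,
      L = as.integer(L),
      temperature = temperature,
      sampler_meta = list(burn_in = as.integer(burn_in),
                          thin = as.integer(thin),
                          seed = as.integer(seed), algorithm = method)
    ),
    class = "lattice_samples"
  )
}

#' @export
print.lattice_samples <- function(x, ...) {
  cat(sprintf(
    "<lattice_samples> %d configurations of a %dx%d Ising lattice at T = %.4g (%s)\n",
    nrow(x$configurations), x$L, x$L, x$temperature,
    x$sampler_meta$algorithm))
  invisible(x)
}

#' Summaries of an Ising sample set
#'
#' Per-configuration magnetization and energy of a `lattice_samples` object,
#' as a tibble. Magnetization is the mean spin (in the +/-1 convention);
#' energy is `-sum_<ij> sigma_i sigma_j` over nearest-neighbour pairs with
#' periodic boundaries.
#'
#' @param samples A `lattice_samples` object.
#' @return A tibble with columns `sample`, `magnetization`, `abs_magnetization`,
#'   `energy`, `energy_per_site`.
#' @export
ising_observables <- function(samples) {
  stopifnot(inherits(samples, "lattice_samples"))
  L <- samples$L
  s <- 2 * samples$configurations - 1   # back to +/-1
  m <- rowMeans(s)
  idx <- matrix(seq_len(L * L), nrow = L, byrow = TRUE)  # row-major site order
  right <- idx[, c(2:L, 1)]
  down <- idx[c(2:L, 1), ]
  e <- -rowSums(s * s[, as.vector(t(right)), drop = FALSE]) -
    rowSums(s * s[, as.vector(t(down)), drop = FALSE])
  tibble::tibble(
    sample = seq_along(m),
    magnetization = m,
    abs_magnetization = abs(m),
    energy = e,
    energy_per_site = e / (L * L)
  )
}

#' Exact spontaneous magnetization of the infinite 2D Ising model
#'
#' Onsager's closed form `(1 - sinh(2/T)^-4)^(1/8)` for `T < Tc`, and 0 above.
#' Used as a large-lattice reference for sampler validation.
#'
#' @param temperature Temperature T > 0.
#' @return Spontaneous magnetization per site.
#' @export
onsager_magnetization <- function(temperature) {
  tc <- onsager_critical_temperature()
  ifelse(temperature < tc,
         (1 - sinh(2 / temperature)^-4)^(1 / 8),
         0)
}
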