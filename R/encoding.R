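#' Kullback-Leibler divergence from held-out data to model samples
#'
#' `KL(heldout || model)` in bits over the union support of the two pattern
#' frequency tables, with an additive pseudocount (default 0.5 per distinct
#' pattern) to regularize patterns seen in one set only.
#'
#' @param model_samples A [pattern_dataset()] of visible patterns sampled
#'   from the model.
#' @param heldout A [pattern_dataset()] of held-out data.
#' @param pseudocount Additive smoothing count per pattern (default 0.5).
#' @return KL divergence in bits.
#' @export
model_data_kl <- function(model_samples, heldout, pseudocount = 0.5) {
  stopifnot(inherits(model_samples, "pattern_dataset"),
            inherits(heldout, "pattern_dataset"))
  if (model_samples$n_obs < 1 || heldout$n_obs < 1) {
    abort("Both datasets must be non-empty.")
  }
  fq_q <- pattern_frequencies(model_samples)
  fq_p <- pattern_frequencies(heldout)
  support <- union(fq_p$pattern, fq_q$pattern)
  k <- length(support)
  cp <- setNames(rep(0, k), support); cp[fq_p$pattern] <- fq_p$count
  cq <- setNames(rep(0, k), support); cq[fq_q$pattern] <- fq_q$count
  p <- (cp + pseudocount) / (heldout$n_obs + pseudocount * k)
  q <- (cq + pseudocount) / (model_samples$n_obs + pseudocount * k)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Sparsity and pairwise correlation of hidden activity
#'
#' Summary activity statistics of sampled hidden states: the grand-mean
#' activation (sparsity) and the mean absolute Pearson correlation over
#' distinct hidden-unit pairs (pairs involving a constant unit contribute 0).
#'
#' @param samples A `state_samples` object from [gibbs_sample()].
#' @return A one-row tibble with `n_hidden`, `sparsity`,
#'   `mean_abs_correlation`.
#' @export
activity_stats <- function(samples) {
  stopifnot(inherits(samples, "state_samples"))
  h <- samples$h
  if (ncol(h) < 2) abort("At least 2 hidden units are required.")
  sparsity <- mean(h)
  suppressWarnings(cmat <- cor(h))
  cmat[!is.finite(cmat)] <- 0   # constant units: correlation defined as 0
  off <- abs(cmat[upper.tri(cmat)])
  tibble::tibble(n_hidden = ncol(h), sparsity = sparsity,
                 mean_abs_correlation = mean(off))
}

#' Assign stimuli to equal-width energy bins
#'
#' Divides the observed energy range evenly into `n_bins` bins; the right
#' edge is inclusive in the last bin. A degenerate (zero-width) range maps
#' everything to bin 1.
#'
#' @param energies Numeric vector of stimulus energies (bits).
#' @param n_bins Number of bins (>= 1).
#' @return Integer bin assignments, with the bin edges in attribute
#'   `"edges"`.
#' @export
bin_by_stimulus_energy <- function(energies, n_bins) {
  check_count(n_bins, "n_bins")
  if (length(energies) < 1) abort("`energies` must be non-empty.")
  lo <- min(energies); hi <- max(energies)
  if (hi <= lo) {
    out <- rep(1L, length(energies))
    attr(out, "edges") <- c(lo, hi)
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  out <- pmin(pmax(findInterval(energies, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  attr(out, "edges") <- edges
  out
}

#' Energy-entropy profile of a trained code
#'
#' The headline analysis: for every distinct stimulus in `data`, compute the
#' empirical stimulus energy `E_v`, the conditional entropy `H_{h|v}` and the
#' expected codeword energy `<E_h>_{h|v}`; bin stimuli into equal-width `E_v`
#' bins; average entropy and codeword energy within bins (weighted by
#' stimulus frequency by default); and fit three ordinary least-squares
#' slopes on the bin means: entropy vs `E_v`, codeword energy vs `E_v`, and
#' codeword energy vs entropy. A fourth slope,
#' `energy_vs_entropy_stimulus`, fits codeword energy against entropy across
#' the distinct stimuli themselves (frequency-weighted). This is the direct
#' measure of the energy-entropy trade-off: it equals 1 for a code at
#' statistical criticality, whereas the bin-mean slope estimates the ratio
#' of the two `E_v` regressions and need not.
#' `I_enc` is the frequency-weighted mean of `<E_h>_{h|v} - H_{h|v}` over all
#' stimuli - the average stimulus-to-marginal KL divergence up to the shared
#' energy-normalization constant.
#'
#' @param model An [rbm()].
#' @param data A [pattern_dataset()] of stimuli.
#' @param n_bins Number of stimulus-energy bins (default 14).
#' @param mode,n_samples,seed Passed to [stimulus_thermo()].
#' @param weighted Weight bin means by stimulus frequency (default TRUE).
#' @return An `energy_entropy_profile` object: list with `per_stimulus`
#'   (the [stimulus_thermo()] table plus `bin`), `bins` (per-bin means and
#'   counts), `slopes` (the three slopes; `NA` when fewer than 2 bins are
#'   nonempty), `I_enc` (bits), `n_hidden`, and the bin `edges`.
#' @export
energy_entropy_profile <- function(model, data, n_bins = 14L,
                                   mode = c("enumerate", "sample"),
                                   n_samples = 10000L, seed = 1L,
                                   weighted = TRUE) {
  mode <- arg_match(mode)
  thermo <- stimulus_thermo(model, data, mode = mode, n_samples = n_samples,
                            seed = seed)
  bins <- bin_by_stimulus_energy(thermo$E_v_bits, n_bins)
  thermo$bin <- as.integer(bins)
  wt <- if (weighted) thermo$frequency else rep(1, nrow(thermo))
  bin_tab <- thermo |>
    dplyr::mutate(.w = wt) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_E_v = sum(.data$.w * .data$E_v_bits) / sum(.data$.w),
      mean_entropy = sum(.data$.w * .data$H_cond_bits) / sum(.data$.w),
      mean_code_energy = sum(.data$.w * .data$E_code_bits) / sum(.data$.w),
      n_stimuli = dplyr::n(),
      weight = sum(.data$.w),
      .groups = "drop"
    )
  slopes <- list(entropy_vs_Ev = NA_real_, energy_vs_Ev = NA_real_,
                 energy_vs_entropy = NA_real_,
                 energy_vs_entropy_stimulus = NA_real_)
  if (nrow(bin_tab) >= 2) {
    slopes$entropy_vs_Ev <-
      coef(lm(mean_entropy ~ mean_E_v, data = bin_tab))[[2]]
    slopes$energy_vs_Ev <-
      coef(lm(mean_code_energy ~ mean_E_v, data = bin_tab))[[2]]
    slopes$energy_vs_entropy <-
      coef(lm(mean_code_energy ~ mean_entropy, data = bin_tab))[[2]]
  }
  if (nrow(thermo) >= 2 && stats::var(thermo$H_cond_bits) > 0) {
    # the trade-off itself lives at stimulus level; bin means only estimate
    # the ratio of the two E_v regressions
    slopes$energy_vs_entropy_stimulus <-
      coef(lm(E_code_bits ~ H_cond_bits, data = thermo,
              weights = thermo$frequency))[[2]]
  }
  i_enc <- sum(thermo$frequency *
                 (thermo$E_code_bits - thermo$H_cond_bits)) /
    sum(thermo$frequency)
  structure(
    list(per_stimulus = thermo, bins = bin_tab, slopes = slopes,
         I_enc = i_enc, n_hidden = model$n_hidden,
         edges = attr(bins, "edges"), n_bins = n_bins, weighted = weighted,
         mode = mode),
    class = "energy_entropy_profile"
  )
}

#' @export
print.energy_entropy_profile <- function(x, ...) {
  cat(sprintf(
    "<energy_entropy_profile> %d hidden units, %d stimuli in %d bins\n",
    x$n_hidden, nrow(x$per_stimulus), nrow(x$bins)))
  cat(sprintf(
    "  slopes: H|Ev = %.3f, E|Ev = %.3f, E|H = %.3f; I_enc = %.3f bits\n",
    x$slopes$entropy_vs_Ev, x$slopes$energy_vs_Ev,
    x$slopes$energy_vs_entropy, x$I_enc))
  invisible(x)
}

#' Slopes and criticality onsets across a model-size family
#'
#' Collects the three profile slopes and `I_enc` for a family of
#' energy-entropy profiles keyed by hidden-layer size, and flags (as
#' attributes) the smallest size whose entropy-vs-`E_v` slope is negative
#' (variability-suppression onset) and the smallest size whose
#' stimulus-level energy-vs-entropy slope is within `criticality_tol` of 1
#' (criticality onset); `NA` when not reached.
#'
#' @param profiles A list of `energy_entropy_profile` objects.
#' @param criticality_tol Half-width of the slope band around 1 (default 0.2).
#' @return A tibble with one row per profile: `n_hidden`,
#'   `slope_entropy_vs_Ev`, `slope_energy_vs_Ev`, `slope_energy_vs_entropy`,
#'   `I_enc`; attributes `onset_suppression` and `onset_criticality`.
#' @export
slope_vs_model_size <- function(profiles, criticality_tol = 0.2) {
  stopifnot(length(profiles) >= 1,
            all(purrr::map_lgl(profiles, inherits, "energy_entropy_profile")))
  tab <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(
      n_hidden = p$n_hidden,
      slope_entropy_vs_Ev = p$slopes$entropy_vs_Ev,
      slope_energy_vs_Ev = p$slopes$energy_vs_Ev,
      slope_energy_vs_entropy = p$slopes$energy_vs_entropy,
      slope_energy_vs_entropy_stimulus = p$slopes$energy_vs_entropy_stimulus,
      I_enc = p$I_enc
    )
  }) |> dplyr::arrange(.data$n_hidden)
  supp <- tab$n_hidden[!is.na(tab$slope_entropy_vs_Ev) &
                         tab$slope_entropy_vs_Ev < 0]
  crit <- tab$n_hidden[!is.na(tab$slope_energy_vs_entropy_stimulus) &
                         abs(tab$slope_energy_vs_entropy_stimulus - 1) <=
                           criticality_tol]
  attr(tab, "onset_suppression") <- if (length(supp)) min(supp) else NA_integer_
  attr(tab, "onset_criticality") <- if (length(crit)) min(crit) else NA_integer_
  tab
}

#' Zipf rank-frequency statistics of a pattern set
#'
#' Sorts distinct patterns by decreasing frequency and fits the ordinary
#' least-squares slope of `log2(frequency)` against `log2(rank)` over ranks
#' with at least `min_count` observations (default 5, to avoid the sampling
#' tail). A slope near -1 is Zipf's law, the rank-frequency signature of
#' statistical criticality.
#'
#' @param samples A [pattern_dataset()] (typically of hidden codewords).
#' @param min_count Minimum pattern count included in the fit.
#' @return A `rank_frequency` object: the rank-frequency tibble (`pattern`,
#'   `count`, `frequency`, `rank`) with attributes `slope` (NA with fewer
#'   than 10 distinct patterns in the fit window) and `min_count`.
#' @export
rank_frequency <- function(samples, min_count = 5L) {
  stopifnot(inherits(samples, "pattern_dataset"))
  tab <- pattern_frequencies(samples)
  tab$rank <- seq_len(nrow(tab))
  fit_rows <- tab$count >= min_count
  slope <- NA_real_
  if (sum(fit_rows) >= 10) {
    slope <- coef(lm(log2(frequency) ~ log2(rank),
                     data = tab[fit_rows, ]))[[2]]
  }
  structure(tab, slope = slope, min_count = min_count,
            class = c("rank_frequency", class(tab)))
}

#' @export
print.rank_frequency <- function(x, ...) {
  cat(sprintf("<rank_frequency> %d distinct patterns; log-log slope %.3f\n",
              nrow(x), attr(x, "slope")))
  NextMethod()
}
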