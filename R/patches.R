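#' Circular patch geometry
#'
#' Defines the fixed raster-order circular mask used to cut patches out of
#' lattice configurations or binary images. The mask contains every integer
#' offset `(dx, dy)` with `dx^2 + dy^2 <= radius^2`, vectorized in row-major
#' order (top-to-bottom, then left-to-right within a row). Radii 2, 2.5 and
#' 3.5 give the 13-, 21- and 37-pixel patches used throughout.
#'
#' @param radius Disk radius in pixels.
#' @return A `patch_spec` object: list with `radius`, `pixel_count`, and
#'   `offsets` (a `pixel_count` x 2 matrix of `(dy, dx)` offsets).
#' @examples
#' patch_spec(2)$pixel_count          # 13
#' patch_spec_for_pixels(21)$radius   # 2.5
#' @export
patch_spec <- function(radius) {
  if (!is.finite(radius) || radius < 0) abort("`radius` must be >= 0.")
  r <- floor(radius)
  grid <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- grid$dx^2 + grid$dy^2 <= radius^2
  grid <- grid[keep, , drop = FALSE]
  # raster order: by row (dy), then by column (dx)
  grid <- grid[order(grid$dy, grid$dx), , drop = FALSE]
  structure(
    list(radius = radius, pixel_count = nrow(grid),
         offsets = cbind(dy = grid$dy, dx = grid$dx)),
    class = "patch_spec"
  )
}

#' @rdname patch_spec
#' @param pixel_count One of 13, 21, 37 (or any count achievable by an
#'   integer-offset disk).
#' @export
patch_spec_for_pixels <- function(pixel_count) {
  radii <- c(`1` = 0, `5` = 1, `13` = 2, `21` = 2.5, `29` = 3, `37` = 3.5)
  key <- as.character(pixel_count)
  if (!key %in% names(radii)) {
    abort(sprintf("No stored disk radius for pixel_count = %s.", key))
  }
  patch_spec(radii[[key]])
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("<patch_spec> radius %.2g px, %d pixels in circular mask\n",
              x$radius, x$pixel_count))
  invisible(x)
}

#' A set of binary visible patterns with empirical frequencies
#'
#' The common container for stimulus ensembles: a binary matrix of observed
#' patterns (one per row). Frequencies of the distinct patterns are computed
#' by [pattern_frequencies()]; per-pattern empirical energies (negative
#' log2-frequency, in bits) by [empirical_stimulus_energy()].
#'
#' @param x Binary matrix, observations in rows.
#' @param meta Optional list of provenance metadata.
#' @return A `pattern_dataset` object.
#' @export
pattern_dataset <- function(x, meta = list()) {
  x <- as.matrix(x)
  check_binary(x)
  storage.mode(x) <- "integer"
  structure(list(x = x, n_units = ncol(x), n_obs = nrow(x), meta = meta),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset> %d observations of %d binary units\n",
              x$n_obs, x$n_units))
  invisible(x)
}

#' Frequency table of the distinct patterns in a dataset
#'
#' @param data A `pattern_dataset`.
#' @return A tibble with columns `pattern` (bit string, most significant bit =
#'   first raster cell), `count` and `frequency`, sorted by decreasing count.
#' @export
pattern_frequencies <- function(data) {
  stopifnot(inherits(data, "pattern_dataset"))
  s <- pattern_strings(data$x)
  tab <- sort(table(s), decreasing = TRUE)
  tibble::tibble(
    pattern = names(tab),
    count = as.integer(tab),
    frequency = as.integer(tab) / data$n_obs
  )
}

#' Extract circular binary patches from lattice samples or images
#'
#' Cuts `n_patches` circular patches at uniformly random centers (and, for
#' lattice or image sets, uniformly random source frames). Lattice sources
#' wrap under periodic boundaries, matching the boundary conditions they were
#' sampled with; image sources require the full mask to fit inside the frame.
#'
#' @param source A `lattice_samples` or `binary_images` object.
#' @param spec A [patch_spec()].
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed.
#' @return A [pattern_dataset()] of `n_patches` rows, `spec$pixel_count`
#'   columns, in the fixed raster order of the mask.
#' @examples
#' lat <- sample_ising(8, 2.5, 50, burn_in = 100, thin = 5, seed = 2)
#' patches <- extract_patches(lat, patch_spec(2), 200, seed = 3)
#' patches
#' @export
extract_patches <- function(source, spec, n_patches, seed = 1L) {
  stopifnot(inherits(spec, "patch_spec"))
  check_count(n_patches, "n_patches")
  if (inherits(source, "lattice_samples")) {
    frames <- source$configurations
    h <- source$L; w <- source$L; wrap <- TRUE
  } else if (inherits(source, "binary_images")) {
    frames <- source$images
    h <- source$height; w <- source$width; wrap <- FALSE
  } else {
    abort("`source` must be a lattice_samples or binary_images object.")
  }
  r <- max(abs(spec$offsets))
  if (!wrap && (h < 2 * r + 1 || w < 2 * r + 1)) {
    abort("Patch mask does not fit inside the source frame.")
  }
  if (wrap && (h < 2 * r + 1 || w < 2 * r + 1)) {
    abort("Patch mask is larger than the (periodic) lattice.")
  }
  withr::local_seed(as.integer(seed))
  n_frames <- nrow(frames)
  frame_idx <- sample.int(n_frames, n_patches, replace = TRUE)
  if (wrap) {
    cy <- sample.int(h, n_patches, replace = TRUE) - 1L
    cx <- sample.int(w, n_patches, replace = TRUE) - 1L
  } else {
    cy <- sample.int(h - 2L * r, n_patches, replace = TRUE) + r - 1L
    cx <- sample.int(w - 2L * r, n_patches, replace = TRUE) + r - 1L
  }
  k <- spec$pixel_count
  out <- matrix(0L, nrow = n_patches, ncol = k)
  for (j in seq_len(k)) {
    py <- cy + spec$offsets[j, "dy"]
    px <- cx + spec$offsets[j, "dx"]
    if (wrap) {
      py <- py %% h
      px <- px %% w
    }
    # frames store pixels in row-major raster order
    out[, j] <- frames[cbind(frame_idx, py * w + px + 1L)]
  }
  pattern_dataset(out, meta = list(
    patch_radius = spec$radius, pixel_count = k, seed = as.integer(seed),
    source = class(source)[[1]],
    temperature = if (wrap) source$temperature else NULL
  ))
}

#' Split a pattern dataset into training and held-out parts
#'
#' @param data A `pattern_dataset`.
#' @param heldout_fraction Fraction of observations held out (default 0.2).
#' @param seed Integer seed for the random split.
#' @return A list with elements `train` and `heldout`, both `pattern_dataset`s.
#' @export
split_dataset <- function(data, heldout_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(data, "pattern_dataset"))
  if (heldout_fraction <= 0 || heldout_fraction >= 1) {
    abort("`heldout_fraction` must be in (0, 1).")
  }
  withr::local_seed(as.integer(seed))
  n <- data$n_obs
  idx <- sample.int(n, round(n * heldout_fraction))
  list(
    train = pattern_dataset(data$x[-idx, , drop = FALSE], meta = data$meta),
    heldout = pattern_dataset(data$x[idx, , drop = FALSE], meta = data$meta)
  )
}

#' Export a pattern frequency table to CSV
#'
#' Writes columns `pattern`, `count`, `frequency`, `energy_bits` (the
#' empirical stimulus energy, -log2 frequency).
#'
#' @param data A `pattern_dataset`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_pattern_csv <- function(data, path) {
  tab <- empirical_stimulus_energy(data)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
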