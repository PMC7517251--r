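# numerically safe primitives shared across modules; energies are handled in
# nats internally and converted to bits only at reporting boundaries

sigmoid <- function(x) {
  p <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  p[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  p[!pos] <- e / (1 + e)
  p[is.na(x)] <- NA_real_
  dim(p) <- dim(x)
  p
}

# softplus g(x) = log(1 + e^x), piecewise to avoid overflow past |x| ~ 30
softplus <- function(x) {
  y <- x
  mid <- !is.na(x) & x <= 30 & x >= -30
  y[mid] <- log1p(exp(x[mid]))
  lo <- !is.na(x) & x < -30
  y[lo] <- exp(x[lo])
  y
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

nats_to_bits <- function(x) x / log(2)

bits_to_nats <- function(x) x * log(2)

# all 2^n binary states as rows; column 1 is the most significant bit
enumerate_states <- function(n) {
  stopifnot(n >= 0, n <= 24)
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  k <- 2^n
  out <- matrix(0L, nrow = k, ncol = n)
  for (j in seq_len(n)) {
    out[, j] <- rep(rep(c(0L, 1L), each = 2^(n - j)), length.out = k)
  }
  out
}

# rows of a binary matrix as bit strings, most significant bit = first column
pattern_strings <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  apply(x, 1L, paste0, collapse = "")
}

pattern_from_string <- function(s) {
  t(vapply(strsplit(s, "", fixed = TRUE),
           function(ch) as.integer(ch == "1"), integer(nchar(s[[1]]))))
}

check_binary <- function(x, arg = "x") {
  if (!all(x %in% c(0L, 1L, 0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 entries.", arg))
  }
  invisible(x)
}

check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  invisible(as.integer(x))
}
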