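# Independent oracles, all deliberately written in the most literal form
# available so they share no code path with the package implementation.

# dbWPLI by the direct O(n_epochs^2) pairwise-product sum over distinct
# epochs, from a vector of imaginary cross-spectra.
dbwpli_pairwise_oracle <- function(imx) {
  n <- length(imx)
  num <- 0
  den <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) {
        num <- num + imx[j] * imx[k]
        den <- den + abs(imx[j]) * abs(imx[k])
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Apply the pairwise oracle to every lower-triangle pair of a complex
# bins x channels x epochs tensor, averaging bins missing-aware.
dbwpli_matrix_oracle <- function(coef, bins) {
  nch <- dim(coef)[2L]
  out <- matrix(NA_real_, nch, nch)
  for (a in 2:nch) {
    for (b in seq_len(a - 1L)) {
      per_bin <- vapply(bins, function(bi) {
        x <- coef[bi, a, ] * Conj(coef[bi, b, ])
        dbwpli_pairwise_oracle(Im(x))
      }, numeric(1L))
      v <- if (all(is.na(per_bin))) NA_real_ else mean(per_bin, na.rm = TRUE)
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}

# Exact Mann-Whitney U null counts by the textbook recurrence
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1), memoised but literal.
u_counts_rec <- local({
  memo <- new.env(parent = emptyenv())
  function(u, m, n) {
    if (u < 0 || u > m * n) return(0)
    if (m == 0L || n == 0L) return(as.numeric(u == 0))
    key <- paste(u, m, n)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- u_counts_rec(u - n, m - 1L, n) + u_counts_rec(u, m, n - 1L)
    memo[[key]] <- val
    val
  }
})

# Exact two-sided p for observed U: total probability of assignments whose U
# deviates from m*n/2 by at least as much as observed.
mw_exact_two_sided_oracle <- function(u, m, n) {
  total <- choose(m + n, m)
  mid <- m * n / 2
  us <- 0:(m * n)
  probs <- vapply(us, u_counts_rec, numeric(1L), m = m, n = n) / total
  sum(probs[abs(us - mid) >= abs(u - mid) - 1e-12])
}

# Brute-force Mann-Whitney two-sided exact p by enumerating every group
# assignment (tiny samples only): anchors the counting oracle itself.
mw_exact_enum_oracle <- function(values_a, values_b) {
  pooled <- c(values_a, values_b)
  m <- length(values_a)
  r <- rank(pooled)
  u_of <- function(rows) sum(r[rows]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  mid <- m * length(values_b) / 2
  assigns <- utils::combn(length(pooled), m, simplify = FALSE)
  us <- vapply(assigns, u_of, numeric(1L))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# Literal Benjamini-Hochberg step-up: largest i with p_(i) <= i q / m.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# Brute-force sliding-window epoch count within one segment of length L
# seconds: enumerate candidate start times on the step grid.
epoch_count_oracle <- function(L, epoch_length, overlap) {
  step <- epoch_length * (1 - overlap)
  k <- 0L
  start <- 0
  while (start + epoch_length <= L + 1e-12) {
    k <- k + 1L
    start <- start + step
  }
  k
}

# Build an epoch_set directly from a samples x channels x epochs array,
# bypassing segmentation (for spectral unit tests).
make_epoch_set <- function(arr, fs, epoch_length = 1, overlap = 0) {
  structure(
    list(epochs = arr, fs = fs, epoch_length = epoch_length,
         overlap = overlap,
         channel_labels = paste0("ch", seq_len(dim(arr)[2L])),
         provenance = data.frame(segment = rep(1L, dim(arr)[3L]),
                                 start = seq_len(dim(arr)[3L]) - 1,
                                 condition = NA_character_)),
    class = "epoch_set")
}

# Build a spectral_tensor directly from a bins x channels x epochs complex
# array with 1 Hz resolution.
make_spectral_tensor <- function(coef, fs = NULL) {
  nbins <- dim(coef)[1L]
  structure(
    list(coefficients = coef, freq = seq_len(nbins) - 1,
         fs = fs %||% (2 * (nbins - 1L)), epoch_length = 1,
         channel_labels = paste0("ch", seq_len(dim(coef)[2L])),
         provenance = NULL),
    class = "spectral_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random complex tensor with iid Gaussian real/imaginary parts.
random_tensor <- function(nbins, nch, nep) {
  array(complex(real = stats::rnorm(nbins * nch * nep),
                imaginary = stats::rnorm(nbins * nch * nep)),
        dim = c(nbins, nch, nep))
}

# Random symmetric connectivity-like matrix with NA diagonal.
random_conn_matrix <- function(n, shift_edges = NULL, shift = 0) {
  m <- matrix(NA_real_, n, n)
  v <- stats::rnorm(n * (n - 1) / 2)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  if (!is.null(shift_edges)) {
    for (k in seq_len(nrow(shift_edges))) {
      i <- shift_edges[k, 1L]; j <- shift_edges[k, 2L]
      m[i, j] <- m[i, j] + shift
      m[j, i] <- m[i, j]
    }
  }
  m
}
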