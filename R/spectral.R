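#' Hanning-tapered FFT of an epoch set
#'
#' Removes each epoch's per-channel mean (DC leakage guard; can be switched
#' off), applies a Hanning window and takes the discrete Fourier transform,
#' keeping the non-redundant bins `0 .. floor(N/2)`. With 1-s epochs the
#' frequency resolution is 1 Hz and bin `k` sits at `k` Hz.
#'
#' @param epochs an `epoch_set` (all epochs share one length by construction).
#' @param demean subtract the per-epoch, per-channel mean before windowing.
#' @return An object of class `spectral_tensor`: complex coefficients as a
#'   bins x channels x epochs array, with the bin frequencies and metadata.
#' @export
taper_fft <- function(epochs, demean = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  nsamp <- d[1L]; nch <- d[2L]; nep <- d[3L]
  win <- hanning_window(nsamp)
  nbins <- nsamp %/% 2L + 1L
  coef <- array(complex(real = 0, imaginary = 0), dim = c(nbins, nch, nep))
  for (e in seq_len(nep)) {
    x <- epochs$epochs[, , e, drop = FALSE]
    dim(x) <- c(nsamp, nch)
    if (demean) x <- sweep(x, 2L, colMeans(x))
    coef[, , e] <- stats::mvfft(x * win)[seq_len(nbins), , drop = FALSE]
  }
  structure(
    list(coefficients = coef,
         freq = (seq_len(nbins) - 1L) / epochs$epoch_length,
         fs = epochs$fs, epoch_length = epochs$epoch_length,
         channel_labels = epochs$channel_labels,
         provenance = epochs$provenance),
    class = "spectral_tensor")
}

# Symmetric Hanning (raised cosine) taper.
hanning_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("<spectral_tensor> %d bins (0-%g Hz) x %d channels x %d epochs\n",
              d[1L], max(x$freq), d[2L], d[3L]))
  invisible(x)
}

#' Power spectrum from a spectral tensor
#'
#' Mean over epochs of the squared coefficient magnitude with 1/N
#' normalisation (N = samples per epoch). Absolute scale is immaterial for
#' the connectivity analyses; dbWPLI is scale invariant.
#'
#' @param spec a `spectral_tensor`.
#' @return channels x frequency matrix; columns named by frequency in Hz.
#' @export
power_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectral_tensor"))
  d <- dim(spec$coefficients)
  if (d[3L] < 1L) stop("need at least one epoch")
  nsamp <- round(spec$fs * spec$epoch_length)
  pw <- apply(Mod(spec$coefficients)^2, c(1L, 2L), mean) / nsamp
  out <- t(pw)
  dimnames(out) <- list(spec$channel_labels, as.character(spec$freq))
  out
}

#' Debiased weighted phase lag index connectivity matrix
#'
#' For each frequency bin in `band` and each channel pair (a, b), with
#' `X_j = F_a(j) * Conj(F_b(j))` the epoch-j cross-spectrum, the estimator is
#'
#' \deqn{\mathrm{dbWPLI} = \frac{\sum_{j \ne k} \Im(X_j)\,\Im(X_k)}
#'   {\sum_{j \ne k} |\Im(X_j)|\,|\Im(X_k)|}
#'   = \frac{(\sum_j \Im X_j)^2 - \sum_j (\Im X_j)^2}
#'   {(\sum_j |\Im X_j|)^2 - \sum_j (\Im X_j)^2}.}
#'
#' Pairwise products across distinct epochs cancel the positive bias of the
#' squared WPLI, so the expectation is near 0 for independent signals; values
#' can be slightly negative. A zero denominator (at most one non-zero
#' imaginary cross-spectrum, e.g. exactly zero-lag coupling) leaves the entry
#' undefined (`NA`). Per-bin matrices are averaged across the band's bins,
#' ignoring undefined bins per entry.
#'
#' @param spec a `spectral_tensor` with at least 2 epochs.
#' @param band numeric `c(f_lo, f_hi)` in Hz, both edges inclusive; default
#'   the 7-8 Hz infant alpha band.
#' @return channels x channels symmetric matrix of class
#'   `connectivity_matrix`; diagonal `NA`, attributes `band`, `n_epochs`,
#'   `bins` (the bin frequencies averaged).
#' @export
dbwpli <- function(spec, band = c(7, 8)) {
  stopifnot(inherits(spec, "spectral_tensor"))
  if (length(band) != 2L || band[1L] > band[2L]) {
    stop("`band` must be c(f_lo, f_hi) with f_lo <= f_hi")
  }
  d <- dim(spec$coefficients)
  if (d[3L] < 2L) stop("dbWPLI needs at least 2 epochs")
  bins <- which(spec$freq >= band[1L] - 1e-9 & spec$freq <= band[2L] + 1e-9)
  if (length(bins) == 0L) {
    stop("band [", band[1L], ", ", band[2L], "] Hz contains no frequency bin ",
         "(resolution ", spec$freq[2L] - spec$freq[1L], " Hz)")
  }
  nch <- d[2L]
  pairs <- lower_pairs(nch)
  acc <- matrix(0, nrow(pairs), length(bins))
  for (bi in seq_along(bins)) {
    fc <- spec$coefficients[bins[bi], , ]          # channels x epochs
    dim(fc) <- c(nch, d[3L])
    re <- Re(fc); im <- Im(fc)
    # Im(F_a conj(F_b)) per epoch for every lower-triangle pair at once
    imx <- im[pairs[, 1L], , drop = FALSE] * re[pairs[, 2L], , drop = FALSE] -
           re[pairs[, 1L], , drop = FALSE] * im[pairs[, 2L], , drop = FALSE]
    s1 <- rowSums(imx)
    s2 <- rowSums(imx^2)
    sa <- rowSums(abs(imx))
    den <- sa^2 - s2
    acc[, bi] <- ifelse(den <= 0, NA_real_, (s1^2 - s2) / den)
  }
  vals <- rowMeans(acc, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_   # all bins undefined
  m <- matrix(NA_real_, nch, nch,
              dimnames = list(spec$channel_labels, spec$channel_labels))
  m[pairs] <- vals
  m[pairs[, c(2L, 1L), drop = FALSE]] <- vals
  structure(m, band = band, n_epochs = d[3L], bins = spec$freq[bins],
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<connectivity_matrix> %d channels, band %g-%g Hz, %d epochs\n",
              nrow(x), b[1L], b[2L], attr(x, "n_epochs")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Global connectivity: mean over all channel pairs
#'
#' Averages the strictly-lower-triangle entries of a connectivity matrix,
#' skipping undefined entries; the result is the whole-scalp mean dbWPLI.
#'
#' @param m a `connectivity_matrix` (or plain symmetric matrix).
#' @return A scalar; `NA` only if every pair is undefined.
#' @export
global_dbwpli <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 channels")
  v <- m[lower.tri(m)]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Build an edge mask from an edge list
#'
#' @param edges two-column matrix/data frame of channel indices (1-based) or
#'   channel labels.
#' @param channels channel count or character vector of channel labels.
#' @return Symmetric logical matrix of class `edge_mask`, diagonal `FALSE`.
#' @export
edge_mask <- function(edges, channels) {
  labels <- if (is.character(channels)) channels else paste0("ch", seq_len(channels))
  n <- length(labels)
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("`edges` needs two columns")
  a <- edges[[1L]]; b <- edges[[2L]]
  if (is.character(a) || is.factor(a)) {
    a <- match(as.character(a), labels)
    b <- match(as.character(b), labels)
    if (anyNA(a) || anyNA(b)) stop("edge label not among channel labels")
  }
  if (any(a < 1 | a > n | b < 1 | b > n)) stop("edge index out of range")
  if (any(a == b)) stop("self-edges are not allowed in an edge mask")
  m <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  m[cbind(a, b)] <- TRUE
  m[cbind(b, a)] <- TRUE
  structure(m, class = c("edge_mask", "matrix", "array"))
}

#' Mean connectivity over a selected set of connections
#'
#' Averages the connectivity values over the edges selected by a symmetric
#' boolean mask (e.g. the fronto-central connections identified in a prior
#' cohort), skipping undefined entries. With a full lower-triangle mask this
#' equals [global_dbwpli()].
#'
#' @param m a `connectivity_matrix`.
#' @param mask an [edge_mask()] (or symmetric logical matrix) of matching
#'   dimension with at least one selected edge.
#' @return A scalar; `NA` if every selected entry is undefined.
#' @export
masked_mean <- function(m, mask) {
  m <- as.matrix(m)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(m))) stop("mask dimensions do not match matrix")
  sel <- mask & lower.tri(mask)
  if (!any(sel)) stop("edge mask selects no connection")
  v <- m[sel]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Read / write connectivity matrices and edge masks as CSV
#'
#' Matrices are stored as CSV with channel labels as header row and first
#' column, plus a JSON sidecar with the band and epoch count. Edge masks are
#' stored as two-column edge lists (`label_a`, `label_b`).
#'
#' @param m a `connectivity_matrix`.
#' @param path output CSV path.
#' @return `path` (writers, invisibly); the reconstructed object (readers).
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  jsonlite::write_json(list(band = attr(m, "band"),
                            n_epochs = attr(m, "n_epochs")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  meta <- list(band = c(NA_real_, NA_real_), n_epochs = NA_integer_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  structure(m, band = as.numeric(meta$band), n_epochs = meta$n_epochs,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @param channels channel labels (or count) the mask applies to.
#' @rdname write_connectivity
#' @export
read_edge_mask <- function(path, channels) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  edge_mask(edges[, 1:2], channels)
}

#' @param mask an [edge_mask()].
#' @rdname write_connectivity
#' @export
write_edge_mask <- function(mask, path) {
  stopifnot(inherits(mask, "edge_mask"))
  idx <- which(as.matrix(mask) & lower.tri(mask), arr.ind = TRUE)
  labels <- rownames(mask) %||% as.character(seq_len(nrow(mask)))
  utils::write.csv(data.frame(label_a = labels[idx[, 1L]],
                              label_b = labels[idx[, 2L]]),
                   path, row.names = FALSE)
  invisible(path)
}
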