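#' Maximal valid segments of a recording
#'
#' Complements the union of excluding annotations (`inattention`,
#' `interference`, `artefact`) within `[0, duration)`. Overlapping or abutting
#' excluded intervals are merged before complementing, so malformed overlaps
#' never raise an error. `condition` annotations label stimulus periods and do
#' not exclude.
#'
#' @param rec an [eeg_recording()].
#' @param exclude_kinds annotation kinds treated as invalid.
#' @return A data frame with columns `start`, `end` (seconds): sorted,
#'   disjoint, half-open intervals containing no excluded annotation.
#' @export
valid_segments <- function(rec,
                           exclude_kinds = c("inattention", "interference",
                                             "artefact")) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- recording_duration(rec)
  ann <- rec$annotations
  bad <- ann[ann$kind %in% exclude_kinds & ann$end > ann$start, , drop = FALSE]
  if (nrow(bad) == 0L) {
    return(data.frame(start = 0, end = dur))
  }
  bad <- bad[order(bad$start, bad$end), , drop = FALSE]
  merged_s <- bad$start[1L]
  merged_e <- bad$end[1L]
  for (k in seq_len(nrow(bad))[-1L]) {
    if (bad$start[k] <= merged_e[length(merged_e)]) {
      merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], bad$end[k])
    } else {
      merged_s <- c(merged_s, bad$start[k])
      merged_e <- c(merged_e, bad$end[k])
    }
  }
  starts <- c(0, merged_e)
  ends <- c(merged_s, dur)
  keep <- ends - starts > 1e-12
  data.frame(start = starts[keep], end = ends[keep])
}

#' Cut valid segments into fixed-length overlapping epochs
#'
#' Slides a `epoch_length`-second window in steps of
#' `epoch_length * (1 - overlap)` within each segment; a segment of length `L`
#' yields `max(0, floor((L - epoch_length) / (epoch_length * (1 - overlap))) + 1)`
#' epochs and no epoch ever crosses a segment boundary. Defaults reproduce
#' 1-s epochs with 50% overlap.
#'
#' @param rec an [eeg_recording()].
#' @param segments a data frame with `start`/`end` columns in seconds;
#'   defaults to [valid_segments()] of the recording.
#' @param epoch_length epoch length in seconds; `fs * epoch_length` must be a
#'   whole number of samples.
#' @param overlap fraction in `[0, 1)` by which consecutive epochs overlap.
#' @return An object of class `epoch_set`: samples x channels x epochs array
#'   plus per-epoch provenance (source segment, start time, condition label).
#' @export
epoch_segments <- function(rec, segments = NULL, epoch_length = 1,
                           overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_length <= 0) stop("`epoch_length` must be > 0")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  nsamp <- rec$fs * epoch_length
  if (abs(nsamp - round(nsamp)) > 1e-9) {
    stop("fs * epoch_length must be a whole number of samples (got ",
         nsamp, ")")
  }
  nsamp <- as.integer(round(nsamp))
  step <- nsamp * (1 - overlap)
  if (abs(step - round(step)) > 1e-9) {
    stop("the epoch step fs * epoch_length * (1 - overlap) must be a whole ",
         "number of samples (got ", step, ")")
  }
  step <- as.integer(round(step))
  segments <- segments %||% valid_segments(rec)
  nch <- nrow(rec$samples)
  starts_samp <- integer(0)
  seg_of <- integer(0)
  for (s in seq_len(nrow(segments))) {
    a <- as.integer(ceiling(segments$start[s] * rec$fs - 1e-9))
    b <- as.integer(ceiling(segments$end[s] * rec$fs - 1e-9))  # exclusive
    len <- b - a
    if (len < nsamp) next
    k <- (len - nsamp) %/% step
    st <- a + step * (0:k)
    starts_samp <- c(starts_samp, st)
    seg_of <- c(seg_of, rep.int(s, k + 1L))
  }
  nep <- length(starts_samp)
  arr <- array(0, dim = c(nsamp, nch, nep))
  for (e in seq_len(nep)) {
    arr[, , e] <- t(rec$samples[, (starts_samp[e] + 1L):(starts_samp[e] + nsamp),
                                drop = FALSE])
  }
  prov <- data.frame(segment = seg_of,
                     start = starts_samp / rec$fs,
                     condition = condition_at(rec, starts_samp / rec$fs),
                     stringsAsFactors = FALSE)
  structure(
    list(epochs = arr, fs = rec$fs, epoch_length = epoch_length,
         overlap = overlap, channel_labels = rec$channel_labels,
         provenance = prov),
    class = "epoch_set")
}

condition_at <- function(rec, times) {
  cond <- rec$annotations[rec$annotations$kind == "condition", , drop = FALSE]
  out <- rep(NA_character_, length(times))
  for (k in seq_len(nrow(cond))) {
    hit <- times >= cond$start[k] & times < cond$end[k]
    out[hit] <- cond$condition[k]
  }
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s, overlap %g)\n",
              n_epochs(x), dim(x$epochs)[2L], dim(x$epochs)[1L],
              x$epoch_length, x$overlap))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs an `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  dim(epochs$epochs)[3L]
}

#' Drop epochs exceeding an absolute amplitude threshold
#'
#' An epoch is rejected when its peak absolute amplitude on any channel
#' exceeds `threshold` (strictly). Epoch order is preserved. The default of
#' 200 microvolts is a conventional automatic rejection bound for infant
#' scalp EEG.
#'
#' @param epochs an `epoch_set`.
#' @param threshold rejection bound in microvolts (> 0); `Inf` keeps all.
#' @return The filtered `epoch_set`.
#' @export
amplitude_artefact_filter <- function(epochs, threshold = 200) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  nep <- n_epochs(epochs)
  if (nep == 0L) return(epochs)
  peak <- apply(abs(epochs$epochs), 3L, max)
  keep <- peak <= threshold
  epochs$epochs <- epochs$epochs[, , keep, drop = FALSE]
  epochs$provenance <- epochs$provenance[keep, , drop = FALSE]
  rownames(epochs$provenance) <- NULL
  epochs
}

#' Epoch-count inclusion rule
#'
#' A subject enters the analysis only with strictly more than `min_epochs`
#' clean epochs pooled across stimulus conditions; exactly `min_epochs`
#' epochs is not enough.
#'
#' @param epochs an `epoch_set` or a plain epoch count.
#' @param min_epochs inclusion cut-off (default 120).
#' @return `TRUE` or `FALSE`.
#' @export
meets_inclusion <- function(epochs, min_epochs = 120) {
  n <- if (inherits(epochs, "epoch_set")) n_epochs(epochs) else as.numeric(epochs)
  n > min_epochs
}
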