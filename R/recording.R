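#' Multichannel EEG recording
#'
#' Container for a continuous multichannel recording: a channels x samples
#' numeric matrix (microvolts), its sampling rate, channel labels and a table
#' of validity annotations. Annotation intervals are half-open `[start, end)`
#' in seconds; sample `i` (0-based) covers time `i / fs`.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `"ch1", "ch2", ...`.
#' @param annotations `NULL` or a data frame with columns `start`, `end`
#'   (seconds), `kind` (one of `"inattention"`, `"interference"`,
#'   `"artefact"`, or `"condition"` for non-excluding stimulus labels) and
#'   optionally `condition` (free-text label).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = NULL,
                          annotations = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  nch <- nrow(samples)
  channel_labels <- channel_labels %||% paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch) {
    stop("`channel_labels` must have one entry per channel (",
         nch, " channels, ", length(channel_labels), " labels)")
  }
  dur <- ncol(samples) / fs
  annotations <- normalize_annotations(annotations, dur)
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         annotations = annotations),
    class = "eeg_recording")
}

annotation_kinds <- c("inattention", "interference", "artefact", "condition")

normalize_annotations <- function(annotations, duration) {
  if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0), condition = character(0),
                      stringsAsFactors = FALSE))
  }
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("start", "end", "kind")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns: ", paste(need, collapse = ", "))
  }
  if (!"condition" %in% names(ann)) ann$condition <- NA_character_
  ann <- ann[, c("start", "end", "kind", "condition")]
  ann$kind <- as.character(ann$kind)
  bad <- setdiff(unique(ann$kind), annotation_kinds)
  if (length(bad)) stop("unknown annotation kind(s): ", paste(bad, collapse = ", "))
  if (any(ann$start < 0 | ann$end > duration + 1e-9 | ann$end < ann$start)) {
    stop("annotation intervals must satisfy 0 <= start <= end <= duration")
  }
  ann[order(ann$start, ann$end), , drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz), %d annotation(s)\n",
              nrow(x$samples), ncol(x$samples),
              recording_duration(x), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [eeg_recording()].
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$samples) / rec$fs
}

#' Read a recording from a delimited matrix plus JSON sidecar
#'
#' The on-disk format is a headerless CSV with one row per channel, a JSON
#' sidecar `<path>.json` holding `fs` and `channel_labels`, and an optional
#' annotations CSV (`start`, `end`, `kind`, `condition` columns).
#'
#' @param path path to the data CSV.
#' @param sidecar path to the JSON sidecar; default `paste0(path, ".json")`.
#' @param annotations path to an annotations CSV, or `NULL`. When the default
#'   path does not exist the recording is treated as fully valid with a
#'   warning, since manual validity coding may be absent for synthetic data.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, sidecar = paste0(path, ".json"),
                           annotations = default_annotation_path(path)) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(sidecar)) {
    stop("sidecar not found (delimited recordings need a JSON sidecar): ",
         sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar is missing `fs`: ", sidecar)
  mat <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(mat) <- NULL
  labels <- meta$channel_labels %||% paste0("ch", seq_len(nrow(mat)))
  if (length(labels) != nrow(mat)) {
    stop(sprintf("channel count mismatch: sidecar declares %d labels, data has %d rows",
                 length(labels), nrow(mat)))
  }
  ann <- NULL
  if (!is.null(annotations)) {
    if (file.exists(annotations)) {
      ann <- utils::read.csv(annotations, stringsAsFactors = FALSE)
    } else if (!identical(annotations, default_annotation_path(path))) {
      stop("annotation file not found: ", annotations)
    } else {
      warning("no annotation file at ", annotations,
              "; treating the whole recording as valid")
    }
  }
  eeg_recording(mat, fs = meta$fs, channel_labels = labels, annotations = ann)
}

default_annotation_path <- function(path) {
  paste0(sub("\\.[^.]+$", "", path), "_annotations.csv")
}

#' Write a recording as delimited matrix + JSON sidecar
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path; the sidecar goes to `paste0(path, ".json")`
#'   and annotations (if any) to `<stem>_annotations.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         n_channels = nrow(rec$samples), n_samples = ncol(rec$samples)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (nrow(rec$annotations) > 0L) {
    utils::write.csv(rec$annotations, default_annotation_path(path),
                     row.names = FALSE)
  }
  invisible(path)
}
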