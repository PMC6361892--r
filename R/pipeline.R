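#' Run the full connectivity analysis pipeline on a cohort
#'
#' Executes, per subject: validity segmentation, overlapping epoching,
#' amplitude artefact rejection, the strict epoch-count inclusion rule,
#' Hanning FFT and band-averaged dbWPLI, and the global / selected-edge
#' connectivity summaries. Included subjects then feed the group analyses:
#' Network-Based Statistics per configured comparison, assumption-dispatched
#' univariate tests of global connectivity, and the brain-behaviour
#' correlation table.
#'
#' @param recordings named list of [eeg_recording()]s keyed by subject id,
#'   or a data frame manifest with columns `id` and `path` (read via
#'   [read_recording()]).
#' @param cohort data frame with one row per subject: `id`, `group`, and any
#'   trait scale columns used by `scales`.
#' @param band analysis band in Hz.
#' @param epoch_length,overlap epoching parameters (seconds, fraction).
#' @param amplitude_threshold artefact bound in microvolts.
#' @param min_epochs strict inclusion cut-off ("more than" this many epochs).
#' @param mask `NULL` or an [edge_mask()] for the selected-connection
#'   summary.
#' @param comparisons list of 2-vectors of group names; each runs an NBS
#'   test (first group = hypothesised-larger side) and a univariate
#'   comparison of global connectivity.
#' @param nbs an [nbs_config()].
#' @param scales trait columns to correlate with connectivity (skipped when
#'   empty).
#' @param correlation_groups groups included in the correlation analysis.
#' @param fdr_q,a_priori passed to [correlation_analysis()].
#' @param out_dir `NULL` or a directory where CSV/JSON artifacts are written.
#' @param seed seed forwarded to the NBS permutation stream.
#' @return An object of class `run_report`: `subjects` (per-subject epoch
#'   counts, inclusion flags with reasons, connectivity summaries),
#'   `matrices` (per included subject), `nbs` (per comparison),
#'   `group_tests` (univariate global-connectivity comparisons),
#'   `correlations`, and the configuration used.
#' @export
run_pipeline <- function(recordings, cohort, band = c(7, 8),
                         epoch_length = 1, overlap = 0.5,
                         amplitude_threshold = 200, min_epochs = 120,
                         mask = NULL, comparisons = list(),
                         nbs = nbs_config(), scales = character(0),
                         correlation_groups = NULL, fdr_q = NULL,
                         a_priori = character(0), out_dir = NULL,
                         seed = NULL) {
  if (is.data.frame(recordings)) {
    if (!all(c("id", "path") %in% names(recordings))) {
      stop("a recording manifest needs `id` and `path` columns")
    }
    paths <- stats::setNames(recordings$path, recordings$id)
    recordings <- lapply(paths, read_recording)
  }
  if (!all(c("id", "group") %in% names(cohort))) {
    stop("`cohort` needs `id` and `group` columns")
  }
  missing_rec <- setdiff(cohort$id, names(recordings))
  if (length(missing_rec)) {
    stop("no recording for subject(s): ", paste(missing_rec, collapse = ", "))
  }
  if (!is.null(seed)) nbs$seed <- seed

  subjects <- cohort
  subjects$n_epochs <- NA_integer_
  subjects$included <- FALSE
  subjects$exclusion_reason <- NA_character_
  subjects$global_dbwpli <- NA_real_
  subjects$selected_dbwpli <- NA_real_
  matrices <- list()

  for (k in seq_len(nrow(subjects))) {
    id <- subjects$id[k]
    rec <- recordings[[id]]
    ep <- tryCatch(
      amplitude_artefact_filter(
        epoch_segments(rec, epoch_length = epoch_length, overlap = overlap),
        threshold = amplitude_threshold),
      error = function(e) e)
    if (inherits(ep, "error")) {
      stop("preprocess failed for subject ", id, ": ", conditionMessage(ep))
    }
    subjects$n_epochs[k] <- n_epochs(ep)
    if (!meets_inclusion(ep, min_epochs = min_epochs)) {
      subjects$exclusion_reason[k] <-
        sprintf("insufficient epochs (%d <= %d)", n_epochs(ep), min_epochs)
      next
    }
    m <- dbwpli(taper_fft(ep), band = band)
    matrices[[id]] <- m
    subjects$included[k] <- TRUE
    subjects$global_dbwpli[k] <- global_dbwpli(m)
    if (!is.null(mask)) subjects$selected_dbwpli[k] <- masked_mean(m, mask)
  }

  nbs_results <- list()
  group_tests <- list()
  inc <- subjects[subjects$included, , drop = FALSE]
  for (cmp in comparisons) {
    key <- paste(cmp, collapse = "_vs_")
    ga <- matrices[inc$id[inc$group == cmp[1L]]]
    gb <- matrices[inc$id[inc$group == cmp[2L]]]
    if (length(ga) < 2L || length(gb) < 2L) {
      warning("comparison ", key, " skipped: fewer than 2 included subjects ",
              "in a group")
      next
    }
    nbs_results[[key]] <- nbs_test(ga, gb, nbs)
    va <- inc$global_dbwpli[inc$group == cmp[1L]]
    vb <- inc$global_dbwpli[inc$group == cmp[2L]]
    dispatch <- choose_test(va, vb)
    group_tests[[key]] <- if (dispatch$test == "t") {
      tt <- stats::t.test(va, vb, var.equal = TRUE)
      alpha_test("t", unname(tt$statistic), p = tt$p.value, tails = 2,
                 n1 = length(va), n2 = length(vb), note = dispatch$reason)
    } else {
      mann_whitney(va, vb)
    }
  }

  correlations <- NULL
  if (length(scales)) {
    measures <- c(global = "global_dbwpli")
    if (!is.null(mask)) measures <- c(measures, selected = "selected_dbwpli")
    correlations <- correlation_analysis(
      inc, group_filter = correlation_groups, measures = measures,
      scales = scales, fdr_q = fdr_q, a_priori = a_priori)
  }

  report <- structure(
    list(subjects = subjects, matrices = matrices, nbs = nbs_results,
         group_tests = group_tests, correlations = correlations,
         config = list(band = band, epoch_length = epoch_length,
                       overlap = overlap,
                       amplitude_threshold = amplitude_threshold,
                       min_epochs = min_epochs, nbs = nbs,
                       comparisons = comparisons, scales = scales,
                       seed = seed)),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  n <- nrow(x$subjects)
  cat(sprintf("<run_report> %d subjects, %d included\n",
              n, sum(x$subjects$included)))
  excl <- x$subjects[!x$subjects$included, , drop = FALSE]
  for (k in seq_len(nrow(excl))) {
    cat(sprintf("  excluded %s: %s\n", excl$id[k], excl$exclusion_reason[k]))
  }
  for (key in names(x$nbs)) {
    cat("NBS ", key, ":\n", sep = "")
    print(x$nbs[[key]])
  }
  for (key in names(x$group_tests)) {
    cat("global connectivity ", key, ": ", sep = "")
    print(x$group_tests[[key]])
  }
  if (!is.null(x$correlations)) {
    cat("correlations:\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}

#' Write a run report's artifacts to a directory
#'
#' Emits `subjects.csv`, one connectivity CSV per included subject,
#' per-comparison NBS summaries (component table CSV + null distribution
#' CSV + JSON summary), univariate test results and the correlation table,
#' plus a `run_config.json` provenance sidecar.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  mat_dir <- file.path(out_dir, "connectivity")
  dir.create(mat_dir, showWarnings = FALSE)
  for (id in names(report$matrices)) {
    write_connectivity(report$matrices[[id]],
                       file.path(mat_dir, paste0(id, ".csv")))
  }
  for (key in names(report$nbs)) {
    res <- report$nbs[[key]]
    utils::write.csv(summary(res),
                     file.path(out_dir, paste0("nbs_", key, "_components.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(max_statistic = res$null_max),
                     file.path(out_dir, paste0("nbs_", key, "_null.csv")),
                     row.names = FALSE)
  }
  tests <- lapply(report$group_tests, unclass)
  jsonlite::write_json(
    list(group_tests = tests,
         config = report$config[setdiff(names(report$config), "nbs")]),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
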