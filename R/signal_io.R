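#' Construct a single-stage EMG recording
#'
#' An `emg_recording` holds one stage's raw surface-EMG trace for one leg:
#' the sample vector (arbitrary acquisition units, never rescaled at
#' ingestion), the sampling rate, and the identifying labels. Recordings are
#' validated on construction: samples must be finite and non-empty and the
#' stage label must be one of the nine admissible time points in [STAGES].
#'
#' @param samples Numeric vector of amplitudes. The acquisition protocol
#'   yields 2 min at 1,000 Hz (120,000 samples); shorter traces are accepted
#'   with a warning as long as at least one 400-sample analysis window fits.
#' @param stage Stage label, one of [STAGES].
#' @param pig_id Subject identifier, e.g. `"P1"`.
#' @param leg `"L"` or `"R"`.
#' @param fs Sampling rate in Hz (default 1000).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, stage, pig_id = "P1", leg = c("L", "R"),
                          fs = 1000) {
  leg <- match.arg(leg)
  check_stage(stage)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stopf("fs must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0) stopf("stage %s: samples are empty", stage)
  if (any(!is.finite(samples))) {
    stopf("stage %s: %d non-finite sample(s)", stage, sum(!is.finite(samples)))
  }
  if (length(samples) < 400) {
    stopf("stage %s: %d samples, need at least 400 for one analysis window",
          stage, length(samples))
  }
  if (length(samples) < 120000) {
    warning(sprintf("stage %s: %d samples (< 2 min at %g Hz)",
                    stage, length(samples), fs), call. = FALSE)
  }
  structure(
    list(pig_id = as.character(pig_id), leg = leg, stage = stage,
         fs = fs, samples = samples),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s-%s stage %s: %d samples @ %g Hz (%.1f s)\n",
              x$pig_id, x$leg, x$stage, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Bundle one leg's stage recordings
#'
#' @param recordings List of [emg_recording] objects, at most one per stage,
#'   all sharing `pig_id`, `leg` and `fs`.
#' @return An object of class `leg_dataset`; `$recordings` is a named list
#'   keyed by stage label in protocol order.
#' @export
leg_dataset <- function(recordings) {
  if (length(recordings) == 0) stopf("no recordings supplied")
  stopifnot(all(vapply(recordings, inherits, TRUE, "emg_recording")))
  stages <- vapply(recordings, `[[`, "", "stage")
  if (anyDuplicated(stages)) {
    stopf("duplicate recordings for stage(s): %s",
          paste(unique(stages[duplicated(stages)]), collapse = ", "))
  }
  fs <- unique(vapply(recordings, `[[`, 0, "fs"))
  if (length(fs) != 1) stopf("recordings disagree on sampling rate")
  pid <- unique(vapply(recordings, `[[`, "", "pig_id"))
  leg <- unique(vapply(recordings, `[[`, "", "leg"))
  if (length(pid) != 1 || length(leg) != 1) {
    stopf("recordings mix pig/leg identities")
  }
  names(recordings) <- stages
  ord <- order(match(stages, STAGES))
  structure(
    list(pig_id = pid, leg = leg, fs = fs, recordings = recordings[ord]),
    class = "leg_dataset"
  )
}

#' @export
print.leg_dataset <- function(x, ...) {
  cat(sprintf("<leg_dataset> %s-%s @ %g Hz, %d stage(s): %s\n",
              x$pig_id, x$leg, x$fs, length(x$recordings),
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}

#' Read a stage-labelled EMG table
#'
#' Reads the supplementary-style layout: first row holds stage labels
#' (`T-1`, `T1`, ..., `T8`), one column per stage, one sample per row.
#' Trailing blank cells in short columns are trimmed; a non-numeric value
#' *inside* a column is a validation error naming the stage. An optional
#' leading index column (non-stage header) is tolerated and ignored. Column
#' order is irrelevant: stage identity follows the header label.
#'
#' `.csv` files are read with [utils::read.csv]; `.xlsx` requires the
#' `readxl` package. A long-format CSV with columns
#' `pig_id, leg, stage, sample_index, value` is also accepted (detected by
#' its header).
#'
#' @param path Path to the table.
#' @param pig_id,leg Identity attached to the recordings (long format
#'   overrides them from its own columns).
#' @param fs Sampling rate in Hz.
#' @return A [leg_dataset] with one recording per labelled column.
#' @export
read_stage_table <- function(path, pig_id = "P1", leg = "L", fs = 1000) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stopf("reading xlsx requires the 'readxl' package")
    }
    tab <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                         stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  }
  hdr <- names(tab)
  if (all(c("pig_id", "leg", "stage", "sample_index", "value") %in% hdr)) {
    return(read_long_table(tab, fs))
  }
  is_stage <- hdr %in% STAGES
  if (!any(is_stage)) {
    stopf("'%s': header row contains no admissible stage label", path)
  }
  if (anyDuplicated(hdr[is_stage])) {
    stopf("'%s': duplicate stage header(s): %s", path,
          paste(unique(hdr[is_stage][duplicated(hdr[is_stage])]),
                collapse = ", "))
  }
  recs <- lapply(which(is_stage), function(j) {
    stage <- hdr[j]
    col <- tab[[j]]
    # trim trailing blanks, then require a clean numeric run
    blank <- is.na(col) | !nzchar(trimws(col))
    last <- if (all(blank)) 0L else max(which(!blank))
    col <- col[seq_len(last)]
    vals <- suppressWarnings(as.numeric(col))
    if (any(is.na(vals))) {
      stopf("stage %s: non-numeric value at row %d", stage,
            which(is.na(vals))[1])
    }
    if (length(vals) < 400) {
      stopf("stage %s: only %d numeric samples (need >= 400)",
            stage, length(vals))
    }
    emg_recording(vals, stage, pig_id = pig_id, leg = leg, fs = fs)
  })
  leg_dataset(recs)
}

read_long_table <- function(tab, fs) {
  tab$value <- suppressWarnings(as.numeric(tab$value))
  tab$sample_index <- suppressWarnings(as.numeric(tab$sample_index))
  if (any(is.na(tab$value))) stopf("long table: non-numeric value cells")
  key <- unique(tab[c("pig_id", "leg")])
  if (nrow(key) != 1) stopf("long table mixes multiple legs")
  recs <- lapply(split(tab, tab$stage), function(d) {
    d <- d[order(d$sample_index), ]
    emg_recording(d$value, d$stage[1], pig_id = d$pig_id[1],
                  leg = d$leg[1], fs = fs)
  })
  leg_dataset(recs)
}

#' Write a leg dataset as a stage-labelled wide CSV
#'
#' Inverse of [read_stage_table] for the wide layout: one column per stage,
#' stage labels in the header, columns padded with blanks to equal length.
#'
#' @param leg A [leg_dataset].
#' @param path Output path.
#' @export
write_stage_table <- function(leg, path) {
  cols <- lapply(leg$recordings, `[[`, "samples")
  n <- max(lengths(cols))
  mat <- vapply(cols, function(x) c(x, rep(NA_real_, n - length(x))),
                numeric(n))
  utils::write.csv(as.data.frame(mat, check.names = FALSE), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a cross-validation result
#'
#' Writes a [cv_result] as JSON (full double precision) so that
#' `read_metrics(write_metrics(x))` round-trips losslessly. The confusion
#' matrix keeps its predicted-by-true orientation and stage labels.
#'
#' @param result A [cv_result].
#' @param path Output file.
#' @seealso [read_metrics], [write_confusion_csv]
#' @export
write_metrics <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  obj <- list(
    protocol = result$protocol,
    unit_names = result$unit_names,
    accuracies = result$accuracies,
    mean = result$mean,
    std = result$std,
    class_labels = result$class_labels,
    confusion = result$confusion  # predicted rows x true columns
  )
  ok <- tryCatch({
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write metrics to '%s'", path)
  invisible(path)
}

#' Read back a serialized cross-validation result
#'
#' @param path File written by [write_metrics].
#' @return A [cv_result].
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # write_json(matrix = "rowmajor") stores row by row; read_json with
  # simplification reconstructs the matrix in the same orientation
  conf <- matrix(as.numeric(obj$confusion), nrow = length(obj$class_labels))
  if (is.matrix(obj$confusion)) conf[] <- obj$confusion
  cv_result(protocol = obj$protocol,
            accuracies = as.numeric(obj$accuracies),
            unit_names = as.character(obj$unit_names),
            confusion = conf,
            class_labels = as.character(obj$class_labels))
}

#' Write a confusion matrix as labelled CSV
#'
#' @param result A [cv_result].
#' @param path Output file; rows are predicted labels, columns true labels.
#' @export
write_confusion_csv <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  utils::write.csv(as.data.frame(result$confusion), path, row.names = TRUE)
  invisible(path)
}
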