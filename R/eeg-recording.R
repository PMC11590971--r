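#' EEG channel montage used throughout the package
#'
#' Eight-channel frontal/parietal montage of the wearable headset the
#' pipeline targets: five anterior-frontal and three parietal electrodes
#' (10-10 positions), sampled at 125 Hz.
#'
#' @format Character vector of channel labels.
#' @export
EEG_CHANNELS <- c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")

#' Parietal channel subset used for alpha GFP
#' @export
PARIETAL_CHANNELS <- c("Pz", "P3", "P4")

#' Protocol condition labels, in order
#' @export
CONDITIONS <- c("EC", "EO1", "Circuit", "EO2", "Monotonous", "EO3")

#' Construct an annotated multichannel EEG recording
#'
#' The substrate of all spectral computation: a channels x samples matrix in
#' microvolts with a sampling rate and condition annotations (non-overlapping
#' labeled intervals in seconds from recording start).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channels character vector of unique channel labels, one per row.
#' @param fs sampling frequency in Hz (> 0).
#' @param annotations data frame with columns `label`, `start`, `end`
#'   (seconds); intervals must lie inside the recording and not overlap.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels = EEG_CHANNELS, fs = 125,
                          annotations = NULL) {
  data <- as.matrix(data)
  assert_that(fs > 0, "`fs` must be positive")
  assert_that(nrow(data) == length(channels),
              "`data` must have one row per channel")
  assert_that(!anyDuplicated(channels), "channel labels must be unique")
  rownames(data) <- channels
  dur <- ncol(data) / fs
  if (is.null(annotations)) {
    annotations <- tibble::tibble(label = character(), start = double(),
                                  end = double())
  } else {
    annotations <- tibble::as_tibble(annotations)
    assert_that(all(c("label", "start", "end") %in% names(annotations)),
                "annotations need columns label, start, end")
    assert_that(all(annotations$start >= 0 & annotations$end <= dur + 1e-9),
                "annotation intervals must lie within the recording")
    ann <- annotations[order(annotations$start), ]
    if (nrow(ann) > 1 &&
        any(ann$start[-1] < ann$end[-nrow(ann)] - 1e-9))
      stop("annotation intervals must not overlap", call. = FALSE)
  }
  structure(
    list(data = data, channels = channels, fs = fs, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (nrow(x$annotations))
    cat("  conditions:", paste(x$annotations$label, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Extract the samples of one annotated condition
#'
#' @param rec an [eeg_recording()].
#' @param label condition label (e.g. `"EC"`).
#' @return An `eeg_recording` holding just that condition's samples (the
#'   annotation is rebased to start at 0).
#' @export
condition_segment <- function(rec, label) {
  ann <- rec$annotations[rec$annotations$label == label, ]
  if (nrow(ann) == 0)
    stop(sprintf("condition '%s' is not annotated", label), call. = FALSE)
  i0 <- floor(ann$start[1] * rec$fs) + 1
  i1 <- min(ncol(rec$data), floor(ann$end[1] * rec$fs))
  eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$channels, rec$fs,
                tibble::tibble(label = label, start = 0,
                               end = (i1 - i0 + 1) / rec$fs))
}

#' Write / read an EEG recording as long CSV plus a JSON annotation sidecar
#'
#' The interchange format is a long table `t, channel, value_uV` and a
#' sidecar `<path>.annotations.json` with `fs` and the condition intervals.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly (writer); an `eeg_recording` (reader).
#' @export
write_eeg_csv <- function(rec, path) {
  t <- rep((seq_len(ncol(rec$data)) - 1) / rec$fs, each = nrow(rec$data))
  long <- data.frame(
    t = t,
    channel = rep(rec$channels, times = ncol(rec$data)),
    value_uV = as.vector(rec$data)
  )
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, annotations = rec$annotations),
    paste0(path, ".annotations.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  long <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".annotations.json"),
                              simplifyVector = TRUE)
  channels <- unique(long$channel)
  m <- matrix(long$value_uV, nrow = length(channels))
  rownames(m) <- channels
  ann <- side$annotations
  if (length(ann) == 0) ann <- NULL
  eeg_recording(m, channels, side$fs, ann)
}
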