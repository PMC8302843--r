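#' A labelled multichannel sEMG recording
#'
#' A recording holds a 10 x T matrix of microvolt-scale samples from the ten
#' facial sEMG channels, the sampling rate, the posed expression label and
#' acquisition metadata (subject and batch/session identifiers). Channel
#' order is fixed: CH1..CH10 record the action units in [feree_channel_aus].
#'
#' @param signals Numeric matrix `10 x T` (channels in rows), microvolts.
#' @param fs Sampling rate in Hz (default 1000).
#' @param expression One of [feree_expressions].
#' @param intensity Intensity level 1-5 or letter A-E.
#' @param subject_id,batch_id Free-form identifiers (no commas or newlines).
#' @param channel_map Character vector of 10 unique AU tags; defaults to
#'   [feree_channel_aus].
#' @return An object of class `emg_recording`.
#' @seealso [segment_windows()], [read_recording()], [write_recording()]
#' @export
recording <- function(signals, fs = 1000, expression, intensity,
                      subject_id = "S1", batch_id = "B1",
                      channel_map = feree_channel_aus) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (nrow(signals) != 10L) {
    stop_feree(sprintf("recording must have exactly 10 channels, got %d",
                       nrow(signals)), "feree_channel_error")
  }
  if (length(channel_map) != 10L || anyDuplicated(channel_map)) {
    stop_feree("channel_map must contain 10 unique AU tags",
               "feree_channel_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_feree("fs must be a positive scalar", "feree_format_error")
  }
  label <- expression_label(expression, intensity)
  rownames(signals) <- paste0("CH", 1:10)
  structure(
    list(signals = signals, fs = as.numeric(fs), label = label,
         subject_id = as.character(subject_id),
         batch_id = as.character(batch_id),
         channel_map = as.character(channel_map)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d ch x %d samples @ %g Hz | %s %s | subject %s, batch %s\n",
    nrow(x$signals), ncol(x$signals), x$fs, x$label$expression,
    intensity_letter(x$label$intensity), x$subject_id, x$batch_id))
  invisible(x)
}

#' Cut a recording into overlapping fixed-length frames
#'
#' Deterministic sliding-window segmentation: frame `i` (0-based) starts at
#' sample `i * hop`, covers `window` samples, and inherits the recording's
#' label and metadata. With the defaults (window 200, hop 50 at 1000 Hz) the
#' frame rate is 20 frames per second with 75% overlap.
#'
#' @param rec An [recording()].
#' @param window Frame length in samples (default 200).
#' @param hop Hop between frame starts in samples (default 50).
#' @return A list of `emg_frame` objects, each with fields `window`
#'   (10 x `window` matrix), `start_index` (0-based sample offset), `label`,
#'   `subject_id`, `batch_id`. Length is `floor((T - window)/hop) + 1`.
#' @examples
#' rec <- recording(matrix(rnorm(10 * 1000), 10), expression = "happiness",
#'                  intensity = 3)
#' length(segment_windows(rec))  # 17
#' @export
segment_windows <- function(rec, window = 200L, hop = 50L) {
  stopifnot(inherits(rec, "emg_recording"))
  window <- as.integer(window)
  hop <- as.integer(hop)
  n <- ncol(rec$signals)
  if (hop < 1L) stop_feree("hop must be >= 1", "feree_format_error")
  if (n < window) {
    stop_feree(sprintf(
      "recording too short: %d samples < window of %d", n, window),
      "feree_empty_input_error")
  }
  starts <- seq.int(0L, n - window, by = hop)
  lapply(starts, function(s) {
    structure(
      list(window = rec$signals[, (s + 1L):(s + window), drop = FALSE],
           start_index = s, label = rec$label,
           subject_id = rec$subject_id, batch_id = rec$batch_id),
      class = "emg_frame"
    )
  })
}

#' Read and write recordings
#'
#' Two interchange formats are supported. The primary dialect is a UTF-8
#' comma-separated file: `#key=value` header lines carry `fs`, `expression`,
#' `intensity`, `subject_id` and `batch_id`, followed by a `CH1,...,CH10`
#' column header and one row per sample, written at full float precision so
#' a write/read round-trip is bit-exact. The secondary format is EDF
#' (European Data Format), a 16-bit format whose round-trip is exact only up
#' to amplitude quantization.
#'
#' @param path File path.
#' @param format `"delimited"` (default) or `"edf"`.
#' @param rec A [recording()].
#' @return `read_recording()` returns an `emg_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_feree(sprintf("file not found: %s", path), "feree_io_error")
  }
  if (format == "edf") return(read_edf_recording(path))
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop_feree(sprintf("bad header line: %s", ln),
                           "feree_format_error")
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  need <- c("fs", "expression", "intensity", "subject_id", "batch_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop_feree(sprintf("missing metadata: %s", paste(miss, collapse = ", ")),
               "feree_format_error")
  }
  body <- lines[!is_meta]
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  if (length(header) != 10L) {
    stop_feree(sprintf("expected 10 channel columns, found %d",
                       length(header)), "feree_channel_error")
  }
  dat <- utils::read.csv(textConnection(body), header = TRUE,
                         colClasses = "numeric")
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs)) stop_feree("unparseable fs", "feree_format_error")
  recording(t(as.matrix(dat)), fs = fs,
            expression = meta$expression, intensity = meta$intensity,
            subject_id = meta$subject_id, batch_id = meta$batch_id)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "emg_recording"))
  if (format == "edf") {
    write_edf_recording(rec, path)
    return(invisible(path))
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_feree(sprintf("cannot open %s for writing", path), "feree_io_error")
  })
  on.exit(close(con))
  meta <- c(
    sprintf("#fs=%s", format(rec$fs, digits = 17)),
    sprintf("#expression=%s", rec$label$expression),
    sprintf("#intensity=%s", intensity_letter(rec$label$intensity)),
    sprintf("#subject_id=%s", rec$subject_id),
    sprintf("#batch_id=%s", rec$batch_id)
  )
  writeLines(meta, con, useBytes = TRUE)
  # format with 17 significant digits: round-trips doubles exactly
  rows <- apply(rec$signals, 2, function(col) {
    paste(vapply(col, function(v) format(v, digits = 17, scientific = TRUE),
                 ""), collapse = ",")
  })
  writeLines(c(paste(paste0("CH", 1:10), collapse = ","), rows), con,
             useBytes = TRUE)
  invisible(path)
}
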