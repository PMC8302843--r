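# Minimal EDF (European Data Format) interchange for 10-channel recordings.
# One data record spanning the whole recording; samples stored as 16-bit
# integers scaled to the per-channel physical range, so amplitude round-trip
# is exact only to quantization (~range/65535). Label metadata travels in the
# 80-char "local recording identification" header field as key=value tokens.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf_recording <- function(rec, path) {
  sig <- rec$signals
  n_ch <- nrow(sig)
  n_samp <- ncol(sig)
  dur <- n_samp / rec$fs
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_feree(sprintf("cannot open %s for writing", path), "feree_io_error")
  })
  on.exit(close(con))

  rid <- sprintf("expr=%s int=%s subj=%s batch=%s",
                 rec$label$expression, intensity_letter(rec$label$intensity),
                 rec$subject_id, rec$batch_id)
  header_bytes <- 256L + 256L * n_ch
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad(rid, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(header_bytes, 8), edf_pad("", 44),
    edf_pad(1, 8), edf_num(dur, 8), edf_pad(n_ch, 4)
  ), con, eos = NULL)

  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  fields <- function(values, width) {
    paste(vapply(values, edf_pad, "", width = width), collapse = "")
  }
  writeChar(paste0(
    fields(paste0("CH", seq_len(n_ch), " ", rec$channel_map), 16),
    fields(rep("", n_ch), 80),
    fields(rep("uV", n_ch), 8),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    fields(rep(dmin, n_ch), 8),
    fields(rep(dmax, n_ch), 8),
    fields(rep("", n_ch), 80),
    fields(rep(n_samp, n_ch), 8),
    fields(rep("", n_ch), 32)
  ), con, eos = NULL)

  for (ch in seq_len(n_ch)) {
    d <- round((sig[ch, ] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                 (dmax - dmin) + dmin)
    writeBin(as.integer(d), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_recording <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80)                                  # patient id
  rid <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch != 10L) {
    stop_feree(sprintf("EDF must declare 10 signals, found %s", n_ch),
               "feree_channel_error")
  }
  rdv <- function(width) vapply(seq_len(n_ch), function(i) trimws(rd(width)), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nspr <- as.integer(rdv(8))
  rdv(32)

  meta <- list()
  for (tok in strsplit(rid, " +")[[1]]) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  need <- c("expr", "int", "subj", "batch")
  if (!all(need %in% names(meta))) {
    stop_feree("EDF recording-id field lacks label metadata",
               "feree_format_error")
  }

  sig <- matrix(0, n_ch, nspr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      d <- readBin(con, "integer", n = nspr[ch], size = 2L, signed = TRUE,
                   endian = "little")
      phys <- (d - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch]) +
        pmin[ch]
      sig[ch, ((r - 1) * nspr[ch] + 1):(r * nspr[ch])] <- phys
    }
  }
  fs <- nspr[1] / dur
  au <- sub("^CH[0-9]+ ", "", labels)
  recording(sig, fs = fs, expression = meta$expr, intensity = meta$int,
            subject_id = meta$subj, batch_id = meta$batch,
            channel_map = au)
}
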