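#' Read a European Data Format (EDF) recording
#'
#' Minimal EDF reader for continuous signals.  Samples are returned in
#' physical units (uV) using the per-signal scaling declared in the header;
#' the sampling rate is taken from the header.  All requested channels must
#' share one sampling rate.
#'
#' @param path path to an EDF file.
#' @param channels character vector of channel labels to load (default: all
#'   channels, in file order).
#' @param channel_map optional named character vector renaming channels,
#'   \code{c("EDF label" = "new label")}, applied after selection.
#' @param state brain-state label to attach.
#' @return a \code{\link{signal_recording}}.
#' @seealso \code{\link{write_edf}}
#' @export
read_edf <- function(path, channels = NULL, channel_map = NULL,
                     state = c("GA", "awake")) {
  state <- match.arg(state)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  if (version != "0") stop(sprintf("not an EDF file (version field '%s'): %s", version, path))
  hdr_txt(80); hdr_txt(80); hdr_txt(8); hdr_txt(8)   # ids, date, time
  hdr_txt(8)                                          # header bytes
  hdr_txt(44)
  n_rec <- as.integer(hdr_txt(8))
  rec_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), "")
  labels <- field(16)
  field(80); units <- field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))                         # samples per record
  field(32)

  if (is.null(channels)) channels <- labels
  missing_ch <- setdiff(channels, labels)
  if (length(missing_ch))
    stop(sprintf("channel(s) not in EDF file: %s", paste(missing_ch, collapse = ", ")))
  sel <- match(channels, labels)
  rates <- spr[sel] / rec_dur
  if (length(unique(rates)) != 1L)
    stop(sprintf("sampling-rate mismatch across requested channels: %s Hz",
                 paste(unique(rates), collapse = " vs ")))
  fs <- rates[1L]

  per_rec <- sum(spr)
  raw_all <- readBin(con, "integer", n = n_rec * per_rec, size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_rec * per_rec)
    stop(sprintf("truncated EDF data section in %s", path))
  offsets <- c(0L, cumsum(spr))
  out <- matrix(0, nrow = n_rec * spr[sel[1L]], ncol = length(sel))
  for (j in seq_along(sel)) {
    s <- sel[j]
    idx <- as.vector(outer(seq_len(spr[s]) + offsets[s],
                           (seq_len(n_rec) - 1L) * per_rec, "+"))
    dig <- raw_all[idx]
    out[, j] <- pmin[s] + (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
  }
  nm <- channels
  if (!is.null(channel_map)) {
    hit <- nm %in% names(channel_map)
    nm[hit] <- unname(channel_map[nm[hit]])
  }
  signal_recording(out, fs = fs, channel_names = nm, state = state)
}

#' Write a recording to EDF
#'
#' Samples are quantized to 16-bit integers over each channel's observed
#' physical range, the resolution declared by the format; a write/read round
#' trip therefore reproduces samples to within one quantization step
#' (range / 65535).
#'
#' @param rec a \code{\link{signal_recording}}.  The number of samples must
#'   be a whole multiple of \code{fs} (1-s data records) or the recording is
#'   written as a single data record.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "signal_recording"))
  n <- nrow(rec$samples); ns <- ncol(rec$samples); fs <- rec$fs
  if (fs == round(fs) && n %% fs == 0) {
    rec_dur <- 1; n_rec <- n %/% fs; spr <- as.integer(fs)
  } else {
    rec_dur <- n / fs; n_rec <- 1L; spr <- n
  }
  pmin <- apply(rec$samples, 2L, min)
  pmax <- apply(rec$samples, 2L, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1      # avoid zero scale for constant channels
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) {
    s <- substr(sprintf(paste0("%-", w, "s"), x), 1L, w)
    writeChar(s, con, nchars = w, eos = NULL)
  }
  put("0", 8)
  put("synthetic subject", 80)
  put("ieskit export", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(as.character(256L + 256L * ns), 8)
  put("", 44)
  put(as.character(n_rec), 8)
  put(format(rec_dur, digits = 7), 8)
  put(as.character(ns), 4)
  for (lab in rec$channel_names) put(lab, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (v in pmin) put(format(v, digits = 7), 8)
  for (v in pmax) put(format(v, digits = 7), 8)
  for (i in seq_len(ns)) put(as.character(dmin), 8)
  for (i in seq_len(ns)) put(as.character(dmax), 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(as.character(spr), 8)
  for (i in seq_len(ns)) put("", 32)

  # header fields round physical min/max to their 8-char form; use the same
  # values for scaling so the file is self-consistent
  pmin_w <- as.numeric(format(pmin, digits = 7))
  pmax_w <- as.numeric(format(pmax, digits = 7))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      dig <- round((rec$samples[rows, j] - pmin_w[j]) /
                     (pmax_w[j] - pmin_w[j]) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
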