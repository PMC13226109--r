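# Minimal EDF/EDF+ I/O, sufficient for continuous multichannel EEG.
# EDF stores 16-bit integers per sample with a per-signal linear mapping
# between digital and physical (microvolt) ranges; amplitudes therefore
# round-trip only to the quantization step ((phys_max-phys_min)/65534).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, scientific = FALSE, digits = 8), width)

#' Write a recording to an EDF file
#'
#' Data records are one second long, so the sampling rate must be a whole
#' number of samples per second; a trailing partial second is zero-padded.
#' Each channel's physical range is taken symmetric around zero from its
#' observed extreme (at least 1 uV), mapped onto the full 16-bit range.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$signals)
  n <- ncol(rec$signals)
  n_rec <- ceiling(n / fs)
  x <- rec$signals
  if (n < n_rec * fs) x <- cbind(x, matrix(0, ns, n_rec * fs - n))

  pmax_ <- pmax(apply(abs(x), 1, max), 1)
  dig_min <- -32767L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))                      # version
  wr(.edf_pad(rec$subject_id, 80))          # patient id
  wr(.edf_pad("synthetic EEG", 80))         # recording id
  wr(.edf_pad("01.01.00", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(256L + 256L * ns, 8))         # header bytes
  wr(.edf_pad("", 44))
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1, 8))                        # record duration, s
  wr(.edf_num(ns, 4))
  for (lab in rec$channel_names) wr(.edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(.edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(.edf_num(-pmax_[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(pmax_[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(dig_min, 8))
  for (i in seq_len(ns)) wr(.edf_num(dig_max, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_num(fs, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  scale <- (dig_max - dig_min) / (2 * pmax_)           # digital units per uV
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(x[i, cols] * scale[i]))
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.edf_read_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < width) stop("EDF format error: truncated header")
    trimws(raw)
  }, character(1))
}

#' Read an EDF file into a recording
#'
#' All signals must share one sampling rate (the container this pipeline
#' uses); a file whose signals disagree is rejected with the offending
#' channel named. Channel labels are preserved verbatim.
#'
#' @param path Path to an existing EDF/EDF+ file.
#' @param subject_id Optional override; defaults to the EDF patient field.
#' @return An `eeg_recording` in microvolts at the file's native rate.
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) < 256) stop("EDF format error: file too short for a header")
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_read_field(con, 8)
  if (version != "0") stop("EDF format error: unsupported version field '", version, "'")
  patient <- .edf_read_field(con, 80)
  .edf_read_field(con, 80); .edf_read_field(con, 8); .edf_read_field(con, 8)
  header_bytes <- as.integer(.edf_read_field(con, 8))
  .edf_read_field(con, 44)
  n_rec <- as.integer(.edf_read_field(con, 8))
  rec_dur <- as.numeric(.edf_read_field(con, 8))
  ns <- as.integer(.edf_read_field(con, 4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("EDF format error: malformed header counts")

  labels <- .edf_read_field(con, 16, ns)
  .edf_read_field(con, 80, ns)
  .edf_read_field(con, 8, ns)
  phys_min <- as.numeric(.edf_read_field(con, 8, ns))
  phys_max <- as.numeric(.edf_read_field(con, 8, ns))
  dig_min <- as.numeric(.edf_read_field(con, 8, ns))
  dig_max <- as.numeric(.edf_read_field(con, 8, ns))
  .edf_read_field(con, 80, ns)
  spr <- as.integer(.edf_read_field(con, 8, ns))   # samples per record
  .edf_read_field(con, 32, ns)
  if (anyNA(spr) || any(spr < 1L)) stop("EDF format error: bad samples-per-record")
  if (length(unique(spr)) > 1L) {
    bad <- labels[spr != spr[1L]]
    stop("EDF format error: signals sampled at differing rates (e.g. channel '",
         bad[1L], "'); montage requires a single rate")
  }
  if (anyNA(phys_min) || anyNA(phys_max) || any(dig_max == dig_min))
    stop("EDF format error: bad scaling fields")

  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- matrix(0, ns, n_rec * spr[1L])
  seek(con, header_bytes)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      if (length(dig) < spr[i]) stop("EDF format error: truncated data record ", r)
      out[i, cols] <- phys_min[i] + (dig - dig_min[i]) * gain[i]
    }
  }
  recording(out, fs, labels,
            subject_id = if (is.null(subject_id)) patient else subject_id)
}
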