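#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels for one
#' night, one label per 30-s epoch, coded 0 = Wake, 1 = NREM, 2 = REM.
#'
#' @param labels Integer vector of stage labels in `{0, 1, 2}`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, subject_id = "anonymous") {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("a hypnogram needs at least one epoch")
  bad <- which(!(labels %in% 0:2) | is.na(labels))
  if (length(bad))
    stop("invalid stage label at epoch ", bad[1L], ": labels must be 0 (Wake), 1 (NREM) or 2 (REM)")
  structure(list(subject_id = subject_id, labels = labels, epoch_length = 30),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 3L)
  cat(sprintf("<hypnogram> subject '%s': %d epochs (%.1f min) | Wake %d, NREM %d, REM %d\n",
              x$subject_id, length(x$labels), length(x$labels) / 2,
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Read a hypnogram from a single-column CSV
#'
#' The on-disk dialect is one integer stage label per row, with an optional
#' `stage` header. Any label outside `{0, 1, 2}` is a validation error that
#' reports the offending row.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier to attach.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, subject_id = "anonymous") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^[A-Za-z]", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) stop("hypnogram file is empty: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals) | vals != round(vals) | !(vals %in% 0:2))
  if (length(bad))
    stop("invalid stage label '", lines[bad[1L]], "' at row ", bad[1L],
         " of ", path, " (expected 0, 1 or 2)")
  hypnogram(vals, subject_id)
}

#' Write a hypnogram to CSV
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @param header Write the optional `stage` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path, header = TRUE) {
  stopifnot(inherits(h, "hypnogram"))
  lines <- as.character(h$labels)
  if (header) lines <- c("stage", lines)
  writeLines(lines, path)
  invisible(path)
}
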