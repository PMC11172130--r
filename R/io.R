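#' Write a recording as a European Data Format (EDF) file
#'
#' Plain EDF: one data record per second, 16 signals in microvolt physical
#' units, 16-bit samples scaled per channel to the full digital range. A
#' trailing partial second is dropped (EDF records are whole seconds).
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) {
    stop("EDF export needs an integer sampling rate.", call. = FALSE)
  }
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop("Recording shorter than one EDF record.", call. = FALSE)
  if (n_rec * fs < ncol(data)) {
    warning("Dropping trailing partial second for EDF export.", call. = FALSE)
  }
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(data)

  pad <- function(x, n) formatC(substr(as.character(x), 1, n),
                                width = n, flag = "-")
  phys_max <- pmax(apply(abs(data), 1, max), 1e-6)
  dig_max <- 32767
  scaled <- round(data / phys_max * dig_max)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad(recording$subject_id, 80),
    pad(paste("grade", recording$grade, "hama",
              ifelse(is.null(recording$hama), "NA", recording$hama)), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad, "", n = width), collapse = ""),
              con, eos = NULL)
  }
  field(rownames(data), 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(format(-phys_max, digits = 6), 8)
  field(format(phys_max, digits = 6), 8)
  field(rep(-dig_max - 1, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(scaled[, idx])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain EDF with equal
#' per-signal rates)
#'
#' @param path EDF file path.
#' @return An `eeg_recording`; grade and HAMA are recovered from the
#'   recording-id field when present, otherwise unknown.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("Mixed per-signal sampling rates are not supported.", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(NA_real_, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block) * scale + (phys_min - dig_min * scale)
  }
  grade <- "unknown"
  hama <- NA_integer_
  m <- regmatches(rec_id, regexec("grade (\\w+) hama (\\w+)", rec_id))[[1]]
  if (length(m) == 3) {
    grade <- m[2]
    hama <- suppressWarnings(as.integer(m[3]))
  }
  structure(list(subject_id = subject_id, fs = fs, data = data,
                 grade = grade, hama = hama),
            class = "eeg_recording")
}

#' Write / read a recording as a plain numeric matrix file
#'
#' Tab-separated text: comment header lines (`#fs=`, `#subject_id=`,
#' `#grade=`, `#hama=`), a channel-name header row, then one row per time
#' sample. The compact container used by tests and for interchange.
#'
#' @param recording An `eeg_recording`.
#' @param path File path.
#' @return `path` invisibly / an `eeg_recording`.
#' @export
write_recording_matrix <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  hdr <- c(paste0("#fs=", recording$fs),
           paste0("#subject_id=", recording$subject_id),
           paste0("#grade=", recording$grade),
           paste0("#hama=", recording$hama %||% NA))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    t(recording$data), path, sep = "\t", row.names = FALSE,
    col.names = TRUE, quote = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_recording_matrix
#' @export
read_recording_matrix <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    line <- hdr[startsWith(hdr, paste0("#", key, "="))]
    sub(paste0("^#", key, "="), "", line)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", check.names = FALSE)
  structure(
    list(subject_id = get_field("subject_id"),
         fs = as.numeric(get_field("fs")),
         data = t(as.matrix(tab)),
         grade = get_field("grade"),
         hama = suppressWarnings(as.integer(get_field("hama")))),
    class = "eeg_recording"
  )
}

#' Write a cohort to disk
#'
#' One EDF file per subject plus a tab-separated `manifest.tsv`
#' (subject_id, grade, hama, fs, duration_s, file).
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tidy(cohort)
  manifest$file <- paste0(manifest$subject_id, ".edf")
  purrr::walk(cohort, function(r) {
    write_edf(r, file.path(dir, paste0(r$subject_id, ".edf")))
  })
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.tsv`.
#' @return An `eeg_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE)
  recs <- purrr::map(seq_len(nrow(manifest)), function(i) {
    r <- read_edf(file.path(dir, manifest$file[i]))
    r$grade <- manifest$grade[i]
    r$hama <- manifest$hama[i]
    r
  })
  structure(recs, class = "eeg_cohort")
}
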