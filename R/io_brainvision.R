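# BrainVision (.vhdr/.vmrk/.eeg) reader and writer. The writer emits
# multiplexed IEEE_FLOAT_32 (lossless round-trip at float precision); the
# reader additionally accepts INT_16 with per-channel resolution scaling.

# Minimal INI parser for the BrainVision header dialect.
parse_ini <- function(lines) {
  out <- list()
  section <- NULL
  for (ln in lines) {
    ln <- sub("\\r$", "", ln)
    if (grepl("^\\s*($|;)", ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(m) == 2L) {
      section <- m[2]
      out[[section]] <- list()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0 && !is.null(section)) {
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision EEG file triplet
#'
#' Parses a BrainVision header (`.vhdr`), reads the binary data file it
#' references, and returns the recording in microvolts. Multiplexed binary
#' data in `IEEE_FLOAT_32` or `INT_16` (scaled by each channel's resolution)
#' are supported. If the referenced marker file exists, its markers are
#' attached as metadata.
#'
#' @param header_path path to the `.vhdr` header file.
#' @return An [eeg_recording()]; markers, if any, are stored in the
#'   `markers` element (a data frame with `label`, `position`, `points`).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  ini <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stop("header lacks a [Common Infos] section")

  fmt <- ci[["DataFormat"]] %||% "BINARY"
  if (toupper(fmt) != "BINARY") {
    stop("unsupported DataFormat keyword: ", fmt)
  }
  orient <- ci[["DataOrientation"]] %||% "MULTIPLEXED"
  if (toupper(orient) != "MULTIPLEXED") {
    stop("unsupported DataOrientation keyword: ", orient)
  }
  binfmt <- toupper(bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  if (!binfmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    stop("unsupported BinaryFormat keyword: ", binfmt)
  }

  n_ch <- as.integer(ci[["NumberOfChannels"]])
  interval_us <- as.numeric(ci[["SamplingInterval"]])
  srate <- 1e6 / interval_us

  datafile <- file.path(dirname(header_path), ci[["DataFile"]])
  if (!file.exists(datafile)) {
    stop("data file referenced by header not found: ", datafile)
  }

  chinfo <- ini[["Channel Infos"]]
  labels <- character(n_ch)
  resolutions <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chinfo[[paste0("Ch", i)]]
    if (is.null(entry)) {
      labels[i] <- paste0("Ch", i)
    } else {
      parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
      labels[i] <- parts[1]
      if (length(parts) >= 3L && nzchar(trimws(parts[3]))) {
        resolutions[i] <- as.numeric(parts[3])
      }
    }
  }

  sz <- file.info(datafile)$size
  bytes <- if (binfmt == "IEEE_FLOAT_32") 4L else 2L
  n_total <- sz %/% (bytes)
  if (n_total %% n_ch != 0L) {
    stop("data file size is not a whole number of multiplexed frames")
  }
  con <- file(datafile, "rb")
  on.exit(close(con))
  raw_vals <- if (binfmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
            endian = "little")
  }
  data <- matrix(raw_vals, nrow = n_ch)   # multiplexed: channels vary fastest
  if (binfmt == "INT_16") data <- data * resolutions

  rec <- eeg_recording(data, srate, labels)

  mrkfile <- ci[["MarkerFile"]]
  if (!is.null(mrkfile)) {
    mrkpath <- file.path(dirname(header_path), mrkfile)
    if (file.exists(mrkpath)) rec$markers <- read_vmrk(mrkpath)
  }
  rec
}

read_vmrk <- function(path) {
  ini <- parse_ini(readLines(path, warn = FALSE))
  mi <- ini[["Marker Infos"]]
  if (is.null(mi) || !length(mi)) {
    return(data.frame(label = character(0), position = integer(0),
                      points = integer(0)))
  }
  rows <- lapply(mi, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    data.frame(label = parts[2],
               position = as.integer(parts[3]),
               points = as.integer(parts[4]))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a BrainVision EEG file triplet
#'
#' Emits the `.vhdr` header (INI dialect with Common Infos, Binary Infos and
#' Channel Infos sections), the multiplexed `IEEE_FLOAT_32` binary `.eeg`
#' file, and a `.vmrk` marker file. The triplet round-trips through
#' [read_brainvision()] exactly at float32 precision.
#'
#' @param rec an [eeg_recording()].
#' @param basepath output path without extension.
#' @param markers optional data frame with `label` and `position` (sample
#'   index, 1-based) columns.
#' @return Invisibly, the header path.
#' @export
write_brainvision <- function(rec, basepath, markers = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) == 0L) stop("cannot write a recording with 0 channels")
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eegf <- paste0(basepath, ".eeg")

  n_ch <- nrow(rec$data)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate,
                                       scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    paste0("Ch", seq_len(n_ch), "=", rec$channel_labels, ",,1,µV")
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (!is.null(markers) && nrow(markers)) {
    mk <- c(mk, paste0("Mk", seq_len(nrow(markers)) + 1L, "=Stimulus,",
                       markers$label, ",", markers$position, ",1,0"))
  }
  writeLines(mk, vmrk)

  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}
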