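# ISHNE Holter (.ecg) reader/writer: magic "ISHNE1.0", a 16-bit CRC-CCITT,
# a 512-byte fixed header plus a variable-length block, then 16-bit
# little-endian multiplexed samples. Amplitude resolution is stored per lead
# in nV per least-significant bit. The CRC is computed over the fixed header
# and variable block; on read a mismatch is only warned about (stale CRCs
# are common in circulating files).

ISHNE_MAGIC <- "ISHNE1.0"
ISHNE_FIXED_HEADER <- 512L
ISHNE_DATA_OFFSET0 <- 8L + 2L + 512L    # magic + CRC + fixed header

crc_env <- new.env(parent = emptyenv())

crc16_ccitt <- function(bytes) {
  if (is.null(crc_env$table)) {
    tab <- integer(256)
    for (i in 0:255) {
      crc <- bitwShiftL(i, 8)
      for (k in 1:8) {
        crc <- if (bitwAnd(crc, 0x8000L) != 0L) {
          bitwXor(bitwShiftL(crc, 1), 0x1021L)
        } else {
          bitwShiftL(crc, 1)
        }
        crc <- bitwAnd(crc, 0xFFFFL)
      }
      tab[i + 1L] <- crc
    }
    crc_env$table <- tab
  }
  tab <- crc_env$table
  crc <- 0xFFFFL
  for (b in as.integer(bytes)) {
    idx <- bitwXor(bitwShiftR(crc, 8), b)
    crc <- bitwAnd(bitwXor(bitwShiftL(crc, 8), tab[idx + 1L]), 0xFFFFL)
  }
  crc
}

pad_raw <- function(s, n) {
  r <- charToRaw(as.character(s))
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

int_raw <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

#' Write a recording as an ISHNE Holter file
#'
#' Serializes a recording to the ISHNE `.ecg` binary layout (standard
#' `"ISHNE1.0"` magic, CRC-CCITT, 512-byte fixed header, 16-bit
#' little-endian multiplexed samples). Samples are quantized at
#' `resolution_nv` nanovolts per unit.
#'
#' @param recording A [ecg_recording()].
#' @param path Output file path.
#' @param subject_id Subject identifier stored in the header (max 20 chars).
#' @param resolution_nv Amplitude resolution in nV per unit (default 1000,
#'   i.e. 1 uV).
#' @return `path`, invisibly.
#' @export
write_ishne <- function(recording, path, subject_id = "",
                        resolution_nv = 1000) {
  recording <- as_qti_ecg(recording)
  sig <- recording$signal
  nleads <- ncol(sig)
  nsamp <- nrow(sig)
  counts <- round(sig * 1e6 / resolution_nv)
  counts[counts > 32767] <- 32767
  counts[counts < -32768] <- -32768
  tm <- as.integer(strsplit(recording$start_time, ":")[[1]])
  if (length(tm) != 3L || anyNA(tm)) tm <- c(0L, 0L, 0L)

  lead12 <- function(values) {
    out <- integer(12)
    out[seq_len(min(length(values), 12L))] <- values[seq_len(min(length(values), 12L))]
    out
  }
  header <- c(
    int_raw(0L, 4),                       # variable block size
    int_raw(nsamp, 4),                    # samples per lead
    int_raw(ISHNE_DATA_OFFSET0, 4),       # offset of variable block
    int_raw(ISHNE_DATA_OFFSET0, 4),       # offset of ECG block (no var block)
    int_raw(1L, 2),                       # file version
    pad_raw("", 40), pad_raw("", 40),     # first/last name
    pad_raw(subject_id, 20),
    int_raw(0L, 2), int_raw(0L, 2),       # sex, race (unspecified)
    int_raw(c(0L, 0L, 0L), 2),            # birth date
    int_raw(c(0L, 0L, 0L), 2),            # record date
    int_raw(c(0L, 0L, 0L), 2),            # file date
    int_raw(tm, 2),                       # start time h m s
    int_raw(nleads, 2),
    int_raw(lead12(seq_len(nleads)), 2),  # lead spec
    int_raw(lead12(rep(0L, nleads)), 2),  # lead quality
    int_raw(lead12(rep(as.integer(resolution_nv), nleads)), 2),
    int_raw(0L, 2),                       # pacemaker
    pad_raw("synthetic Holter generator", 40),
    int_raw(as.integer(round(recording$fs_hz)), 2),
    pad_raw("", 80), pad_raw("", 80),     # proprietary, copyright
    raw(88L)                              # reserved padding to 512 bytes
  )
  stopifnot(length(header) == ISHNE_FIXED_HEADER)
  crc <- crc16_ccitt(header)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(ISHNE_MAGIC), con)
  writeBin(int_raw(crc, 2), con)
  writeBin(header, con)
  writeBin(as.integer(t(counts)), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an ISHNE Holter file
#'
#' Parses the header (sampling rate, lead count, sample count, start time,
#' per-lead amplitude resolution), verifies the magic and the declared data
#' size against the file size, checks the CRC (warning only on mismatch),
#' and de-multiplexes the 16-bit samples into a mV matrix.
#'
#' @param path Path to an ISHNE `.ecg` file.
#' @return A [ecg_recording()].
#' @export
read_ishne <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fsize <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, ISHNE_MAGIC)) {
    stop("not an ISHNE file: bad magic at offset 0 (got '", magic, "')")
  }
  crc_stored <- readBin(con, "integer", 1L, size = 2, endian = "little",
                        signed = FALSE)
  header <- readBin(con, "raw", ISHNE_FIXED_HEADER)
  if (length(header) < ISHNE_FIXED_HEADER) {
    stop("truncated ISHNE file: header ends at offset ", 10 + length(header))
  }
  if (crc16_ccitt(header) != crc_stored) {
    warning("ISHNE header CRC mismatch (file may be stale); continuing")
  }
  rd_int <- function(off, size, n = 1L, signed = TRUE) {
    readBin(header[(off + 1L):(off + n * size)], "integer", n, size = size,
            endian = "little", signed = signed)
  }
  var_size <- rd_int(0L, 4L)
  nsamp <- rd_int(4L, 4L)
  start_time <- rd_int(140L, 2L, 3L)
  nleads <- rd_int(146L, 2L)
  if (nleads < 1L || nleads > 12L) stop("implausible lead count: ", nleads)
  res_nv <- rd_int(196L, 2L, 12L)[seq_len(nleads)]
  fs_hz <- rd_int(262L, 2L)
  expected <- ISHNE_DATA_OFFSET0 + var_size + 2 * as.double(nsamp) * nleads
  if (fsize < expected) {
    stop(sprintf(
      "truncated ISHNE file: expected %d data bytes from offset %d, file ends at %d",
      as.integer(2 * nsamp * nleads), as.integer(ISHNE_DATA_OFFSET0 + var_size),
      as.integer(fsize)))
  }
  if (var_size > 0) readBin(con, "raw", var_size)
  raw_counts <- readBin(con, "integer", nsamp * nleads, size = 2,
                        endian = "little", signed = TRUE)
  sig <- matrix(raw_counts, ncol = nleads, byrow = TRUE)
  sig <- sweep(sig, 2L, res_nv / 1e6, "*")
  ecg_recording(sig, fs_hz,
                start_time = sprintf("%02d:%02d:%02d", start_time[1],
                                     start_time[2], start_time[3]))
}
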