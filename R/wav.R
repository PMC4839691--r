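#' Write a mono waveform to a RIFF WAV file
#'
#' Supports 16-bit integer PCM and 32-bit IEEE float encodings. Samples
#' outside \[-1, 1\] are clipped for 16-bit output.
#'
#' @param x Numeric waveform (mono).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 48000, bit_depth = 16) {
  if (!bit_depth %in% c(16, 32)) stop_input("bit_depth must be 16 or 32")
  fmt_code <- if (bit_depth == 16) 1L else 3L
  block_align <- bit_depth %/% 8L
  data_size <- length(x) * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    s <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(s, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF WAV file
#'
#' Reads 16-bit integer PCM (rescaled to \[-1, 1\] by 1/32767) or 32-bit
#' IEEE float mono files.
#'
#' @param path Input file path.
#' @return A list with `samples` (numeric waveform), `sample_rate` (Hz) and
#'   `bit_depth`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_input("cannot read WAV file '%s'", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop_input("'%s' is not a valid WAV file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  riff_size <- readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "RIFF") || !identical(wave, "WAVE")) {
    stop_input("'%s' is not a RIFF/WAVE file", path)
  }
  fmt <- NULL
  samples <- NULL
  while (TRUE) {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    chunk_size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", chunk_size + chunk_size %% 2)
      fmt <- list(
        code = readBin(raw[1:2], "integer", size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", size = 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", size = 4,
                              endian = "little"),
        bits = readBin(raw[15:16], "integer", size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_input("'%s': data chunk before fmt chunk", path)
      if (fmt$channels != 1) {
        stop_input("'%s': only mono WAV is supported (%d channels)",
                   path, fmt$channels)
      }
      if (fmt$code == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", n = chunk_size / 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt$code == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", n = chunk_size / 4, size = 4,
                           endian = "little")
      } else {
        stop_input("'%s': unsupported WAV encoding (format %d, %d bits)",
                   path, fmt$code, fmt$bits)
      }
      break
    } else {
      seek(con, chunk_size + chunk_size %% 2, origin = "current")
    }
  }
  if (is.null(samples)) stop_input("'%s': no data chunk found", path)
  list(samples = samples, sample_rate = fmt$sample_rate,
       bit_depth = fmt$bits)
}
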