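# Minimal RIFF/WAVE reader and writer for mono/stereo PCM16 and IEEE
# float32, enough to round-trip stimulus audio.

#' Write a waveform to a WAV file
#'
#' @param x numeric vector (mono) or matrix with one column per channel;
#'   values in `[-1, 1]` (PCM16 clips outside).
#' @param path output file.
#' @param fs_hz sampling rate written to the header.
#' @param format `"pcm16"` or `"float32"`.
#' @export
wav_write <- function(x, path, fs_hz, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x); n <- nrow(x)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits / 8L
  block <- n_ch * bytes_per
  data_size <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  inter <- as.vector(t(x))  # interleave channels
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(-1, pmin(1, inter)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(inter), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written in PCM16 or float32
#'
#' @param path input file.
#' @return list with `data` (matrix, one column per channel, floats in
#'   `[-1, 1]` for PCM) and `fs_hz`.
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        n_ch = readBin(con, integer(), size = 2, endian = "little"),
        fs_hz = readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, raw(), n = sz - 8))
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = sz)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk")
  if (fmt$audio_format == 1L) {
    vals <- readBin(data_raw, integer(), n = length(data_raw) / 2,
                    size = 2, signed = TRUE, endian = "little") / 32767
  } else if (fmt$audio_format == 3L) {
    vals <- readBin(data_raw, numeric(), n = length(data_raw) / 4,
                    size = 4, endian = "little")
  } else stop("unsupported WAV encoding (PCM16 and float32 only)")
  list(data = matrix(vals, ncol = fmt$n_ch, byrow = TRUE), fs_hz = fmt$fs_hz)
}
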