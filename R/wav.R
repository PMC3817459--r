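# Minimal RIFF/WAVE codec for mono PCM: 16-bit integer and 32-bit float
# subtypes, which cover every file this package reads or writes.

#' Write a waveform to a WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param subtype `"float32"` (IEEE float, lossless) or `"pcm16"`.
#' @return `path`, invisibly. Samples outside [-1, 1] raise an error
#'   (clipping is reported, never silently applied).
#' @export
write_wav <- function(w, path, subtype = c("float32", "pcm16")) {
  stopifnot(inherits(w, "waveform"))
  subtype <- match.arg(subtype)
  x <- w$samples
  if (length(x) && max(abs(x)) > 1)
    stop("samples exceed full scale; refusing to clip on write",
         call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  if (subtype == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    data_bytes <- 2L * length(x)
  } else {
    fmt_code <- 3L; bits <- 32L
    data_bytes <- 4L * length(x)
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(w$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate_hz * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (subtype == "pcm16") {
    q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path Input path (mono PCM16 or float32 RIFF/WAVE).
#' @return A [waveform()]. Truncated or malformed files raise a structured
#'   `fricshift_wav_error` condition rather than crashing.
#' @export
read_wav <- function(path) {
  fail <- function(msg) stop(structure(
    class = c("fricshift_wav_error", "error", "condition"),
    list(message = paste0(msg, " [", path, "]"), call = NULL)))
  if (!file.exists(path)) fail("no such file")
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) fail("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    fail("not a WAVE file")
  fmt_code <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_
  channels <- NA_integer_
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) fail("truncated file: no data chunk")
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (length(len) == 0) fail("truncated chunk header")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = len - 8))
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) fail("data chunk precedes fmt chunk")
      if (!channels %in% 1L) fail("only mono files are supported")
      bits <- if (fmt_code == 1L) 16L else if (fmt_code == 3L) 32L
              else fail(paste("unsupported format code", fmt_code))
      n <- len %/% (bits %/% 8L)
      avail <- size - seek(con)
      if (avail < len) fail("truncated file: data chunk shorter than declared")
      x <- if (fmt_code == 1L) {
        readBin(con, integer(), n = n, size = 2, endian = "little",
                signed = TRUE) / 32768
      } else {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      }
      if (length(x) < n) fail("truncated file: short read")
      return(waveform(pmax(pmin(x, 1), -1), rate))
    } else {
      invisible(readBin(con, raw(), n = len))
    }
  }
}
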