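## Minimal RIFF/WAVE PCM I/O. Only uncompressed integer PCM (16- or
## 24-bit) is supported, which covers the stimulus recordings the
## envelope pipeline consumes.

#' Read a PCM WAV file
#'
#' @param path Path to a RIFF/WAVE file with 16- or 24-bit integer PCM.
#' @return List: `samples` (samples x channels matrix scaled to
#'   `[-1, 1]`), `fs` (Hz), `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- function(n) rawToChar(readBin(con, "raw", n))
  u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  u16 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                            endian = "little")
  if (tag(4) != "RIFF") stop2("bad_input", "not a RIFF file")
  u32()
  if (tag(4) != "WAVE") stop2("bad_input", "not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- tag(4)
    if (!nchar(id)) break
    sz <- u32()
    if (id == "fmt ") {
      fmt <- list(format = u16(), n_channels = u16(), fs = u32(),
                  byte_rate = u32(), block_align = u16(), bits = u16())
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop2("bad_input", "missing fmt/data chunk")
  if (fmt$format != 1) stop2("bad_input", "only integer PCM (format 1) supported")
  if (!fmt$bits %in% c(16, 24)) stop2("bad_input", "only 16/24-bit PCM supported")
  if (fmt$bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, size = 2, signed = TRUE,
                 endian = "little") / 2^15
  } else {
    b <- as.integer(dat)
    n <- length(b) %/% 3
    idx <- 3 * (seq_len(n) - 1)
    v <- b[idx + 1] + 256 * b[idx + 2] + 65536 * b[idx + 3]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  }
  list(samples = matrix(x, ncol = fmt$n_channels, byrow = TRUE),
       fs = fmt$fs, bits = fmt$bits)
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples Numeric vector or samples x channels matrix in
#'   `[-1, 1]`.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  x <- as.integer(round(pmax(pmin(t(samples), 1), -1) * (2^15 - 1)))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(ncol(samples)); w32(fs)
  w32(fs * ncol(samples) * 2L); w16(ncol(samples) * 2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(n_bytes)
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
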