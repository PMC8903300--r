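# Minimal mono 16-bit PCM WAV input/output. Only the canonical RIFF layout
# produced by this package (and by most field recorders) is supported.

#' Write a recording to a 16-bit PCM WAV file
#'
#' Samples are expected in \[-1, 1\]; values outside are clipped (hard
#' saturation, as in a real recording chain driven past full scale).
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param rate sampling rate in samples/second.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (amplitudes in \[-1, 1\]) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV supported")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM WAV supported")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2,
                     endian = "little", signed = TRUE)
      if (is.null(rate)) stop("data chunk precedes fmt chunk in ", path)
      return(list(samples = pcm / 32767, rate = rate))
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
  }
}
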