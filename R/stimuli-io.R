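# Minimal RIFF/WAVE I/O (16-bit integer or 32-bit float PCM, mono) and
# JSON (de)serialization of stimulus specs.

#' Write a waveform to a WAV file
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16L) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  sr <- as.integer(round(w$sample_rate))
  fmt <- if (bits == 16L) 1L else 3L          # PCM / IEEE float
  block_align <- as.integer(bits / 8)
  data_bytes <- n * block_align
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    s <- pmax(-1, pmin(1, w$samples))
    writeBin(as.integer(round(s * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; sr <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1L) stop("only mono WAV supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))  # byte rate
      invisible(readBin(con, integer(), size = 2, endian = "little"))  # block align
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      n <- sz / (bits / 8)
      samples <- if (fmt == 1L && bits == 16L) {
        readBin(con, integer(), n = n, size = 2, endian = "little") / 32767
      } else if (fmt == 3L && bits == 32L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stop(sprintf("unsupported WAV format %d/%d-bit", fmt, bits))
      return(waveform(pmax(-1, pmin(1, samples)), sr))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}

#' Write / read a stimulus spec as JSON
#'
#' @param spec A `stimulus_spec`.
#' @param path JSON file path.
#' @return `write_stimulus_spec` returns `path` invisibly;
#'   `read_stimulus_spec` returns a `stimulus_spec`.
#' @export
write_stimulus_spec <- function(spec, path) {
  stopifnot(inherits(spec, "stimulus_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_stimulus_spec
#' @export
read_stimulus_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stimulus_spec, x[setdiff(names(x), character(0))])
}
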