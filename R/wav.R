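# Minimal RIFF/WAVE reader and writer (mono PCM16 / IEEE float32). Hand-rolled
# because no audio I/O package is available in the target library; covers
# exactly the subset of the format the package emits.

#' Write a waveform to a WAV file
#'
#' Writes mono RIFF/WAVE audio together with an optional JSON sidecar holding
#' the stimulus specification and the segment markers.
#'
#' @param wave A [waveform()].
#' @param path Output path (`.wav`).
#' @param bits Either 16 (integer PCM, samples clipped to \[-1, 1\] full scale)
#'   or 32 (IEEE float, lossless).
#' @param sidecar If `TRUE`, write `<path>.json` with sample rate, markers and
#'   `spec`.
#' @param spec Optional list (e.g. a [stimulus_spec()]) stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 32L, sidecar = TRUE, spec = NULL) {
  stopifnot(inherits(wave, "waveform"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stop("`bits` must be 16 or 32", call. = FALSE)
  x <- wave$samples
  fs <- as.integer(round(wave$sample_rate))
  n <- length(x)
  fmt_tag <- if (bits == 32L) 3L else 1L   # IEEE float / PCM
  bytes_ps <- bits %/% 8L
  data_size <- n * bytes_ps
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_ps), con, size = 4, endian = "little")
  writeBin(bytes_ps, con, size = 2, endian = "little")      # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  if (sidecar) {
    meta <- list(
      sample_rate = fs,
      n_samples = n,
      bits = bits,
      markers = as.list(wave$markers),
      spec = spec
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path Path to a mono 16-bit PCM or 32-bit float WAV file. Markers are
#'   restored from the JSON sidecar when present.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt_tag <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (nch != 1L) stop("only mono WAV supported", call. = FALSE)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (bits == 16L) {
        samples <- readBin(con, "integer", size %/% 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (bits == 32L && fmt_tag == 3L) {
        samples <- readBin(con, "numeric", size %/% 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding", call. = FALSE)
      }
    } else {
      readBin(con, "raw", size)
    }
    if (!is.null(samples) && !is.null(fs)) break
  }
  markers <- integer(0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (length(meta$markers)) {
      markers <- vapply(meta$markers, function(m) as.integer(m), integer(1))
    }
  }
  waveform(samples, fs, markers)
}
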