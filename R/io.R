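# Plain-text interchange: phoneme and electrode tables as TSV, matrices as
# TSV with a JSON-like sidecar, and minimal PCM16 WAV audio I/O.

#' Read / write a phoneme event table (TSV)
#'
#' Columns: phoneme, onset_s, offset_s, speaker, manner, place, voicing,
#' height, backness (forced-aligner style output).
#' @param path file path
#' @return data.frame
#' @export
read_phoneme_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phoneme", "onset_s", "offset_s", "speaker")
  if (!all(need %in% names(tab)))
    stop("phoneme table must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(tab$onset_s)) stop("phoneme onsets must be non-decreasing")
  tab
}

#' @rdname read_phoneme_table
#' @param table data.frame to write
#' @export
write_phoneme_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an electrode geometry table (TSV)
#'
#' Columns: site_id, subject, hemisphere, ml_mm, pa_mm.
#' @param path file path
#' @return data.frame
#' @export
read_electrode_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "hemisphere", "ml_mm", "pa_mm")
  if (!all(need %in% names(tab)))
    stop("electrode table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_electrode_table
#' @param table data.frame to write
#' @export
write_electrode_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a spectrogram as TSV (frames x bands) with header metadata
#'
#' The first two lines are comments carrying the frame rate and band
#' centers so the file round-trips losslessly as text.
#' @param x a [spectrogram]
#' @param path file path
#' @export
write_spectrogram_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate\t%.10g", x$frame_rate), con)
  writeLines(paste0("# band_centers\t",
                    paste(sprintf("%.10g", x$band_centers), collapse = "\t")), con)
  utils::write.table(x$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrogram_tsv
#' @return for the reader, a [spectrogram]
#' @export
read_spectrogram_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  fr <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  bc <- as.numeric(strsplit(hdr[2], "\t")[[1]][-1])
  vals <- as.matrix(utils::read.table(path, sep = "\t", skip = 2))
  dimnames(vals) <- NULL
  spectrogram(vals, fr, bc)
}

#' Minimal PCM16 WAV reader
#'
#' Reads uncompressed 16-bit PCM WAV files (mono or multichannel),
#' returning samples scaled to \[-1, 1\].
#' @param path file path
#' @return list with `samples` (channels x n matrix) and `sr`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  sr <- NULL; n_ch <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only uncompressed PCM supported")
      n_ch <- fmt[2]
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM supported")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      data <- readBin(con, "integer", sz / 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(data)) stop("no data chunk found")
  list(samples = matrix(data / 32768, nrow = n_ch), sr = sr)
}

#' Minimal PCM16 WAV writer
#' @param samples numeric vector or channels x n matrix in \[-1, 1\]
#' @param sr sampling rate in Hz
#' @param path file path
#' @export
write_wav <- function(samples, sr, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  n_ch <- nrow(samples)
  pcm <- as.integer(pmax(pmin(round(as.vector(samples) * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_sz, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr) * n_ch * 2L, con, size = 4, endian = "little")
  writeBin(n_ch * 2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
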