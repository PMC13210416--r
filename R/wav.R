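# Minimal RIFF/WAVE I/O (32-bit float, the format used for calibrated
# synthetic scenes) and the JSON label sidecar. Float samples round-trip
# losslessly at single precision.

#' Write a WAV file (IEEE float32)
#'
#' @param x numeric vector (mono) or a matrix / list of equal-length numeric
#'   vectors (one channel per column / element).
#' @param fs sample rate in Hz.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, fs, path) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  nch <- ncol(x)
  nsamp <- nrow(x)
  bytes_per_sample <- 4L
  block_align <- nch * bytes_per_sample
  data_size <- nsamp * block_align
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(4 + (8 + 16) + (8 + 4) + (8 + data_size))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(3)                      # IEEE float
  w16(nch)
  w32(round(fs))
  w32(round(fs) * block_align)
  w16(block_align)
  w16(8L * bytes_per_sample)
  writeChar("fact", con, eos = NULL)
  w32(4)
  w32(nsamp)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file
#'
#' Supports IEEE float32 and 16-bit integer PCM, mono or multi-channel.
#'
#' @param path input file path.
#' @return List with \code{samples} (matrix, one column per channel) and
#'   \code{fs}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- r32()
    if (id == "fmt ") {
      fmt <- list(code = r16(), nch = r16(), fs = r32())
      r32(); r16()
      fmt$bits <- r16()
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      nval <- size %/% (fmt$bits %/% 8L)
      if (fmt$code == 3L && fmt$bits == 32L) {
        v <- readBin(con, "numeric", n = nval, size = 4, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        v <- readBin(con, "integer", n = nval, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else {
        stop("unsupported WAV format (code ", fmt$code, ", ", fmt$bits, " bit)")
      }
      samples <- matrix(v, ncol = fmt$nch, byrow = TRUE)
      return(list(samples = samples, fs = fmt$fs))
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
}

#' Write the JSON label sidecar of a rendered scene
#'
#' Schema: \code{events} (onset/duration in seconds, angle in degrees, band
#' in Hz, realised gain \code{a1}), \code{noise_segments} as 0-based
#' half-open \code{[start, end)} sample intervals, \code{fs},
#' \code{sinr_db}, \code{inr_db}, \code{seed}.
#'
#' @param rec a \code{\link{render_scene}} recording.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(rec, path) {
  stopifnot(inherits(rec, "stereo_recording"))
  ev <- rec$labels$events
  seg <- rec$labels$noise_segments
  obj <- list(
    events = lapply(seq_len(nrow(ev)), function(i) list(
      onset = ev$onset[i], duration = ev$duration[i], angle = ev$angle[i],
      band = c(ev$band_lo[i], ev$band_hi[i]), a1 = ev$a1[i])),
    noise_segments = lapply(seq_len(nrow(seg)), function(i)
      c(seg[i, 1] - 1L, seg[i, 2])),          # 1-based inclusive -> 0-based half-open
    fs = rec$fs,
    sinr_db = rec$achieved_sinr_db,
    inr_db = rec$achieved_inr_db,
    seed = rec$spec$noise_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON label sidecar
#'
#' @param path label file path.
#' @return List with \code{events} (data.frame), \code{noise_segments}
#'   (1-based inclusive matrix), \code{fs}, \code{sinr_db}, \code{inr_db},
#'   \code{seed}.
#' @export
read_labels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- obj$noise_segments
  if (is.list(seg)) seg <- do.call(rbind, seg)
  if (is.null(seg) || length(seg) == 0L) {
    seg <- matrix(integer(0), ncol = 2)
  } else {
    seg <- matrix(as.integer(seg), ncol = 2)
    seg[, 1] <- seg[, 1] + 1L                 # back to 1-based inclusive
  }
  colnames(seg) <- c("start", "end")
  ev <- obj$events
  events <- if (is.null(ev) || length(ev) == 0L) {
    data.frame(onset = numeric(0), duration = numeric(0), angle = numeric(0),
               band_lo = numeric(0), band_hi = numeric(0), a1 = numeric(0))
  } else if (is.data.frame(ev)) {
    band <- do.call(rbind, ev$band)
    data.frame(onset = ev$onset, duration = ev$duration, angle = ev$angle,
               band_lo = band[, 1], band_hi = band[, 2], a1 = ev$a1)
  } else {
    do.call(rbind, lapply(ev, function(e)
      data.frame(onset = e$onset, duration = e$duration, angle = e$angle,
                 band_lo = e$band[1], band_hi = e$band[2], a1 = e$a1)))
  }
  list(events = events, noise_segments = seg, fs = obj$fs,
       sinr_db = obj$sinr_db, inr_db = obj$inr_db, seed = obj$seed)
}

#' Write a rendered scene as WAV + JSON sidecar
#'
#' @param rec a \code{\link{render_scene}} recording.
#' @param wav_path,labels_path output paths.
#' @return \code{wav_path}, invisibly.
#' @export
write_scene <- function(rec, wav_path, labels_path) {
  write_wav(cbind(rec$x1, rec$x2), rec$fs, wav_path)
  write_labels(rec, labels_path)
  invisible(wav_path)
}

#' Read a scene (stereo WAV + JSON labels) as a stereo recording
#'
#' The result carries the two channels and the labels needed by the
#' beamforming pipeline; clean components are only available for scenes
#' rendered in-session.
#'
#' @param wav_path stereo WAV path (channel 1 = M1, channel 2 = M2).
#' @param labels_path JSON sidecar path (optional: without it the recording
#'   has no noise labels and cannot drive the adaptive stages).
#' @return A \code{stereo_recording}.
#' @export
read_scene <- function(wav_path, labels_path = NULL) {
  w <- read_wav(wav_path)
  if (ncol(w$samples) < 2L) stop("scene WAV must have two channels")
  lab <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  rec <- list(x1 = w$samples[, 1], x2 = w$samples[, 2], fs = w$fs,
              labels = if (is.null(lab)) NULL else
                list(events = lab$events, noise_segments = lab$noise_segments,
                     Y = sum(lab$noise_segments[, 2] - lab$noise_segments[, 1] + 1L)),
              clean1 = NULL, clean2 = NULL,
              achieved_sinr_db = if (is.null(lab)) NA_real_ else lab$sinr_db,
              achieved_inr_db = if (is.null(lab)) NA_real_ else lab$inr_db,
              spec = NULL)
  class(rec) <- "stereo_recording"
  rec
}
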