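# File interfaces: 16-bit PCM WAV, trajectory CSV with JSON sidecar,
# repeat-event CSV and scene metadata JSON.

#' Write a 16-bit PCM WAV file
#'
#' Minimal RIFF writer (mono or stereo). Samples are clipped to \[-1, 1\]
#' and quantized to 16 bits.
#'
#' @param x numeric vector (mono) or a [BinauralSignal-class].
#' @param path output path.
#' @param fsHz sampling rate (taken from the object if binaural).
#' @return `path`, invisibly.
#' @export
writeWav <- function(x, path, fsHz = NULL) {
  if (is(x, "BinauralSignal")) {
    ch <- rbind(x@left, x@right)
    fsHz <- x@fsHz
  } else ch <- matrix(x, nrow = 1)
  stopifnot(!is.null(fsHz))
  nCh <- as.integer(nrow(ch))
  pcm <- matrix(as.integer(round(pmin(1, pmax(-1, ch)) * 32767)), nrow = nCh)
  inter <- as.vector(pcm)                       # column-major = interleaved
  dataBytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(nCh, con, size = 2, endian = "little")
  writeBin(as.integer(fsHz), con, size = 4, endian = "little")
  writeBin(as.integer(fsHz * nCh * 2), con, size = 4, endian = "little")
  writeBin(as.integer(nCh * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV path (PCM 16-bit, mono or stereo).
#' @return mono: list(wave, fsHz); stereo: a [BinauralSignal-class].
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  fs <- nCh <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      nCh <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      x <- readBin(con, integer(), n = sz / 2, size = 2,
                   endian = "little") / 32767
      break
    } else invisible(readBin(con, "raw", n = sz))
  }
  if (nCh == 1) return(list(wave = x, fsHz = fs))
  m <- matrix(x, nrow = nCh)
  new("BinauralSignal", left = m[1, ], right = m[2, ], fsHz = fs)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' CSV columns `time_s,azimuth_deg`; the sidecar records rate and offset.
#'
#' @param traj a [Trajectory-class].
#' @param path CSV path (sidecar gets `.json` appended).
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCsv <- function(traj, path, seed = NULL) {
  tt <- traj@t0S + (seq_along(traj@azimuthDeg) - 1) / traj@rateHz
  write.csv(data.frame(time_s = tt, azimuth_deg = traj@azimuthDeg),
            path, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = traj@rateHz, t0_s = traj@t0S,
                            seed = seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trajectory CSV (with its JSON sidecar)
#'
#' @param path CSV path written by [writeTrajectoryCsv()].
#' @return a [Trajectory-class].
#' @export
readTrajectoryCsv <- function(path) {
  d <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("Trajectory", azimuthDeg = d$azimuth_deg, rateHz = meta$rate_hz,
      t0S = meta$t0_s)
}

#' Export a trial scene to disk
#'
#' Writes stereo WAVs for the mixture and components, a repeat-event CSV
#' (`time_s,stream,event_type`), trajectory CSVs and a metadata JSON with
#' the seeds and levels needed for bit-identical regeneration.
#'
#' @param scene a [TrialScene-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "trial_001").
#' @return the directory, invisibly.
#' @export
exportScene <- function(scene, dir, prefix = "trial_001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  writeWav(scene@mixture, p("mix.wav"))
  writeWav(scene@conv1, p("conv1.wav"))
  writeWav(scene@conv2, p("conv2.wav"))
  writeWav(scene@noise@left, p("noise.wav"), fsHz = scene@noise@fsHz)
  ev <- repeatEvents(scene)
  write.csv(data.frame(time_s = ev$onset_s, stream = ev$stream,
                       event_type = "repeat_onset"),
            p("events.csv"), row.names = FALSE)
  writeTrajectoryCsv(scene@trajectories@trajA, p("traj1.csv"))
  writeTrajectoryCsv(scene@trajectories@trajB, p("traj2.csv"))
  meta <- scene@meta
  meta$mono1 <- meta$mono2 <- meta$plan <- NULL
  meta$noise_level_db <- scene@noiseLevelDb
  meta$uncued_delay_s <- scene@uncuedDelayS
  jsonlite::write_json(meta, p("meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
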