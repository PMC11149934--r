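#' Write a recording to the package's on-disk container
#'
#' Serializes a recording as a directory holding `data.bin` (little-endian
#' doubles, column-major channels x samples) and `meta.json` (geometry,
#' paradigm, masks, provenance, and — when present — the planted burst
#' ground truth).
#'
#' @param recording [Recording-class].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording@data), con, size = 8, endian = "little")
  meta <- list(
    dims = dim(recording@data), fs = recording@fs,
    subjectId = recording@subjectId, age = recording@age,
    positions = recording@sensors@positions,
    orientations = recording@sensors@orientations,
    labels = recording@sensors@labels,
    sensorIndex = recording@sensors@sensorIndex,
    paradigm = list(
      nTrialsPerFinger = recording@paradigm@nTrialsPerFinger,
      stimDuration = recording@paradigm@stimDuration,
      restDuration = recording@paradigm@restDuration,
      tapUp = recording@paradigm@tapUp, tapDown = recording@paradigm@tapDown,
      leadIn = recording@paradigm@leadIn,
      onsets = recording@paradigm@onsets,
      fingers = recording@paradigm@fingers),
    channelKeep = recording@channelKeep,
    channelReason = as.list(recording@channelReason),
    provenance = recording@provenance,
    bursts = attr(recording, "bursts"))
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a recording written by [writeRecording()]
#' @param path Container directory.
#' @return A [Recording-class] (planted bursts restored as attribute
#'   `"bursts"` when present).
#' @export
readRecording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  X <- matrix(readBin(con, "double", n = prod(dims), size = 8,
                      endian = "little"), dims[1], dims[2])
  sensors <- new("SensorArray", positions = as.matrix(meta$positions),
                 orientations = as.matrix(meta$orientations),
                 labels = as.character(meta$labels),
                 sensorIndex = as.integer(meta$sensorIndex))
  pd <- meta$paradigm
  paradigm <- new("Paradigm",
                  nTrialsPerFinger = as.integer(pd$nTrialsPerFinger),
                  stimDuration = pd$stimDuration,
                  restDuration = pd$restDuration, tapUp = pd$tapUp,
                  tapDown = pd$tapDown, leadIn = pd$leadIn,
                  onsets = as.numeric(pd$onsets),
                  fingers = as.character(pd$fingers))
  reason <- unlist(meta$channelReason) %||% character(0)
  rec <- new("Recording", data = X, fs = meta$fs, sensors = sensors,
             paradigm = paradigm, subjectId = meta$subjectId,
             age = meta$age %||% NA_real_,
             channelKeep = as.logical(meta$channelKeep),
             channelReason = if (length(reason)) reason else character(0),
             provenance = meta$provenance %||% list())
  if (!is.null(meta$bursts) && length(meta$bursts)) {
    attr(rec, "bursts") <- as.data.frame(meta$bursts)
  }
  rec
}

# Deterministically formatted CSV writer (fixed significant digits so that
# identical runs produce byte-identical files).
writeTableCSV <- function(df, path, digits = 12) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf(paste0("%.", digits, "g"), out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Matrix CSV with row labels.
writeMatrixCSV <- function(M, path, rowLabel = "row", digits = 12) {
  df <- data.frame(rownames(M) %||% seq_len(nrow(M)),
                   matrix(sprintf(paste0("%.", digits, "g"), M), nrow(M)))
  names(df) <- c(rowLabel, colnames(M) %||% paste0("c", seq_len(ncol(M))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
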