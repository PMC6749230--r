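#' Construct a RecordingSession
#'
#' @param subjectID subject label (single string).
#' @param pressure `n x 16` matrix of quantized pressure values (0/1/2),
#'   columns left-foot sensors 1--8 then right-foot sensors 1--8.
#' @param acceleration `n x 6` matrix, columns left (x,y,z) then right
#'   (x,y,z), in raw sensor units.
#' @param sampleRate frames per second; the insole samples at 100 Hz.
#' @return A validated [RecordingSession].
#' @examples
#' s <- RecordingSession("S01", matrix(0, 3, 16), matrix(0, 3, 6))
#' nFrames(s)
#' @export
RecordingSession <- function(subjectID, pressure, acceleration,
                             sampleRate = DEFAULT_SAMPLE_RATE) {
  pressure <- as.matrix(pressure)
  acceleration <- as.matrix(acceleration)
  storage.mode(pressure) <- "double"
  storage.mode(acceleration) <- "double"
  if (ncol(pressure) == N_PRESSURE_CHANNELS) {
    colnames(pressure) <- pressureChannelNames()
  }
  if (ncol(acceleration) == N_ACCEL_CHANNELS) {
    colnames(acceleration) <- accelChannelNames()
  }
  new("RecordingSession", subjectID = as.character(subjectID),
      sampleRate = as.numeric(sampleRate),
      pressure = pressure, acceleration = acceleration)
}

sessionHeader <- function() {
  c("t", pressureChannelNames(), accelChannelNames())
}

#' Read a recording session from its CSV representation
#'
#' The on-disk format is one CSV per recording: two comment lines carrying
#' the subject label and sample rate (`# subject_id: ...`,
#' `# sample_rate: ...`), a header row
#' `t,Lp1..Lp8,Rp1..Rp8,Lax,Lay,Laz,Rax,Ray,Raz`, and one row per frame.
#' Pressure columns must contain only 0, 1 or 2.
#'
#' @param path path to a session CSV file.
#' @return A validated [RecordingSession].
#' @seealso [writeSession()], [readCohort()]
#' @export
readSession <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty session file: ", path)

  isMeta <- startsWith(lines, "#")
  meta <- lines[isMeta]
  parseMeta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1L]))
  }
  subj <- parseMeta("subject_id")
  rate <- parseMeta("sample_rate")
  if (is.na(subj)) stop("missing '# subject_id:' metadata line in ", path)
  rate <- if (is.na(rate)) DEFAULT_SAMPLE_RATE else as.numeric(rate)

  body <- lines[!isMeta]
  if (length(body) < 2L) stop("session file has no data rows: ", path)
  hdr <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), sessionHeader())) {
    stop("unexpected header in ", path, "; expected: ",
         paste(sessionHeader(), collapse = ","))
  }

  bodyLineNo <- which(!isMeta)  # file line numbers of non-comment lines
  ncolExpect <- length(sessionHeader())
  fields <- strsplit(body[-1L], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncolExpect)) {
    bad <- which(nf != ncolExpect)[1L]
    stop(sprintf("malformed row at line %d of %s: %d fields, expected %d",
                 bodyLineNo[bad + 1L], path, nf[bad], ncolExpect))
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                 ncol = ncolExpect, byrow = TRUE)
  if (any(is.na(vals))) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop(sprintf("non-numeric value at line %d of %s",
                 bodyLineNo[bad + 1L], path))
  }

  pcols <- 1L + seq_len(N_PRESSURE_CHANNELS)
  pressure <- vals[, pcols, drop = FALSE]
  badP <- !(pressure %in% PRESSURE_LEVELS)
  if (any(badP)) {
    idx <- which(matrix(badP, nrow = nrow(pressure)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid pressure value %g in channel %s at line %d of %s (must be 0, 1 or 2)",
      pressure[idx[1L], idx[2L]], pressureChannelNames()[idx[2L]],
      bodyLineNo[idx[1L] + 1L], path))
  }
  accel <- vals[, 1L + N_PRESSURE_CHANNELS + seq_len(N_ACCEL_CHANNELS),
                drop = FALSE]
  RecordingSession(subj, pressure, accel, rate)
}

#' Write a recording session to CSV
#'
#' Writes the format read by [readSession()]. Acceleration values are
#' written with 17 significant digits so that a write/read round trip
#' reproduces the session exactly; writing is deterministic (two writes of
#' the same session yield byte-identical files).
#'
#' @param session a [RecordingSession].
#' @param path output file path; parent directories are created.
#' @return `invisible(path)`.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "RecordingSession"))
  validObject(session)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  n <- nFrames(session)
  pr <- apply(session@pressure, 1L, function(r)
    paste(as.character(as.integer(r)), collapse = ","))
  ac <- apply(session@acceleration, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  lines <- c(
    paste0("# subject_id: ", session@subjectID),
    paste0("# sample_rate: ", sprintf("%.17g", session@sampleRate)),
    paste(sessionHeader(), collapse = ","),
    paste(seq_len(n) - 1L, pr, ac, sep = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a cohort directory of session files
#'
#' Expects the layout `<cohort>/<subject_id>/<session>.csv`; ground-truth
#' sidecar files (`*_steps.csv`) written by the simulator are ignored.
#'
#' @param dir cohort directory.
#' @return A list of [RecordingSession] objects, ordered by subject then
#'   file name.
#' @export
readCohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                      full.names = TRUE)
  files <- files[!grepl("_steps\\.csv$", files)]
  if (length(files) == 0L) stop("no session files found under ", dir)
  lapply(sort(files), readSession)
}

#' Write a cohort of sessions into the standard directory layout
#'
#' @param sessions list of [RecordingSession] objects.
#' @param dir output cohort directory; one subdirectory per subject.
#' @return `invisible(dir)`.
#' @export
writeCohort <- function(sessions, dir) {
  counts <- new.env()
  for (s in sessions) {
    id <- subjectID(s)
    i <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
    counts[[id]] <- i
    writeSession(s, file.path(dir, id, sprintf("session%03d.csv", i)))
  }
  invisible(dir)
}
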