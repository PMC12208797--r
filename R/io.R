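# Delimited trace format
#
# Block dialect (native, supports dual sampling rates):
#   # corowia-trace v1
#   # vessel_id=V001 phase=pre condition=rest
#   # channel=Pa fs=200 units=mmHg
#   time,value
#   0,70.0000000
#   ...
#   # channel=Pd fs=200 units=mmHg
#   ...
#   # channel=U fs=100 units=cm/s
#   ...
# Wide dialect (single common rate):
#   # corowia-trace v1
#   # vessel_id=V001 phase=pre condition=rest fs=200
#   time,Pa,Pd,U
#   ...

#' Write a recording to a delimited trace file
#'
#' @param rec a \code{\link{vessel_recording}}.
#' @param path output file path.
#' @param dialect \code{"block"} (dual-rate capable, default) or
#'   \code{"wide"} (requires a common sampling rate).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("block", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "vessel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# vessel_id=%s phase=%s condition=%s",
                 rec$vessel_id, rec$phase, rec$condition)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  if (dialect == "block") {
    writeLines(c("# corowia-trace v1", hdr), con)
    blk <- function(name, x, fs, units) {
      writeLines(sprintf("# channel=%s fs=%g units=%s", name, fs, units), con)
      writeLines("time,value", con)
      tt <- (seq_along(x) - 1) / fs
      writeLines(paste(fmt(tt), fmt(x), sep = ","), con)
    }
    blk("Pa", rec$pa, rec$fs_pressure, "mmHg")
    blk("Pd", rec$pd, rec$fs_pressure, "mmHg")
    blk("U", rec$u, rec$fs_velocity, "cm/s")
  } else {
    if (rec$fs_pressure != rec$fs_velocity ||
        length(rec$u) != length(rec$pa))
      stop_corowia("corowia_format_error",
                   "wide dialect requires all channels on one common grid")
    writeLines(c("# corowia-trace v1",
                 sprintf("%s fs=%g", hdr, rec$fs_pressure)), con)
    writeLines("time,Pa,Pd,U", con)
    tt <- (seq_along(rec$pa) - 1) / rec$fs_pressure
    writeLines(paste(fmt(tt), fmt(rec$pa), fmt(rec$pd), fmt(rec$u), sep = ","), con)
  }
  invisible(path)
}

parse_kv <- function(line) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_)
  names(out) <- vapply(kv, `[[`, "", 1)
  out
}

#' Read a recording from a delimited trace file
#'
#' Auto-detects the block and wide dialects written by
#' \code{\link{write_recording}}. All three channels (Pa, Pd, U) must be
#' present; the time column of every channel must be strictly increasing.
#'
#' @param path input file path.
#' @param dialect \code{"auto"}, \code{"block"} or \code{"wide"}.
#' @return A \code{\link{vessel_recording}} with native per-channel rates.
#' @export
read_recording <- function(path, dialect = c("auto", "block", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_corowia("corowia_format_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (any(grepl("^#\\s*channel=", lines))) "block" else "wide"

  meta_line <- grep("^#\\s*vessel_id=", lines, value = TRUE)
  meta <- if (length(meta_line)) parse_kv(meta_line[1]) else list()
  vessel_id <- meta$vessel_id %||% "unknown"
  phase <- meta$phase %||% "pre"
  condition <- meta$condition %||% "rest"

  check_time <- function(tt, where) {
    if (any(diff(tt) <= 0))
      stop_corowia("corowia_format_error",
                   sprintf("non-monotone time column in %s", where))
  }

  if (dialect == "block") {
    starts <- grep("^#\\s*channel=", lines)
    if (!length(starts))
      stop_corowia("corowia_format_error", "no channel blocks found")
    ends <- c(starts[-1] - 1L, length(lines))
    chans <- list()
    for (i in seq_along(starts)) {
      kv <- parse_kv(lines[starts[i]])
      body <- lines[(starts[i] + 1L):ends[i]]
      body <- body[!grepl("^#", body) & nzchar(trimws(body))]
      body <- body[body != "time,value"]
      m <- do.call(rbind, strsplit(body, ",", fixed = TRUE))
      tt <- as.numeric(m[, 1])
      check_time(tt, paste("channel", kv$channel))
      chans[[kv$channel]] <- list(x = as.numeric(m[, 2]),
                                  fs = as.numeric(kv$fs))
    }
    for (nm in c("Pa", "Pd", "U"))
      if (is.null(chans[[nm]]))
        stop_corowia("corowia_format_error",
                     sprintf("required channel '%s' missing", nm))
    return(vessel_recording(
      chans$Pa$x, chans$Pd$x, chans$U$x,
      fs_pressure = chans$Pa$fs, fs_velocity = chans$U$fs,
      vessel_id = vessel_id, phase = phase, condition = condition))
  }

  hd <- grep("^time,", lines)
  if (!length(hd))
    stop_corowia("corowia_format_error", "wide header 'time,...' not found")
  cols <- strsplit(lines[hd[1]], ",", fixed = TRUE)[[1]]
  body <- lines[(hd[1] + 1L):length(lines)]
  body <- body[!grepl("^#", body) & nzchar(trimws(body))]
  m <- do.call(rbind, strsplit(body, ",", fixed = TRUE))
  storage.mode(m) <- "character"
  dat <- as.data.frame(m, stringsAsFactors = FALSE)
  names(dat) <- cols
  for (nm in c("Pa", "Pd", "U"))
    if (!nm %in% cols)
      stop_corowia("corowia_format_error",
                   sprintf("required channel '%s' missing", nm))
  tt <- as.numeric(dat$time)
  check_time(tt, "wide table")
  fs <- as.numeric(meta$fs %||% (1 / stats::median(diff(tt))))
  vessel_recording(as.numeric(dat$Pa), as.numeric(dat$Pd), as.numeric(dat$U),
                   fs_pressure = fs, fs_velocity = fs,
                   vessel_id = vessel_id, phase = phase, condition = condition)
}
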