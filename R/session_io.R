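#' Write a session record to a directory
#'
#' Serializes a `session_record` as plain-text artifacts: `events.jsonl`
#' (one `{t, kind, payload}` object per line), `tones.jsonl`
#' (`{t, f_hz, active}`), `kinematics.csv`, `metrics.csv`, and
#' `session.json` (mode and metadata) plus `config.yaml`.
#'
#' @param record a `session_record`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonl <- function(df, path) {
    writeLines(vapply(seq_len(nrow(df)), function(i)
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA,
                       na = "null"), character(1)), path)
  }
  jsonl(record$events, file.path(dir, "events.jsonl"))
  jsonl(record$tones, file.path(dir, "tones.jsonl"))
  write.csv(record$kinematics, file.path(dir, "kinematics.csv"),
            row.names = FALSE)
  write.csv(record$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(list(mode = record$mode, meta = record$meta),
                       file.path(dir, "session.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  cfg <- default_run_config()
  cfg$trial <- record$config$trial
  cfg$sonification <- record$config$sonification
  dump_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a session record from a directory
#'
#' Inverse of [write_session_record()] (calibration is not persisted; the
#' reloaded record carries everything the offline analysis and audio
#' rendering need).
#'
#' @param dir directory written by [write_session_record()].
#' @return A `session_record`.
#' @export
read_session_record <- function(dir) {
  read_jsonl <- function(path, proto) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) return(proto)
    do.call(rbind, lapply(lines, function(l) {
      as.data.frame(lapply(jsonlite::fromJSON(l),
                           function(v) if (is.null(v)) NA else v))
    }))
  }
  events <- read_jsonl(file.path(dir, "events.jsonl"),
                       data.frame(t = numeric(0), kind = character(0),
                                  payload = numeric(0)))
  tones <- read_jsonl(file.path(dir, "tones.jsonl"),
                      data.frame(t = numeric(0), f_hz = numeric(0),
                                 active = logical(0)))
  if (!"payload" %in% names(events)) events$payload <- NA_real_
  ses <- jsonlite::fromJSON(file.path(dir, "session.json"))
  cfg <- load_config(file.path(dir, "config.yaml"))
  structure(list(
    events = events,
    kinematics = read.csv(file.path(dir, "kinematics.csv")),
    tones = tones,
    metrics = read.csv(file.path(dir, "metrics.csv")),
    config = list(trial = cfg$trial, sonification = cfg$sonification,
                  calibration = NULL),
    mode = ses$mode, meta = ses$meta), class = "session_record")
}
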