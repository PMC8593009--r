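# Canonical event-log data model and CSV dialect.
#
# Dialect (version 1): comma-separated, UTF-8, "." decimal. Metadata lines
# start with "# " and precede the header row `time_ms,event,payload`.
# Required metadata: the log version; optional: paradigm, seed, duration_ms
# and one "param:" line per task parameter, so a log documents the protocol
# constants it was produced under. Event names come from a closed, versioned
# vocabulary; timestamps are non-negative, non-decreasing integers.

LOG_FORMAT <- "fivechoice event log v1"

#' The closed event vocabulary of the log dialect
#'
#' @return Character vector of valid `event` values. `state` events carry the
#'   task state name as payload; `poke`, `hole_light_*` carry the hole index;
#'   `ttl_*` the channel; `reward` carries `"<microlitres>;<motor steps>"`.
#' @export
event_vocabulary <- function() {
  c("session_start", "session_end", "state",
    "poke", "receptacle_in", "receptacle_out",
    "hole_light_on", "hole_light_off",
    "house_light_on", "house_light_off",
    "receptacle_light_on", "receptacle_light_off",
    "ttl_high", "ttl_low", "reward")
}

new_event_log <- function(df, paradigm = NA_character_, seed = NA_integer_,
                          duration_ms = NA_integer_, task_params = NULL,
                          engine_counts = NULL) {
  structure(df,
            paradigm = paradigm, seed = seed, duration_ms = duration_ms,
            task_params = task_params, engine_counts = engine_counts,
            class = c("event_log", "data.frame"))
}

#' @export
print.event_log <- function(x, n = 10L, ...) {
  cat(sprintf("<event_log: %s, %d events, %g ms%s>\n",
              attr(x, "paradigm"), nrow(x), max(c(0, x$time_ms)),
              if (!is.na(attr(x, "seed"))) {
                sprintf(", seed %d", attr(x, "seed"))
              } else ""))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more events\n", nrow(x) - n))
  invisible(x)
}

log_parse_error <- function(msg, line = NA_integer_) {
  stop(errorCondition(
    if (is.na(line)) msg else sprintf("%s (line %d)", msg, line),
    class = c("fivechoice_parse_error", "error")))
}

#' Write an event log to CSV
#'
#' @param log An `event_log` (from [run_session()] or [read_event_csv()]).
#' @param path Output file path.
#' @param extra_meta Named character vector of additional metadata lines
#'   (e.g. a config hash) written into the header.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(log, path, extra_meta = NULL) {
  stopifnot(inherits(log, "event_log"))
  meta <- c(sprintf("# %s", LOG_FORMAT))
  if (!is.na(attr(log, "paradigm"))) {
    meta <- c(meta, sprintf("# paradigm: %s", attr(log, "paradigm")))
  }
  if (!is.na(attr(log, "seed"))) {
    meta <- c(meta, sprintf("# seed: %d", attr(log, "seed")))
  }
  if (!is.na(attr(log, "duration_ms"))) {
    meta <- c(meta, sprintf("# duration_ms: %d",
                            as.integer(attr(log, "duration_ms"))))
  }
  tp <- attr(log, "task_params")
  if (!is.null(tp)) {
    meta <- c(meta, sprintf("# param: %s=%.10g", names(tp), unname(tp)))
  }
  if (!is.null(extra_meta)) {
    meta <- c(meta, sprintf("# %s: %s", names(extra_meta),
                            unname(extra_meta)))
  }
  body <- sprintf("%d,%s,%s", log$time_ms, log$event, log$payload)
  writeLines(c(meta, "time_ms,event,payload", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read an event log from CSV
#'
#' Validates the documented dialect: a header row, event names from
#' [event_vocabulary()], integer non-negative timestamps in non-decreasing
#' order. Malformed input raises a parse error naming the offending line.
#'
#' @param path File written by [write_event_csv()] or an external log in the
#'   same dialect.
#' @return An `event_log`.
#' @export
read_event_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) log_parse_error("empty file")
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) log_parse_error("no header row found")
  meta <- sub("^#\\s*", "", lines[seq_len(n_meta)])

  header_line <- n_meta + 1L
  if (lines[header_line] != "time_ms,event,payload") {
    log_parse_error("expected header 'time_ms,event,payload'", header_line)
  }

  get_meta <- function(key) {
    hit <- grep(sprintf("^%s:\\s*", key), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(sprintf("^%s:\\s*", key), "", hit[1L])
  }
  paradigm <- get_meta("paradigm")
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  duration <- suppressWarnings(as.integer(get_meta("duration_ms")))
  par_lines <- grep("^param:\\s*", meta, value = TRUE)
  task_params <- NULL
  if (length(par_lines)) {
    kv <- strsplit(sub("^param:\\s*", "", par_lines), "=", fixed = TRUE)
    task_params <- stats::setNames(
      vapply(kv, function(x) as.numeric(x[2L]), numeric(1)),
      vapply(kv, `[`, character(1), 1L))
  }

  body <- lines[-seq_len(header_line)]
  body_lineno <- header_line + seq_along(body)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    log_parse_error("expected 'time_ms,event,payload'", body_lineno[bad[1L]])
  }
  time_chr <- vapply(parts, `[`, character(1), 1L)
  event <- vapply(parts, `[`, character(1), 2L)
  payload <- vapply(parts, function(x) {
    if (length(x) >= 3L) paste(x[-(1:2)], collapse = ",") else ""
  }, character(1))

  time_ms <- suppressWarnings(as.numeric(time_chr))
  bad <- which(is.na(time_ms) | time_ms < 0 | time_ms != floor(time_ms))
  if (length(bad)) {
    log_parse_error(sprintf("invalid timestamp '%s'", time_chr[bad[1L]]),
                    body_lineno[bad[1L]])
  }
  bad <- which(!event %in% event_vocabulary())
  if (length(bad)) {
    log_parse_error(sprintf("unknown event name '%s'", event[bad[1L]]),
                    body_lineno[bad[1L]])
  }
  if (length(time_ms) > 1L) {
    bad <- which(diff(time_ms) < 0)
    if (length(bad)) {
      log_parse_error("timestamps decrease", body_lineno[bad[1L] + 1L])
    }
  }

  new_event_log(data.frame(time_ms = as.integer(time_ms), event = event,
                           payload = payload, stringsAsFactors = FALSE),
                paradigm = paradigm, seed = seed, duration_ms = duration,
                task_params = task_params)
}
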