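# Alignment of behavioural millisecond timestamps with an acquisition-system
# timeline via shared TTL pulse trains.
#
# The mapping is affine: received ~ offset + drift * emitted. Over a 30-min
# session clock-drift curvature is negligible, so no piecewise fitting is
# attempted (documented assumption). Pulse matching is greedy
# nearest-neighbour after a coarse offset estimate, tolerating a small
# fraction of dropped pulses on the receiving side.

#' A TTL pulse train on one clock
#'
#' @param times_ms Strictly increasing pulse timestamps (ms).
#' @param clock_id Label of the clock the times live on.
#' @return A `pulse_train` object.
#' @export
pulse_train <- function(times_ms, clock_id = "behaviour") {
  if (!is.numeric(times_ms)) config_error("`times_ms` must be numeric")
  if (length(times_ms) > 1L && any(diff(times_ms) <= 0)) {
    config_error("pulse times must be strictly increasing")
  }
  structure(list(times_ms = as.numeric(times_ms),
                 clock_id = as.character(clock_id)),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train: %d pulses on clock '%s'>\n",
              length(x$times_ms), x$clock_id))
  invisible(x)
}

as_pulse_times <- function(x) {
  if (inherits(x, "pulse_train")) x$times_ms else as.numeric(x)
}

#' Affine clock model between two timelines
#'
#' @param offset_ms Offset (ms) of the acquisition clock at behavioural t=0.
#' @param drift Dimensionless rate (acquisition ms per behavioural ms);
#'   sensible values are within 1 +/- 0.01.
#' @param residual_sd_ms Residual standard deviation of the fit (ms).
#' @param se_offset_ms,se_drift Standard errors of the fitted parameters.
#' @param n_matched Number of matched pulse pairs used.
#' @return A `clock_model` object.
#' @export
clock_model <- function(offset_ms, drift = 1, residual_sd_ms = NA_real_,
                        se_offset_ms = NA_real_, se_drift = NA_real_,
                        n_matched = NA_integer_) {
  if (drift <= 0) config_error("`drift` must be positive")
  structure(list(offset_ms = as.numeric(offset_ms),
                 drift = as.numeric(drift),
                 residual_sd_ms = as.numeric(residual_sd_ms),
                 se_offset_ms = as.numeric(se_offset_ms),
                 se_drift = as.numeric(se_drift),
                 n_matched = as.integer(n_matched)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model: offset %.3f ms, drift %.8f, residual sd %.3f ms, n=%s>\n",
              x$offset_ms, x$drift, x$residual_sd_ms, x$n_matched))
  invisible(x)
}

# Coarse offset search: candidate offsets come from pairings of the leading
# pulses; each candidate is scored by how many probe pulses (drawn from both
# ends of the received train, so periodic trains are disambiguated at their
# boundaries) find an emitted partner within tolerance, ties broken by median
# deviation. The winning offset is refined by the median signed residual.
coarse_offset <- function(emitted, received, tol) {
  e <- emitted
  r <- received
  head_n <- seq_len(min(10L, length(r)))
  cand <- unique(round(as.vector(outer(r[head_n],
                                       e[seq_len(min(10L, length(e)))],
                                       "-"))))
  n <- length(r)
  probe <- r[unique(c(seq_len(min(150L, n)), seq(max(1L, n - 149L), n)))]
  nearest_dev <- function(x) {
    idx <- findInterval(x, e)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(e))
    signed <- ifelse(abs(x - e[lo]) <= abs(x - e[hi]), x - e[lo], x - e[hi])
    signed
  }
  best <- NULL
  for (c0 in cand) {
    dev <- nearest_dev(probe - c0)
    score <- c(n_ok = sum(abs(dev) <= tol), neg_mad = -stats::median(abs(dev)))
    if (is.null(best) || score[1L] > best$score[1L] ||
        (score[1L] == best$score[1L] && score[2L] > best$score[2L])) {
      best <- list(c0 = c0, score = score, dev = dev)
    }
  }
  ok <- abs(best$dev) <= tol
  best$c0 + if (any(ok)) stats::median(best$dev[ok]) else 0
}

#' Fit the affine mapping between emitted and received pulse trains
#'
#' Matches pulses greedily (nearest neighbour after a coarse offset
#' estimate), then least-squares fits `received ~ offset + drift * emitted`.
#'
#' @param emitted Pulse times on the behavioural clock ([pulse_train()] or
#'   numeric vector, ms).
#' @param received Pulse times recorded by the acquisition system.
#' @param match_tol_ms Maximum deviation (ms) for a pulse pair to count as
#'   matched.
#' @param max_unmatched_frac Error if more than this fraction of received
#'   pulses finds no emitted partner.
#' @return A [clock_model()].
#' @examples
#' e <- seq(0, 60000, by = 1000)
#' m <- fit_clock_mapping(e, 123 + 1.00002 * e)
#' m$offset_ms  # ~123
#' @export
fit_clock_mapping <- function(emitted, received, match_tol_ms = 50,
                              max_unmatched_frac = 0.1) {
  e <- as_pulse_times(emitted)
  r <- as_pulse_times(received)
  if (length(e) < 2L || length(r) < 2L) {
    config_error("need at least 2 pulses on each clock to fit a mapping")
  }
  off0 <- coarse_offset(e, r, tol = match_tol_ms)
  # each received pulse claims its nearest emitted pulse under the coarse
  # offset; emitted pulses with no claimant are treated as dropped
  idx <- findInterval(r - off0, e)
  cand_lo <- pmax(idx, 1L)
  cand_hi <- pmin(idx + 1L, length(e))
  d_lo <- abs((r - off0) - e[cand_lo])
  d_hi <- abs((r - off0) - e[cand_hi])
  match <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  dev <- pmin(d_lo, d_hi)
  ok <- dev <= match_tol_ms & !duplicated(match)
  if (mean(!ok) > max_unmatched_frac) {
    config_error(sprintf(
      "pulse count mismatch: %d received pulses unmatched (indices %s)",
      sum(!ok), paste(utils::head(which(!ok), 10L), collapse = ", ")))
  }
  em <- e[match[ok]]
  rm_ <- r[ok]
  fit <- stats::lm(rm_ ~ em)
  cf <- stats::coef(fit)
  # a zero-jitter train fits perfectly; the "unreliable summary" note that
  # lm emits for it is expected here
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  model <- clock_model(offset_ms = unname(cf[1L]), drift = unname(cf[2L]),
                       residual_sd_ms = stats::sigma(fit),
                       se_offset_ms = unname(se[1L]),
                       se_drift = unname(se[2L]),
                       n_matched = sum(ok))
  if (abs(model$drift - 1) >= 0.01) {
    warning(sprintf("fitted drift %.6f deviates from 1 by >= 1%%: check pulse matching",
                    model$drift))
  }
  model
}

#' Map timestamps onto the acquisition timeline
#'
#' Every behavioural time `t` becomes `offset + drift * t`; ordering is
#' preserved. Accepts an `event_log` (its `time_ms` column is mapped, kept at
#' full precision) or a numeric vector.
#'
#' @param x An `event_log` or numeric vector of times (ms).
#' @param model A [clock_model()].
#' @return Same shape as `x`, on the acquisition timeline.
#' @export
map_timestamps <- function(x, model) {
  stopifnot(inherits(model, "clock_model"))
  if (inherits(x, "event_log") || is.data.frame(x)) {
    x$time_ms <- model$offset_ms + model$drift * x$time_ms
    attr(x, "clock") <- "acquisition"
    return(x)
  }
  model$offset_ms + model$drift * as.numeric(x)
}

#' Invert an affine clock model
#'
#' @param model A [clock_model()].
#' @return The inverse mapping (acquisition -> behavioural) as a
#'   [clock_model()].
#' @export
invert_clock_mapping <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  clock_model(offset_ms = -model$offset_ms / model$drift,
              drift = 1 / model$drift,
              residual_sd_ms = model$residual_sd_ms / model$drift,
              n_matched = model$n_matched)
}

#' Simulate an acquisition-system clock receiving TTL pulses
#'
#' Test harness for alignment: received times are
#' `offset + drift * t + noise`, with pulses dropped independently at
#' `drop_rate`.
#'
#' @param true_times_ms Emitted pulse times on the behavioural clock (ms).
#' @param offset_ms,drift Affine clock parameters.
#' @param jitter_sd_ms Gaussian timestamping jitter (ms).
#' @param drop_rate Probability that a pulse is not recorded.
#' @param seed Seed for jitter and drops.
#' @return A [pulse_train()] on clock `"acquisition"`.
#' @export
simulate_acquisition_clock <- function(true_times_ms, offset_ms = 0,
                                       drift = 1, jitter_sd_ms = 0,
                                       drop_rate = 0, seed = 1L) {
  t <- as_pulse_times(true_times_ms)
  if (drop_rate < 0 || drop_rate >= 1) {
    config_error("`drop_rate` must be in [0, 1)")
  }
  stream <- new_rng_stream(seed)
  rec <- with_stream(stream, {
    keep <- stats::runif(length(t)) >= drop_rate
    r <- offset_ms + drift * t[keep]
    if (jitter_sd_ms > 0) r <- r + stats::rnorm(sum(keep), 0, jitter_sd_ms)
    sort(r)
  })
  pulse_train(rec, clock_id = "acquisition")
}

# ---- pulse-train CSV -----------------------------------------------------

#' Write a pulse train to CSV
#'
#' One `time_ms` value per line, clock id in the header.
#'
#' @param train A [pulse_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  writeLines(c(sprintf("# fivechoice pulse train v1"),
               sprintf("# clock: %s", train$clock_id),
               "time_ms",
               sprintf("%.10g", train$times_ms)), path, useBytes = TRUE)
  invisible(path)
}

#' Read a pulse train from CSV
#'
#' @param path File written by [write_pulse_csv()].
#' @return A [pulse_train()].
#' @export
read_pulse_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  clock <- sub("^#\\s*clock:\\s*", "",
               grep("^#\\s*clock:", meta, value = TRUE)[1L])
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1L] != "time_ms") {
    log_parse_error("expected header 'time_ms'")
  }
  times <- suppressWarnings(as.numeric(body[-1L]))
  if (any(is.na(times))) {
    log_parse_error("non-numeric pulse time",
                    which(is.na(times))[1L] + length(meta) + 1L)
  }
  pulse_train(times, clock_id = if (is.na(clock)) "unknown" else clock)
}
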