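# Session performance indicators.
#
# The three percentage formulas are the standard 5-choice definitions:
#   accuracy     = 100 * correct / (correct + incorrect)
#   %omissions   = 100 * omissions / trials
#   %premature   = 100 * prematures / trials
# with `trials` the number of classified trials. Undefined metrics (zero
# denominator) are reported as NA, never 0 or 100, so degenerate sessions
# cannot silently bias training-stage decisions. Percentages are kept at full
# float precision; rounding is presentation-only.

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' 5-CSRTT session summary
#'
#' @param trials Trial table from [trials_5csrtt()].
#' @param duration_ms Optional session duration for the record.
#' @param stage Optional stage label for the record.
#' @return A one-row `session_summary` data frame with class counts, the
#'   three percentage metrics and mean latencies over correct trials.
#' @examples
#' tr <- data.frame(class = rep(c("correct", "incorrect", "omission",
#'                                "premature"), c(10, 5, 5, 5)),
#'                  response_latency_ms = NA, reward_latency_ms = NA)
#' compute_5csrtt_metrics(tr)  # accuracy 66.67, %omissions 20, %premature 20
#' @export
compute_5csrtt_metrics <- function(trials, duration_ms = NA_real_,
                                   stage = NA_character_) {
  stopifnot(is.data.frame(trials), "class" %in% names(trials))
  n <- nrow(trials)
  counts <- table(factor(trials$class,
                         levels = c("correct", "incorrect", "premature",
                                    "omission")))
  nc <- unname(counts["correct"]); ni <- unname(counts["incorrect"])
  np <- unname(counts["premature"]); no <- unname(counts["omission"])
  resp <- trials$response_latency_ms
  rew <- trials$reward_latency_ms
  out <- data.frame(
    paradigm = "5csrtt", stage = stage, duration_ms = duration_ms,
    n_trials = n, n_correct = nc, n_incorrect = ni, n_premature = np,
    n_omission = no, n_rewards = nc,
    accuracy = pct(nc, nc + ni),
    pct_omissions = pct(no, n),
    pct_premature = pct(np, n),
    mean_response_latency_ms =
      if (any(!is.na(resp))) mean(resp, na.rm = TRUE) else NA_real_,
    mean_reward_latency_ms =
      if (any(!is.na(rew))) mean(rew, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("session_summary", "data.frame")
  out
}

#' 5-CSWM session summary
#'
#' Sample-phase metrics use the same formulas as the 5-CSRTT over all
#' classified trials; choice-phase (working-memory) accuracy is
#' `100 * match / (match + nonmatch)` over trials that reached the choice
#' phase, and CP omissions are relative to that same denominator.
#'
#' @param trials Trial table from [trials_5cswm()].
#' @inheritParams compute_5csrtt_metrics
#' @return A one-row `session_summary` data frame.
#' @export
compute_5cswm_metrics <- function(trials, duration_ms = NA_real_,
                                  stage = NA_character_) {
  stopifnot(is.data.frame(trials), all(c("sp_class", "cp_class") %in%
                                         names(trials)))
  n <- nrow(trials)
  spc <- sum(trials$sp_class == "correct", na.rm = TRUE)
  spi <- sum(trials$sp_class == "incorrect", na.rm = TRUE)
  spo <- sum(trials$sp_class == "omission", na.rm = TRUE)
  reached <- !is.na(trials$cp_class)
  ncp <- sum(reached)
  cpm <- sum(trials$cp_class[reached] == "match")
  cpn <- sum(trials$cp_class[reached] == "nonmatch")
  cpo <- sum(trials$cp_class[reached] == "omission")
  out <- data.frame(
    paradigm = "5cswm", stage = stage, duration_ms = duration_ms,
    n_trials = n, n_sp_correct = spc, n_sp_incorrect = spi,
    n_sp_omission = spo, n_cp_reached = ncp, n_cp_match = cpm,
    n_cp_nonmatch = cpn, n_cp_omission = cpo,
    sp_accuracy = pct(spc, spc + spi),
    sp_pct_omissions = pct(spo, n),
    cp_accuracy = pct(cpm, cpm + cpn),
    cp_pct_omissions = pct(cpo, ncp),
    mean_sp_response_latency_ms =
      if (any(!is.na(trials$sp_response_latency_ms))) {
        mean(trials$sp_response_latency_ms, na.rm = TRUE)
      } else NA_real_,
    mean_cp_response_latency_ms =
      if (any(!is.na(trials$cp_response_latency_ms))) {
        mean(trials$cp_response_latency_ms, na.rm = TRUE)
      } else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Time-binned performance across a session
#'
#' Recomputes trial counts, accuracy and omission rate in fixed time bins
#' (default 3 min) across the session, e.g. to look for within-session
#' fatigue. Trials are assigned to bins by stimulus onset (premature trials,
#' which have none, by trial start). Empty bins report NA metrics.
#'
#' @param trials Trial table from [trials_5csrtt()] (column `class`) with
#'   onset times.
#' @param bin_width_ms Bin width in ms (> 0); default 180000 (3 min).
#' @param duration_ms Session duration; bins tile `[0, duration_ms)`.
#' @return Data frame with one row per bin: `bin`, `t_start_ms`, `t_end_ms`,
#'   `n_trials`, `accuracy`, `pct_omissions`.
#' @export
time_binned_metrics <- function(trials, bin_width_ms = 180000,
                                duration_ms) {
  if (!is.numeric(bin_width_ms) || bin_width_ms <= 0) {
    config_error("`bin_width_ms` must be positive")
  }
  n_bins <- ceiling(duration_ms / bin_width_ms)
  at <- ifelse(is.na(trials$stim_onset_ms), trials$t_start_ms,
               trials$stim_onset_ms)
  bin <- pmin(floor(at / bin_width_ms) + 1L, n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    tr <- trials[which(bin == b), , drop = FALSE]
    nc <- sum(tr$class == "correct"); ni <- sum(tr$class == "incorrect")
    no <- sum(tr$class == "omission")
    data.frame(bin = b, t_start_ms = (b - 1) * bin_width_ms,
               t_end_ms = min(b * bin_width_ms, duration_ms),
               n_trials = nrow(tr),
               accuracy = pct(nc, nc + ni),
               pct_omissions = pct(no, nrow(tr)))
  })
  do.call(rbind, out)
}

#' Chi-square comparison of response-class shares
#'
#' Pearson chi-square on the 2 x 4 table of response-class counts (correct,
#' incorrect, premature, omission) between two conditions, e.g. baseline vs
#' an optogenetic stimulation session. Classes with zero counts in both
#' conditions are pooled out (df reduced accordingly, flagged in the
#' result).
#'
#' @param counts_a,counts_b Non-negative integer vectors of the four class
#'   counts, in the same order.
#' @return List with `statistic`, `df`, `p_value`, `pooled` (dropped class
#'   indices, if any).
#' @export
response_share_test <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    config_error("count vectors must have equal length")
  }
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a != floor(counts_a)) || any(counts_b != floor(counts_b))) {
    config_error("counts must be non-negative integers")
  }
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    config_error("both conditions need at least one response")
  }
  zero_both <- which(counts_a + counts_b == 0)
  keep <- setdiff(seq_along(counts_a), zero_both)
  tab <- rbind(counts_a[keep], counts_b[keep])
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       pooled = zero_both)
}

#' Latency quantiles and histogram per response class
#'
#' @param trials Trial table from [trials_5csrtt()].
#' @param which Latency column to summarise (`"response_latency_ms"` or
#'   `"reward_latency_ms"`).
#' @param breaks Histogram bin edges (ms); default 250-ms bins spanning the
#'   data.
#' @return Data frame with one row per class that has latencies: `n`,
#'   `mean`, `median`, `q25`, `q75`, plus the histogram as an attribute
#'   `histogram` (list of per-class count vectors over `breaks`).
#' @export
latency_summary <- function(trials, which = "response_latency_ms",
                            breaks = NULL) {
  stopifnot(which %in% names(trials))
  lat <- trials[[which]]
  ok <- !is.na(lat)
  if (!any(ok)) {
    out <- data.frame(class = character(0), n = integer(0), mean = numeric(0),
                      median = numeric(0), q25 = numeric(0), q75 = numeric(0))
    attr(out, "histogram") <- list()
    return(out)
  }
  if (is.null(breaks)) {
    top <- 250 * ceiling(max(lat[ok]) / 250)
    breaks <- seq(0, max(250, top), by = 250)
  }
  cls <- split(lat[ok], trials$class[ok])
  out <- do.call(rbind, lapply(names(cls), function(k) {
    x <- cls[[k]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = k, n = length(x), mean = mean(x), median = q[2L],
               q25 = q[1L], q75 = q[3L], stringsAsFactors = FALSE)
  }))
  attr(out, "histogram") <-
    lapply(cls, function(x) {
      as.vector(table(cut(x, breaks = breaks, right = FALSE,
                          include.lowest = TRUE)))
    })
  attr(out, "breaks") <- breaks
  out
}

# ---- summary CSV ---------------------------------------------------------

#' Write session summaries to CSV
#'
#' One row per session, stable column order, full numeric precision, with a
#' `# fivechoice session summary v1` header line.
#'
#' @param summaries A `session_summary`, a data frame of stacked summaries,
#'   or a list of them (same paradigm).
#' @param path Output file path.
#' @param extra_meta Named character vector of additional header metadata.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path, extra_meta = NULL) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L)
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  meta <- "# fivechoice session summary v1"
  if (!is.null(extra_meta)) {
    meta <- c(meta, sprintf("# %s: %s", names(extra_meta),
                            unname(extra_meta)))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read session summaries from CSV
#'
#' @param path File written by [write_summary_csv()].
#' @return Data frame with one row per session.
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
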