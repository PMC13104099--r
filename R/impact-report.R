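#' @title Corpus-level impact, feasibility and accounting summaries
#' @name impact_report
NULL

#' Median and interquartile range
#'
#' Median uses the midpoint convention (mean of the two central order
#' statistics for even n); quartiles use the linear-interpolation convention
#' selected by `type` (default type 7, R's default).
#'
#' @param values Numeric vector, length >= 1.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named numeric vector `(median, q1, q3)`.
#' @export
median_iqr <- function(values, type = 7) {
  if (length(values) < 1L) stop("empty summary: no values", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  c(median = stats::median(values), q1 = q[1], q3 = q[2])
}

#' Retention of eligible trials after the integrity screen
#'
#' Per-unit retained percentage is `100 * after / before`; units with a zero
#' denominator are dropped with a warning. Summaries are median and IQR,
#' overall and optionally stratified by review type.
#'
#' @param reviews Data frame of review records. Needs the before/after
#'   columns named by `before` and `after`, and `review_type` when
#'   stratifying.
#' @param by `"review"` or `"meta_analysis"` selects the default columns
#'   (`n_rcts_included`/`n_no_concern` vs `k_original`/`k_sensitivity`);
#'   `"review_type"` stratifies the meta-analysis-level retention by
#'   `review_type`.
#' @param before,after Optional explicit column names overriding `by`.
#' @return For unstratified calls a named vector from [median_iqr()] plus
#'   `n_units`; for `by = "review_type"` a data frame with one row per
#'   stratum.
#' @export
retention_summary <- function(reviews,
                              by = c("review", "meta_analysis", "review_type"),
                              before = NULL, after = NULL) {
  by <- match.arg(by)
  if (is.null(before)) {
    before <- if (by == "review") "n_rcts_included" else "k_original"
  }
  if (is.null(after)) {
    after <- if (by == "review") "n_no_concern" else "k_sensitivity"
  }
  bef <- reviews[[before]]
  aft <- reviews[[after]]
  keep <- bef > 0
  if (any(!keep)) {
    warning(sum(!keep), " unit(s) with zero denominator dropped")
  }
  pct <- 100 * aft[keep] / bef[keep]
  if (by != "review_type") {
    out <- c(median_iqr(pct), n_units = sum(keep))
    return(out)
  }
  strata <- split(pct, reviews$review_type[keep])
  do.call(rbind, lapply(names(strata), function(s) {
    m <- median_iqr(strata[[s]])
    data.frame(review_type = s, median = m[["median"]], q1 = m[["q1"]],
               q3 = m[["q3"]], n_units = length(strata[[s]]),
               stringsAsFactors = FALSE)
  }))
}

#' Risk-of-bias distribution within integrity-screen strata
#'
#' @param labels Data frame with columns `study_id`, `rob` (one of `low`,
#'   `some_concerns`, `high`) and `ria_pass` (logical).
#' @return Data frame with one row per (stratum, rob category): counts and
#'   within-stratum percentages (1 decimal, round half away from zero).
#'   Empty strata are simply absent.
#' @export
rob_crosstab <- function(labels) {
  if (anyDuplicated(labels$study_id)) {
    stop("duplicate study_id in RoB labels", call. = FALSE)
  }
  cats <- c("low", "some_concerns", "high")
  out <- list()
  for (stratum in c(TRUE, FALSE)) {
    sub <- labels[labels$ria_pass == stratum, , drop = FALSE]
    if (nrow(sub) == 0L) next
    counts <- table(factor(sub$rob, levels = cats))
    pct <- .round_half_away(100 * as.numeric(counts) / nrow(sub), 1)
    out[[length(out) + 1L]] <- data.frame(
      ria_pass = stratum, rob = cats, n = as.integer(counts),
      pct = pct, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-tier assessment-time summary
#'
#' Mean time per domain and the per-tier total (the sum over the six domain
#' means). A tier missing one or more domains gets a total flagged partial.
#'
#' @param logs Data frame with columns `assessor_tier`, `domain` and either
#'   `mean_duration` (seconds per study, one row per tier x domain) or raw
#'   `duration` rows to be averaged.
#' @return List with `per_domain` (data frame `assessor_tier, domain,
#'   mean_seconds, hms`) and `totals` (data frame `assessor_tier,
#'   total_seconds, hms, partial`).
#' @export
feasibility_summary <- function(logs) {
  dur_col <- if ("mean_duration" %in% names(logs)) "mean_duration" else "duration"
  if (any(logs[[dur_col]] < 0)) stop("negative duration", call. = FALSE)
  agg <- stats::aggregate(logs[[dur_col]],
                          by = list(assessor_tier = logs$assessor_tier,
                                    domain = logs$domain),
                          FUN = mean)
  names(agg)[3] <- "mean_seconds"
  agg <- agg[order(agg$assessor_tier, agg$domain), , drop = FALSE]
  agg$hms <- format_hms(agg$mean_seconds)
  totals <- do.call(rbind, lapply(split(agg, agg$assessor_tier), function(g) {
    data.frame(assessor_tier = g$assessor_tier[1],
               total_seconds = sum(g$mean_seconds),
               hms = format_hms(sum(g$mean_seconds)),
               partial = length(unique(g$domain)) < 6L,
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  rownames(agg) <- NULL
  list(per_domain = agg, totals = totals)
}

#' Format seconds as h:mm:ss
#' @param seconds Nonnegative numeric vector.
#' @return Character vector `"hh:mm:ss"` (seconds rounded to integers).
#' @export
format_hms <- function(seconds) {
  s <- round(seconds)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Parse "hh:mm:ss" or "mm:ss" into seconds
#' @param x Character vector.
#' @return Numeric seconds.
#' @export
parse_hms <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE), function(p) {
    p <- as.numeric(p)
    sum(p * 60^(rev(seq_along(p)) - 1))
  }, numeric(1))
}

#' Record-filter accounting
#'
#' Chains removal stages from an initial pool and audits conservation: each
#' stage removes `n_removed` records for `reason`, and the running count may
#' never go negative.
#'
#' @param n_initial Records entering the filter.
#' @param stages Data frame with columns `reason` and `n_removed` (applied
#'   in row order).
#' @return List with `n_final` and `table`, a per-stage audit data frame
#'   (`stage, reason, n_in, n_removed, n_out`).
#' @export
filter_accounting <- function(n_initial, stages) {
  n <- n_initial
  rows <- vector("list", nrow(stages))
  for (i in seq_len(nrow(stages))) {
    removed <- stages$n_removed[i]
    if (removed < 0 || removed > n) {
      stop(sprintf("ledger error at stage %d ('%s'): removing %d from %d",
                   i, stages$reason[i], removed, n), call. = FALSE)
    }
    rows[[i]] <- data.frame(stage = i, reason = stages$reason[i],
                            n_in = n, n_removed = removed,
                            n_out = n - removed, stringsAsFactors = FALSE)
    n <- n - removed
  }
  list(n_final = n, table = do.call(rbind, rows))
}
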