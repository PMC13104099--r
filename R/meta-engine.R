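#' @title Pairwise meta-analysis engine
#' @description
#' Per-trial risk ratios / odds ratios from 2x2 tables and inverse-variance
#' pooling, either fixed-effect or DerSimonian-Laird random-effects, as used
#' for sensitivity re-analyses that drop trials failing the integrity
#' screen.
#' @name meta_engine
NULL

#' Validate and construct a 2x2 trial outcome table
#'
#' @param study_id Study identifier.
#' @param events_int,n_int Events and arm size, intervention arm.
#' @param events_ctl,n_ctl Events and arm size, control arm.
#' @param outcome_name Outcome label.
#' @param patient_relevant Logical; laboratory-only outcomes are not used in
#'   re-analyses.
#' @return A one-row data frame of class `trial_table`.
#' @export
trial_table <- function(study_id, events_int, n_int, events_ctl, n_ctl,
                        outcome_name = "mortality", patient_relevant = TRUE) {
  if (n_int < 1 || n_ctl < 1) stop("arm sizes must be >= 1", call. = FALSE)
  if (events_int < 0 || events_int > n_int ||
      events_ctl < 0 || events_ctl > n_ctl) {
    stop("events must satisfy 0 <= events <= n in each arm", call. = FALSE)
  }
  structure(
    data.frame(study_id = as.character(study_id),
               events_int = events_int, n_int = n_int,
               events_ctl = events_ctl, n_ctl = n_ctl,
               outcome_name = outcome_name,
               patient_relevant = patient_relevant,
               stringsAsFactors = FALSE),
    class = c("trial_table", "data.frame")
  )
}

#' Log-scale effect and standard error for one 2x2 table
#'
#' Risk ratio: `RR = (a/n1) / (c/n2)`, `SE = sqrt(1/a - 1/n1 + 1/c - 1/n2)`.
#' Odds ratio: `OR = ad / bc`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#' If any cell of the table (a, b, c, d) is zero, 0.5 is added to all four
#' cells before estimation. A trial with zero events in both arms carries no
#' information about a ratio effect and is flagged non-estimable.
#'
#' @param events_int,n_int,events_ctl,n_ctl The 2x2 table (a = events_int,
#'   c = events_ctl; non-events are b and d).
#' @param measure `"RR"` or `"OR"`.
#' @return List with `yi` (log effect), `sei`, `estimable`, `corrected`
#'   (whether the continuity correction was applied).
#' @export
trial_effect <- function(events_int, n_int, events_ctl, n_ctl,
                         measure = c("RR", "OR")) {
  measure <- match.arg(measure)
  a <- events_int; c_ <- events_ctl
  b <- n_int - a;  d <- n_ctl - c_
  if (a == 0 && c_ == 0) {
    return(list(yi = NA_real_, sei = NA_real_, estimable = FALSE,
                corrected = FALSE))
  }
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  n1 <- a + b; n2 <- c_ + d
  if (measure == "RR") {
    yi <- log((a / n1) / (c_ / n2))
    sei <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n2)
  } else {
    yi <- log((a * d) / (b * c_))
    sei <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  }
  if (!is.finite(yi) || !is.finite(sei) || sei <= 0) {
    return(list(yi = NA_real_, sei = NA_real_, estimable = FALSE,
                corrected = corrected))
  }
  list(yi = yi, sei = sei, estimable = TRUE, corrected = corrected)
}

#' Pool log-scale effects by inverse variance
#'
#' Fixed-effect: weights `1/v_i`. DerSimonian-Laird random-effects:
#' `Q = sum w_i (y_i - y_fixed)^2`,
#' `tau2 = max(0, (Q - (k - 1)) / (sum w_i - sum w_i^2 / sum w_i))`,
#' then weights `1/(v_i + tau2)`. The 95% CI uses the normal quantile 1.96
#' and is exponentiated to the ratio scale.
#'
#' @param yi Numeric vector of log effects.
#' @param sei Their standard errors.
#' @param method `"random_dl"` (default) or `"fixed_iv"`.
#' @param measure Effect measure label carried through (`"RR"` or `"OR"`).
#' @return Object of class `ria_meta`: `k`, `method`, `measure`, `beta`
#'   (pooled log effect), `se`, `ci_low`/`ci_high` (ratio scale), `point`
#'   (ratio scale), `tau2`, `q_statistic`, `estimable`.
#' @examples
#' eff <- mapply(trial_effect, c(15, 12, 9), 100, c(10, 10, 10), 100,
#'               MoreArgs = list(measure = "RR"), SIMPLIFY = FALSE)
#' meta_pool(sapply(eff, `[[`, "yi"), sapply(eff, `[[`, "sei"))
#' @export
meta_pool <- function(yi, sei, method = c("random_dl", "fixed_iv"),
                      measure = "RR") {
  method <- match.arg(method)
  keep <- is.finite(yi) & is.finite(sei) & sei > 0
  yi <- yi[keep]; sei <- sei[keep]
  k <- length(yi)
  if (k == 0L) {
    return(structure(
      list(k = 0L, method = method, measure = measure, estimable = FALSE,
           beta = NA_real_, se = NA_real_, point = NA_real_,
           ci_low = NA_real_, ci_high = NA_real_,
           tau2 = NA_real_, q_statistic = NA_real_),
      class = "ria_meta"))
  }
  vi <- sei^2
  wf <- 1 / vi
  beta_f <- sum(wf * yi) / sum(wf)
  q <- sum(wf * (yi - beta_f)^2)
  if (method == "fixed_iv" || k == 1L) {
    tau2 <- 0
    w <- wf
  } else {
    denom <- sum(wf) - sum(wf^2) / sum(wf)
    tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
    w <- 1 / (vi + tau2)
  }
  beta <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(
    list(k = k, method = method, measure = measure, estimable = TRUE,
         beta = beta, se = se,
         point = exp(beta),
         ci_low = exp(beta - 1.96 * se),
         ci_high = exp(beta + 1.96 * se),
         tau2 = tau2, q_statistic = q),
    class = "ria_meta")
}

#' @export
print.ria_meta <- function(x, digits = 2, ...) {
  meth <- c(random_dl = "DerSimonian-Laird random-effects",
            fixed_iv = "fixed-effect inverse-variance")[x$method]
  if (!x$estimable) {
    cat(sprintf("Meta-analysis (%s): not estimable (k = %d)\n", meth, x$k))
    return(invisible(x))
  }
  cat(sprintf("Meta-analysis (%s), k = %d trials\n", meth, x$k))
  cat(sprintf("  %s %.*f (95%% CI %.*f to %.*f)\n", x$measure,
              digits, x$point, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  tau^2 = %.4f, Q = %.2f\n", x$tau2, x$q_statistic))
  invisible(x)
}

#' @export
summary.ria_meta <- function(object, ...) print(object, ...)

#' @export
coef.ria_meta <- function(object, ...) c(logeffect = object$beta)

#' @export
confint.ria_meta <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list("logeffect",
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

#' Pool a set of 2x2 tables
#'
#' Convenience wrapper: computes per-trial effects via [trial_effect()] and
#' pools the estimable ones. Double-zero trials drop out.
#'
#' @param tables Data frame with columns `events_int, n_int, events_ctl,
#'   n_ctl` (one row per trial).
#' @inheritParams meta_pool
#' @return An `ria_meta` object; attribute `"n_dropped"` counts
#'   non-contributing trials.
#' @export
pool_tables <- function(tables, method = c("random_dl", "fixed_iv"),
                        measure = c("RR", "OR")) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  eff <- lapply(seq_len(nrow(tables)), function(i) {
    trial_effect(tables$events_int[i], tables$n_int[i],
                 tables$events_ctl[i], tables$n_ctl[i], measure)
  })
  yi <- vapply(eff, `[[`, numeric(1), "yi")
  sei <- vapply(eff, `[[`, numeric(1), "sei")
  res <- meta_pool(yi, sei, method, measure)
  attr(res, "n_dropped") <- sum(!vapply(eff, `[[`, logical(1), "estimable"))
  res
}

#' Sensitivity re-analysis restricted to trials passing the integrity screen
#'
#' @param tables Data frame of 2x2 tables (columns as in [pool_tables()],
#'   plus `study_id`).
#' @param final_assessments List of final `study_assessment` objects covering
#'   every study in `tables`.
#' @inheritParams meta_pool
#' @return An `ria_meta` object with attributes `"excluded_ids"` (studies
#'   dropped by the screen, sorted) and `"k_screened"` = number passing.
#' @export
sensitivity_reanalysis <- function(tables, final_assessments,
                                   method = c("random_dl", "fixed_iv"),
                                   measure = c("RR", "OR")) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  ids <- vapply(final_assessments, `[[`, character(1), "study_id")
  missing <- setdiff(tables$study_id, ids)
  if (length(missing)) {
    stop("unassessed studies in outcome tables: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  overall <- vapply(final_assessments, `[[`, character(1), "overall")
  pass_ids <- ids[overall == "no_concern"]
  keep <- tables$study_id %in% pass_ids
  res <- pool_tables(tables[keep, , drop = FALSE], method, measure)
  attr(res, "excluded_ids") <- sort(unique(tables$study_id[!keep]))
  attr(res, "k_screened") <- sum(keep)
  res
}

#' Select the comparison to re-analyze within a review
#'
#' The comparison with the most trials wins; ties break by total randomized
#' participants, remaining ties by lexicographic comparison id.
#'
#' @param comparisons List of lists, each with `comparison_id`, `n_trials`,
#'   `n_participants`.
#' @return The chosen element.
#' @export
select_comparison <- function(comparisons) {
  if (length(comparisons) == 0L) {
    stop("no comparisons to select from", call. = FALSE)
  }
  ids <- vapply(comparisons, `[[`, character(1), "comparison_id")
  nt <- vapply(comparisons, function(x) as.numeric(x$n_trials), numeric(1))
  np <- vapply(comparisons, function(x) as.numeric(x$n_participants), numeric(1))
  ord <- order(-nt, -np, ids)
  comparisons[[ord[1]]]
}
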