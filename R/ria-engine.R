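#' @title Hierarchical research-integrity assessment engine
#' @description
#' The integrity screen walks six domains in a fixed order: 1 retraction,
#' 2 trial registration, 3 ethics approval / informed consent, 4 study
#' authorship, 5 plausibility of methods, 6 plausibility of study results.
#' At every domain an assessor issues one of three decisions -- `no_concern`,
#' `awaiting` (classification pending, usually author clarification), or
#' `exclude`. In domains 2 and 5 a study can additionally be flagged
#' `non_rct` (a non-randomized study mislabelled as an RCT), which acts as a
#' fourth terminal state parallel to exclusion. Once a terminal verdict is
#' reached, all later domains are `not_assessed`.
#' @name ria_engine
NULL

#' Verdict vocabulary of the integrity screen
#'
#' @return Character vector of the five verdict tokens, in severity order for
#'   the three ratable categories followed by the two bookkeeping states.
#' @export
ria_verdicts <- function() {
  c("no_concern", "awaiting", "exclude", "non_rct", "not_assessed")
}

#' Terminal verdicts that truncate the hierarchical workflow
#' @return Character vector `c("exclude", "non_rct")`.
#' @export
ria_terminal_verdicts <- function() c("exclude", "non_rct")

# domains where a non-RCT flag can be raised (registration and plausibility
# of methods are the only domains that surface randomization status)
.non_rct_domains <- c(2L, 5L)

.check_verdicts <- function(verdicts) {
  if (!is.character(verdicts)) {
    stop("verdicts must be a character vector", call. = FALSE)
  }
  bad <- setdiff(unique(verdicts), ria_verdicts())
  if (length(bad)) {
    stop("unknown verdict token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(verdicts)
}

#' Derive the overall classification from a six-domain verdict vector
#'
#' Walks the domains in order. The first terminal verdict (`exclude` or
#' `non_rct`) decides the overall classification and truncates the
#' assessment; otherwise any `awaiting` verdict makes the study
#' `awaiting`; otherwise the study is `no_concern`.
#'
#' @param verdicts Character vector of verdict tokens in domain order
#'   (see [ria_verdicts()]). Must contain six entries unless a terminal
#'   verdict appears earlier, in which case trailing `not_assessed` entries
#'   may be omitted.
#' @return A list with `overall` (one of `no_concern`, `awaiting`,
#'   `exclude`, `non_rct`) and `truncated_at` (domain index of the first
#'   terminal verdict, or 6L when none).
#' @examples
#' assess_overall(c("no_concern", "exclude", rep("not_assessed", 4)))
#' assess_overall(rep("no_concern", 6))
#' @export
assess_overall <- function(verdicts) {
  .check_verdicts(verdicts)
  n <- length(verdicts)
  terminal <- ria_terminal_verdicts()
  first_terminal <- which(verdicts %in% terminal)[1]
  if (is.na(first_terminal)) {
    if (n < 6L) {
      stop("malformed assessment: fewer than 6 domains without a terminal verdict",
           call. = FALSE)
    }
    if (any(verdicts == "not_assessed")) {
      stop("malformed assessment: 'not_assessed' before any terminal verdict",
           call. = FALSE)
    }
    overall <- if (any(verdicts == "awaiting")) "awaiting" else "no_concern"
    return(list(overall = overall, truncated_at = 6L))
  }
  v <- verdicts[first_terminal]
  if (v == "non_rct" && !(first_terminal %in% .non_rct_domains)) {
    stop("malformed assessment: 'non_rct' may only be raised in domains ",
         paste(.non_rct_domains, collapse = " or "), call. = FALSE)
  }
  if (first_terminal > 1L &&
      any(verdicts[seq_len(first_terminal - 1L)] == "not_assessed")) {
    stop("malformed assessment: 'not_assessed' before the terminal verdict",
         call. = FALSE)
  }
  later <- verdicts[-seq_len(first_terminal)]
  if (length(later) && any(later != "not_assessed")) {
    stop("malformed assessment: domains after a terminal verdict must be 'not_assessed'",
         call. = FALSE)
  }
  list(overall = v, truncated_at = first_terminal)
}

#' Construct a single-assessor study assessment
#'
#' @param study_id Study identifier.
#' @param assessor_id Assessor identifier.
#' @param verdicts Six-domain verdict vector; trailing `not_assessed` after a
#'   terminal verdict are filled in automatically if omitted.
#' @param tier Assessor expertise tier: `"beginner"`, `"intermediate"` or
#'   `"senior"`.
#' @return An object of class `study_assessment`: list with `study_id`,
#'   `assessor_id`, `tier`, `verdicts` (length 6), `overall`, `truncated_at`.
#' @export
study_assessment <- function(study_id, assessor_id, verdicts,
                             tier = c("beginner", "intermediate", "senior")) {
  tier <- match.arg(tier)
  res <- assess_overall(verdicts)
  v <- verdicts
  if (length(v) < 6L) v <- c(v, rep("not_assessed", 6L - length(v)))
  structure(
    list(study_id = as.character(study_id),
         assessor_id = as.character(assessor_id),
         tier = tier,
         verdicts = v,
         overall = res$overall,
         truncated_at = res$truncated_at),
    class = "study_assessment"
  )
}

#' @export
print.study_assessment <- function(x, ...) {
  cat(sprintf("Study %s (assessor %s, %s)\n", x$study_id, x$assessor_id, x$tier))
  cat(sprintf("  domains: %s\n", paste(x$verdicts, collapse = " | ")))
  cat(sprintf("  overall: %s (truncated at domain %d)\n",
              x$overall, x$truncated_at))
  invisible(x)
}

#' Adjudication policy for the third assessor
#'
#' Domains listed in `always_reassess` are re-rated for every study. For the
#' remaining domains the third assessor steps in when the first/second pair
#' is discrepant, both non-`no_concern` (consistent but concerning), only one
#' rating exists, or no rating exists, according to the flags.
#'
#' @param always_reassess Integer domains always re-rated (default 1:3).
#' @param discrepant,consistent_non_no_concern,single_rating,no_rating
#'   Logical flags controlling when domains outside `always_reassess` are
#'   re-rated.
#' @return An object of class `adjudication_policy`.
#' @export
adjudication_policy <- function(always_reassess = 1:3,
                                discrepant = TRUE,
                                consistent_non_no_concern = TRUE,
                                single_rating = TRUE,
                                no_rating = TRUE) {
  always_reassess <- as.integer(always_reassess)
  if (length(always_reassess) && !all(always_reassess %in% 1:6)) {
    stop("always_reassess must be a subset of 1..6", call. = FALSE)
  }
  structure(
    list(always_reassess = sort(unique(always_reassess)),
         discrepant = isTRUE(discrepant),
         consistent_non_no_concern = isTRUE(consistent_non_no_concern),
         single_rating = isTRUE(single_rating),
         no_rating = isTRUE(no_rating)),
    class = "adjudication_policy"
  )
}

# ratable = one of the three ordinal categories (not a bookkeeping state);
# non_rct counts as a rating (terminal) for pairing logic here
.is_rated <- function(v) v != "not_assessed"

#' Adjudicate a pair of assessments with a third assessor
#'
#' @param first,second `study_assessment` objects for the same study from the
#'   first and second assessors.
#' @param third Named character vector of the third assessor's verdicts,
#'   names `"1"`..`"6"` (partial coverage allowed as long as every
#'   policy-required domain is present).
#' @param policy An [adjudication_policy()].
#' @return List with `final` (a `study_assessment` attributed to the third
#'   assessor), and `worklist`, a data frame of `(study_id, domain, reason)`
#'   rows the third assessor had to re-rate, ordered by study then domain.
#' @export
adjudicate <- function(first, second, third, policy = adjudication_policy()) {
  stopifnot(inherits(first, "study_assessment"),
            inherits(second, "study_assessment"))
  if (first$study_id != second$study_id) {
    stop("first and second assessments cover different studies", call. = FALSE)
  }
  if (is.null(names(third)) || !all(names(third) %in% as.character(1:6))) {
    stop("third must be a named vector with domain names in 1..6", call. = FALSE)
  }
  .check_verdicts(unname(third))

  needed <- integer(0)
  reasons <- character(0)
  final <- character(6)
  for (d in 1:6) {
    a <- first$verdicts[d]
    b <- second$verdicts[d]
    if (d %in% policy$always_reassess) {
      take_third <- TRUE
      reason <- "always"
    } else if (.is_rated(a) && .is_rated(b)) {
      if (a != b) {
        take_third <- policy$discrepant
        reason <- "discrepant"
      } else if (a != "no_concern") {
        take_third <- policy$consistent_non_no_concern
        reason <- "consistent_non_no_concern"
      } else {
        take_third <- FALSE
        reason <- ""
      }
    } else if (.is_rated(a) || .is_rated(b)) {
      take_third <- policy$single_rating
      reason <- "single_rating"
    } else {
      take_third <- policy$no_rating
      reason <- "no_rating"
    }
    if (take_third) {
      needed <- c(needed, d)
      reasons <- c(reasons, reason)
      key <- as.character(d)
      if (!key %in% names(third)) {
        stop(sprintf(
          "incomplete adjudication: third assessor missing required domain(s): %s",
          paste(setdiff(needed, as.integer(names(third))), collapse = ", ")),
          call. = FALSE)
      }
      final[d] <- third[[key]]
    } else {
      final[d] <- a  # consistent benign pair: either assessor's verdict
    }
  }

  # re-truncate after the first terminal verdict of the merged vector
  term <- which(final %in% ria_terminal_verdicts())[1]
  if (!is.na(term) && term < 6L) {
    final[(term + 1L):6L] <- "not_assessed"
  }
  # domains never reached by anyone and not re-rated stay not_assessed; that
  # is only coherent after a terminal verdict, which .study_assessment checks
  fin <- study_assessment(first$study_id, "adjudicated", final, tier = "senior")
  worklist <- data.frame(study_id = rep(first$study_id, length(needed)),
                         domain = needed,
                         reason = reasons,
                         stringsAsFactors = FALSE)
  worklist <- worklist[order(worklist$study_id, worklist$domain), ,
                       drop = FALSE]
  rownames(worklist) <- NULL
  list(final = fin, worklist = worklist)
}

#' Apply author-correspondence outcomes to a final assessment
#'
#' Trial authors are queried about every unresolved (`awaiting`) domain and
#' given a response window (default 14 days) plus a reminder extension
#' (default 7 days). A domain flips from `awaiting` to `no_concern` only when
#' a matching query is marked resolved and, if dates are present, the
#' response arrived within the window.
#'
#' @param final A `study_assessment` (post-adjudication).
#' @param queries Data frame with columns `study_id, domain, sent_date,
#'   response_date, resolved`. Dates may be `NA` (then the window check is
#'   skipped and `resolved` alone decides).
#' @param response_window_days,reminder_extension_days Window lengths in
#'   days.
#' @return The updated `study_assessment` with `overall` recomputed.
#' @export
apply_author_responses <- function(final, queries,
                                   response_window_days = 14,
                                   reminder_extension_days = 7) {
  stopifnot(inherits(final, "study_assessment"))
  if (is.null(queries) || nrow(queries) == 0L) return(final)
  q <- queries[queries$study_id == final$study_id, , drop = FALSE]
  if (nrow(q) == 0L) return(final)
  v <- final$verdicts
  window <- response_window_days + reminder_extension_days
  for (i in seq_len(nrow(q))) {
    d <- as.integer(q$domain[i])
    if (is.na(d) || d < 1L || d > 6L) {
      stop("query with invalid domain for study ", final$study_id, call. = FALSE)
    }
    if (v[d] != "awaiting") {
      stop(sprintf(
        "inconsistent state: query for study %s domain %d, but verdict is '%s'",
        final$study_id, d, v[d]), call. = FALSE)
    }
    resolved <- isTRUE(q$resolved[i])
    sent <- q$sent_date[i]
    resp <- q$response_date[i]
    if (resolved && !is.na(sent) && !is.na(resp)) {
      sent <- as.Date(sent); resp <- as.Date(resp)
      if (resp < sent) {
        stop("query response_date precedes sent_date for study ",
             final$study_id, call. = FALSE)
      }
      if (as.numeric(resp - sent) > window) resolved <- FALSE
    }
    if (resolved) v[d] <- "no_concern"
  }
  study_assessment(final$study_id, final$assessor_id, v, tier = final$tier)
}

#' Tabulate final classifications across a corpus
#'
#' @param assessments List of `study_assessment` objects, one per study.
#' @return List with `overall` (named integer vector over the four final
#'   categories), `by_domain` (5 x 6 integer matrix, verdict x domain) and
#'   `n_studies`.
#' @export
classification_summary <- function(assessments) {
  ids <- vapply(assessments, function(a) a$study_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate study_id in assessments: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cats <- c("no_concern", "awaiting", "exclude", "non_rct")
  overall <- stats::setNames(integer(4), cats)
  by_domain <- matrix(0L, nrow = 5L, ncol = 6L,
                      dimnames = list(ria_verdicts(), paste0("domain", 1:6)))
  for (a in assessments) {
    overall[a$overall] <- overall[a$overall] + 1L
    for (d in 1:6) {
      by_domain[a$verdicts[d], d] <- by_domain[a$verdicts[d], d] + 1L
    }
  }
  list(overall = overall, by_domain = by_domain,
       n_studies = length(assessments))
}
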