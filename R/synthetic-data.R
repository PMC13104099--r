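#' @title Synthetic corpus generator
#' @description
#' Generates complete synthetic review corpora -- reviews, trials with
#' binomial 2x2 outcomes, per-domain integrity ground truth, multi-assessor
#' ratings with expertise-dependent confusion, risk-of-bias labels and
#' assessment time logs -- with the statistical structure the pipeline
#' assumes, so every stage runs without external data. Default calibration
#' lives in a versioned YAML file shipped with the package
#' (`inst/extdata/default_calibration.yaml`).
#' @name synthetic_data
NULL

#' Specification of a synthetic corpus
#'
#' Starts from the shipped calibration defaults and overrides any field
#' passed as an argument.
#'
#' @param ... Named overrides of calibration fields (`n_reviews`,
#'   `trials_per_review`, `arm_size`, `control_risk`, `true_log_effect`,
#'   `issue_prevalence`, `author_response`, `assessor_profiles`,
#'   `rob_distribution`, `time_model`).
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(...) {
  path <- system.file("extdata", "default_calibration.yaml",
                      package = "riaimpact")
  spec <- yaml::read_yaml(path)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(spec))
  if (length(unknown)) {
    stop("unknown corpus_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec[names(overrides)] <- overrides
  .validate_spec(spec)
  structure(spec, class = "corpus_spec")
}

.validate_spec <- function(spec) {
  for (d in 1:6) {
    p <- spec$issue_prevalence[[paste0("domain", d)]]
    probs <- unlist(p)
    if (any(probs < 0) || sum(probs) > 1) {
      stop("invalid issue_prevalence for domain ", d, call. = FALSE)
    }
  }
  for (tier in names(spec$assessor_profiles)) {
    m <- .profile_matrix(spec$assessor_profiles[[tier]])
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("assessor profile for ", tier, " is not row-stochastic",
           call. = FALSE)
    }
  }
  if (!is.null(spec$trials_per_review$size) &&
      spec$trials_per_review$size <= 0) {
    stop("invalid trials_per_review dispersion", call. = FALSE)
  }
  invisible(spec)
}

.profile_matrix <- function(rows) {
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(.kappa_categories, .kappa_categories)
  m
}

# deterministic per-unit substream seed so adding a review never perturbs
# earlier reviews' draws (hierarchical stream: corpus -> review -> trial)
.substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic corpus
#'
#' For each trial a true per-domain status vector is drawn from the
#' prevalence spec (honouring hierarchical truncation: sampling stops at the
#' first exclusion or non-RCT status). Each assessor's verdict per domain is
#' drawn from their tier's confusion row given the truth, and each assessor
#' truncates on their own terminal verdicts. 2x2 outcomes are binomial with
#' risk ratio `exp(true_log_effect)`; awaiting domains resolve to no-concern
#' after simulated author correspondence with the per-domain response
#' probabilities.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed; the same spec and seed reproduce the corpus
#'   exactly.
#' @return Object of class `ria_corpus`: list with data frames `reviews`,
#'   `trials` (2x2 outcomes + RoB label), `truth` (per-domain true status and
#'   resolution flags), `assessments` (long format, all three assessors),
#'   `queries`, `time_logs`, and the `spec` and `seed` used.
#' @export
simulate_ria_corpus <- function(spec = corpus_spec(), seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  seed <- as.integer(seed)
  statuses <- c("no_concern", "awaiting", "exclude", "non_rct")
  prev <- lapply(1:6, function(d) {
    p <- spec$issue_prevalence[[paste0("domain", d)]]
    c(exclude = p$exclude, awaiting = p$awaiting, non_rct = p$non_rct)
  })
  resolve_p <- vapply(1:6, function(d) {
    spec$author_response[[paste0("domain", d)]]
  }, numeric(1))
  profiles <- lapply(spec$assessor_profiles, .profile_matrix)
  tiers <- c(assessor_1 = "beginner", assessor_2 = "intermediate",
             assessor_3 = "senior")

  reviews <- data.frame(
    review_id = sprintf("R%02d", seq_len(spec$n_reviews)),
    review_type = ifelse(seq_len(spec$n_reviews) %% 2 == 1,
                         "cochrane", "non_cochrane"),
    true_log_effect = rep_len(unlist(spec$true_log_effect), spec$n_reviews),
    stringsAsFactors = FALSE
  )

  trials <- list(); truth <- list(); assess <- list()
  queries <- list(); times <- list()
  trial_no <- 0L
  for (r in seq_len(spec$n_reviews)) {
    set.seed(.substream(seed, r))
    tpr <- spec$trials_per_review
    k <- max(tpr$min, stats::rnbinom(1, mu = tpr$mu, size = tpr$size))
    for (t in seq_len(k)) {
      trial_no <- trial_no + 1L
      sid <- sprintf("S%04d", trial_no)
      # --- ground truth per domain, honouring truncation
      status <- rep("not_reached", 6L)
      for (d in 1:6) {
        p <- prev[[d]]
        u <- stats::runif(1)
        status[d] <- if (u < p["exclude"]) "exclude"
          else if (u < p["exclude"] + p["non_rct"]) "non_rct"
          else if (u < p["exclude"] + p["non_rct"] + p["awaiting"]) "awaiting"
          else "no_concern"
        if (status[d] %in% c("exclude", "non_rct")) break
      }
      term <- which(status %in% c("exclude", "non_rct"))[1]
      reached <- if (is.na(term)) 6L else term
      # author-correspondence resolution of awaiting domains
      resolved <- rep(FALSE, 6L)
      for (d in seq_len(reached)) {
        if (status[d] == "awaiting") {
          resolved[d] <- stats::runif(1) < resolve_p[d]
          queries[[length(queries) + 1L]] <- data.frame(
            study_id = sid, domain = d,
            sent_date = NA_character_, response_date = NA_character_,
            resolved = resolved[d], stringsAsFactors = FALSE)
        }
      }
      truth[[trial_no]] <- data.frame(
        study_id = sid, review_id = reviews$review_id[r],
        domain = 1:6, status = status, resolved = resolved,
        stringsAsFactors = FALSE)

      # --- assessor verdicts: confusion draw given truth, own truncation
      for (aid in names(tiers)) {
        cm <- profiles[[tiers[[aid]]]]
        verdicts <- rep("not_assessed", 6L)
        for (d in 1:6) {
          true_d <- status[d]
          if (true_d == "not_reached") {
            # truth truncated earlier; if this assessor hasn't truncated,
            # the underlying study is clean from here on
            true_cat <- "no_concern"
          } else {
            true_cat <- if (true_d == "non_rct") "exclude" else true_d
          }
          rated <- sample(.kappa_categories, 1L, prob = cm[true_cat, ])
          if (rated == "exclude" && true_d == "non_rct" &&
              d %in% .non_rct_domains) {
            rated <- "non_rct"
          }
          verdicts[d] <- rated
          if (rated %in% ria_terminal_verdicts()) break
        }
        assess[[length(assess) + 1L]] <- data.frame(
          study_id = sid, assessor_id = aid,
          assessor_tier = tiers[[aid]], domain = 1:6,
          verdict = verdicts, stringsAsFactors = FALSE)
        # time logs for the domains this assessor actually worked on
        worked <- which(verdicts != "not_assessed")
        mu <- spec$time_model[[tiers[[aid]]]][worked]
        sdlog <- spec$time_model$sdlog
        times[[length(times) + 1L]] <- data.frame(
          study_id = sid, assessor_tier = tiers[[aid]], domain = worked,
          duration = stats::rlnorm(length(worked),
                                   meanlog = log(mu) - sdlog^2 / 2,
                                   sdlog = sdlog),
          stringsAsFactors = FALSE)
      }

      # --- binomial 2x2 outcome and RoB label
      as_ <- spec$arm_size
      n_arm <- max(as_$min, round(stats::rlnorm(1, as_$meanlog, as_$sdlog)))
      p_ctl <- spec$control_risk
      p_int <- min(1, p_ctl * exp(reviews$true_log_effect[r]))
      rd <- unlist(spec$rob_distribution)
      trials[[trial_no]] <- data.frame(
        study_id = sid, review_id = reviews$review_id[r],
        comparison_id = "primary", outcome_name = "mortality",
        patient_relevant = TRUE,
        events_int = stats::rbinom(1, n_arm, p_int), n_int = n_arm,
        events_ctl = stats::rbinom(1, n_arm, p_ctl), n_ctl = n_arm,
        rob = sample(names(rd), 1L, prob = rd),
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(reviews = reviews,
         trials = do.call(rbind, trials),
         truth = do.call(rbind, truth),
         assessments = do.call(rbind, assess),
         queries = if (length(queries)) do.call(rbind, queries) else
           data.frame(study_id = character(), domain = integer(),
                      sent_date = character(), response_date = character(),
                      resolved = logical()),
         time_logs = do.call(rbind, times),
         spec = spec, seed = seed),
    class = "ria_corpus")
}

#' @export
print.ria_corpus <- function(x, ...) {
  cat(sprintf("Synthetic review corpus (seed %d)\n", x$seed))
  cat(sprintf("  %d reviews, %d trials, %d assessment rows\n",
              nrow(x$reviews), nrow(x$trials), nrow(x$assessments)))
  invisible(x)
}

#' Convert long-format assessment rows into study_assessment objects
#'
#' @param assessments Long data frame (`study_id, assessor_id,
#'   assessor_tier, domain, verdict`).
#' @param assessor_id Which assessor to extract.
#' @return Named list of [study_assessment()] objects keyed by study id.
#' @export
assessments_as_objects <- function(assessments, assessor_id) {
  sub <- assessments[assessments$assessor_id == assessor_id, , drop = FALSE]
  split_ids <- split(sub, sub$study_id)
  out <- lapply(split_ids, function(g) {
    g <- g[order(g$domain), , drop = FALSE]
    study_assessment(g$study_id[1], assessor_id, g$verdict,
                     tier = g$assessor_tier[1])
  })
  out[order(names(out))]
}

#' Run the full screening pipeline on a corpus
#'
#' Chains adjudication (third assessor re-rates per the policy), author
#' correspondence, and final classification for every study. Closure over
#' the synthetic generator: no external input required.
#'
#' @param corpus An `ria_corpus` (or a list with `assessments` and
#'   `queries` in the same schemas).
#' @param policy An [adjudication_policy()].
#' @return List with `final` (list of final `study_assessment`s),
#'   `worklist` (row-bound adjudication worklists) and `summary`
#'   (classification counts from [classification_summary()]).
#' @export
run_ria_pipeline <- function(corpus, policy = adjudication_policy()) {
  a1 <- assessments_as_objects(corpus$assessments, "assessor_1")
  a2 <- assessments_as_objects(corpus$assessments, "assessor_2")
  a3 <- corpus$assessments[corpus$assessments$assessor_id == "assessor_3", ,
                           drop = FALSE]
  ids <- names(a1)
  finals <- vector("list", length(ids))
  worklists <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sid <- ids[i]
    third_rows <- a3[a3$study_id == sid, , drop = FALSE]
    third <- stats::setNames(third_rows$verdict,
                             as.character(third_rows$domain))
    # the senior re-rates from scratch, so every domain is available even
    # where the senior's own pass truncated: untruncated domains are clean
    third[third == "not_assessed"] <- "no_concern"
    adj <- adjudicate(a1[[sid]], a2[[sid]], third, policy)
    # queries are only actionable for domains the adjudicated assessment
    # left awaiting (a consistent first-round error can hide a concern)
    q <- corpus$queries
    q <- q[q$study_id == sid &
             adj$final$verdicts[q$domain] == "awaiting", , drop = FALSE]
    fin <- apply_author_responses(adj$final, q)
    finals[[i]] <- fin
    worklists[[i]] <- adj$worklist
  }
  names(finals) <- ids
  list(final = finals,
       worklist = do.call(rbind, worklists),
       summary = classification_summary(finals))
}

#' Expected weighted kappa implied by two rater profiles
#'
#' Closed form: the joint rating distribution is
#' `sum_t P(t) row_a(t) (x) row_b(t)`; the weighted kappa of that joint
#' distribution is returned. Used as the analytic oracle for reliability
#' recovery tests.
#'
#' @param profile_a,profile_b 3x3 row-stochastic confusion matrices
#'   (rated category given true category).
#' @param truth_distribution Probability vector over the three true
#'   categories.
#' @param weights `"linear"` or `"unweighted"`.
#' @return The expected kappa (numeric scalar).
#' @export
analytic_kappa <- function(profile_a, profile_b, truth_distribution,
                           weights = c("linear", "unweighted")) {
  weights <- match.arg(weights)
  pa <- if (is.matrix(profile_a)) profile_a else .profile_matrix(profile_a)
  pb <- if (is.matrix(profile_b)) profile_b else .profile_matrix(profile_b)
  pt <- truth_distribution / sum(truth_distribution)
  joint <- matrix(0, 3, 3)
  for (t in 1:3) {
    joint <- joint + pt[t] * outer(pa[t, ], pb[t, ])
  }
  w <- if (weights == "linear") .linear_weights(3L) else diag(3L)
  .kappa_from_matrix(joint, w)$kappa
}
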