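# Deterministic fixture corpora built in code.

# A 206-study final-classification corpus whose per-domain and overall
# counts match the reference screening exercise exactly: 8 retraction
# exclusions (domain 1), 51 registration exclusions + 10 non-RCT flags
# (domain 2), 1 non-RCT flag in domain 5, awaiting flags spread so that 79
# studies end awaiting and 57 clean.
final_classification_fixture <- function() {
  mk <- function(id, verdicts) {
    study_assessment(sprintf("T%03d", id), "final", verdicts, tier = "senior")
  }
  out <- list()
  id <- 0L
  # 136 terminal-free studies; awaiting flags per domain by survivor index
  aw <- list(
    `1` = 65:66,
    `2` = c(1:11, 63:79),
    `3` = 1:62,
    `4` = 57:64,
    `5` = 1:28,
    `6` = 29:56
  )
  for (s in 1:136) {
    v <- rep("no_concern", 6)
    for (d in 1:6) if (s %in% aw[[as.character(d)]]) v[d] <- "awaiting"
    id <- id + 1L
    out[[id]] <- mk(id, v)
  }
  # one non-RCT flagged in domain 5 (clean up to there)
  id <- id + 1L
  out[[id]] <- mk(id, c(rep("no_concern", 4), "non_rct", "not_assessed"))
  # 10 non-RCT flagged in domain 2
  for (i in 1:10) {
    id <- id + 1L
    out[[id]] <- mk(id, c("no_concern", "non_rct", rep("not_assessed", 4)))
  }
  # 51 excluded in domain 2
  for (i in 1:51) {
    id <- id + 1L
    out[[id]] <- mk(id, c("no_concern", "exclude", rep("not_assessed", 4)))
  }
  # 8 excluded in domain 1
  for (i in 1:8) {
    id <- id + 1L
    out[[id]] <- mk(id, c("exclude", rep("not_assessed", 5)))
  }
  out
}

# small three-study 2x2 set with hand-checkable effects
toy_trials <- function() {
  data.frame(
    study_id = c("A", "B", "C"),
    events_int = c(15, 12, 8), n_int = c(100, 120, 80),
    events_ctl = c(10, 18, 9), n_ctl = c(100, 115, 85),
    stringsAsFactors = FALSE
  )
}
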