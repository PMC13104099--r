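test_that("overall classification follows the hierarchical truncation rules", {
  r <- assess_overall(c("no_concern", "exclude", rep("not_assessed", 4)))
  expect_equal(r$overall, "exclude")
  expect_equal(r$truncated_at, 2L)

  r <- assess_overall(rep("no_concern", 6))
  expect_equal(r$overall, "no_concern")
  expect_equal(r$truncated_at, 6L)

  r <- assess_overall(c("no_concern", "awaiting", "awaiting",
                        "no_concern", "no_concern", "no_concern"))
  expect_equal(r$overall, "awaiting")

  r <- assess_overall(c("no_concern", "non_rct", rep("not_assessed", 4)))
  expect_equal(r$overall, "non_rct")
  expect_equal(r$truncated_at, 2L)
})

test_that("malformed verdict vectors are rejected", {
  expect_error(assess_overall(rep("no_concern", 5)), "malformed")
  expect_error(assess_overall(c("no_concern", "not_assessed",
                                rep("no_concern", 4))), "malformed")
  expect_error(assess_overall(c("no_concern", "exclude", "awaiting",
                                rep("not_assessed", 3))), "malformed")
  # non-RCT flags only arise in registration or plausibility-of-methods
  expect_error(assess_overall(c("non_rct", rep("not_assessed", 5))),
               "non_rct")
  expect_error(assess_overall(c("No_Concern", rep("no_concern", 5))),
               "unknown verdict")
})

test_that("verdicts after the first terminal verdict never matter", {
  set.seed(11)
  cats <- c("no_concern", "awaiting", "exclude")
  for (rep_i in 1:200) {
    k <- sample(1:5, 1)
    head <- sample(c("no_concern", "awaiting"), k - 1, replace = TRUE)
    v1 <- c(head, "exclude", rep("not_assessed", 6 - k))
    r1 <- assess_overall(v1)
    expect_equal(r1$overall, "exclude")
    expect_equal(r1$truncated_at, k)
  }
})

test_that("adjudication takes the third assessor where the policy demands", {
  pol <- adjudication_policy()
  a <- study_assessment("S1", "a1", rep("no_concern", 6), "beginner")
  b <- study_assessment("S1", "a2", rep("no_concern", 6), "intermediate")
  third <- setNames(rep("no_concern", 6), 1:6)
  res <- adjudicate(a, b, third, pol)
  expect_equal(res$final$overall, "no_concern")
  # domains 1-3 are always re-rated; benign consistent 4-6 are not
  expect_setequal(res$worklist$domain, 1:3)

  # discrepant registration verdicts: third decides
  a2 <- study_assessment("S1", "a1", rep("no_concern", 6), "beginner")
  b2 <- study_assessment("S1", "a2",
                         c("no_concern", "exclude", rep("not_assessed", 4)),
                         "intermediate")
  third2 <- setNames(c("no_concern", "exclude", rep("no_concern", 4)), 1:6)
  res2 <- adjudicate(a2, b2, third2, pol)
  expect_equal(res2$final$overall, "exclude")
  expect_equal(res2$final$truncated_at, 2L)
  expect_true(2 %in% res2$worklist$domain)

  # consistent non-benign rating in domain 5 goes on the worklist
  va <- c(rep("no_concern", 4), "awaiting", "no_concern")
  a3 <- study_assessment("S1", "a1", va, "beginner")
  b3 <- study_assessment("S1", "a2", va, "intermediate")
  third3 <- setNames(c(rep("no_concern", 4), "no_concern", "no_concern"), 1:6)
  res3 <- adjudicate(a3, b3, third3, pol)
  expect_true(5 %in% res3$worklist$domain)
  expect_equal(res3$final$overall, "no_concern")

  # ...but a consistent benign pair keeps the pair verdict without re-rating
  pol_only_consistent <- adjudication_policy(always_reassess = integer(0))
  res4 <- adjudicate(a, b, setNames(character(0), character(0)),
                     pol_only_consistent)
  expect_equal(res4$final$overall, "no_concern")
  expect_equal(nrow(res4$worklist), 0L)
})

test_that("adjudication errors when the third assessor misses a required domain", {
  a <- study_assessment("S1", "a1", rep("no_concern", 6), "beginner")
  b <- study_assessment("S1", "a2", rep("no_concern", 6), "intermediate")
  third <- setNames(c("no_concern", "no_concern"), 1:2)  # domain 3 missing
  expect_error(adjudicate(a, b, third), "incomplete adjudication")
})

test_that("author responses flip awaiting domains only when resolved in window", {
  fin <- study_assessment("S9", "final",
                          c("no_concern", "no_concern", "awaiting",
                            rep("no_concern", 3)), "senior")
  q_ok <- data.frame(study_id = "S9", domain = 3, sent_date = "2021-03-01",
                     response_date = "2021-03-10", resolved = TRUE)
  expect_equal(apply_author_responses(fin, q_ok)$overall, "no_concern")

  q_late <- transform(q_ok, response_date = "2021-04-15")
  expect_equal(apply_author_responses(fin, q_late)$overall, "awaiting")

  q_unresolved <- transform(q_ok, resolved = FALSE)
  expect_equal(apply_author_responses(fin, q_unresolved)$overall, "awaiting")

  # dates absent: resolved alone decides
  q_nodate <- data.frame(study_id = "S9", domain = 3,
                         sent_date = NA_character_,
                         response_date = NA_character_, resolved = TRUE)
  expect_equal(apply_author_responses(fin, q_nodate)$overall, "no_concern")

  # a second awaiting domain keeps the study awaiting
  fin2 <- study_assessment("S9", "final",
                           c("no_concern", "awaiting", "awaiting",
                             rep("no_concern", 3)), "senior")
  expect_equal(apply_author_responses(fin2, q_ok)$overall, "awaiting")

  # empty query list is the identity
  expect_identical(apply_author_responses(fin, q_ok[0, ]), fin)

  # query against a non-awaiting domain is an inconsistent state
  q_bad <- transform(q_ok, domain = 1)
  expect_error(apply_author_responses(fin, q_bad), "inconsistent state")
})

test_that("classification summary conserves counts and tracks truncation", {
  mk <- function(i, v) study_assessment(paste0("S", i), "f", v, "senior")
  studies <- c(
    lapply(1:3, function(i)
      mk(i, c("no_concern", "exclude", rep("not_assessed", 4)))),
    lapply(4:10, function(i) mk(i, rep("no_concern", 6)))
  )
  s <- classification_summary(studies)
  expect_equal(sum(s$overall), 10)
  expect_equal(unname(s$overall["exclude"]), 3)
  expect_true(s$by_domain["not_assessed", "domain3"] >= 3)

  empty <- classification_summary(list())
  expect_equal(sum(empty$overall), 0)

  dup <- c(studies, studies[1])
  expect_error(classification_summary(dup), "duplicate")
})

test_that("the 206-study fixture reproduces the reference final classification", {
  fx <- final_classification_fixture()
  s <- classification_summary(fx)
  expect_equal(unname(s$overall),
               c(57L, 79L, 59L, 11L))  # no_concern, awaiting, exclude, non_rct
  expect_equal(sum(s$overall), 206L)
  # per-domain marginals
  expect_equal(unname(s$by_domain["exclude", ]), c(8, 51, 0, 0, 0, 0))
  expect_equal(unname(s$by_domain["non_rct", ]), c(0, 10, 0, 0, 1, 0))
  expect_equal(unname(s$by_domain["awaiting", ]), c(2, 28, 62, 8, 28, 28))
  expect_equal(unname(s$by_domain["no_concern", ]),
               c(196, 109, 75, 129, 108, 108))
  expect_equal(unname(s$by_domain["not_assessed", ]), c(0, 8, 69, 69, 69, 70))
})
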