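test_that("weighted kappa matches the brute-force oracle on a fixed table", {
  m <- matrix(c(40, 5, 5,
                 5, 20, 5,
                 5, 5, 10), 3, 3, byrow = TRUE)
  k <- weighted_kappa(m)
  expect_equal(k$kappa, oracle_kappa(m), tolerance = 1e-12)
  expect_equal(k$kappa_unweighted, oracle_kappa(m, weighted = FALSE),
               tolerance = 1e-12)
  expect_equal(k$n, 100)
  expect_equal(k$pct_disagree, 100 * 30 / 100)
})

test_that("asymptotic SE agrees with a 10,000-rep bootstrap within 5%", {
  m <- matrix(c(40, 5, 5,
                 5, 20, 5,
                 5, 5, 10), 3, 3, byrow = TRUE)
  se <- weighted_kappa(m)$se
  se_boot <- oracle_kappa_boot_se(m, reps = 10000, seed = 42)
  expect_lt(abs(se - se_boot) / se_boot, 0.05)
})

test_that("perfect agreement and independence are the fixed points", {
  diag_m <- diag(c(30, 20, 10))
  k <- weighted_kappa(diag_m)
  expect_equal(k$kappa, 1)
  expect_equal(k$pct_disagree, 0)

  marg <- c(30, 20, 10)
  indep <- outer(marg, marg) / sum(marg)  # p_o = p_e by construction
  expect_equal(weighted_kappa(indep)$kappa, 0, tolerance = 1e-12)

  # all mass in one category: kappa undefined
  degenerate <- matrix(0, 3, 3); degenerate[1, 1] <- 50
  expect_error(weighted_kappa(degenerate), "undefined kappa")
})

test_that("kappa is symmetric in the raters and rises when disagreement drops", {
  set.seed(21)
  for (i in 1:50) {
    f <- random_confusion()
    expect_equal(weighted_kappa(f)$kappa, weighted_kappa(t(f))$kappa,
                 tolerance = 1e-12)
    off <- which(row(f) != col(f) & f > 0)
    if (length(off)) {
      cell <- off[sample.int(length(off), 1)]
      g <- f
      g[cell] <- g[cell] - 1
      d <- sample(1:3, 1)
      g[d, d] <- g[d, d] + 1
      k_f <- weighted_kappa(f)$kappa
      k_g <- tryCatch(weighted_kappa(g)$kappa, error = function(e) NA_real_)
      if (!is.na(k_g)) expect_gte(k_g + 1e-12, k_f)
    }
  }
})

test_that("unweighted kappa on a 2-category collapse equals classical Cohen", {
  set.seed(33)
  a <- sample(c("no_concern", "exclude"), 200, replace = TRUE,
              prob = c(0.6, 0.4))
  b <- ifelse(stats::runif(200) < 0.75, a,
              sample(c("no_concern", "exclude"), 200, replace = TRUE))
  pairs <- data.frame(
    rating_a = factor(a, levels = c("no_concern", "exclude")),
    rating_b = factor(b, levels = c("no_concern", "exclude"))
  )
  k <- weighted_kappa(pairs, weights = "unweighted")
  expect_equal(k$kappa, oracle_cohen(a, b), tolerance = 1e-12)
})

test_that("interpretation bands follow the two-decimal rounding rule", {
  expect_equal(interpret_band(0.748), "substantial")
  expect_equal(interpret_band(0.503), "moderate")
  expect_equal(interpret_band(-0.1), "no_agreement")
  expect_equal(interpret_band(0.205), "fair")      # rounds to 0.21
  expect_equal(interpret_band(0.204), "slight")    # rounds to 0.20
  expect_equal(interpret_band(c(0, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61,
                                0.80, 0.81, 1)),
               c("slight", "slight", "fair", "fair", "moderate", "moderate",
                 "substantial", "substantial", "almost_perfect",
                 "almost_perfect"))
})

test_that("pair building respects truncation and tallies missing ratings", {
  mk <- function(id, who, v, tier) study_assessment(id, who, v, tier)
  # A excluded at domain 2; B rated domain 3
  a <- list(mk("S1", "a", c("no_concern", "exclude", rep("not_assessed", 4)),
               "beginner"),
            mk("S2", "a", rep("no_concern", 6), "beginner"))
  b <- list(mk("S1", "b", rep("no_concern", 6), "intermediate"),
            mk("S2", "b", rep("no_concern", 6), "intermediate"))
  bp <- build_pairs(a, b, 3)
  expect_equal(nrow(bp$pairs), 1L)          # only S2 double-rated
  expect_equal(bp$n_one_rating, 1L)         # S1: B only
  expect_equal(bp$n_no_rating, 0L)

  # both excluded at domain 1: later domains have no rating at all
  a2 <- list(mk("S1", "a", c("exclude", rep("not_assessed", 5)), "beginner"))
  b2 <- list(mk("S1", "b", c("exclude", rep("not_assessed", 5)),
                "intermediate"))
  bp2 <- build_pairs(a2, b2, 2)
  expect_equal(nrow(bp2$pairs), 0L)
  expect_equal(bp2$n_no_rating, 1L)

  # non-RCT flags count as exclusions for agreement
  a3 <- list(mk("S1", "a", c("no_concern", "non_rct", rep("not_assessed", 4)),
                "beginner"))
  b3 <- list(mk("S1", "b", c("no_concern", "exclude", rep("not_assessed", 4)),
                "intermediate"))
  bp3 <- build_pairs(a3, b3, 2)
  expect_equal(as.character(bp3$pairs$rating_a), "exclude")
})

test_that("estimated kappa converges to the analytic value of the generating process", {
  p_a <- matrix(c(0.8, 0.15, 0.05,
                  0.1, 0.8, 0.1,
                  0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  p_b <- matrix(c(0.85, 0.1, 0.05,
                  0.15, 0.75, 0.1,
                  0.05, 0.1, 0.85), 3, 3, byrow = TRUE)
  truth_dist <- c(0.5, 0.3, 0.2)
  k_true <- analytic_kappa(p_a, p_b, truth_dist)

  set.seed(7)
  n <- 5000
  truth <- sample(1:3, n, replace = TRUE, prob = truth_dist)
  rate <- function(p, t) {
    vapply(t, function(ti) sample.int(3, 1, prob = p[ti, ]), integer(1))
  }
  cats <- c("no_concern", "awaiting", "exclude")
  pairs <- data.frame(
    rating_a = factor(cats[rate(p_a, truth)], levels = cats),
    rating_b = factor(cats[rate(p_b, truth)], levels = cats)
  )
  k_hat <- weighted_kappa(pairs)
  expect_lt(abs(k_hat$kappa - k_true), 3 * k_hat$se)

  # analytic oracle sanity: identical perfect raters agree perfectly,
  # truth-blind raters have zero chance-corrected agreement
  expect_equal(analytic_kappa(diag(3), diag(3), truth_dist), 1)
  unif <- matrix(1 / 3, 3, 3)
  expect_equal(analytic_kappa(unif, unif, truth_dist), 0, tolerance = 1e-12)
})

test_that("the domain-wise agreement report has the reference layout", {
  set.seed(5)
  corpus <- simulate_ria_corpus(corpus_spec(n_reviews = 10), seed = 5)
  a <- assessments_as_objects(corpus$assessments, "assessor_1")
  b <- assessments_as_objects(corpus$assessments, "assessor_2")
  rep <- agreement_report(a, b)
  expect_equal(rep$domain, c(as.character(1:6), "overall"))
  expect_true(all(c("n_pairs", "n_one_rating", "n_no_rating", "kappa", "se",
                    "weighted_kappa", "band", "pct_disagree") %in% names(rep)))
  n_studies <- length(a)
  expect_true(all(rep$n_pairs + rep$n_one_rating + rep$n_no_rating ==
                    n_studies))
  ok <- !is.na(rep$weighted_kappa)
  expect_true(all(rep$weighted_kappa[ok] >= -1 & rep$weighted_kappa[ok] <= 1))
})
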