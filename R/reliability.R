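#' @title Interrater reliability: linear-weighted Cohen's kappa
#' @description
#' Agreement between two assessors on the three ordered integrity categories
#' (no concern < awaiting classification < exclude). Linear weights give
#' partial credit to near-miss disagreements; the asymptotic standard error
#' follows the large-sample weighted-kappa variance of Fleiss, Cohen and
#' Everitt.
#' @name reliability
NULL

.kappa_categories <- c("no_concern", "awaiting", "exclude")

# map a raw verdict to the three-category ordinal scale used for agreement;
# a non-RCT flag is a form of exclusion for reliability purposes
.to_category <- function(v) {
  v[v == "non_rct"] <- "exclude"
  ifelse(v %in% .kappa_categories, v, NA_character_)
}

#' Build rating pairs for one domain from two assessors' corpora
#'
#' A pair is emitted only when both assessors produced one of the three
#' ratable categories for that domain (non-RCT flags count as exclusions).
#' Studies where exactly one assessor rated the domain (the other having
#' truncated earlier) are tallied as one-rating; studies rated by neither
#' as no-rating.
#'
#' @param a,b Lists of `study_assessment` objects covering the same corpus.
#' @param domain Domain index 1-6.
#' @return List with `pairs` (data frame `study_id, rating_a, rating_b`,
#'   factor ratings on the ordinal scale), `n_one_rating`, `n_no_rating`.
#' @export
build_pairs <- function(a, b, domain) {
  stopifnot(domain %in% 1:6)
  ids_a <- vapply(a, `[[`, character(1), "study_id")
  ids_b <- vapply(b, `[[`, character(1), "study_id")
  common <- intersect(ids_a, ids_b)
  va <- vapply(a[match(common, ids_a)],
               function(x) x$verdicts[domain], character(1))
  vb <- vapply(b[match(common, ids_b)],
               function(x) x$verdicts[domain], character(1))
  ca <- .to_category(va)
  cb <- .to_category(vb)
  both <- !is.na(ca) & !is.na(cb)
  one <- xor(!is.na(ca), !is.na(cb))
  pairs <- data.frame(
    study_id = common[both],
    rating_a = factor(ca[both], levels = .kappa_categories),
    rating_b = factor(cb[both], levels = .kappa_categories),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       n_one_rating = sum(one),
       n_no_rating = sum(!both & !one))
}

.linear_weights <- function(k = 3L) {
  i <- matrix(seq_len(k), k, k)
  1 - abs(i - t(i)) / (k - 1)
}

.kappa_from_matrix <- function(f, w) {
  n <- sum(f)
  p <- f / n
  po <- sum(w * p)
  r <- rowSums(p); s <- colSums(p)
  pe <- sum(w * outer(r, s))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("undefined kappa: expected agreement is 1 (all mass in one category)",
         call. = FALSE)
  }
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

# large-sample SE of (weighted) kappa, Fleiss-Cohen-Everitt form
.kappa_se <- function(f, w) {
  n <- sum(f)
  p <- f / n
  r <- rowSums(p); s <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, s))
  wbar_row <- as.vector(w %*% s)    # E_j[w_ij] over B's marginal, per row i
  wbar_col <- as.vector(t(w) %*% r) # E_i[w_ij] over A's marginal, per col j
  term <- outer(wbar_row, wbar_col, function(x, y) x + y)
  inner <- sum(p * (w * (1 - pe) - term * (1 - po))^2)
  v <- (inner - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  sqrt(max(v, 0))
}

#' Weighted Cohen's kappa for two raters on ordered categories
#'
#' Fits the chance-corrected agreement statistic from paired ratings (or a
#' 3x3 confusion matrix), with linear weights `w_ij = 1 - |i - j| / (k - 1)`
#' by default. Returns both the unweighted and the weighted coefficient, the
#' asymptotic standard error of the requested one, the percentage of raw
#' disagreements and the verbal interpretation band.
#'
#' @param pairs Either the data frame of pairs from [build_pairs()] (columns
#'   `rating_a`, `rating_b` as factors on a shared ordinal scale) or a square
#'   numeric confusion matrix of counts (rows = rater A, columns = rater B).
#' @param weights `"linear"` (default) or `"unweighted"`.
#' @return An object of class `ria_kappa`: `n`, `confusion`, `p_observed`,
#'   `p_expected`, `kappa_unweighted`, `kappa_weighted`, `kappa` (the one
#'   selected by `weights`), `se`, `band`, `pct_disagree`, `weights`.
#' @examples
#' m <- matrix(c(40, 5, 5, 5, 20, 5, 5, 5, 10), 3, 3, byrow = TRUE)
#' weighted_kappa(m)
#' @export
weighted_kappa <- function(pairs, weights = c("linear", "unweighted")) {
  weights <- match.arg(weights)
  if (is.matrix(pairs)) {
    f <- pairs
    if (nrow(f) != ncol(f)) stop("confusion matrix must be square", call. = FALSE)
  } else {
    stopifnot(is.data.frame(pairs), all(c("rating_a", "rating_b") %in% names(pairs)))
    if (nrow(pairs) < 1L) stop("need at least one rating pair", call. = FALSE)
    f <- table(pairs$rating_a, pairs$rating_b)
    f <- unclass(as.matrix(f))
  }
  k <- nrow(f)
  n <- sum(f)
  w_id <- diag(k)
  w_lin <- .linear_weights(k)
  w <- if (weights == "linear") w_lin else w_id
  res <- .kappa_from_matrix(f, w)
  res_u <- tryCatch(.kappa_from_matrix(f, w_id)$kappa, error = function(e) NA_real_)
  res_l <- tryCatch(.kappa_from_matrix(f, w_lin)$kappa, error = function(e) NA_real_)
  structure(
    list(n = n,
         confusion = f,
         weights = weights,
         p_observed = res$po,
         p_expected = res$pe,
         kappa_unweighted = res_u,
         kappa_weighted = res_l,
         kappa = res$kappa,
         se = .kappa_se(f, w),
         band = interpret_band(res$kappa),
         pct_disagree = 100 * (n - sum(diag(f))) / n),
    class = "ria_kappa"
  )
}

#' @export
print.ria_kappa <- function(x, digits = 3, ...) {
  cat(sprintf("Cohen's kappa (%s weights), %d rating pairs\n",
              x$weights, x$n))
  cat(sprintf("  kappa = %.*f (SE %.*f), interpretation: %s\n",
              digits, x$kappa, digits, x$se, gsub("_", " ", x$band)))
  cat(sprintf("  observed agreement %.*f, expected %.*f, disagreements %.1f%%\n",
              digits, x$p_observed, digits, x$p_expected, x$pct_disagree))
  invisible(x)
}

#' @export
summary.ria_kappa <- function(object, ...) {
  print(object, ...)
  cat("\nConfusion matrix (rows = rater A):\n")
  print(object$confusion)
  invisible(object)
}

#' @export
coef.ria_kappa <- function(object, ...) {
  c(kappa = object$kappa, se = object$se)
}

#' Verbal interpretation band for a kappa value
#'
#' Bands follow the conventional two-decimal closed ranges: below 0 no
#' agreement, 0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect. The coefficient is
#' rounded half-away-from-zero to two decimals before banding, so 0.205
#' lands in "fair".
#'
#' @param kappa Numeric in \[-1, 1\] (vectorized).
#' @return Character vector of band labels.
#' @export
interpret_band <- function(kappa) {
  stopifnot(all(kappa >= -1 - 1e-9 & kappa <= 1 + 1e-9))
  r <- sign(kappa) * floor(abs(kappa) * 100 + 0.5) / 100
  cut_labels <- c("no_agreement", "slight", "fair", "moderate",
                  "substantial", "almost_perfect")
  idx <- findInterval(r, c(-Inf, 0, 0.205, 0.405, 0.605, 0.805))
  # findInterval on rounded values: r < 0 -> 1, 0<=r<=0.20 -> 2, etc.
  cut_labels[idx]
}

#' Domain-by-domain agreement report for two assessors
#'
#' One row per domain plus an overall row (agreement on the overall
#' classification, with non-RCT mapped to exclude), mirroring the layout of
#' a standard interrater-agreement table.
#'
#' @param a,b Lists of `study_assessment` objects for the two assessors.
#' @return Data frame with columns `domain, n_pairs, n_one_rating,
#'   n_no_rating, n_agree, n_disagree, pct_disagree, kappa, se,
#'   weighted_kappa, band`.
#' @export
agreement_report <- function(a, b) {
  rows <- vector("list", 7L)
  for (d in 1:6) {
    bp <- build_pairs(a, b, d)
    rows[[d]] <- .agreement_row(as.character(d), bp$pairs,
                                bp$n_one_rating, bp$n_no_rating)
  }
  ov <- data.frame(
    study_id = vapply(a, `[[`, character(1), "study_id"),
    rating_a = factor(.to_category(vapply(a, `[[`, character(1), "overall")),
                      levels = .kappa_categories),
    rating_b = factor(.to_category(vapply(b, `[[`, character(1), "overall")),
                      levels = .kappa_categories)
  )
  rows[[7L]] <- .agreement_row("overall", ov, 0L, 0L)
  do.call(rbind, rows)
}

.agreement_row <- function(label, pairs, n_one, n_no) {
  n <- nrow(pairs)
  if (n >= 1L) {
    kk <- weighted_kappa(pairs, "linear")
    agree <- sum(as.integer(pairs$rating_a) == as.integer(pairs$rating_b))
    data.frame(domain = label, n_pairs = n, n_one_rating = n_one,
               n_no_rating = n_no, n_agree = agree, n_disagree = n - agree,
               pct_disagree = 100 * (n - agree) / n,
               kappa = kk$kappa_unweighted, se = kk$se,
               weighted_kappa = kk$kappa_weighted, band = kk$band,
               stringsAsFactors = FALSE)
  } else {
    data.frame(domain = label, n_pairs = 0L, n_one_rating = n_one,
               n_no_rating = n_no, n_agree = 0L, n_disagree = 0L,
               pct_disagree = NA_real_, kappa = NA_real_, se = NA_real_,
               weighted_kappa = NA_real_, band = NA_character_,
               stringsAsFactors = FALSE)
  }
}
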