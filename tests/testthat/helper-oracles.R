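# Independent oracles used across the suite. These deliberately re-derive
# every quantity by explicit loops / brute force and never call the package
# functions they check.

# weighted kappa by explicit double loop over cells
oracle_kappa <- function(f, weighted = TRUE) {
  k <- nrow(f)
  n <- sum(f)
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (weighted) 1 - abs(i - j) / (k - 1) else as.numeric(i == j)
      po <- po + w * f[i, j] / n
      pe <- pe + w * (sum(f[i, ]) / n) * (sum(f[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

# classical unweighted Cohen kappa from raw pair vectors
oracle_cohen <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(a, b)))
  f <- table(factor(a, lev), factor(b, lev))
  po <- sum(diag(f)) / sum(f)
  pe <- sum(rowSums(f) * colSums(f)) / sum(f)^2
  (po - pe) / (1 - pe)
}

# bootstrap SE of the weighted kappa of a count matrix (multinomial
# resampling of the n pairs)
oracle_kappa_boot_se <- function(f, reps = 10000, seed = 1) {
  set.seed(seed)
  n <- sum(f)
  p <- as.vector(f) / n
  draws <- stats::rmultinom(reps, n, p)
  ks <- apply(draws, 2, function(v) {
    m <- matrix(v, nrow(f), ncol(f))
    tryCatch(oracle_kappa(m), error = function(e) NA_real_)
  })
  stats::sd(ks, na.rm = TRUE)
}

# DerSimonian-Laird pooling, step by step
oracle_dl <- function(yi, vi) {
  w <- 1 / vi
  beta_f <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - beta_f)^2)
  k <- length(yi)
  tau2 <- if (k > 1) {
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  } else 0
  wr <- 1 / (vi + tau2)
  beta <- sum(wr * yi) / sum(wr)
  list(beta = beta, se = sqrt(1 / sum(wr)), tau2 = tau2, q = q)
}

# fixed-effect inverse-variance pooling
oracle_fixed <- function(yi, vi) {
  w <- 1 / vi
  list(beta = sum(w * yi) / sum(w), se = sqrt(1 / sum(w)))
}

random_confusion <- function(n_max = 50) {
  repeat {
    f <- matrix(stats::rpois(9, lambda = 3), 3, 3)
    if (sum(f) >= 2 && sum(f) <= n_max && sum(f > 0) >= 2) {
      return(f)  # at least two occupied cells, so p_e < 1
    }
  }
}
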