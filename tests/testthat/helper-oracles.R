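# Independent brute-force reference implementations used as oracles.
# These translate the definitions directly (explicit loop over templates)
# and share no code with the package's vectorized implementations.

oracle_sampen <- function(x, m, r_frac) {
  r <- r_frac * sd(x)
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_fuzzyen <- function(x, m, r_frac, p = 2) {
  r <- r_frac * sd(x)
  n <- length(x)
  N <- n - m
  phi <- function(len) {
    tot <- 0
    for (i in 1:(N - 1)) {
      ti <- x[i:(i + len - 1)]; ti <- ti - mean(ti)
      for (j in (i + 1):N) {
        tj <- x[j:(j + len - 1)]; tj <- tj - mean(tj)
        tot <- tot + exp(-(max(abs(ti - tj)) / r)^p)
      }
    }
    2 * tot / (N * (N - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Reverse an RR series in time (intervals and flags reversed).
rev_rr <- function(series) {
  rr_series(rev(series$rr_ms), valid = rev(series$valid))
}

# Detector scoring against planted beat times.
match_beats <- function(detected, truth, tol_s = 0.05) {
  used <- rep(FALSE, length(truth))
  tp <- 0
  for (d in detected) {
    k <- which(!used & abs(truth - d) <= tol_s)
    if (length(k) > 0) {
      used[k[1]] <- TRUE
      tp <- tp + 1
    }
  }
  list(precision = tp / length(detected), recall = tp / length(truth))
}
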