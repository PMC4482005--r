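# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-element loops, exhaustive enumeration) and share
# no code with the package internals they check.

# Single CWT coefficient by direct summation: interpolate the wavelet
# sample-by-sample, re-center over the window, normalize, sum.
oracle_cwt_coeff <- function(window, wav, a, b,
                             norm = c("inverse_sqrt_scale", "inverse_scale")) {
  norm <- match.arg(norm)
  L <- length(window)
  r <- numeric(L)
  for (t in 0:(L - 1)) {
    u <- (t - b) / a + 0.5
    r[t + 1] <- if (u < 0 || u > 1) 0 else
      stats::approx(wav$x, wav$psi, xout = u)$y
  }
  r <- r - mean(r)
  fac <- if (norm == "inverse_sqrt_scale") 1 / sqrt(sum(r^2)) else 1 / a
  fac * sum(window * r)
}

# Mann-Whitney AUC with half credit for ties (exhaustive pair count).
oracle_auc <- function(scores, is_fall) {
  pos <- scores[is_fall]; neg <- scores[!is_fall]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Best achievable Youden index by exhaustive threshold enumeration
# (rule: fall iff score > threshold).
oracle_max_yi <- function(scores, is_fall) {
  th <- c(-Inf, sort(unique(scores)))
  best <- -Inf
  for (q in th) {
    sens <- mean(scores[is_fall] > q)
    spec <- mean(scores[!is_fall] <= q)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Exact two-sided signed-rank p-value by full enumeration of all 2^m sign
# assignments (zeros dropped, mid-ranks).
oracle_signrank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w + -1e-9)))
}

# A quiet 1 g recording of `n` samples with a given SV segment embedded
# starting at 1-based index `at`.
embed_sv <- function(segment, n = 6000, at = 2901, fs = 100) {
  sv <- rep(1, n)
  sv[seq(at, length.out = length(segment))] <- segment
  sv_series(sv, fs)
}

# Small cached synthetic dataset so several test files can share one.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(n_falls = 12, n_adls = 15,
                                            seed = 421))
    cache
  }
})

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
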