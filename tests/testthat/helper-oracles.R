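# Independent oracles used across tests. These deliberately avoid the
# package's own vectorized code paths: plain loops, direct definitions.

# Exhaustive Otsu search over an n_bins histogram: for every candidate
# split, compute the two classes' weights and mean bin centers with
# explicit loops and score the between-class variance.
oracle_otsu <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf
  best_k <- NA_integer_
  for (k in 1:(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(centers[bin[lo]])
    mu1 <- mean(centers[bin[!lo]])
    score <- n0 * n1 * (mu0 - mu1)^2
    if (score > best) {   # first maximum wins: lowest-split tie-break
      best <- score
      best_k <- k
    }
  }
  edges[best_k + 1L]
}

# Per-value exhaustive Otsu: candidate thresholds are the observed
# values; classes are x <= t vs x > t.
oracle_otsu_exact <- function(x) {
  vals <- sort(unique(x))
  best <- -Inf
  best_t <- NA_real_
  for (t in vals[-length(vals)]) {
    lo <- x <= t
    score <- sum(lo) * sum(!lo) * (mean(x[lo]) - mean(x[!lo]))^2
    if (score > best) {
      best <- score
      best_t <- t
    }
  }
  best_t
}

# All-pairs brute-force Euclidean distance transform.
oracle_distance <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      out[r, cc] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2))
    }
  }
  out * pixel_size_um
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups; U is computed by direct pair
# counting (ties count one half).
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  count_u <- function(g1, g2) {
    u <- 0
    for (x in g1) for (y in g2) {
      u <- u + (x > y) + 0.5 * (x == y)
    }
    u
  }
  u_obs <- count_u(a, b)
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(i) count_u(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
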