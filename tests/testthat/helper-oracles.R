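# Independent brute-force oracles used to cross-check package code.

# Benjamini-Hochberg step-up from its definition: sort ascending,
# p_(k) * m / k, enforce monotone non-increase from the largest rank,
# cap at 1, restore input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive O(L^2) evaluation of every contiguous window of the Mott
# score, with the tie rule: highest score, then leftmost start, then
# longest window. Returns c(start, end) as 0-based half-open indices
# (c(0, 0) when no window has positive score).
brute_mott_window <- function(quals, cutoff = 40) {
  s <- 10^(-cutoff / 10) - 10^(-quals / 10)
  L <- length(s)
  prefix <- c(0, cumsum(s))  # shared scoring representation; the
  best <- 0                  # exhaustive window enumeration is the oracle
  best_se <- c(0L, 0L)
  for (st in seq_len(L)) {
    for (en in st:L) {
      acc <- prefix[en + 1L] - prefix[st]
      better <- acc > best ||
        (acc == best && best > 0 &&
           (st - 1L < best_se[1] ||
              (st - 1L == best_se[1] && en > best_se[2])))
      if (better) {
        best <- acc
        best_se <- c(st - 1L, en)
      }
    }
  }
  if (best <= 0) c(0L, 0L) else best_se
}

# Fixed-step Euler integrator for gLV batch dynamics (pairwise only).
euler_glv <- function(r, A, n0, days, dt = 1e-4) {
  N <- n0
  steps <- round(days / dt)
  for (i in seq_len(steps)) {
    N <- N + dt * N * (r + as.vector(A %*% N))
    N <- pmax(N, 0)
  }
  N
}

# Random synthetic Sanger-style read with quality structure typical of
# chromatograms: poor ends, a better middle, plus noise.
random_quality_read <- function(id, len = 60, with_peaks = FALSE) {
  pos <- seq_len(len)
  base_q <- 15 + 35 * exp(-((pos - len / 2) / (len / 3))^2)
  quals <- pmax(0L, as.integer(round(base_q + rnorm(len, 0, 12))))
  bases <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  peaks <- NULL
  if (with_peaks) {
    primary <- round(runif(len, 200, 1000))
    secondary <- round(primary * runif(len, 0, 0.6))
    peaks <- data.frame(position = pos, primary = primary,
                        secondary = secondary)
  }
  quality_read(id, bases, quals, peaks)
}

# Small two-species parameter set used across simulator tests.
two_species_params <- function() {
  glv_params(r = c(0.8, 1.0),
             A = rbind(c(-0.8 / 4e8, -0.2 * 0.8 / 4e8),
                       c(-0.25 * 1.0 / 6e8, -1.0 / 6e8)),
             species = c("spA", "spB"))
}
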