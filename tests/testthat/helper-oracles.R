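# Independent brute-force oracles used to validate the package implementations.
# These deliberately share no code with the functions they check.

# longest run of missing (FALSE) slots by explicit scan
oracle_longest_gap <- function(mask) {
  best <- 0L
  run <- 0L
  for (m in mask) {
    run <- if (!m) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# BH step-up rejections by explicit enumeration over all k
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kstar <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kstar <- k
  rej <- logical(m)
  if (kstar > 0) rej[o[seq_len(kstar)]] <- TRUE
  rej
}

# exact K-medoids optimum by enumerating all medoid subsets
oracle_pam_cost <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  best <- Inf
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, sub, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# Davies-Bouldin straight from its definition, scalar loops
oracle_db <- function(x, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  cent <- lapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE]))
  S <- sapply(seq_len(k), function(i) {
    rows <- x[labels == ks[i], , drop = FALSE]
    mean(apply(rows, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  })
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / k
}

# vectorized log-rank statistic for permutation nulls: risk sets are fixed,
# only the group labels vary, so precompute indicator matrices once
perm_logrank_chisq <- function(time, event, G) {
  ut <- sort(unique(time[event == 1]))
  atrisk <- outer(ut, time, function(t, s) as.numeric(s >= t))   # u x n
  dmat <- sweep(outer(ut, time, "==") * 1, 2, event, "*")        # death indicators
  N <- rowSums(atrisk)
  d <- rowSums(dmat)
  G <- as.matrix(G)
  N1 <- atrisk %*% G            # u x B
  D1 <- dmat %*% G
  E <- d * N1 / N
  V <- d * (N1 / N) * (1 - N1 / N) * (N - d) / pmax(N - 1, 1)
  V[N <= 1, ] <- 0
  OE <- colSums(D1 - E)
  Vs <- colSums(V)
  ifelse(Vs > 0, OE^2 / Vs, 0)
}

# small survival fixture with distinct event times, used in several tests
surv_fixture <- function() {
  data.frame(time = 1:6,
             event = rep(1L, 6),
             group = c(1L, 1L, 0L, 1L, 0L, 0L))
}
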