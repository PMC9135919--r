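# Independent brute-force oracles used to cross-check the package
# implementations, written deliberately naively.

# BH step-up, textbook form: p_(i) * m / i, cumulative minimum from the top,
# capped at 1, mapped back to the original order.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# node connectivity as an explicit double loop over absolute weights
bruteConnectivity <- function(A) {
  P <- nrow(A)
  chi <- numeric(P)
  for (i in seq_len(P))
    for (j in seq_len(P))
      if (i != j) chi[i] <- chi[i] + abs(A[i, j])
  chi
}

# CLR scores by explicit per-edge loops
bruteCLR <- function(R) {
  P <- nrow(R)
  s <- abs(R)
  diag(s) <- 0
  out <- matrix(0, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i == j) next
      zi <- rowZ(s, i, j)
      zj <- rowZ(s, j, i)
      out[i, j] <- sqrt(zi^2 + zj^2)
    }
  }
  out
}

rowZ <- function(s, i, j) {
  bg <- s[i, -i]
  mu <- mean(bg)
  sd <- sqrt(mean((bg - mu)^2))
  if (sd == 0) return(0)
  max(0, (s[i, j] - mu) / sd)
}

# random symmetric weighted adjacency with zero diagonal, |weights| <= 1
randomAdjacency <- function(P) {
  A <- matrix(runif(P * P, -1, 1), P, P)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# null two-group cohort on the log scale (independent features)
nullCohortPair <- function(n, P, seed) {
  spec <- cohortSpec(nPerGroup = c(n, n), P = P, M = 4, nBlocks = 0,
                     withinBlockRho = 0, missingRate = 0, seed = seed)
  ch <- generateCohort(spec)
  list(A = log(ch$concentrations$A), B = log(ch$concentrations$B))
}
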