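# Independent oracles used across the suite.  These deliberately favour the
# most literal, brute-force formulation over efficiency so that they share no
# code path with the package implementation.

randomPeptides <- function(n, L = 9) {
  vapply(seq_len(n),
         function(i) paste(sample(aminoAcids(), L, replace = TRUE),
                           collapse = ""),
         character(1))
}

# direct substring enumeration of the weighted degree kernel definition
naiveWDKernel <- function(s1, s2, d) {
  L <- nchar(s1)
  beta <- 2 * (d - seq_len(d) + 1) / (d * (d + 1))
  total <- 0
  for (p in seq_len(d)) {
    for (l in seq_len(L - p + 1)) {
      if (substr(s1, l, l + p - 1) == substr(s2, l, l + p - 1))
        total <- total + beta[p]
    }
  }
  total
}

# pairwise enumeration of the Mann-Whitney AUC, ties counted half
naiveAUC <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# textbook confusion-matrix metrics
naiveACC <- function(cnt) (cnt[["TP"]] + cnt[["TN"]]) / sum(cnt)
naiveMCC <- function(cnt) {
  TP <- cnt[["TP"]]; TN <- cnt[["TN"]]; FP <- cnt[["FP"]]; FN <- cnt[["FN"]]
  den <- sqrt(TP + FN) * sqrt(TP + FP) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / den
}

# SVM dual objective in minimization form: 0.5 a'Qa - e'a, Q = (y y') * K
dualObjectiveOf <- function(alpha, K, y) {
  v <- alpha * y
  0.5 * as.numeric(t(v) %*% K %*% v) - sum(alpha)
}

# brute-force dual maximization by random pairwise coordinate ascent under
# the box and equality constraints; adequate for tiny problems
dualOracle <- function(K, y, C, iters = 100000) {
  n <- length(y)
  a <- rep(0, n)
  for (it in seq_len(iters)) {
    ij <- sample.int(n, 2L)
    i <- ij[1L]; j <- ij[2L]
    q <- K[i, i] + K[j, j] - 2 * y[i] * y[j] * K[i, j]
    if (q < 1e-12) next
    G <- y[c(i, j)] * as.vector(K[c(i, j), ] %*% (a * y)) - 1
    if (y[i] != y[j]) {
      delta <- (-G[1L] - G[2L]) / q
      lo <- max(-a[i], -a[j]); hi <- min(C - a[i], C - a[j])
      delta <- min(max(delta, lo), hi)
      a[i] <- a[i] + delta; a[j] <- a[j] + delta
    } else {
      delta <- (G[2L] - G[1L]) / q
      lo <- max(-a[i], a[j] - C); hi <- min(C - a[i], a[j])
      delta <- min(max(delta, lo), hi)
      a[i] <- a[i] + delta; a[j] <- a[j] - delta
    }
  }
  a
}

# planted-rule dataset shared by several files
makeRuleData <- function(n = 200, seed = 42, pos = 4, res = "G") {
  generateDataset(n %/% 2, n - n %/% 2, mode = "deterministic",
                  rule = c(position = pos, residue = res), seed = seed)
}
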