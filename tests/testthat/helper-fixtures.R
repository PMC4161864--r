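# Shared fixture builders and independent oracles.

# small labelled experiment from a seeded random matrix
makeMe <- function(n = 6L, m = 8L, seed = 1L,
                   labels = rep(c("control", "patient"), each = m / 2)) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n * m, mean = 5, sd = 2), n, m,
                dimnames = list(sprintf("hsa-miR-t%02d", seq_len(n)),
                                sprintf("s%02d", seq_len(m))))
  })
  MirnaExperiment(v, labels = labels)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Benjamini-Hochberg step-up by direct definition: reject the largest j
# with p_(j) <= j*q/n; adjusted p_i = min over j >= rank(i) of
# n*p_(j)/j, capped at 1.
bhStepUpOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  run <- rev(cummin(rev(sorted * n / seq_len(n))))
  adj[o] <- pmin(run, 1)
  adj
}

# two-sided Fisher exact p by full hypergeometric enumeration of all
# tables with the observed margins
fisherEnumOracle <- function(TP, FN, TN, FP) {
  m1 <- TP + FN          # patients (first margin)
  n2 <- TN + FP          # controls
  k <- TP + FP           # predicted patients
  support <- max(0L, k - n2):min(k, m1)
  probs <- stats::dhyper(support, m1, n2, k)
  pObs <- stats::dhyper(TP, m1, n2, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Mann-Whitney AUC by explicit pair counting (ties half credit)
aucPairOracle <- function(scores, labels) {
  pat <- scores[labels == "patient"]; ctl <- scores[labels == "control"]
  tot <- 0
  for (a in pat) for (b in ctl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pat) * length(ctl))
}
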