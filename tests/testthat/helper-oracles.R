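# Independent brute-force oracles used by the property suites. These stay
# deliberately naive (all-pairs counts, exhaustive enumeration) so they are
# independent of the package's rank-based implementations.

# AUC as the all-pairs Mann-Whitney probability, ties counted one half
auc_bruteforce <- function(values, labels) {
  x1 <- values[labels]
  x0 <- values[!labels]
  total <- 0
  for (a in x1) for (b in x0)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x1) * length(x0))
}

# Youden maximization by exhaustive loop with the package's tie-break rule
# (max J, then max SNS, then lowest cutoff) re-derived from first principles
youden_bruteforce <- function(values, labels, direction = "greater") {
  best <- list(j = -Inf, sns = -Inf, cutoff = Inf)
  for (t in sort(unique(values))) {
    pos <- if (direction == "greater") values > t else values < t
    sns <- mean(pos[labels])
    spc <- mean(!pos[!labels])
    j <- sns + spc - 1
    better <- (j > best$j + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && sns > best$sns + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sns - best$sns) <= 1e-12 &&
         t < best$cutoff)
    if (better) best <- list(j = j, sns = sns, spc = spc, cutoff = t)
  }
  best
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (probability-mass method)
fisher_enumeration <- function(tab) {
  m <- rowSums(tab)[1]
  n <- rowSums(tab)[2]
  k <- colSums(tab)[1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a small deterministic CP table: two patients, three references + two
# targets, hand-checkable numbers
tiny_cp_table <- function() {
  data.frame(
    sample_id = rep(c("S1", "S2"), each = 5),
    assay = rep(c("PPIA", "RPLP0", "TBP", "AMACR", "MALAT1"), 2),
    cp_rep1 = c(24.0, 25.0, 26.0, 28.0, 30.0,
                24.0, 24.0, 24.0, 25.0, 36.0),
    cp_rep2 = c(24.0, 25.0, 26.0, 28.0, 30.0,
                24.0, 24.0, 24.0, 25.0, 36.2),
    stringsAsFactors = FALSE)
}
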