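# Independent oracles, deliberately naive: brute-force path enumeration for
# the HMM likelihood, exhaustive pair counting for the AUC, and a
# choose-or-skip recursion for negative-slot packing. None of them share
# code with the package implementations they check.

# log p(X|theta) by summing over all K^T state paths
brute_force_loglik <- function(initial, transition, means, variances, x) {
  k <- length(initial)
  tt <- ncol(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), tt)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    st <- paths[i, ]
    p <- initial[st[1]]
    if (tt > 1) {
      for (t in 2:tt) p <- p * transition[st[t - 1], st[t]]
    }
    for (t in seq_len(tt)) {
      p <- p * prod(dnorm(x[, t], means[st[t], ], sqrt(variances[st[t], ])))
    }
    total <- total + p
  }
  log(total)
}

# AUC as the fraction of (positive, negative) pairs won, ties counting 1/2
pairwise_auc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# maximum number of negative slots by choose-or-skip recursion over every
# feasible start frame (1-based), under the same constraint definitions
max_slots_exhaustive <- function(n_frames, rate, peaks, slot_s = 6,
                                 peak_gap_s = 120, slot_gap_s = 6,
                                 discard_head_s = 1, valid = NULL) {
  slot_frames <- round(slot_s * rate)
  if (is.null(valid)) valid <- rep(TRUE, n_frames)
  feasible <- integer(0)
  for (f in seq_len(n_frames - slot_frames + 1L)) {
    a <- (f - 1) / rate
    b <- a + slot_frames / rate
    if (a < discard_head_s) next
    if (!all(valid[f:(f + slot_frames - 1L)])) next
    if (!all(peaks <= a - peak_gap_s | peaks >= b + peak_gap_s)) next
    feasible <- c(feasible, f)
  }
  step <- slot_frames + round(slot_gap_s * rate)
  m <- length(feasible)
  if (m == 0) return(0L)
  # best[i] = max slots obtainable from feasible[i..m]; filled back to front
  best <- integer(m + 1L)
  for (i in rev(seq_len(m))) {
    j <- findInterval(feasible[i] + step - 0.5, feasible) + 1L
    take <- 1L + if (j > m) 0L else best[j]
    best[i] <- max(best[i + 1L], take)
  }
  best[1L]
}
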