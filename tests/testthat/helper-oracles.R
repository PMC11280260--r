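# Independent brute-force metric oracles, deliberately written differently
# from the package implementations (explicit loops and polylines rather than
# rank statistics and vectorized sweeps).

# AUC: enumerate every (positive, negative) pair; ties get half credit.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    return(NA_real_)
  }
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# AUPRC: walk the full precision-recall polyline threshold by threshold,
# accumulating precision at each recall increase (step rule).
auprc_bruteforce <- function(labels, scores) {
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) {
    return(NA_real_)
  }
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in ths) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    prec <- tp / sum(called)
    recall <- tp / P
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}
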