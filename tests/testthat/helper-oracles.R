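# Independent brute-force oracles used to check the implementation, plus
# small in-code fixture builders. Oracles deliberately avoid the code paths
# they verify.

# Quantile matching by definition: for each distinct alignment score a, look
# up its ECDF level q = #{alignment <= a}/n and read off the reference
# quantile at level q with stats::quantile type 4 (linear interpolation of
# the ECDF, order statistic i of n at level i/n).
oracle_quantile_match <- function(reference, alignment) {
  src <- sort(unique(alignment))
  q <- vapply(src, function(a) sum(alignment <= a), numeric(1)) / length(alignment)
  list(source = src,
       target = unname(quantile(reference, probs = q, type = 4)))
}

# Mann-Whitney concordance by exhaustive pair enumeration.
oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# ECE by explicit per-bin loop over equal-width bins of [0, 1].
oracle_ece <- function(scores, labels, n_bins) {
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    idx <- if (b == 1) scores >= 0 & scores <= hi else scores > lo & scores <= hi
    if (any(idx)) {
      total <- total + sum(idx) * abs(mean(scores[idx]) - mean(labels[idx]))
    }
  }
  total / length(scores)
}

# Exhaustive scan over candidate thresholds with plain loops.
oracle_balanced_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, (u[-length(u)] + u[-1]) / 2, 1)))
  best_t <- NA_real_
  best_gap <- Inf
  for (t in cand) {
    sen <- mean(scores[labels == 1] >= t)
    spc <- mean(scores[labels == 0] < t)
    gap <- abs(sen - spc)
    if (gap < best_gap) {
      best_gap <- gap
      best_t <- t
    }
  }
  list(threshold = best_t, gap = best_gap, candidates = cand)
}

oracle_spc_threshold <- function(scores, labels, target) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, (u[-length(u)] + u[-1]) / 2, 1)))
  for (t in cand) {
    if (t < 1 && mean(scores[labels == 0] < t) >= target) {
      return(t)
    }
  }
  1
}

# Two-sample KS by sup over the pooled unique values, ECDFs by counting.
oracle_ks <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}

# Fraction of positive-negative pairs tied on the score.
tied_pair_fraction <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, "=="))
}

# A small labelled record set with distinct scores, built deterministically.
make_labelled_records <- function(n_cases = 25, prevalence = 0.5, seed = 1,
                                  images_per_case = 2, device_id = "dev_a",
                                  time_index = 0) {
  generate_records(domain_model(), n_cases = n_cases, prevalence = prevalence,
                   images_per_case = images_per_case, device_id = device_id,
                   time_index = time_index, seed = seed)
}
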