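# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition by a different route than the package implementation.

oracle_prr05 <- function(a, b, c, d) {
  if (a < 1 || c < 1) return(NA_real_)
  prr <- (a / (a + b)) / (c / (c + d))
  exp(log(prr) - 1.96 * sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)))
}

oracle_ror05 <- function(a, b, c, d) {
  if (min(a, b, c, d) < 1) return(NA_real_)
  exp(log((a * d) / (b * c)) - 1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

oracle_jaccard <- function(on_a, on_b) {
  u <- length(union(on_a, on_b))
  if (u == 0) 0 else length(intersect(on_a, on_b)) / u
}

# Contingency cells by exhaustive enumeration over raw reports.
oracle_contingency <- function(reports, drug, adr) {
  has_d <- vapply(reports, function(r) drug %in% r$drugs, logical(1))
  has_a <- vapply(reports, function(r) adr %in% r$adrs, logical(1))
  list(a = sum(has_d & has_a), b = sum(has_d & !has_a),
       c = sum(!has_d & has_a), d = sum(!has_d & !has_a))
}

# AUC by exhaustive pairwise comparison: concordant pairs plus half ties.
oracle_auc <- function(s_pos, s_neg) {
  total <- 0
  for (p in s_pos) for (n in s_neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(s_pos) * length(s_neg))
}

# AUPR by an explicit threshold sweep over the distinct scores, descending;
# step-wise (no interpolation).
oracle_aupr <- function(s_pos, s_neg) {
  thr <- sort(unique(c(s_pos, s_neg)), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    tp <- sum(s_pos >= t)
    fp <- sum(s_neg >= t)
    recall <- tp / length(s_pos)
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Thresholded binary metrics by direct counting (predict positive iff >).
oracle_binary_metrics <- function(s_pos, s_neg, threshold) {
  tp <- sum(s_pos > threshold); fn <- length(s_pos) - tp
  fp <- sum(s_neg > threshold); tn <- length(s_neg) - fp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  list(precision = precision, recall = recall,
       accuracy = (tp + tn) / (tp + fn + fp + tn),
       f1 = if (precision + recall > 0)
         2 * precision * recall / (precision + recall) else 0)
}

# Monte-Carlo quantile of the EB posterior: sample the mixture component from
# its posterior weight, then the corresponding gamma. Independent of the
# package's CDF root-solving path.
oracle_eb_quantile_mc <- function(a, E, h, prob = 0.05, n = 1e6, seed = 42) {
  lnb_o <- function(n_, alpha, beta)
    lgamma(alpha + n_) - lgamma(alpha) - lgamma(n_ + 1) +
      alpha * log(beta / (beta + E)) + n_ * log(E / (beta + E))
  l1 <- log(h$p) + lnb_o(a, h$alpha1, h$beta1)
  l2 <- log(1 - h$p) + lnb_o(a, h$alpha2, h$beta2)
  Q <- exp(l1) / (exp(l1) + exp(l2))
  set.seed(seed)
  comp <- runif(n) < Q
  draws <- ifelse(comp,
                  rgamma(n, h$alpha1 + a, rate = h$beta1 + E),
                  rgamma(n, h$alpha2 + a, rate = h$beta2 + E))
  unname(quantile(draws, prob, type = 7))
}

# Point information component log2(p11 / (p1 q1)) from raw proportions.
oracle_point_ic <- function(a, b, c, d) {
  total <- a + b + c + d
  log2((a / total) / (((a + b) / total) * ((a + c) / total)))
}

# Random small contingency table with all cells >= 1.
random_table <- function() {
  list(a = sample(1:50, 1), b = sample(1:500, 1),
       c = sample(1:100, 1), d = sample(1:2000, 1))
}
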