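# Small in-code fixtures shared across test files.

# Two-report collection whose contingency cells are easy to enumerate by hand:
# report 1 mentions {D1, D2} with {A1}; report 2 mentions {D1} with {A2}.
two_report_collection <- function() {
  report_collection(list(
    list(report_id = "r1", drugs = c("D1", "D2"), adrs = "A1", year = 2004L),
    list(report_id = "r2", drugs = "D1", adrs = "A2", year = 2005L)
  ))
}

# Write a reports TSV and return its path.
write_reports_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("report_id\tdrugs\tadrs\tyear", rows), path)
  path
}

# Random row-stochastic transition matrix of size n.
random_transition <- function(n) {
  A <- matrix(runif(n * n), n, n)
  diag(A) <- 0
  A / rowSums(A)
}

# Random fingerprint with k on-keys.
random_fingerprint <- function(drug, k = 50) {
  fingerprint(drug, sample.int(881L, k))
}

# Enhanced scores for the holdout drugs of a synthetic dataset, together with
# the holdout positive/negative pairs (negatives = all other holdout pairs).
holdout_scores <- function(ds, fit) {
  hold <- ds$holdout_drugs
  known <- ds$fingerprints[setdiff(names(ds$fingerprints), hold)]
  y <- do.call(rbind, lapply(hold, function(d)
    score_new_drug(ds$fingerprints[[d]], known, fit$signal, fit$gamma)))
  rownames(y) <- hold
  pos <- ds$truth[ds$truth$drug %in% hold, , drop = FALSE]
  all_pairs <- expand.grid(drug = hold, adr = colnames(y),
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(df$drug, df$adr, sep = "\r")
  neg <- all_pairs[!key(all_pairs) %in% key(pos), , drop = FALSE]
  list(y = y, pos = pos, neg = neg)
}
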