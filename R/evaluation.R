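#' Sample negative control pairs
#'
#' Known drug-ADR pairs (e.g. from drug labels) serve as positive controls;
#' negatives are drawn uniformly without replacement from the unknown pairs
#' of the drug x ADR universe. The default ratio of 2 gives twice as many
#' negatives as positives. Fully seeded; the caller's RNG state is preserved.
#'
#' @param positives data frame with character columns `drug` and `adr`.
#' @param drugs,adrs the drug and ADR universes (character vectors).
#' @param ratio negatives per positive (must be > 0).
#' @param seed integer RNG seed.
#' @return Data frame of sampled negative pairs (`drug`, `adr`).
#' @export
sample_negatives <- function(positives, drugs, adrs, ratio = 2, seed) {
  stopifnot(is.data.frame(positives), all(c("drug", "adr") %in% names(positives)))
  if (missing(seed)) stop("sample_negatives requires an explicit seed")
  if (ratio <= 0)
    stop("ratio must be positive; for an all-pairs evaluation use every unknown pair instead of sampling")
  if (!all(positives$drug %in% drugs) || !all(positives$adr %in% adrs))
    stop("positive pairs contain IDs outside the universes")
  n_neg <- round(ratio * nrow(positives))
  all_pairs <- expand.grid(drug = drugs, adr = adrs, stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(df$drug, df$adr, sep = "\r")
  unknown <- all_pairs[!key(all_pairs) %in% key(positives), , drop = FALSE]
  if (nrow(unknown) < n_neg)
    stop("only ", nrow(unknown), " unknown pairs available but ", n_neg,
         " negatives requested")
  with_preserved_rng({
    set.seed(seed)
    idx <- sample.int(nrow(unknown), n_neg)
    out <- unknown[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Mann-Whitney rank AUC with ties counted 0.5. Internal core shared with the
# brute-force oracle in the tests.
auc_rank <- function(scores_pos, scores_neg) {
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Step-wise precision-recall integration (no interpolation): points are taken
# at each distinct score threshold, descending; ties enter as one block.
aupr_step <- function(scores_pos, scores_neg) {
  scores <- c(scores_pos, scores_neg)
  labels <- c(rep(1L, length(scores_pos)), rep(0L, length(scores_neg)))
  o <- order(scores, decreasing = TRUE)
  scores <- scores[o]; labels <- labels[o]
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(labels)
  fp <- cumsum(1L - labels)
  last <- which(grp != c(grp[-1L], -1L))  # last index of each tie block
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / length(scores_pos)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a score matrix against ground truth
#'
#' Computes the ranking metrics (AUC by the Mann-Whitney rank statistic with
#' ties counted 0.5; AUPR by step-wise precision-recall integration) and the
#' thresholded binary metrics (precision, recall, accuracy, F1; predict
#' positive iff score > threshold) over the positive and negative control
#' pairs.
#'
#' @param scores a `signal_matrix`, `propagated_signals`, or numeric matrix
#'   with drug rownames and ADR colnames.
#' @param positives,negatives data frames with columns `drug`, `adr`; both
#'   must be nonempty and every pair must have a score.
#' @param threshold decision threshold for the binary metrics. `NULL` uses
#'   the conventional signal criterion for the matrix's method: score > 1
#'   for PRR05/ROR05/EB05, score > 0 for BCPNN25 (and 0 for unknown tags).
#' @return An object of class `lpsda_eval`: list with `auc`, `aupr`,
#'   `precision`, `recall`, `accuracy`, `f1`, `threshold`, `n_pos`, `n_neg`.
#' @export
evaluate <- function(scores, positives, negatives, threshold = NULL) {
  method <- if (inherits(scores, "signal_matrix")) scores$method
    else if (inherits(scores, "propagated_signals")) scores$source_method
    else NULL
  m <- score_matrix_of(scores)
  if (is.null(threshold)) threshold <- default_threshold(method)
  s_pos <- pair_scores(m, positives)
  s_neg <- pair_scores(m, negatives)
  if (length(s_pos) < 1L || length(s_neg) < 1L)
    stop("evaluation needs at least one positive and one negative pair")
  tp <- sum(s_pos > threshold)
  fn <- length(s_pos) - tp
  fp <- sum(s_neg > threshold)
  tn <- length(s_neg) - fp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(
    auc = auc_rank(s_pos, s_neg),
    aupr = aupr_step(s_pos, s_neg),
    precision = precision,
    recall = recall,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    f1 = f1,
    threshold = threshold,
    n_pos = length(s_pos),
    n_neg = length(s_neg)
  ), class = "lpsda_eval")
}

# Conventional signal-screening threshold per algorithm. Internal.
default_threshold <- function(method) {
  if (is.null(method)) return(0)
  if (method %in% c("PRR05", "ROR05", "EB05")) 1 else 0
}

# Extract scores for a pair data frame, erroring on unknown IDs. Internal.
pair_scores <- function(m, pairs) {
  stopifnot(is.data.frame(pairs), all(c("drug", "adr") %in% names(pairs)))
  di <- match(pairs$drug, rownames(m))
  ai <- match(pairs$adr, colnames(m))
  if (anyNA(di))
    stop("unknown drug ID(s) in evaluation pairs: ",
         paste(unique(pairs$drug[is.na(di)]), collapse = ", "))
  if (anyNA(ai))
    stop("unknown ADR ID(s) in evaluation pairs: ",
         paste(unique(pairs$adr[is.na(ai)]), collapse = ", "))
  m[cbind(di, ai)]
}

#' @export
print.lpsda_eval <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f  AUPR %.3f  precision %.3f  recall %.3f  accuracy %.3f  F1 %.3f\n",
    x$auc, x$aupr, x$precision, x$recall, x$accuracy, x$f1))
  cat(sprintf("  (%d positives, %d negatives, threshold %g)\n",
              x$n_pos, x$n_neg, x$threshold))
  invisible(x)
}

#' Grid search over the absorbing probability
#'
#' Propagates the signal matrix at every gamma of the grid (closed form),
#' scores each propagated matrix by AUC on the same positive/negative
#' controls, and selects the gamma with maximum AUC; ties resolve to the
#' smallest gamma.
#'
#' @param W transition matrix from [row_normalize()].
#' @param S `signal_matrix` (or numeric matrix).
#' @param positives,negatives control pairs as in [evaluate()].
#' @param grid gamma values to try, all strictly inside (0, 1); default
#'   `0.1, 0.2, ..., 0.9`.
#' @return An object of class `gamma_search`: list with `grid`, `auc`
#'   (per-gamma), and `best_gamma`.
#' @export
grid_search_gamma <- function(W, S, positives, negatives,
                              grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(grid) >= 1L, all(grid > 0 & grid < 1))
  grid <- sort(grid)
  aucs <- vapply(grid, function(g) {
    evaluate(propagate_closed_form(W, S, g), positives, negatives)$auc
  }, numeric(1))
  structure(list(grid = grid, auc = aucs,
                 best_gamma = grid[which.max(aucs)]),
            class = "gamma_search")
}

#' @export
print.gamma_search <- function(x, ...) {
  df <- data.frame(gamma = x$grid, auc = round(x$auc, 4))
  print(df, row.names = FALSE)
  cat("best gamma:", x$best_gamma, "\n")
  invisible(x)
}

#' Per-ADR evaluation with a minimum-positives filter
#'
#' For each ADR with at least `min_drugs` positive drugs, ranks the ADR's
#' whole score column: positives are the ground-truth drugs for that ADR,
#' negatives the remaining drugs of the column. ADRs below the filter are
#' excluded and listed in the `excluded` attribute. The default filter of 10
#' positive drugs mirrors the representative-ADR protocol.
#'
#' @param scores score container as in [evaluate()].
#' @param positives ground-truth pairs (`drug`, `adr`).
#' @param min_drugs minimum number of positive drugs per retained ADR.
#' @return Data frame with one row per retained ADR: `adr`, `n_pos`, `auc`,
#'   `aupr`; excluded ADR IDs in `attr(, "excluded")`.
#' @export
evaluate_per_adr <- function(scores, positives, min_drugs = 10L) {
  stopifnot(min_drugs >= 1L)
  m <- score_matrix_of(scores)
  adrs <- intersect(unique(positives$adr), colnames(m))
  rows <- list()
  excluded <- character(0)
  for (adr in adrs) {
    pos_drugs <- intersect(positives$drug[positives$adr == adr], rownames(m))
    if (length(pos_drugs) < min_drugs) {
      excluded <- c(excluded, adr)
      next
    }
    neg_drugs <- setdiff(rownames(m), pos_drugs)
    if (length(neg_drugs) == 0L) {
      excluded <- c(excluded, adr)
      next
    }
    s_pos <- m[pos_drugs, adr]
    s_neg <- m[neg_drugs, adr]
    rows[[adr]] <- data.frame(adr = adr, n_pos = length(pos_drugs),
                              auc = auc_rank(s_pos, s_neg),
                              aupr = aupr_step(s_pos, s_neg),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no ADR has at least ", min_drugs, " positive drugs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Cumulative-year evaluation curve
#'
#' For each cutoff year, rebuilds the pipeline from the reports accumulated
#' up to that year (counts, original signals, similarity network over the
#' sliced universe, propagation) and evaluates both the baseline and the
#' label-propagation-enhanced scores on the ground truth restricted to the
#' sliced universe. Shows how much chemistry helps when only early reports
#' are available.
#'
#' @param rc full [report_collection()].
#' @param profiles named list of fingerprints.
#' @param truth ground-truth positive pairs (`drug`, `adr`).
#' @param years ascending integer cutoffs.
#' @param method signal-detection algorithm tag.
#' @param gamma absorbing probability (fixed across years).
#' @param ratio,seed negative-sampling controls (fresh sample per slice).
#' @param n_mc,mc_seed BCPNN25 Monte-Carlo controls.
#' @return Data frame with one row per usable year: `year`, `n_reports`,
#'   `auc`, `aupr` (baseline), `auc_lp`, `aupr_lp` (enhanced).
#' @export
cumulative_year_curve <- function(rc, profiles, truth, years,
                                  method = "EB05", gamma = 0.5,
                                  ratio = 2, seed = 1L,
                                  n_mc = 1e4, mc_seed = 1L) {
  stopifnot(inherits(rc, "report_collection"), !is.unsorted(years))
  rows <- list()
  for (yr in years) {
    sliced <- tryCatch(filter_by_year(rc, yr), error = function(e) NULL)
    if (is.null(sliced)) {
      warning("no reports at or before ", yr, "; year skipped")
      next
    }
    ct <- build_count_table(sliced)
    S <- compute_signal_matrix(ct, method, n_mc = n_mc, seed = mc_seed)
    W <- row_normalize(build_similarity_matrix(
      align_profiles(profiles, sliced$drug_universe)))
    Y <- propagate_closed_form(W, S, gamma)
    pos <- truth[truth$drug %in% sliced$drug_universe &
                   truth$adr %in% sliced$adr_universe, , drop = FALSE]
    if (nrow(pos) == 0L) {
      warning("no ground-truth pairs inside the ", yr, " slice; year skipped")
      next
    }
    neg <- sample_negatives(pos, sliced$drug_universe, sliced$adr_universe,
                            ratio = ratio, seed = seed)
    e0 <- evaluate(S, pos, neg)
    e1 <- evaluate(Y, pos, neg)
    rows[[as.character(yr)]] <- data.frame(
      year = yr, n_reports = length(sliced$reports),
      auc = e0$auc, aupr = e0$aupr, auc_lp = e1$auc, aupr_lp = e1$aupr)
  }
  if (length(rows) == 0L) stop("no usable year slices")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank percentile of a drug for a given ADR
#'
#' Sorts all drugs by their score for the ADR in descending order and
#' returns `100 * rank / N`, where rank 1 is the highest score; tied scores
#' receive their average rank. Smaller percentiles mean stronger standing of
#' the drug among all drugs for that ADR.
#'
#' @param scores score container as in [evaluate()].
#' @param drug,adr IDs present in the matrix.
#' @return Percentile in `(0, 100]`.
#' @export
rank_percentile <- function(scores, drug, adr) {
  m <- score_matrix_of(scores)
  if (!drug %in% rownames(m)) stop("unknown drug ID: ", drug)
  if (!adr %in% colnames(m)) stop("unknown ADR ID: ", adr)
  r <- rank(-m[, adr], ties.method = "average")
  100 * r[[drug]] / nrow(m)
}

#' Write evaluation reports as TSV
#'
#' @param evals named list of `lpsda_eval` objects (names become the method
#'   column).
#' @param path output file path.
#' @param gamma,seed optional values recorded per row.
#' @return `path`, invisibly.
#' @export
write_eval_table <- function(evals, path, gamma = NA, seed = NA) {
  df <- do.call(rbind, lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    data.frame(method = nm, auc = e$auc, aupr = e$aupr,
               precision = e$precision, recall = e$recall,
               accuracy = e$accuracy, f1 = e$f1,
               threshold = e$threshold, gamma = gamma, seed = seed,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
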