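# Assemble a score matrix plus controls from raw positive/negative score
# vectors, so metric tests can feed evaluate() arbitrary configurations.
eval_fixture <- function(s_pos, s_neg) {
  n <- length(s_pos) + length(s_neg)
  m <- matrix(c(s_pos, s_neg), nrow = n, ncol = 1,
              dimnames = list(sprintf("D%03d", 1:n), "A1"))
  list(
    m = m,
    pos = data.frame(drug = sprintf("D%03d", seq_along(s_pos)), adr = "A1"),
    neg = data.frame(drug = sprintf("D%03d", length(s_pos) + seq_along(s_neg)),
                     adr = "A1")
  )
}

test_that("metrics match hand enumeration on the four-pair example", {
  f <- eval_fixture(c(0.9, 0.4), c(0.6, 0.1))
  e <- evaluate(f$m, f$pos, f$neg, threshold = 0.5)
  expect_equal(e$auc, 0.75)        # 3 of 4 pairs concordant
  expect_equal(e$precision, 0.5)   # TP=1 (0.9), FP=1 (0.6)
  expect_equal(e$recall, 0.5)
  expect_equal(e$accuracy, 0.5)
  expect_equal(e$f1, 0.5)
  expect_identical(e$n_pos, 2L)
  expect_identical(e$n_neg, 2L)
})

test_that("ranking metrics hit their boundary values", {
  perfect <- eval_fixture(c(5, 4, 3), c(2, 1, 0))
  e <- evaluate(perfect$m, perfect$pos, perfect$neg, threshold = 2.5)
  expect_equal(e$auc, 1); expect_equal(e$aupr, 1)
  expect_equal(e$precision, 1); expect_equal(e$recall, 1)

  tied <- eval_fixture(rep(1, 3), rep(1, 5))
  et <- evaluate(tied$m, tied$pos, tied$neg, threshold = 0)
  expect_equal(et$auc, 0.5)
})

test_that("AUC and AUPR agree exactly with the brute-force oracles", {
  set.seed(53)
  for (i in 1:25) {
    n_pos <- sample(2:12, 1); n_neg <- sample(2:25, 1)
    # coarse scores force plenty of ties
    s_pos <- sample(0:5, n_pos, replace = TRUE) / 5
    s_neg <- sample(0:5, n_neg, replace = TRUE) / 5
    f <- eval_fixture(s_pos, s_neg)
    thr <- runif(1)
    e <- evaluate(f$m, f$pos, f$neg, threshold = thr)
    o <- oracle_binary_metrics(s_pos, s_neg, thr)
    expect_equal(e$auc, oracle_auc(s_pos, s_neg), tolerance = 1e-12)
    expect_equal(e$aupr, oracle_aupr(s_pos, s_neg), tolerance = 1e-12)
    expect_equal(e$precision, o$precision, tolerance = 1e-12)
    expect_equal(e$recall, o$recall, tolerance = 1e-12)
    expect_equal(e$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(e$f1, o$f1, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent library implementation", {
  set.seed(59)
  s_pos <- rnorm(40, 1); s_neg <- rnorm(60)
  f <- eval_fixture(s_pos, s_neg)
  e <- evaluate(f$m, f$pos, f$neg, threshold = 0)
  ref <- as.numeric(pROC::auc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(s_pos, s_neg),
    direction = "<", quiet = TRUE))
  expect_equal(e$auc, ref, tolerance = 1e-12)
})

test_that("negative sampling honors ratio, determinism and disjointness", {
  drugs <- sprintf("D%02d", 1:12); adrs <- sprintf("A%02d", 1:8)
  pos <- data.frame(drug = drugs[1:10], adr = adrs[1])
  neg <- sample_negatives(pos, drugs, adrs, ratio = 2, seed = 4)
  expect_identical(nrow(neg), 20L)
  expect_false(any(paste(neg$drug, neg$adr) %in% paste(pos$drug, pos$adr)))
  expect_identical(sample_negatives(pos, drugs, adrs, ratio = 2, seed = 4), neg)
  expect_false(identical(sample_negatives(pos, drugs, adrs, ratio = 2,
                                          seed = 5), neg))
  expect_error(sample_negatives(pos, drugs, adrs, ratio = 0, seed = 1),
               "positive")
  expect_error(sample_negatives(pos, drugs, adrs, ratio = 50, seed = 1),
               "unknown pairs")
})

test_that("gamma grid search maximizes AUC with ties to the smallest gamma", {
  set.seed(61)
  n <- 10
  S <- matrix(runif(n * 3), n, 3,
              dimnames = list(sprintf("D%02d", 1:n), sprintf("A%02d", 1:3)))
  pos <- data.frame(drug = sprintf("D%02d", 1:4), adr = "A01")
  neg <- data.frame(drug = sprintf("D%02d", 5:10), adr = "A01")

  # identity network: every gamma gives the same AUC, tie goes to 0.1
  gs <- grid_search_gamma(diag(n), S, pos, neg)
  expect_identical(gs$grid, seq(0.1, 0.9, by = 0.1))
  expect_true(all(abs(gs$auc - gs$auc[1]) < 1e-12))
  expect_identical(gs$best_gamma, 0.1)

  gs1 <- grid_search_gamma(diag(n), S, pos, neg, grid = 0.3)
  expect_identical(gs1$best_gamma, 0.3)

  W <- random_transition(n)
  dimnames(W) <- list(rownames(S), rownames(S))
  gs2 <- grid_search_gamma(W, S, pos, neg)
  expect_identical(gs2$best_gamma, gs2$grid[which.max(gs2$auc)])
})

test_that("per-ADR evaluation filters sparse ADRs and matches hand ranking", {
  m <- matrix(c(5, 4, 3, 2, 1,   # A1 column: positives D1, D2 rank on top
                1, 2, 3, 4, 5),
              nrow = 5, dimnames = list(paste0("D", 1:5), c("A1", "A2")))
  pos <- data.frame(drug = c("D1", "D2", "D1", "D2", "D3"),
                    adr = c("A1", "A1", "A2", "A2", "A2"))
  r <- evaluate_per_adr(m, pos, min_drugs = 2)
  expect_setequal(r$adr, c("A1", "A2"))
  expect_equal(r$auc[r$adr == "A1"], 1)
  expect_equal(r$aupr[r$adr == "A1"], 1)
  # A2 column positives D1(1), D2(2), D3(3) vs negatives D4(4), D5(5)
  expect_equal(r$auc[r$adr == "A2"], oracle_auc(c(1, 2, 3), c(4, 5)))
  expect_equal(r$aupr[r$adr == "A2"], oracle_aupr(c(1, 2, 3), c(4, 5)))

  r3 <- evaluate_per_adr(m, pos, min_drugs = 3)
  expect_identical(r3$adr, "A2")
  expect_identical(attr(r3, "excluded"), "A1")
  expect_error(evaluate_per_adr(m, pos, min_drugs = 10), "at least 10")
  expect_identical(nrow(evaluate_per_adr(m, pos, min_drugs = 1)), 2L)
})

test_that("rank percentile uses descending ranks with tie averaging", {
  m <- matrix(seq(100, 1), nrow = 100, ncol = 1,
              dimnames = list(sprintf("D%03d", 1:100), "A1"))
  expect_equal(rank_percentile(m, "D001", "A1"), 1)
  expect_equal(rank_percentile(m, "D100", "A1"), 100)

  tied <- matrix(rep(2, 4), 4, 1, dimnames = list(paste0("D", 1:4), "A1"))
  expect_equal(rank_percentile(tied, "D2", "A1"), 62.5)  # 100 * 2.5 / 4
  expect_error(rank_percentile(m, "DX", "A1"), "unknown drug")
})

test_that("cumulative-year curve is monotone in reports and matches the full slice", {
  set.seed(67)
  ds <- generate_dataset(synth_config(n_drugs = 20, n_adrs = 12,
                                      n_reports = 1200, n_clusters = 4,
                                      frac_holdout_drugs = 0, seed = 67))
  curve <- cumulative_year_curve(ds$reports, ds$fingerprints, ds$truth,
                                 years = c(2006, 2010, 2014),
                                 method = "PRR05", gamma = 0.5, seed = 3)
  expect_true(all(diff(curve$n_reports) >= 0))
  expect_identical(curve$year, c(2006, 2010, 2014))

  # last cutoff covers all reports: equals the whole-data evaluation
  ct <- build_count_table(ds$reports)
  S <- compute_signal_matrix(ct, "PRR05")
  W <- row_normalize(build_similarity_matrix(
    lpsda:::align_profiles(ds$fingerprints, ds$reports$drug_universe)))
  Y <- propagate_closed_form(W, S, 0.5)
  neg <- sample_negatives(ds$truth, ds$reports$drug_universe,
                          ds$reports$adr_universe, ratio = 2, seed = 3)
  expect_equal(curve$auc[3], evaluate(S, ds$truth, neg)$auc, tolerance = 1e-12)
  expect_equal(curve$auc_lp[3], evaluate(Y, ds$truth, neg)$auc,
               tolerance = 1e-12)
})

test_that("degenerate evaluation inputs raise errors", {
  f <- eval_fixture(1, 0)
  expect_error(evaluate(f$m, f$pos[0, ], f$neg), "at least one")
  expect_error(evaluate(f$m, data.frame(drug = "DX", adr = "A1"), f$neg),
               "unknown drug")
})
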