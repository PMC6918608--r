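two_node_case <- function() {
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("D1", "D2"), c("D1", "D2")))
  S <- matrix(c(1, 0), 2, 1, dimnames = list(c("D1", "D2"), "A1"))
  list(W = W, S = S)
}

test_that("closed form reproduces the hand-inverted two-node system", {
  x <- two_node_case()
  # (I - 0.5 W)^{-1} = (1/0.75) [[1, 0.5], [0.5, 1]]; Y = 0.5 * that * S
  y <- propagate_closed_form(x$W, x$S, gamma = 0.5)$y
  expect_equal(unname(y[, 1]), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("iterative and closed-form solutions agree on random instances", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    W <- random_transition(n)
    S <- matrix(rnorm(n * 3), n, 3)
    g <- sample(seq(0.1, 0.9, by = 0.1), 1)
    yc <- propagate_closed_form(W, S, g)$y
    yi <- propagate_iterative(W, S, g, tol = 1e-12)
    expect_true(yi$converged)
    expect_lt(max(abs(yc - yi$y)), 1e-8)
  }
})

test_that("identity network and constant columns are fixed points", {
  n <- 5
  S <- matrix(rnorm(n * 2), n, 2)
  expect_equal(propagate_closed_form(diag(n), S, 0.7)$y, S, tolerance = 1e-12)

  set.seed(19)
  W <- random_transition(6)
  S2 <- cbind(rep(3.5, 6), rnorm(6))
  y <- propagate_closed_form(W, S2, 0.4)$y
  expect_equal(unname(y[, 1]), rep(3.5, 6), tolerance = 1e-10)
})

test_that("propagation approaches S as gamma vanishes", {
  set.seed(23)
  W <- random_transition(8)
  S <- matrix(rnorm(8 * 2), 8, 2)
  y <- propagate_closed_form(W, S, 1e-6)$y
  expect_lt(max(abs(y - S)), 1e-4)
})

test_that("the propagation operator is linear and bounded by S columnwise", {
  set.seed(29)
  W <- random_transition(10)
  S1 <- matrix(rnorm(10 * 2), 10, 2)
  S2 <- matrix(rnorm(10 * 2), 10, 2)
  g <- 0.6
  y_sum <- propagate_closed_form(W, 2 * S1 - 3 * S2, g)$y
  expect_equal(y_sum,
               2 * propagate_closed_form(W, S1, g)$y -
                 3 * propagate_closed_form(W, S2, g)$y,
               tolerance = 1e-10)

  y1 <- propagate_closed_form(W, S1, g)$y
  for (j in 1:2) {
    expect_gte(min(y1[, j]), min(S1[, j]) - 1e-12)
    expect_lte(max(y1[, j]), max(S1[, j]) + 1e-12)
  }
})

test_that("iteration contracts geometrically at rate gamma", {
  set.seed(37)
  W <- random_transition(12)
  S <- matrix(rnorm(12), 12, 1)
  g <- 0.8
  ystar <- propagate_closed_form(W, S, g)$y
  y <- S
  for (t in 1:20) {
    y_next <- g * (W %*% y) + (1 - g) * S
    expect_lte(max(abs(y_next - ystar)), g * max(abs(y - ystar)) + 1e-14)
    y <- y_next
  }
})

test_that("stopping rules and input checks behave as documented", {
  x <- two_node_case()
  r <- propagate_iterative(x$W, x$S, 0.5, tol = 10)
  expect_identical(r$iterations, 1L)
  expect_true(r$converged)

  expect_error(propagate_closed_form(x$W, x$S, 0), "gamma")
  expect_error(propagate_closed_form(x$W, x$S, 1), "gamma")
  expect_error(propagate_closed_form(x$W, x$S[1, , drop = FALSE], 0.5), "rows")
  Wbad <- x$W; rownames(Wbad) <- c("D2", "D1")
  expect_error(propagate_closed_form(Wbad, x$S, 0.5), "ordering")
})

test_that("a new drug inherits scores from its chemical twin", {
  set.seed(47)
  profiles <- lapply(1:6, function(i) random_fingerprint(paste0("D", i), 60))
  names(profiles) <- paste0("D", 1:6)
  S <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(paste0("D", 1:6), paste0("A", 1:4)))
  # twin of D3
  fp_new <- fingerprint("DNEW", profiles$D3$on)
  y_new <- score_new_drug(fp_new, profiles, S, gamma = 0.5)
  expect_named(y_new, paste0("A", 1:4))
  W <- row_normalize(build_similarity_matrix(profiles))
  y_known <- propagate_closed_form(W, S, 0.5)$y
  expect_true(all(y_new[y_known["D3", ] > 0] > 0))

  # isolated new drug keeps its zero label
  fp_far <- fingerprint("DFAR", integer(0))
  expect_warning(y_far <- score_new_drug(fp_far, profiles, S, 0.5),
                 "zero similarity")
  expect_equal(unname(y_far), rep(0, 4))

  # negligible absorption: scores are near zero everywhere
  y_tiny <- score_new_drug(fp_new, profiles, S, gamma = 1e-6)
  expect_lt(max(abs(y_tiny)), 1e-4)

  expect_error(score_new_drug(fingerprint("D3", 1:5), profiles, S, 0.5),
               "already")
})

test_that("propagated signals round-trip with sidecar metadata", {
  x <- two_node_case()
  y <- propagate_closed_form(x$W, x$S, 0.5)
  y$source_method <- "PRR05"
  path <- tempfile(fileext = ".tsv")
  write_propagated(y, path)
  df <- read.delim(path)
  expect_identical(unique(df$method), "LP-PRR05")
  meta <- readLines(paste0(path, ".meta"))
  expect_true("gamma=0.5" %in% meta)
  expect_true("source_method=PRR05" %in% meta)
})
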