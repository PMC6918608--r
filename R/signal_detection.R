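#' Disproportionality signal scores
#'
#' The four classical signal-detection algorithms score a drug-ADR pair by how
#' disproportionately often it is co-reported relative to its expectation
#' under independence across the whole report database. Each returns the
#' conventional conservative lower bound used for signal screening:
#'
#' * `prr05`: lower bound of the 95% CI of the proportional reporting ratio
#'   PRR = (a/(a+b)) / (c/(c+d)), log-scale Wald interval with
#'   se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)).
#' * `ror05`: lower bound of the 95% CI of the reporting odds ratio
#'   ROR = (a d)/(b c), se = sqrt(1/a + 1/b + 1/c + 1/d).
#'
#' Both return `NA` when a required cell or denominator is zero; matrix-level
#' callers substitute the documented fallback (see
#' [compute_signal_matrix()]).
#'
#' @param t a `contingency_table` (see [contingency()]) or a named list/vector
#'   with elements `a`, `b`, `c`, `d`.
#' @return A single numeric score, or `NA_real_` if undefined.
#' @examples
#' t <- list(a = 10, b = 90, c = 20, d = 880)
#' prr05(t)
#' ror05(t)
#' @export
prr05 <- function(t) {
  t <- as_abcd(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a < 1 || c < 1 || (a + b) == 0 || (c + d) == 0) return(NA_real_)
  prr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  exp(log(prr) - 1.96 * se)
}

#' @rdname prr05
#' @export
ror05 <- function(t) {
  t <- as_abcd(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a < 1 || b < 1 || c < 1 || d < 1) return(NA_real_)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(log(ror) - 1.96 * se)
}

# log density of the negative-binomial marginal of a gamma-Poisson cell:
# N ~ Poisson(lambda * E), lambda ~ Gamma(shape = alpha, rate = beta).
# Vectorized over n and E. Internal.
lnb <- function(n, E, alpha, beta) {
  lgamma(alpha + n) - lgamma(alpha) - lgamma(n + 1) +
    alpha * (log(beta) - log(beta + E)) +
    n * (log(E) - log(beta + E))
}

# log of the two-component mixture marginal. Internal.
lmix <- function(n, E, h) {
  l1 <- log(h$p) + lnb(n, E, h$alpha1, h$beta1)
  l2 <- log1p(-h$p) + lnb(n, E, h$alpha2, h$beta2)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Fit the empirical-Bayes gamma-Poisson (MGPS) prior
#'
#' The multi-item gamma Poisson shrinker models each observed drug-ADR count
#' as N ~ Poisson(lambda E) with E = (drug margin x ADR margin) / total the
#' expected count under independence, and a two-component gamma mixture prior
#' lambda ~ p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2). The prior is
#' fitted by maximizing the marginal likelihood (a two-component
#' negative-binomial mixture) over all cells with E > 0, including zero
#' counts. Optimization is bounded quasi-Newton (L-BFGS-B) on log-transformed
#' shapes/rates and a logit-transformed mixture weight, started from
#' DuMouchel's canonical values (0.2, 0.1, 2, 4, 1/3).
#'
#' @param ct a [build_count_table()] result.
#' @param start optional named numeric vector with entries `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p` overriding the canonical start.
#' @return An object of class `mgps_prior`: list with the five hyperparameters,
#'   the achieved `loglik`, the number of cells used (`n_cells`) and the
#'   optimizer `convergence` code (0 = converged).
#' @export
fit_mgps_prior <- function(ct, start = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (ct$total <= 0) stop("count table has no reports")
  E <- outer(as.numeric(ct$drug_margins), as.numeric(ct$adr_margins)) / ct$total
  keep <- E > 0
  n <- as.numeric(ct$n[keep])
  E <- E[keep]
  if (length(n) == 0L) stop("no cells with positive expected count")
  s0 <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, p = 1 / 3)
  if (!is.null(start)) s0[names(start)] <- start
  theta0 <- c(log(s0[["alpha1"]]), log(s0[["beta1"]]),
              log(s0[["alpha2"]]), log(s0[["beta2"]]),
              stats::qlogis(s0[["p"]]))
  unpack <- function(theta) {
    list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
         alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
         p = stats::plogis(theta[5]))
  }
  negll <- function(theta) {
    h <- unpack(theta)
    -sum(lmix(n, E, h))
  }
  fit <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = rep(-12, 5), upper = rep(12, 5),
                      control = list(maxit = 500))
  if (!is.finite(fit$value))
    stop("MGPS prior fit failed: non-finite likelihood at ",
         paste(signif(unpack(fit$par), 4), collapse = ", "))
  if (!fit$convergence %in% c(0L, 1L))
    stop("MGPS prior fit did not converge (code ", fit$convergence, "): ",
         fit$message)
  h <- unpack(fit$par)
  structure(c(h, list(loglik = -fit$value, n_cells = length(n),
                      convergence = fit$convergence)),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "MGPS gamma-mixture prior: p=%.4f, Gamma(%.4f, %.4f) / Gamma(%.4f, %.4f)\n",
    x$p, x$alpha1, x$beta1, x$alpha2, x$beta2))
  cat(sprintf("  marginal log-likelihood %.3f over %d cells\n",
              x$loglik, x$n_cells))
  invisible(x)
}

#' EB05: posterior 5th percentile of the shrunken reporting ratio
#'
#' Given the fitted gamma-mixture prior, the posterior of the reporting-ratio
#' parameter lambda for a pair with observed count a and expected count
#' E = (a+b)(a+c)/total is the mixture
#' Q Gamma(alpha1 + a, beta1 + E) + (1-Q) Gamma(alpha2 + a, beta2 + E),
#' with Q the posterior component weight from the negative-binomial marginals.
#' EB05 is the 5th percentile of this mixture, found by root-solving the
#' mixture CDF.
#'
#' @param t a `contingency_table` or named a/b/c/d structure.
#' @param h an `mgps_prior` from [fit_mgps_prior()].
#' @param prob posterior quantile level (default 0.05).
#' @return The posterior quantile, or `NA_real_` when E = 0.
#' @export
eb05 <- function(t, h, prob = 0.05) {
  stopifnot(inherits(h, "mgps_prior"))
  t <- as_abcd(t)
  a <- t$a
  total <- t$a + t$b + t$c + t$d
  if (total <= 0) return(NA_real_)
  E <- (t$a + t$b) * (t$a + t$c) / total
  if (E <= 0) return(NA_real_)
  posterior_mixture_quantile(a, E, h, prob)
}

# Quantile of the posterior gamma mixture for count a, expectation E. Internal.
posterior_mixture_quantile <- function(a, E, h, prob) {
  l1 <- log(h$p) + lnb(a, E, h$alpha1, h$beta1)
  l2 <- log1p(-h$p) + lnb(a, E, h$alpha2, h$beta2)
  Q <- 1 / (1 + exp(l2 - l1))
  s1 <- h$alpha1 + a; r1 <- h$beta1 + E
  s2 <- h$alpha2 + a; r2 <- h$beta2 + E
  cdf <- function(x) Q * stats::pgamma(x, s1, rate = r1) +
    (1 - Q) * stats::pgamma(x, s2, rate = r2)
  lo <- min(stats::qgamma(prob, s1, rate = r1), stats::qgamma(prob, s2, rate = r2))
  hi <- max(stats::qgamma(prob, s1, rate = r1), stats::qgamma(prob, s2, rate = r2))
  if (hi - lo < .Machine$double.eps * max(1, hi)) return(lo)
  stats::uniroot(function(x) cdf(x) - prob, lower = lo, upper = hi,
                 tol = 1e-12, extendInt = "upX")$root
}

#' BCPNN25: Monte-Carlo posterior 2.5% quantile of the information component
#'
#' The information component is IC = log2(p11 / (p1 q1)) where p11 is the
#' joint probability of the drug-ADR pair, p1 the drug's marginal and q1 the
#' ADR's marginal reporting probability. With independent uniform Beta priors,
#' the posteriors are p1 ~ Beta(a+b+1, c+d+1), q1 ~ Beta(a+c+1, b+d+1) and
#' p11 ~ Beta(a+1, b+c+d+1); the score is the 2.5% quantile of the sampled IC
#' distribution. Fully seeded and deterministic; the caller's RNG state is
#' preserved.
#'
#' @param t a `contingency_table` or named a/b/c/d structure.
#' @param n_mc number of Monte-Carlo posterior draws (minimum 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @return The 2.5% posterior quantile of IC (bits).
#' @export
bcpnn25 <- function(t, n_mc = 1e5, seed) {
  t <- as_abcd(t)
  if (missing(seed)) stop("bcpnn25 requires an explicit seed")
  if (n_mc < 1000) stop("n_mc must be at least 1000 (quantile too unstable below)")
  total <- t$a + t$b + t$c + t$d
  if (total <= 0) return(NA_real_)
  with_preserved_rng({
    set.seed(seed)
    ic_draws <- bcpnn_ic_draws(t, n_mc)
    unname(stats::quantile(ic_draws, 0.025, type = 7))
  })
}

# Draw n_mc posterior IC samples for one table; assumes RNG already seeded.
bcpnn_ic_draws <- function(t, n_mc) {
  p1 <- stats::rbeta(n_mc, t$a + t$b + 1, t$c + t$d + 1)
  q1 <- stats::rbeta(n_mc, t$a + t$c + 1, t$b + t$d + 1)
  p11 <- stats::rbeta(n_mc, t$a + 1, t$b + t$c + t$d + 1)
  log2(p11 / (p1 * q1))
}

# Evaluate expr with the global RNG state restored afterwards. Internal.
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  expr
}

#' Compute the full original signal matrix
#'
#' Applies one of the four algorithms to every (drug, ADR) cell of a count
#' table and returns the complete drugs x ADRs score matrix S. Pairs where
#' the score is undefined (zero cells breaking a formula) receive a fallback
#' so that the matrix is finite everywhere, as required by label propagation:
#' 0 for PRR05/ROR05/EB05 and -10 for BCPNN25 (ranking those pairs last on
#' the log2 scale).
#'
#' @param ct a [build_count_table()] result.
#' @param method one of `"PRR05"`, `"ROR05"`, `"EB05"`, `"BCPNN25"`.
#' @param prior optional pre-fitted `mgps_prior` for EB05 (fitted internally
#'   when absent).
#' @param n_mc Monte-Carlo draws per pair for BCPNN25.
#' @param seed RNG seed for BCPNN25 (drawing order is fixed column-major, so
#'   one seed makes the whole matrix reproducible).
#' @return An object of class `signal_matrix`: list with `scores` (numeric
#'   matrix with the count table's dimnames), `method` and `fallback`.
#' @export
compute_signal_matrix <- function(ct, method = c("PRR05", "ROR05", "EB05", "BCPNN25"),
                                  prior = NULL, n_mc = 1e4, seed = 1L) {
  stopifnot(inherits(ct, "count_table"))
  method <- match.arg(method)
  drugs <- rownames(ct$n)
  adrs <- colnames(ct$n)
  scores <- matrix(NA_real_, length(drugs), length(adrs),
                   dimnames = list(drugs, adrs))
  fallback <- if (method == "BCPNN25") -10 else 0
  if (method == "EB05" && is.null(prior)) prior <- fit_mgps_prior(ct)
  if (method == "BCPNN25") {
    scores <- with_preserved_rng({
      set.seed(seed)
      out <- scores
      for (j in seq_along(adrs)) for (i in seq_along(drugs)) {
        t <- cell_abcd(ct, i, j)
        out[i, j] <- unname(stats::quantile(bcpnn_ic_draws(t, n_mc), 0.025,
                                            type = 7))
      }
      out
    })
  } else if (method == "EB05") {
    for (j in seq_along(adrs)) for (i in seq_along(drugs)) {
      scores[i, j] <- eb05(cell_abcd(ct, i, j), prior)
    }
  } else {
    f <- if (method == "PRR05") prr05 else ror05
    for (j in seq_along(adrs)) for (i in seq_along(drugs)) {
      scores[i, j] <- f(cell_abcd(ct, i, j))
    }
  }
  scores[!is.finite(scores)] <- fallback
  structure(list(scores = scores, method = method, fallback = fallback,
                 prior = if (method == "EB05") prior else NULL),
            class = "signal_matrix")
}

# a/b/c/d for cell (i, j) by index, without ID lookup. Internal.
cell_abcd <- function(ct, i, j) {
  a <- ct$n[i, j]
  list(a = a,
       b = ct$drug_margins[[i]] - a,
       c = ct$adr_margins[[j]] - a,
       d = ct$total - ct$drug_margins[[i]] - ct$adr_margins[[j]] + a)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix (", x$method, "): ", nrow(x$scores), " drugs x ",
      ncol(x$scores), " ADRs; score range [",
      sprintf("%.3f", min(x$scores)), ", ", sprintf("%.3f", max(x$scores)),
      "]\n", sep = "")
  invisible(x)
}

#' Write a signal matrix as long or dense TSV
#'
#' @param x a `signal_matrix` or `propagated_signals` object, or a plain
#'   numeric matrix with dimnames.
#' @param path output file path.
#' @param layout `"long"` for `drug<TAB>adr<TAB>score<TAB>method` rows,
#'   `"dense"` for a drugs x ADRs matrix with ID header row/column.
#' @param method method tag used in the long layout when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path, layout = c("long", "dense"),
                                method = NULL) {
  layout <- match.arg(layout)
  m <- score_matrix_of(x)
  if (is.null(method))
    method <- if (!is.null(x$method)) x$method else "score"
  if (layout == "long") {
    df <- data.frame(
      drug = rep(rownames(m), times = ncol(m)),
      adr = rep(colnames(m), each = nrow(m)),
      score = as.vector(m),
      method = method,
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

# Extract the numeric score matrix from any of the score containers.
# Dimnames are mandatory wherever pairs are looked up by ID. Internal.
score_matrix_of <- function(x, require_names = TRUE) {
  if (inherits(x, "signal_matrix")) return(x$scores)
  if (inherits(x, "propagated_signals")) return(x$y)
  if (is.matrix(x) && is.numeric(x)) {
    if (require_names && (is.null(rownames(x)) || is.null(colnames(x))))
      stop("score matrix must have drug rownames and ADR colnames")
    return(x)
  }
  stop("expected a signal_matrix, propagated_signals, or named numeric matrix")
}
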