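#' Label propagation of signal scores over the drug similarity network
#'
#' Starting from the original signal matrix S (one column per ADR), each drug
#' node repeatedly absorbs its neighbors' scores with probability `gamma`
#' while retaining a (1 - gamma) share of its own original score:
#' `Y_t = gamma W Y_{t-1} + (1 - gamma) S`, with `W` the row-stochastic
#' transition matrix of the similarity network. Because the spectral radius
#' of `W` is at most 1 and `0 < gamma < 1`, the iteration converges
#' geometrically to the closed form `Y = (1 - gamma) (I - gamma W)^{-1} S`.
#'
#' `propagate_closed_form` solves the linear system directly (the default,
#' exact up to solver precision); `propagate_iterative` runs the fixed-point
#' iteration from `Y_0 = S` until the max-norm change falls below `tol`.
#'
#' @param W row-stochastic transition matrix from [row_normalize()].
#' @param S original signal matrix: a `signal_matrix` object or a numeric
#'   matrix with drug rownames matching `W`.
#' @param gamma absorbing probability, strictly inside (0, 1).
#' @param max_iter iteration cap for the iterative mode.
#' @param tol max-norm convergence tolerance for the iterative mode.
#' @return An object of class `propagated_signals`: list with the enhanced
#'   matrix `y`, `gamma`, `iterations` (0 for the closed form), `converged`
#'   and `source_method` (the originating algorithm tag, when known).
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("D1", "D2"), c("D1", "D2")))
#' S <- matrix(c(1, 0), 2, 1, dimnames = list(c("D1", "D2"), "A1"))
#' propagate_closed_form(W, S, gamma = 0.5)$y  # (2/3, 1/3)
#' @export
propagate_closed_form <- function(W, S, gamma) {
  x <- check_propagation_inputs(W, S, gamma)
  n <- nrow(x$W)
  y <- solve(diag(n) - gamma * x$W, (1 - gamma) * x$S)
  if (!all(is.finite(y)))
    stop("propagation produced non-finite values; check W and S")
  dimnames(y) <- dimnames(x$S)
  structure(list(y = y, gamma = gamma, iterations = 0L, converged = TRUE,
                 source_method = x$method),
            class = "propagated_signals")
}

#' @rdname propagate_closed_form
#' @export
propagate_iterative <- function(W, S, gamma, max_iter = 10000L, tol = 1e-9) {
  x <- check_propagation_inputs(W, S, gamma)
  stopifnot(max_iter >= 1L, tol > 0)
  y <- x$S
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    y_new <- gamma * (x$W %*% y) + (1 - gamma) * x$S
    if (!all(is.finite(y_new)))
      stop("propagation produced non-finite values at iteration ", iter)
    delta <- max(abs(y_new - y))
    y <- y_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(y) <- dimnames(x$S)
  structure(list(y = y, gamma = gamma, iterations = iter, converged = converged,
                 source_method = x$method),
            class = "propagated_signals")
}

# Shared validation for the propagation entry points. Internal.
check_propagation_inputs <- function(W, S, gamma) {
  method <- if (inherits(S, "signal_matrix")) S$method else NULL
  S <- score_matrix_of(S, require_names = FALSE)
  stopifnot(is.matrix(W), is.numeric(W), nrow(W) == ncol(W))
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma < 1))
    stop("gamma must lie strictly inside (0, 1)")
  if (nrow(S) != nrow(W))
    stop("S has ", nrow(S), " drug rows but W is ", nrow(W), "x", ncol(W))
  if (!is.null(rownames(W)) && !identical(rownames(W), rownames(S)))
    stop("drug ordering of W and S differ")
  list(W = W, S = S, method = method)
}

#' @export
print.propagated_signals <- function(x, ...) {
  cat("Propagated signals",
      if (!is.null(x$source_method)) paste0("(", x$source_method, ")") else "",
      ": ", nrow(x$y), " drugs x ", ncol(x$y), " ADRs, gamma=", x$gamma,
      if (x$iterations > 0L)
        paste0(", ", x$iterations, " iterations",
               if (!x$converged) " (NOT converged)")
      else ", closed form",
      "\n", sep = "")
  invisible(x)
}

#' Score a newly approved drug with no case reports
#'
#' A drug absent from the report database has no original signal: its row of
#' S is all zeros. Its chemistry is still informative, so the similarity
#' network is extended with the new drug's Jaccard row/column, re-normalized,
#' and the closed-form propagation is run on the augmented system; the new
#' drug's row of Y is returned. A drug whose fingerprint matches nothing
#' (all-zero similarity) keeps its zero label (isolated-node fallback) and a
#' warning is raised.
#'
#' @param fp [fingerprint()] of the new drug (ID must not be in `S`).
#' @param known_profiles named list of fingerprints for the drugs already in
#'   `S`; drugs of `S` missing from this list participate as isolated nodes.
#' @param S original `signal_matrix` (or named numeric matrix).
#' @param gamma absorbing probability in (0, 1).
#' @return Named numeric vector of enhanced scores, one per ADR.
#' @export
score_new_drug <- function(fp, known_profiles, S, gamma) {
  stopifnot(inherits(fp, "fingerprint"))
  Sm <- score_matrix_of(S)
  if (fp$drug %in% rownames(Sm))
    stop("drug ", fp$drug, " is already in the signal matrix universe")
  profiles <- align_profiles(known_profiles, rownames(Sm))
  A <- build_similarity_matrix(c(profiles, list(fp)))
  W <- row_normalize(A)
  if (all(A[fp$drug, ] == 0))
    warning("new drug ", fp$drug,
            " has zero similarity to every known drug; scores are all zero")
  S_ext <- rbind(Sm, matrix(0, 1, ncol(Sm)))
  rownames(S_ext) <- c(rownames(Sm), fp$drug)
  ord <- rownames(W)
  y <- propagate_closed_form(W, S_ext[ord, , drop = FALSE], gamma)$y
  stats::setNames(y[fp$drug, ], colnames(Sm))
}

# Ensure every drug of the universe has a profile, adding empty fingerprints
# (isolated nodes) for drugs lacking chemistry. Internal.
align_profiles <- function(profiles, drugs) {
  names(profiles) <- vapply(profiles, `[[`, character(1), "drug")
  out <- lapply(drugs, function(d) {
    if (!is.null(profiles[[d]])) profiles[[d]] else fingerprint(d, integer(0))
  })
  names(out) <- drugs
  out
}

#' Write propagated signals with a sidecar metadata file
#'
#' The matrix is written with [write_signal_matrix()]; `gamma` and the source
#' method are recorded in `<path>.meta` as `key=value` lines.
#'
#' @param x a `propagated_signals` object.
#' @param path output file path.
#' @param layout passed to [write_signal_matrix()].
#' @return `path`, invisibly.
#' @export
write_propagated <- function(x, path, layout = "long") {
  stopifnot(inherits(x, "propagated_signals"))
  method <- if (is.null(x$source_method)) "unknown" else x$source_method
  write_signal_matrix(x$y, path, layout = layout,
                      method = paste0("LP-", method))
  writeLines(c(paste0("gamma=", x$gamma),
               paste0("source_method=", method),
               paste0("iterations=", x$iterations),
               paste0("converged=", tolower(as.character(x$converged)))),
             paste0(path, ".meta"))
  invisible(path)
}
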