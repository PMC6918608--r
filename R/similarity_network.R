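#' Substructure fingerprint profiles
#'
#' A fingerprint is an 881-position binary profile over predefined chemical
#' substructure keys; position k is 1 when the substructure is present in the
#' drug's 2D structure. Profiles are stored sparsely as the sorted integer
#' positions (1-based) of the "on" keys.
#'
#' @param drug drug ID (string).
#' @param on_keys integer vector of 1-based on-key positions, or a length-881
#'   0/1 vector, or a single 881-character "0"/"1" string.
#' @return An object of class `fingerprint`: list with `drug` and `on`
#'   (sorted integer positions).
#' @examples
#' fp <- fingerprint("D1", c(1, 6, 881))
#' @export
fingerprint <- function(drug, on_keys) {
  stopifnot(is.character(drug), length(drug) == 1L, nzchar(drug))
  if (is.character(on_keys) && length(on_keys) == 1L) {
    if (nchar(on_keys) != FP_LEN)
      stop("fingerprint string must have exactly ", FP_LEN, " characters, got ",
           nchar(on_keys))
    bits <- strsplit(on_keys, "", fixed = TRUE)[[1L]]
    if (!all(bits %in% c("0", "1")))
      stop("fingerprint string may contain only 0 and 1")
    on_keys <- which(bits == "1")
  } else if (is.numeric(on_keys) && length(on_keys) == FP_LEN &&
             all(on_keys %in% c(0, 1))) {
    on_keys <- which(on_keys == 1)
  }
  on_keys <- as.integer(on_keys)
  if (anyNA(on_keys) || any(on_keys < 1L) || any(on_keys > FP_LEN))
    stop("on-key positions must be integers in 1..", FP_LEN)
  structure(list(drug = drug, on = sort(unique(on_keys))), class = "fingerprint")
}

# Number of substructure keys in the fingerprint dictionary.
FP_LEN <- 881L

#' @export
print.fingerprint <- function(x, ...) {
  cat("Fingerprint for", x$drug, "-", length(x$on), "of", FP_LEN, "keys on\n")
  invisible(x)
}

#' Jaccard similarity of two fingerprints
#'
#' `|on(a) intersect on(b)| / |on(a) union on(b)|`. Two empty fingerprints
#' have similarity 0 (no evidence of similarity, avoiding 0/0).
#'
#' @param a,b [fingerprint()] objects.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  u <- length(union(a$on, b$on))
  if (u == 0L) return(0)
  length(intersect(a$on, b$on)) / u
}

#' Build the drug-drug similarity matrix
#'
#' Drugs are nodes of the similarity network; the edge weight between two
#' drugs is the Jaccard similarity of their substructure fingerprints. The
#' diagonal is set to 0 (no self-edges): the propagation update already
#' retains each drug's own signal through its (1 - gamma) S term, so
#' self-loops would double-count self-information.
#'
#' @param profiles a list of [fingerprint()] objects with unique drug IDs.
#' @return A symmetric numeric matrix with drug IDs as dimnames, entries in
#'   `[0, 1]`, zero diagonal.
#' @export
build_similarity_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  stopifnot(all(vapply(profiles, inherits, logical(1), "fingerprint")))
  drugs <- unname(vapply(profiles, `[[`, character(1), "drug"))
  if (anyDuplicated(drugs))
    stop("duplicate drug ID(s) in fingerprint list: ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
  n <- length(drugs)
  M <- matrix(0, n, FP_LEN)
  for (i in seq_len(n)) M[i, profiles[[i]]$on] <- 1
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  un <- outer(sizes, sizes, `+`) - inter
  A <- ifelse(un > 0, inter / un, 0)
  diag(A) <- 0
  dimnames(A) <- list(drugs, drugs)
  A
}

#' Row-normalize a similarity matrix into a transition matrix
#'
#' Each row of the similarity matrix is divided by its sum so that rows sum
#' to one (the propagation operator's premise: spectral radius at most 1).
#' A drug with no similarity to any other (all-zero row) becomes a unit
#' self-loop row, so that under propagation it retains a gamma-weighted copy
#' of its own label and its enhanced score equals its original score.
#'
#' @param A symmetric nonnegative similarity matrix (see
#'   [build_similarity_matrix()]).
#' @return Row-stochastic matrix `W` of the same shape and dimnames.
#' @export
row_normalize <- function(A) {
  stopifnot(is.matrix(A), is.numeric(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("similarity matrix must be nonnegative")
  rs <- rowSums(A)
  W <- A
  pos <- rs > 0
  W[pos, ] <- A[pos, , drop = FALSE] / rs[pos]
  if (any(!pos)) {
    W[!pos, ] <- 0
    W[cbind(which(!pos), which(!pos))] <- 1
  }
  W
}

#' Read fingerprints from a TSV file
#'
#' Two dialects are accepted in the `keys` column: an 881-character 0/1
#' string, or a pipe-separated list of 0-based on-key indices (an empty field
#' is an empty fingerprint). Header must be `drug<TAB>keys`.
#'
#' @param path path to the fingerprint TSV.
#' @return A named list of [fingerprint()] objects (names = drug IDs).
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("fingerprint file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("fingerprint file is empty: ", path)
  if (!identical(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]], c("drug", "keys")))
    stop("bad header in ", path, ": expected drug<TAB>keys")
  out <- list()
  for (i in 2L:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!length(f) %in% c(1L, 2L))
      stop("parse error at line ", i, " of ", path, ": expected 2 fields")
    drug <- f[1L]
    keys <- if (length(f) == 2L) f[2L] else ""
    if (!is.null(out[[drug]]))
      stop("parse error at line ", i, " of ", path, ": duplicate drug ", drug)
    is_bitstring <- !grepl("|", keys, fixed = TRUE) &&
      grepl("^[01]+$", keys) && nchar(keys) > 4L
    fp <- if (is_bitstring) {
      if (nchar(keys) != FP_LEN)
        stop("parse error at line ", i, " of ", path, ": bit string must have ",
             FP_LEN, " characters, got ", nchar(keys))
      fingerprint(drug, keys)
    } else if (keys == "") {
      fingerprint(drug, integer(0))
    } else {
      idx <- suppressWarnings(as.integer(strsplit(keys, "|", fixed = TRUE)[[1L]]))
      if (anyNA(idx) || any(idx < 0L) || any(idx >= FP_LEN))
        stop("parse error at line ", i, " of ", path,
             ": on-key indices must be 0-based integers below ", FP_LEN)
      fingerprint(drug, idx + 1L)
    }
    out[[drug]] <- fp
  }
  out
}

#' Write fingerprints to a TSV file (0-based on-key index dialect)
#'
#' @param profiles named list of [fingerprint()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(profiles, path) {
  rows <- vapply(profiles, function(fp) {
    paste0(fp$drug, "\t", paste(fp$on - 1L, collapse = "|"))
  }, character(1))
  writeLines(c("drug\tkeys", rows), path)
  invisible(path)
}

#' Write the similarity matrix as an upper-triangle edge list
#'
#' @param A similarity matrix from [build_similarity_matrix()].
#' @param path output file path.
#' @param min_sim edges with similarity below this value are omitted
#'   (default 0 keeps all nonzero edges).
#' @return `path`, invisibly.
#' @export
write_similarity_edges <- function(A, path, min_sim = 0) {
  idx <- which(upper.tri(A) & A > min_sim, arr.ind = TRUE)
  df <- data.frame(drug_i = rownames(A)[idx[, 1]],
                   drug_j = colnames(A)[idx[, 2]],
                   sim = A[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
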