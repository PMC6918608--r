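#' Case-report collections
#'
#' A report collection holds spontaneous case reports -- one record per report
#' with an opaque report ID, the set of drugs mentioned, the set of adverse
#' drug reactions (ADRs) mentioned, and the calendar year of the report. The
#' drug and ADR universes are the sorted unique IDs appearing in any retained
#' report; every matrix downstream (counts, signals, similarities) uses this
#' lexicographic ordering, so results are independent of file row order.
#'
#' @param reports a list of reports, each a list with elements `report_id`
#'   (string), `drugs` (character vector, deduplicated), `adrs` (character
#'   vector, deduplicated) and `year` (integer).
#' @return An object of class `report_collection`: a list with elements
#'   `reports`, `drug_universe` and `adr_universe`.
#' @examples
#' rc <- report_collection(list(
#'   list(report_id = "r1", drugs = "D1", adrs = c("A1", "A2"), year = 2004L)
#' ))
#' rc$drug_universe
#' @export
report_collection <- function(reports) {
  stopifnot(is.list(reports))
  if (length(reports) == 0L)
    stop("report collection must contain at least one report")
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    if (!all(c("report_id", "drugs", "adrs", "year") %in% names(r)))
      stop("report ", i, " is missing required fields")
    if (length(r$drugs) < 1L || any(!nzchar(r$drugs)))
      stop("report ", i, " ('", r$report_id, "'): empty drug set")
    if (length(r$adrs) < 1L || any(!nzchar(r$adrs)))
      stop("report ", i, " ('", r$report_id, "'): empty ADR set")
    yr <- r$year
    if (length(yr) != 1L || is.na(yr) || yr != as.integer(yr) ||
        yr < 1000L || yr > 9999L)
      stop("report ", i, " ('", r$report_id, "'): year must be a 4-digit integer")
    reports[[i]]$drugs <- unique(as.character(r$drugs))
    reports[[i]]$adrs <- unique(as.character(r$adrs))
    reports[[i]]$year <- as.integer(yr)
  }
  structure(
    list(
      reports = reports,
      drug_universe = sort(unique(unlist(lapply(reports, `[[`, "drugs")))),
      adr_universe = sort(unique(unlist(lapply(reports, `[[`, "adrs"))))
    ),
    class = "report_collection"
  )
}

#' @export
print.report_collection <- function(x, ...) {
  yrs <- range(vapply(x$reports, `[[`, integer(1), "year"))
  cat("Report collection:", length(x$reports), "reports,",
      length(x$drug_universe), "drugs,", length(x$adr_universe), "ADRs,",
      "years", yrs[1], "-", yrs[2], "\n")
  invisible(x)
}

#' Read case reports from a tab-separated file
#'
#' The file must be UTF-8, tab-separated, with a header row
#' `report_id<TAB>drugs<TAB>adrs<TAB>year`; `drugs` and `adrs` are
#' pipe-separated ID lists. Duplicate report IDs keep the first occurrence;
#' later duplicates are dropped with a warning.
#'
#' @param path path to the reports TSV file.
#' @param format input format; only `"tabular"` is supported.
#' @return A [report_collection()].
#' @export
read_reports <- function(path, format = "tabular") {
  format <- match.arg(format, "tabular")
  if (!file.exists(path)) stop("reports file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("reports file is empty: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("report_id", "drugs", "adrs", "year")))
    stop("bad header in ", path, ": expected report_id/drugs/adrs/year")
  reports <- vector("list", length(lines) - 1L)
  for (i in 2L:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L)
      stop("parse error at line ", i, " of ", path, ": expected 4 fields, got ",
           length(f))
    drugs <- strsplit(f[2L], "|", fixed = TRUE)[[1L]]
    adrs <- strsplit(f[3L], "|", fixed = TRUE)[[1L]]
    if (length(drugs) == 0L || any(!nzchar(drugs)))
      stop("parse error at line ", i, " of ", path, ": empty drug field")
    if (length(adrs) == 0L || any(!nzchar(adrs)))
      stop("parse error at line ", i, " of ", path, ": empty ADR field")
    year <- suppressWarnings(as.integer(f[4L]))
    if (is.na(year))
      stop("parse error at line ", i, " of ", path, ": bad year '", f[4L], "'")
    reports[[i - 1L]] <- list(report_id = f[1L], drugs = drugs, adrs = adrs,
                              year = year)
  }
  ids <- vapply(reports, `[[`, character(1), "report_id")
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicate report_id(s) dropped (first occurrence kept): ",
            paste(unique(ids[dup]), collapse = ", "))
    reports <- reports[!dup]
  }
  report_collection(reports)
}

#' Restrict a collection to reports up to a cutoff year
#'
#' Used for cumulative-year analyses: keep the reports with
#' `year <= last_year` and rebuild the drug/ADR universes from the retained
#' reports only.
#'
#' @param rc a [report_collection()].
#' @param last_year integer cutoff (inclusive).
#' @return A [report_collection()] containing reports with `year <= last_year`.
#' @export
filter_by_year <- function(rc, last_year) {
  stopifnot(inherits(rc, "report_collection"))
  years <- vapply(rc$reports, `[[`, integer(1), "year")
  keep <- years <= last_year
  if (!any(keep))
    stop("no reports at or before year ", last_year,
         " (earliest report year is ", min(years), ")")
  report_collection(rc$reports[keep])
}

#' Aggregate reports into a drug-by-ADR count table
#'
#' Counts are report-based: `n[i, j]` is the number of reports mentioning both
#' drug i and ADR j, the drug margin counts reports mentioning the drug, and
#' the ADR margin counts reports mentioning the ADR. A multi-drug report
#' contributes to the margin of every listed drug.
#'
#' @param rc a [report_collection()].
#' @return An object of class `count_table`: list with the count matrix `n`
#'   (drugs x ADRs, dimnames from the universes), `drug_margins`,
#'   `adr_margins` and `total` (number of reports).
#' @export
build_count_table <- function(rc) {
  stopifnot(inherits(rc, "report_collection"))
  drugs <- rc$drug_universe
  adrs <- rc$adr_universe
  n <- matrix(0L, length(drugs), length(adrs), dimnames = list(drugs, adrs))
  drug_margins <- stats::setNames(integer(length(drugs)), drugs)
  adr_margins <- stats::setNames(integer(length(adrs)), adrs)
  for (r in rc$reports) {
    di <- match(r$drugs, drugs)
    ai <- match(r$adrs, adrs)
    n[di, ai] <- n[di, ai] + 1L
    drug_margins[di] <- drug_margins[di] + 1L
    adr_margins[ai] <- adr_margins[ai] + 1L
  }
  structure(
    list(n = n, drug_margins = drug_margins, adr_margins = adr_margins,
         total = length(rc$reports)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$n), "drugs x", ncol(x$n), "ADRs,",
      x$total, "reports,", sum(x$n > 0L), "nonzero drug-ADR cells\n")
  invisible(x)
}

#' 2x2 contingency table for one drug-ADR pair
#'
#' Cells follow the standard layout: `a` reports with both drug and ADR, `b`
#' with the drug but not the ADR, `c` with the ADR but not the drug, `d` with
#' neither. `a + b` is the drug's report count, `a + c` the ADR's, and
#' `a + b + c + d` the total number of reports.
#'
#' @param ct a [build_count_table()] result.
#' @param drug,adr IDs present in the table's universes.
#' @return An object of class `contingency_table`: list with integer fields
#'   `a`, `b`, `c`, `d`.
#' @export
contingency <- function(ct, drug, adr) {
  stopifnot(inherits(ct, "count_table"))
  if (!drug %in% rownames(ct$n)) stop("unknown drug ID: ", drug)
  if (!adr %in% colnames(ct$n)) stop("unknown ADR ID: ", adr)
  a <- ct$n[drug, adr]
  b <- ct$drug_margins[[drug]] - a
  c <- ct$adr_margins[[adr]] - a
  d <- ct$total - a - b - c
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("ADR", "no ADR")))
  print(m)
  invisible(x)
}

# Coerce a contingency_table or a named list/vector with a,b,c,d to a
# plain list of nonnegative numbers. Internal.
as_abcd <- function(t) {
  if (inherits(t, "contingency_table")) return(t)
  if (is.numeric(t) && all(c("a", "b", "c", "d") %in% names(t)))
    t <- as.list(t)
  if (is.list(t) && all(c("a", "b", "c", "d") %in% names(t))) {
    v <- c(t$a, t$b, t$c, t$d)
    if (any(is.na(v)) || any(v < 0)) stop("contingency cells must be nonnegative")
    return(t[c("a", "b", "c", "d")])
  }
  stop("expected a contingency_table or a named a/b/c/d structure")
}

#' Read ground-truth drug-ADR pairs
#'
#' Reads a two-column TSV (header `drug<TAB>adr`) of known positive drug-ADR
#' associations and restricts it to the universes of a report collection.
#' Duplicate rows collapse to one pair (set semantics); out-of-universe pairs
#' are dropped with a message of how many.
#'
#' @param path path to the ground-truth TSV.
#' @param universe a [report_collection()] supplying the drug/ADR universes,
#'   or `NULL` to keep all pairs.
#' @return A data frame with character columns `drug` and `adr`.
#' @export
read_ground_truth <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug", "adr") %in% names(df)))
    stop("bad header in ", path, ": expected columns drug, adr")
  df <- unique(df[, c("drug", "adr")])
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "report_collection"))
    keep <- df$drug %in% universe$drug_universe &
      df$adr %in% universe$adr_universe
    if (sum(!keep) > 0L)
      message(sum(!keep), " ground-truth pair(s) outside the report universe dropped")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop("no ground-truth pairs remain after restriction to the universe")
  rownames(df) <- NULL
  df
}
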