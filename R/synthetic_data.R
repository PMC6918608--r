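#' Configuration for the planted-cluster synthetic dataset
#'
#' The generator emulates the statistical structure that the framework
#' exploits in real pharmacovigilance data: drugs fall into chemical
#' clusters with similar substructure fingerprints, cluster members share a
#' latent ADR profile (the ground truth), and case reports over-report the
#' true drug-ADR pairs by a controlled relative-risk multiplier. A fraction
#' of drugs is held out of the reports entirely, emulating newly approved
#' drugs whose only evidence is chemistry.
#'
#' @param n_drugs,n_adrs,n_reports problem dimensions.
#' @param n_clusters number of chemical clusters (at most `n_drugs`).
#' @param within_cluster_key_overlap probability, in (0, 1], that a member
#'   keeps each on-key of its cluster's template fingerprint (off-template
#'   keys switch on at a compensating rate so the expected on-count is
#'   preserved).
#' @param adr_signal_strength relative-risk multiplier (>= 1) applied to the
#'   background ADR rate for a drug's true ADRs, capped at probability 1.
#' @param background_report_rate per-report probability that any given ADR is
#'   mentioned, absent a true association.
#' @param frac_holdout_drugs fraction of drugs withheld from all reports.
#' @param adr_per_cluster_frac fraction of the ADR universe planted as each
#'   cluster's latent ADR profile (at least one ADR per cluster).
#' @param template_on_keys number of on-keys in each cluster template
#'   fingerprint (of the 881-key dictionary).
#' @param drugs_per_report drugs mentioned per report (1 keeps contingency
#'   counting simple; higher values exercise multi-drug reports).
#' @param years calendar years the reports are spread uniformly over.
#' @param seed integer RNG seed driving all randomness.
#' @return An object of class `synth_config` (validated list of the above).
#' @export
synth_config <- function(n_drugs = 60L, n_adrs = 30L, n_reports = 5000L,
                         n_clusters = 6L, within_cluster_key_overlap = 0.9,
                         adr_signal_strength = 5,
                         background_report_rate = 0.05,
                         frac_holdout_drugs = 0.1,
                         adr_per_cluster_frac = 0.15,
                         template_on_keys = 120L,
                         drugs_per_report = 1L,
                         years = 2004:2014,
                         seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_adrs = as.integer(n_adrs),
              n_reports = as.integer(n_reports),
              n_clusters = as.integer(n_clusters),
              within_cluster_key_overlap = within_cluster_key_overlap,
              adr_signal_strength = adr_signal_strength,
              background_report_rate = background_report_rate,
              frac_holdout_drugs = frac_holdout_drugs,
              adr_per_cluster_frac = adr_per_cluster_frac,
              template_on_keys = as.integer(template_on_keys),
              drugs_per_report = as.integer(drugs_per_report),
              years = as.integer(years),
              seed = as.integer(seed))
  stopifnot(cfg$n_drugs >= 2L, cfg$n_adrs >= 1L, cfg$n_reports >= 1L,
            cfg$n_clusters >= 1L, cfg$n_clusters <= cfg$n_drugs,
            cfg$within_cluster_key_overlap > 0,
            cfg$within_cluster_key_overlap <= 1,
            cfg$adr_signal_strength >= 1,
            cfg$background_report_rate >= 0, cfg$background_report_rate <= 1,
            cfg$frac_holdout_drugs >= 0, cfg$frac_holdout_drugs < 1,
            cfg$template_on_keys >= 1L, cfg$template_on_keys <= FP_LEN,
            cfg$drugs_per_report >= 1L, length(cfg$years) >= 1L)
  structure(cfg, class = "synth_config")
}

#' Generate a planted-cluster synthetic dataset
#'
#' Performs, in order and entirely from the configured seed: (1) drugs are
#' assigned to clusters and each cluster draws a random template fingerprint;
#' member fingerprints copy the template, keeping each on-key with the
#' configured overlap probability and switching each off-key on at the
#' compensating rate; (2) each cluster draws a latent ADR subset, and the
#' ground truth is every (member, cluster ADR) pair; (3) each report picks
#' its drug(s) uniformly among the non-holdout drugs and mentions each ADR
#' with the background rate, multiplied by the signal strength for the
#' drug's true ADRs (capped at 1); a report whose ADR draw comes up empty is
#' redrawn; (4) holdout drugs appear in the fingerprints and the truth but
#' in no report. Ground-truth pairs whose ADR never occurs in a report are
#' dropped so that every truth ADR is observed.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `synth_dataset`: list with `reports`
#'   (a [report_collection()]), `fingerprints` (named list), `truth`
#'   (data frame `drug`, `adr`), `clusters` (named integer vector),
#'   `holdout_drugs` (character) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_preserved_rng({
    set.seed(cfg$seed)
    drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))
    adrs <- sprintf("A%03d", seq_len(cfg$n_adrs))

    # (1) clusters and fingerprints
    clusters <- stats::setNames(
      sample(rep_len(seq_len(cfg$n_clusters), cfg$n_drugs)), drugs)
    templates <- lapply(seq_len(cfg$n_clusters), function(k)
      sort(sample.int(FP_LEN, cfg$template_on_keys)))
    o <- cfg$within_cluster_key_overlap
    n_on <- cfg$template_on_keys
    off_rate <- min(1, n_on * (1 - o) / (FP_LEN - n_on))
    fingerprints <- lapply(drugs, function(d) {
      tmpl <- templates[[clusters[[d]]]]
      keep <- tmpl[stats::runif(length(tmpl)) < o]
      extra <- setdiff(seq_len(FP_LEN), tmpl)
      extra <- extra[stats::runif(length(extra)) < off_rate]
      fingerprint(d, c(keep, extra))
    })
    names(fingerprints) <- drugs

    # (2) latent cluster ADR profiles -> ground truth
    n_true_adrs <- max(1L, round(cfg$adr_per_cluster_frac * cfg$n_adrs))
    cluster_adrs <- lapply(seq_len(cfg$n_clusters), function(k)
      sample(adrs, n_true_adrs))
    truth <- do.call(rbind, lapply(drugs, function(d) {
      data.frame(drug = d, adr = cluster_adrs[[clusters[[d]]]],
                 stringsAsFactors = FALSE)
    }))

    # (3) holdout drugs: keep at least two reporting members per cluster so
    # the planted mechanism (neighbors carry the signal) remains defined
    n_holdout <- floor(cfg$frac_holdout_drugs * cfg$n_drugs)
    holdout <- character(0)
    if (n_holdout > 0L) {
      retained <- table(clusters)
      for (d in sample(drugs)) {
        if (length(holdout) >= n_holdout) break
        k <- as.character(clusters[[d]])
        if (retained[[k]] > 2L) {
          holdout <- c(holdout, d)
          retained[[k]] <- retained[[k]] - 1L
        }
      }
    }
    reporting <- setdiff(drugs, holdout)

    # (4) reports: vectorized ADR inclusion draws with per-drug probabilities
    P <- matrix(cfg$background_report_rate, cfg$n_drugs, cfg$n_adrs,
                dimnames = list(drugs, adrs))
    P[cbind(match(truth$drug, drugs), match(truth$adr, adrs))] <-
      min(1, cfg$background_report_rate * cfg$adr_signal_strength)
    report_drugs <- replicate(cfg$n_reports,
                              sample(reporting, cfg$drugs_per_report),
                              simplify = FALSE)
    prob_rows <- t(vapply(report_drugs, function(ds) {
      1 - apply(1 - P[ds, , drop = FALSE], 2, prod)
    }, numeric(cfg$n_adrs)))
    draws <- matrix(stats::runif(cfg$n_reports * cfg$n_adrs),
                    cfg$n_reports, cfg$n_adrs) < prob_rows
    for (i in which(rowSums(draws) == 0L)) {
      for (try in 1:100) {
        draws[i, ] <- stats::runif(cfg$n_adrs) < prob_rows[i, ]
        if (any(draws[i, ])) break
      }
      if (!any(draws[i, ]))  # pathological rates; keep the report well-formed
        draws[i, sample.int(cfg$n_adrs, 1L)] <- TRUE
    }
    report_years <- sample(cfg$years, cfg$n_reports, replace = TRUE)
    reports <- lapply(seq_len(cfg$n_reports), function(i) {
      list(report_id = sprintf("R%06d", i), drugs = report_drugs[[i]],
           adrs = adrs[draws[i, ]], year = report_years[[i]])
    })
    rc <- report_collection(reports)

    observed_adrs <- rc$adr_universe
    dropped <- truth[!truth$adr %in% observed_adrs, , drop = FALSE]
    if (nrow(dropped) > 0L)
      truth <- truth[truth$adr %in% observed_adrs, , drop = FALSE]
    zero_report <- setdiff(reporting, rc$drug_universe)
    if (length(zero_report) > 0L)
      warning("non-holdout drug(s) received no reports: ",
              paste(zero_report, collapse = ", "))
    rownames(truth) <- NULL
    structure(list(reports = rc, fingerprints = fingerprints, truth = truth,
                   clusters = clusters, holdout_drugs = sort(holdout),
                   config = cfg),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset:", x$config$n_drugs, "drugs in", x$config$n_clusters,
      "clusters,", x$config$n_adrs, "ADRs,", length(x$reports$reports),
      "reports,", nrow(x$truth), "truth pairs,",
      length(x$holdout_drugs), "holdout drugs (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `reports.tsv`, `fingerprints.tsv` and `truth.tsv` in the package's
#' standard formats, plus `manifest.txt` recording every configuration field
#' (including the seed) as `key=value` lines.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(ds$reports$reports, function(r) {
    paste(r$report_id, paste(r$drugs, collapse = "|"),
          paste(r$adrs, collapse = "|"), r$year, sep = "\t")
  }, character(1))
  writeLines(c("report_id\tdrugs\tadrs\tyear", rows),
             file.path(dir, "reports.tsv"))
  write_fingerprints(ds$fingerprints, file.path(dir, "fingerprints.tsv"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- ds$config
  writeLines(
    vapply(names(cfg), function(k)
      paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1)),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}
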