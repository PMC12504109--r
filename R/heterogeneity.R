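#' Leave-one-out meta-analysis
#'
#' Re-pools the consortium once per study with that study removed,
#' preserving the array-stratified two-stage structure. Used to check that
#' no single study drives a pooled association.
#'
#' @param stats_by_study list of \code{summary_stats} tables (>= 2).
#' @param probes probe ids to report (default: all probes in the full
#'   pooled table).
#' @param config a \code{\link{meta_config}}; by default the presence and
#'   sample-size filters are disabled so every probe requested is pooled
#'   from whatever studies carry it.
#' @return data.frame: probe, left_out, beta, se, p — k rows per probe for
#'   k studies.
#' @export
leave_one_out_meta <- function(stats_by_study, probes = NULL,
                               config = meta_config(presence_fraction = 1e-9,
                                                    n_fraction_of_max = 1e-9)) {
  if (length(stats_by_study) < 2) stop("need at least 2 studies")
  ids <- vapply(stats_by_study, function(s) s$study_id[1], character(1))
  out <- lapply(seq_along(stats_by_study), function(i) {
    mt <- two_stage_meta(stats_by_study[-i], config)
    if (!is.null(probes)) mt <- mt[mt$probe %in% probes, , drop = FALSE]
    if (nrow(mt) == 0) return(NULL)
    data.frame(probe = mt$probe, left_out = ids[i], beta = mt$beta,
               se = mt$se, p = mt$p, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Meta-regression of study effects on mean age
#'
#' Mixed-effects meta-regression of the per-study standardized
#' coefficients on cohort mean age, with inverse-variance weights and
#' between-study variance estimated by REML (via \pkg{metafor}).
#'
#' @param per_study_beta,per_study_se study-level effect and standard
#'   error for one probe.
#' @param mean_ages cohort mean ages in years; must vary.
#' @param method \code{"REML"} (default) or \code{"FE"} (forces tau^2 = 0,
#'   reducing to weighted least squares).
#' @return list: \code{coef} (effect per year of mean age), \code{se},
#'   \code{p}, \code{tau2}, \code{k}.
#' @export
meta_regression_age <- function(per_study_beta, per_study_se, mean_ages,
                                method = "REML") {
  k <- length(per_study_beta)
  if (k < 3) stop("need at least 3 studies")
  if (stats::sd(mean_ages) < 1e-12)
    stop("zero moderator variance: mean ages are all equal")
  fit <- metafor::rma(yi = per_study_beta, sei = per_study_se,
                      mods = ~mean_ages, method = method)
  list(coef = unname(fit$beta["mean_ages", 1]),
       se = unname(fit$se[2]), p = unname(fit$pval[2]),
       tau2 = fit$tau2, k = k)
}

#' Effect-direction concordance between two sets of summary statistics
#'
#' @param stats_a,stats_b tables with \code{probe} and \code{beta}.
#' @param probes probes to compare; must be present in both tables.
#' @return list: \code{n_concordant}, \code{n_total}, \code{percent}
#'   (1 d.p.), and \code{flagged} (probes with a zero beta, counted
#'   non-concordant).
#' @export
direction_concordance <- function(stats_a, stats_b, probes) {
  ia <- match(probes, stats_a$probe); ib <- match(probes, stats_b$probe)
  if (anyNA(ia) || anyNA(ib))
    stop("probes missing from one of the tables: ",
         paste(utils::head(probes[is.na(ia) | is.na(ib)], 5),
               collapse = ", "))
  sa <- sign(stats_a$beta[ia]); sb <- sign(stats_b$beta[ib])
  zero <- sa == 0 | sb == 0
  conc <- sa == sb & !zero
  list(n_concordant = sum(conc), n_total = length(probes),
       percent = round(100 * sum(conc) / length(probes), 1),
       flagged = probes[zero])
}

#' Select a reference study's top-k probes by p-value
#'
#' Deterministic: ordered by p ascending with probe id as tie-break.
#'
#' @param stats a \code{summary_stats} or \code{meta_result} table.
#' @param k number of probes.
#' @return character vector of probe ids.
#' @export
top_k_probes <- function(stats, k) {
  ord <- order(stats$p, stats$probe)
  stats$probe[ord][seq_len(min(k, nrow(stats)))]
}

#' Pairwise between-study correlation of effect sizes
#'
#' Pearson correlation of per-study effect sizes over a fixed probe list
#' (typically the reference study's top-k associations), for every
#' unordered study pair. Pairs are computed on complete-case overlap;
#' pairs with fewer than 3 shared probes are reported missing.
#'
#' @param stats_by_study list of \code{summary_stats} tables.
#' @param probe_list probes over which to correlate.
#' @return list: \code{correlation} (k x k symmetric matrix, unit
#'   diagonal), \code{n_pairs}, \code{n_positive}, \code{percent_positive},
#'   \code{missing_pairs}.
#' @export
pairwise_effect_correlation <- function(stats_by_study, probe_list) {
  if (length(stats_by_study) < 2) stop("need at least 2 studies")
  ids <- vapply(stats_by_study, function(s) s$study_id[1], character(1))
  B <- sapply(stats_by_study, function(s)
    s$beta[match(probe_list, s$probe)])
  colnames(B) <- ids
  k <- length(ids)
  R <- diag(1, k); dimnames(R) <- list(ids, ids)
  missing_pairs <- character()
  rs <- numeric()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(B[, c(i, j)])
    if (sum(ok) < 3) {
      R[i, j] <- R[j, i] <- NA
      missing_pairs <- c(missing_pairs, paste(ids[i], ids[j], sep = ":"))
    } else {
      R[i, j] <- R[j, i] <- stats::cor(B[ok, i], B[ok, j])
      rs <- c(rs, R[i, j])
    }
  }
  n_pairs <- k * (k - 1) / 2
  list(correlation = R, n_pairs = n_pairs, n_positive = sum(rs > 0),
       percent_positive = round(100 * sum(rs > 0) / n_pairs, 1),
       missing_pairs = missing_pairs)
}
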