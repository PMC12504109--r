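#' Meta-analysis configuration
#'
#' Probe-inclusion filters and the family-wise level for the two-stage,
#' array-stratified fixed-effect meta-analysis. Within each array a probe is
#' kept if it is available in more than \code{presence_fraction} of that
#' array's studies (strict: 3 of 6 fails, 4 of 6 passes) or if its summed
#' analyzed sample size reaches \code{n_fraction_of_max} of the array's
#' maximum possible total. Individual study records with standard errors
#' above \code{se_max} are dropped before either test.
#'
#' @param se_max per-record standard-error ceiling (excessive-s.e. filter).
#' @param presence_fraction strict presence threshold ("more than half").
#' @param n_fraction_of_max sample-size rescue threshold ("over 80%"),
#'   applied as \code{>=} by default; set \code{n_rule_strict = TRUE} for a
#'   strict \code{>}.
#' @param alpha family-wise error level for Bonferroni significance.
#' @param n_rule_strict see \code{n_fraction_of_max}.
#' @return a \code{meta_config} list.
#' @export
meta_config <- function(se_max = 0.5, presence_fraction = 0.5,
                        n_fraction_of_max = 0.80, alpha = 0.05,
                        n_rule_strict = FALSE) {
  check_number(se_max, "se_max", lower = 0, open_lower = TRUE)
  check_number(presence_fraction, "presence_fraction", lower = 0, upper = 1,
               open_lower = TRUE)
  check_number(n_fraction_of_max, "n_fraction_of_max", lower = 0, upper = 1,
               open_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  structure(list(se_max = se_max, presence_fraction = presence_fraction,
                 n_fraction_of_max = n_fraction_of_max, alpha = alpha,
                 n_rule_strict = isTRUE(n_rule_strict)),
            class = "meta_config")
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each estimate by its inverse squared standard error:
#' \code{w_i = 1/se_i^2}, pooled beta \code{sum(w b)/sum(w)}, pooled
#' \code{se = 1/sqrt(sum(w))}, \code{z = beta/se}, two-sided normal p.
#' No genomic-control correction is applied.
#'
#' @param betas,ses equal-length vectors; all \code{ses > 0}.
#' @return list with \code{beta}, \code{se}, \code{z}, \code{p}.
#' @export
ivw_fixed_effect <- function(betas, ses) {
  if (length(betas) == 0) stop("empty input")
  if (length(betas) != length(ses)) stop("betas and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be finite and > 0")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Apply the probe-inclusion filters
#'
#' @param stats_by_study list of \code{summary_stats} tables, each labeled
#'   with its array.
#' @param config a \code{\link{meta_config}}.
#' @return list with \code{records} (the concatenated study records that
#'   survive the s.e. filter, restricted to retained probes), and
#'   \code{report}: one row per (array, probe) stating \code{retained} and
#'   the \code{rule} responsible (\code{presence}, \code{n_rule},
#'   \code{both}, or \code{dropped}).
#' @export
filter_probes <- function(stats_by_study, config = meta_config()) {
  all_rec <- do.call(rbind, stats_by_study)
  n_dropped_se <- sum(all_rec$se > config$se_max)
  rec <- all_rec[all_rec$se <= config$se_max, , drop = FALSE]

  reports <- list()
  kept <- list()
  for (arr in unique(rec$array)) {
    ra <- rec[rec$array == arr, , drop = FALSE]
    studies <- unique(all_rec$study_id[all_rec$array == arr])
    k_arr <- length(studies)
    max_n <- sum(vapply(studies, function(s)
      max(all_rec$n[all_rec$study_id == s & all_rec$array == arr]),
      numeric(1)))
    pres <- tapply(ra$study_id, ra$probe, function(s) length(unique(s)))
    nsum <- tapply(ra$n, ra$probe, sum)
    by_presence <- pres / k_arr > config$presence_fraction
    by_n <- if (config$n_rule_strict)
      nsum / max_n > config$n_fraction_of_max
    else nsum / max_n >= config$n_fraction_of_max
    retained <- by_presence | by_n
    rule <- ifelse(by_presence & by_n, "both",
            ifelse(by_presence, "presence",
            ifelse(by_n, "n_rule", "dropped")))
    reports[[arr]] <- data.frame(array = arr, probe = names(pres),
                                 k_present = as.integer(pres),
                                 k_studies = k_arr,
                                 n_sum = as.numeric(nsum), n_max = max_n,
                                 retained = as.logical(retained),
                                 rule = rule, row.names = NULL,
                                 stringsAsFactors = FALSE)
    kept[[arr]] <- ra[retained[ra$probe], , drop = FALSE]
  }
  list(records = do.call(rbind, kept),
       report = do.call(rbind, reports),
       n_dropped_se = n_dropped_se)
}

pool_records <- function(rec, study_order = NULL) {
  # IVW-pool a set of per-study records probe by probe; optionally emit a
  # direction string over a stable study order ('+', '-', '?' if absent).
  split_idx <- split(seq_len(nrow(rec)), rec$probe)
  out <- lapply(names(split_idx), function(pr) {
    ri <- rec[split_idx[[pr]], , drop = FALSE]
    pool <- ivw_fixed_effect(ri$beta, ri$se)
    dir_str <- NA_character_
    if (!is.null(study_order)) {
      signs <- rep("?", length(study_order))
      m <- match(ri$study_id, study_order)
      signs[m] <- ifelse(ri$beta > 0, "+", ifelse(ri$beta < 0, "-", "0"))
      dir_str <- paste(signs, collapse = "")
    }
    data.frame(probe = pr, chr = ri$chr[1], pos = ri$pos[1],
               beta = pool$beta, se = pool$se, z = pool$z, p = pool$p,
               n_total = sum(ri$n), k_studies = length(unique(ri$study_id)),
               direction = dir_str, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-stage array-stratified fixed-effect meta-analysis
#'
#' Stage one pools studies within each array (after the probe-inclusion
#' filters); stage two pools the per-array results probe by probe, passing
#' through probes retained on a single array only. Bonferroni and
#' Benjamini-Hochberg adjustments are computed over all probes in the final
#' pooled table.
#'
#' @param stats_by_study list of \code{summary_stats} tables.
#' @param config a \code{\link{meta_config}}.
#' @return a \code{meta_result} data.frame: probe, chr, pos, beta, se, z,
#'   p, p_bonferroni, q_fdr, n_total, k_studies, direction. Attributes:
#'   \code{"filter_report"}, \code{"m_tests"}, \code{"study_order"}.
#' @export
two_stage_meta <- function(stats_by_study, config = meta_config()) {
  if (length(stats_by_study) < 1) stop("need at least one study")
  study_order <- vapply(stats_by_study, function(s) s$study_id[1],
                        character(1))
  flt <- filter_probes(stats_by_study, config)
  rec <- flt$records
  if (is.null(rec) || nrow(rec) == 0) {
    out <- data.frame(probe = character(), chr = character(),
                      pos = integer(), beta = numeric(), se = numeric(),
                      z = numeric(), p = numeric(),
                      p_bonferroni = numeric(), q_fdr = numeric(),
                      n_total = numeric(), k_studies = integer(),
                      direction = character(), stringsAsFactors = FALSE)
    class(out) <- c("meta_result", "data.frame")
    attr(out, "filter_report") <- flt$report
    return(out)
  }

  # Stage 1: within-array pooling (direction string spans all studies).
  stage1 <- lapply(split(rec, rec$array), pool_records,
                   study_order = study_order)
  # Stage 2: pool array-level results per probe.
  s1 <- do.call(rbind, c(stage1, list(make.row.names = FALSE)))
  split_idx <- split(seq_len(nrow(s1)), s1$probe)
  out <- lapply(names(split_idx), function(pr) {
    ri <- s1[split_idx[[pr]], , drop = FALSE]
    pool <- ivw_fixed_effect(ri$beta, ri$se)
    dirs <- strsplit(ri$direction, "")
    dir_str <- vapply(seq_along(study_order), function(j) {
      ds <- unique(unlist(lapply(dirs, `[[`, j)))
      ds <- setdiff(ds, "?")
      if (length(ds) == 0) "?" else ds[1]
    }, character(1))
    data.frame(probe = pr, chr = ri$chr[1], pos = ri$pos[1],
               beta = pool$beta, se = pool$se, z = pool$z, p = pool$p,
               n_total = sum(ri$n_total), k_studies = sum(ri$k_studies),
               direction = paste(dir_str, collapse = ""), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  m <- nrow(out)
  out$p_bonferroni <- vapply(out$p, bonferroni_adjust, numeric(1), m = m)
  out$q_fdr <- bh_fdr(out$p)
  out <- out[, c("probe", "chr", "pos", "beta", "se", "z", "p",
                 "p_bonferroni", "q_fdr", "n_total", "k_studies",
                 "direction")]
  class(out) <- c("meta_result", "data.frame")
  attr(out, "filter_report") <- flt$report
  attr(out, "m_tests") <- m
  attr(out, "study_order") <- study_order
  out
}

#' @export
print.meta_result <- function(x, n = 6L, ...) {
  k <- attr(x, "study_order")
  cat(sprintf("<meta_result> %d probes%s; %d Bonferroni-significant at m = %d\n",
              nrow(x),
              if (is.null(k)) "" else sprintf(" pooled from %d studies",
                                              length(k)),
              sum(x$p_bonferroni < 0.05), attr(x, "m_tests") %||% nrow(x)))
  if (nrow(x))
    print.data.frame(utils::head(x[order(x$p), ], n), row.names = FALSE)
  invisible(x)
}

#' Bonferroni adjustment and threshold
#'
#' \code{bonferroni_adjust} returns \code{min(1, p * m)};
#' \code{bonferroni_threshold} returns \code{alpha / m}. The number of
#' tests \code{m} is supplied by the caller (e.g. all probes in the pooled
#' table) rather than inferred from the vector length.
#'
#' @param p a p-value in (0, 1].
#' @param m number of tests (>= 1).
#' @return adjusted p-value.
#' @export
bonferroni_adjust <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  min(1, p * m)
}

#' @rdname bonferroni_adjust
#' @param alpha family-wise level in (0, 1).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  check_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  alpha / m
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values vector of p-values in (0, 1].
#' @return step-up adjusted q-values (order-preserving, \code{q >= p}).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
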