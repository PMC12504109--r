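#' Build threshold-indexed score weights from meta-analysis results
#'
#' For each p-value threshold, the probes with meta p at or below the
#' threshold are selected and their pooled effect sizes become the score
#' weights. Weight sets are nested across decreasing thresholds.
#'
#' @param meta a \code{meta_result} table.
#' @param thresholds p-value cutoffs, each in (0, 1].
#' @return named list of \code{score_weights} (data.frames: probe,
#'   weight, threshold).
#' @export
build_weights <- function(meta,
                          thresholds = c(1, 0.01, 0.001, 1e-6, 5e-8)) {
  if (nrow(meta) == 0) stop("empty meta-analysis table")
  if (any(thresholds <= 0) || any(thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  out <- lapply(thresholds, function(th) {
    sel <- meta$p <= th
    structure(data.frame(probe = meta$probe[sel], weight = meta$beta[sel],
                         threshold = rep(th, sum(sel)),
                         stringsAsFactors = FALSE),
              class = c("score_weights", "data.frame"))
  })
  names(out) <- formatC(thresholds, format = "g")
  out
}

#' Compute per-sample methylation scores
#'
#' The score of a sample is the weighted sum of its M values over the
#' weighted probes. Weighted probes absent from the matrix are skipped and
#' counted in the \code{"n_missing"} attribute.
#'
#' @param m_values probes x samples matrix.
#' @param weights a \code{score_weights} table.
#' @return named numeric vector of raw scores.
#' @export
compute_scores <- function(m_values, weights) {
  present <- weights$probe %in% rownames(m_values)
  if (!any(present))
    stop("no weighted probes overlap the M-value matrix")
  w <- weights[present, , drop = FALSE]
  sc <- as.numeric(crossprod(m_values[w$probe, , drop = FALSE], w$weight))
  names(sc) <- colnames(m_values)
  structure(sc, n_missing = sum(!present))
}

#' Residualize and standardize a vector against covariates
#'
#' OLS residuals of \code{values} on the covariates (with intercept),
#' standardized to mean 0 and SD 1.
#'
#' @param values numeric vector.
#' @param covariates data.frame or matrix aligned with \code{values}.
#' @return standardized residuals.
#' @export
residualize <- function(values, covariates) {
  X <- stats::model.matrix(~., data = as.data.frame(covariates))
  if (nrow(X) != length(values))
    stop("covariate rows must align with values")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  r <- stats::lm.fit(X, values)$residuals
  s <- stats::sd(r)
  if (s < 1e-12)
    stop("degenerate residuals: values are exactly linear in the covariates")
  (r - mean(r)) / s
}

#' Mann-Whitney estimate of the area under the ROC curve
#'
#' AUC = (concordant case-control pairs + half the tied pairs) / (n_case *
#' n_control), computed from midranks.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = case).
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as half-concordant
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-sample case-control evaluation of a methylation score
#'
#' Follows the reporting convention of score-based classification in
#' methylation studies: the (standardized, residualized) score is the
#' dependent variable regressed on case status with covariates, so the
#' case coefficient is on the score's SD scale; discrimination is reported
#' as the Mann-Whitney AUC of the residualized score, and the two-group
#' standardized difference as Cohen's d.
#'
#' @param scores residualized score vector (see \code{\link{residualize}}).
#' @param phenotype binary vector (1 = case).
#' @param covariates optional data.frame of additional covariates for the
#'   regression (e.g. age, sex, smoking-proxy M values).
#' @return list with \code{beta}, \code{se}, \code{p} (case coefficient),
#'   \code{auc}, and \code{cohens_d}.
#' @export
classify_case_control <- function(scores, phenotype, covariates = NULL) {
  if (length(unique(phenotype)) < 2)
    stop("phenotype must contain both classes")
  df <- data.frame(score = as.numeric(scores),
                   case = as.numeric(phenotype))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- stats::lm(score ~ ., data = df)
  cs <- summary(fit)$coefficients["case", ]
  x1 <- scores[phenotype == 1]; x0 <- scores[phenotype == 0]
  sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                (length(x0) - 1) * stats::var(x0)) /
               (length(x1) + length(x0) - 2))
  list(beta = unname(cs[1]), se = unname(cs[2]), p = unname(cs[4]),
       auc = auc_mann_whitney(scores, phenotype),
       cohens_d = (mean(x1) - mean(x0)) / sp)
}

#' Rank-based inverse normal transform
#'
#' Blom offsets: \code{qnorm((rank - 3/8) / (n + 1/4))}, with average
#' ranks for ties. Rank order is preserved and any monotone transform of
#' the input yields the same output.
#'
#' @param values numeric vector, length >= 3, not constant.
#' @return transformed vector.
#' @export
rank_inverse_normal <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (length(unique(values)) == 1) stop("constant vector: all values tied")
  stats::qnorm((rank(values, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Filter a protein panel on detection rate
#'
#' Removes proteins for which strictly more than \code{max_below_fraction}
#' of samples fall below the lower limit of detection.
#'
#' @param panel a \code{protein_panel}.
#' @param max_below_fraction detection-failure threshold (strict).
#' @return the filtered \code{protein_panel}; attribute \code{"report"}
#'   lists every protein with its below-LLOD fraction and retention.
#' @export
filter_proteins_by_detection <- function(panel, max_below_fraction = 0.40) {
  frac <- colMeans(panel$below_llod)
  keep <- frac <= max_below_fraction
  report <- data.frame(protein = colnames(panel$abundance),
                       below_fraction = as.numeric(frac),
                       retained = as.logical(keep), row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- panel
  out$abundance <- panel$abundance[, keep, drop = FALSE]
  out$below_llod <- panel$below_llod[, keep, drop = FALSE]
  attr(out, "report") <- report
  out
}

#' Proteome-wide association with a methylation score
#'
#' Each retained protein's abundance is rank-based inverse-normal
#' transformed and residualized against the protein-side covariates, then
#' regressed on the (residualized) methylation score together with the
#' model covariates. P-values are Benjamini-Hochberg corrected across
#' proteins.
#'
#' @param score residualized methylation score, one per sample.
#' @param panel a detection-filtered \code{protein_panel}.
#' @param protein_covariates covariates removed from the abundances before
#'   association (e.g. age, sex, genetic PCs, proteomic array); optional.
#' @param model_covariates covariates entering the association model
#'   alongside the score (e.g. methylation array, smoking-proxy M values);
#'   optional.
#' @return data.frame: protein, beta, se, p, q_fdr, ordered by p.
#' @export
pwas <- function(score, panel, protein_covariates = NULL,
                 model_covariates = NULL) {
  A <- panel$abundance
  if (nrow(A) != length(score))
    stop(sprintf("panel has %d samples but score has %d",
                 nrow(A), length(score)))
  res <- lapply(colnames(A), function(p) {
    y <- rank_inverse_normal(A[, p])
    if (!is.null(protein_covariates)) y <- residualize(y, protein_covariates)
    df <- data.frame(y = y, score = as.numeric(score))
    if (!is.null(model_covariates)) df <- cbind(df, model_covariates)
    cs <- summary(stats::lm(y ~ ., data = df))$coefficients["score", ]
    data.frame(protein = p, beta = unname(cs[1]), se = unname(cs[2]),
               p = unname(cs[4]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
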