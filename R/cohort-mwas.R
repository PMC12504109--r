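#' Convert beta values to M values and back
#'
#' The logit2 transform \code{m = log2(beta / (1 - beta))} maps the
#' methylated fraction in (0, 1) onto the unbounded M-value scale used for
#' association analysis.
#'
#' @param beta_value methylated fraction(s) in (0, 1).
#' @return M value(s).
#' @export
beta_to_m <- function(beta_value) {
  if (any(!is.finite(beta_value)) || any(beta_value <= 0) ||
      any(beta_value >= 1))
    stop("beta values must lie strictly in (0, 1)")
  log2(beta_value / (1 - beta_value))
}

#' @rdname beta_to_m
#' @param m_value M value(s).
#' @export
m_to_beta <- function(m_value) {
  if (any(!is.finite(m_value))) stop("M values must be finite")
  2^m_value / (1 + 2^m_value)
}

#' Methylation principal components
#'
#' Sample-level principal component scores of the M-value matrix, used as
#' covariates to absorb latent technical and biological structure. Scores
#' are variance-ordered and sign-fixed so that each component's
#' largest-magnitude probe loading is positive.
#'
#' @param m_values probes x samples matrix.
#' @param k number of components.
#' @return samples x k matrix of scores, columns \code{PC1..PCk};
#'   attribute \code{"var_explained"} carries the variance fractions.
#' @export
compute_methylation_pcs <- function(m_values, k) {
  if (k > min(dim(m_values)))
    stop(sprintf("k = %d exceeds min(n_probes, n_samples) = %d",
                 k, min(dim(m_values))))
  pc <- stats::prcomp(t(m_values), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (k > rank)
    stop(sprintf("k = %d exceeds the matrix rank; achievable k <= %d",
                 k, rank))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(scores,
            var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2))
}

#' Convert a regression t statistic to Cohen's d
#'
#' Standard two-group conversion for a case-control coefficient embedded in
#' a linear regression: \code{d = t * (n1 + n2) / (sqrt(n1 * n2) *
#' sqrt(df))}, with \code{se_d = d / t} (the conversion factor itself when
#' t = 0).
#'
#' @param t t statistic of the case-status coefficient.
#' @param n_case,n_control group sizes.
#' @param df residual degrees of freedom.
#' @return list with \code{d} and \code{se_d}.
#' @export
t_to_cohens_d <- function(t, n_case, n_control, df) {
  if (any(df <= 0)) stop("df must be > 0")
  if (any(n_case <= 0) || any(n_control <= 0))
    stop("group counts must be > 0")
  fac <- (n_case + n_control) / (sqrt(n_case * n_control) * sqrt(df))
  list(d = t * fac, se_d = rep_len(fac, length(t)))
}

#' Probe-wise association of M values with case-control status
#'
#' Fits, for every probe, an ordinary least-squares regression of the
#' probe's M values (dependent) on case status (independent) plus the
#' covariate set of the chosen model:
#' \describe{
#'   \item{basic}{age, sex, batch (one-hot, first level reference),
#'     methylation PCs, and four of the five cell proportions (granulocytes
#'     dropped to avoid the sum-to-one singularity).}
#'   \item{ahrr}{basic plus the smoking-proxy probe's M values. When the
#'     smoking-proxy probe itself is the outcome it is excluded from its
#'     own covariate set.}
#'   \item{complex}{ahrr plus BMI and alcohol consumption.}
#' }
#' The case-status coefficient is converted to Cohen's d via
#' \code{\link{t_to_cohens_d}}; p-values are two-sided from the t
#' distribution at the residual df. Zero-variance probes are skipped and
#' listed in the \code{"skipped"} attribute.
#'
#' @param data a \code{\link{cohort_dataset}}.
#' @param model \code{"basic"}, \code{"ahrr"} or \code{"complex"}.
#' @param n_pcs methylation PCs to include (truncated to what the design
#'   can support; 0 disables).
#' @return a \code{summary_stats} data.frame with columns probe, chr, pos,
#'   beta (Cohen's d), se, p, n, n_case, n_control, study_id, array, model.
#' @export
run_probe_regression <- function(data, model = c("ahrr", "basic", "complex"),
                                 n_pcs = 10L) {
  stopifnot(inherits(data, "cohort_dataset"))
  model <- match.arg(model)
  cov <- data$covariates
  n <- ncol(data$m_values)
  if (model == "complex" && (is.null(cov$bmi) || is.null(cov$alcohol)))
    stop("complex model requires BMI and alcohol covariates")

  batch <- factor(cov$batch)
  X <- cbind(`(Intercept)` = 1, case = as.numeric(data$phenotype),
             age = cov$age, sex = cov$sex)
  if (nlevels(batch) > 1L) {
    B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
    X <- cbind(X, B)
  }
  cells <- as.matrix(cov[, setdiff(CELL_TYPES, "Gran")])
  X <- cbind(X, cells)
  if (n_pcs > 0) {
    k <- min(n_pcs, min(dim(data$m_values)) - ncol(X) - 2L)
    if (k > 0) X <- cbind(X, compute_methylation_pcs(data$m_values, k))
  }
  if (model %in% c("ahrr", "complex"))
    X <- cbind(X, smoking = cov$smoking)
  if (model == "complex")
    X <- cbind(X, bmi = cov$bmi, alcohol = cov$alcohol)

  kap <- kappa(X, exact = TRUE)
  if (kap > 1e10) {
    sdx <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    stop("collinear design matrix (condition number ", format(kap),
         "); check columns: ",
         paste(colnames(X)[-1][sdx < 1e-12], collapse = ", "))
  }

  probe_sd <- apply(data$m_values, 1, stats::sd)
  skipped <- rownames(data$m_values)[probe_sd == 0]
  keep <- setdiff(rownames(data$m_values), skipped)
  Y <- data$m_values[keep, , drop = FALSE]

  fit_stats <- function(Xm, Ym) {
    XtXinv <- chol2inv(chol(crossprod(Xm)))
    dimnames(XtXinv) <- list(colnames(Xm), colnames(Xm))
    coefs <- XtXinv %*% crossprod(Xm, t(Ym))  # p_cov x n_probes
    res <- t(Ym) - Xm %*% coefs
    df <- nrow(Xm) - ncol(Xm)
    sigma2 <- colSums(res^2) / df
    b <- coefs["case", ]
    se <- sqrt(sigma2 * XtXinv["case", "case"])
    list(t = b / se, df = df)
  }

  smoke <- data$smoking_probe
  fs <- fit_stats(X, Y)
  t_stat <- fs$t; df_res <- rep(fs$df, length(keep))
  names(df_res) <- keep
  # Smoking-proxy probe as outcome: drop it from its own covariate set.
  if (!is.null(smoke) && smoke %in% keep &&
      "smoking" %in% colnames(X)) {
    X2 <- X[, colnames(X) != "smoking", drop = FALSE]
    fs2 <- fit_stats(X2, Y[smoke, , drop = FALSE])
    t_stat[smoke] <- fs2$t
    df_res[smoke] <- fs2$df
  }

  n_case <- sum(data$phenotype == 1L)
  n_control <- n - n_case
  conv <- t_to_cohens_d(t_stat, n_case, n_control, df_res)
  p <- 2 * stats::pt(-abs(t_stat), df_res)
  mi <- data$manifest[match(keep, data$manifest$probe), ]
  out <- data.frame(probe = keep, chr = mi$chr, pos = mi$pos,
                    beta = conv$d, se = conv$se_d, p = p,
                    n = n, n_case = n_case, n_control = n_control,
                    study_id = data$study_id, array = data$array,
                    model = model, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the one-degree-of-freedom chi-square statistics
#' implied by the p-values, divided by the null median 0.4549364. Values
#' near 1 indicate well-calibrated test statistics.
#'
#' @param p_values vector of two-sided p-values in (0, 1].
#' @return lambda, with attribute \code{"n"} giving the probe count used.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  structure(stats::median(chisq) / stats::qchisq(0.5, df = 1),
            n = length(p_values))
}
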