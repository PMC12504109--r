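#' Simulation configuration for a synthetic methylation consortium
#'
#' Describes a multi-cohort case-control methylation consortium: per-cohort
#' sample sizes, case prevalence, array membership (450K probes are a strict
#' subset of EPIC probes), the number of planted case-control effects, and
#' the confounder structure added on the M-value scale.
#'
#' @param n_cohorts number of cohorts.
#' @param n_samples integer vector of per-cohort sample sizes (recycled).
#' @param case_prevalence per-cohort case fraction in (0, 1) (recycled).
#'   Defaults span the 6-63% range seen in real MD consortia.
#' @param array per-cohort array, \code{"450K"} or \code{"EPIC"} (recycled).
#' @param n_probes_shared number of probes on both arrays (the 450K set).
#' @param n_probes_epic_only number of probes present only on EPIC.
#' @param n_causal number of isolated causal probes with planted effects.
#' @param effect_size_d planted standardized mean difference (Cohen's d)
#'   between cases and controls at causal probes; scalar or length
#'   \code{n_causal}.
#' @param n_dmr_blocks number of planted blocks of positionally adjacent
#'   causal probes (for DMR recovery); block members share the sign of
#'   \code{dmr_block_d}.
#' @param dmr_block_size probes per planted block (>= 2).
#' @param dmr_block_d planted d shared by block members.
#' @param dmr_gap base-pair gap between consecutive block probes.
#' @param confounder_sd named numeric: standard deviations of per-probe
#'   loadings for each covariate's additive effect on M values. Names
#'   \code{age, sex, batch, cell, smoking, bmi, alcohol}.
#' @param noise_sd residual M-value standard deviation.
#' @param mean_age per-cohort mean age in years (recycled).
#' @param seed master seed; per-cohort streams are spawned from it so
#'   cohort-level output is reproducible independent of cohort order.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_cohorts = 4L,
                       n_samples = c(200L, 300L, 400L, 500L),
                       case_prevalence = c(0.06, 0.17, 0.3, 0.63),
                       array = c("450K", "EPIC"),
                       n_probes_shared = 800L,
                       n_probes_epic_only = 200L,
                       n_causal = 5L,
                       effect_size_d = 0.2,
                       n_dmr_blocks = 0L,
                       dmr_block_size = 3L,
                       dmr_block_d = 0.3,
                       dmr_gap = 150L,
                       confounder_sd = c(age = 0.05, sex = 0.05, batch = 0.2,
                                         cell = 0.3, smoking = 0.1,
                                         bmi = 0.05, alcohol = 0.05),
                       noise_sd = 1,
                       mean_age = c(25, 35, 45, 55),
                       seed = 1L) {
  check_number(n_cohorts, "n_cohorts", lower = 1)
  n_samples <- rep_len(as.integer(n_samples), n_cohorts)
  if (any(n_samples < 4L))
    stop_config("n_samples", "must be >= 4 per cohort")
  case_prevalence <- rep_len(case_prevalence, n_cohorts)
  for (p in case_prevalence)
    check_number(p, "case_prevalence", lower = 0, upper = 1,
                 open_lower = TRUE, open_upper = TRUE)
  array <- rep_len(match.arg(array, c("450K", "EPIC"), several.ok = TRUE),
                  n_cohorts)
  check_number(n_probes_shared, "n_probes_shared", lower = 10)
  check_number(n_probes_epic_only, "n_probes_epic_only", lower = 0)
  check_number(n_causal, "n_causal", lower = 0)
  check_number(n_dmr_blocks, "n_dmr_blocks", lower = 0)
  check_number(dmr_block_size, "dmr_block_size", lower = 2)
  if (length(effect_size_d) != 1L && length(effect_size_d) != n_causal)
    stop_config("effect_size_d", "must be scalar or length n_causal")
  if (!is.numeric(effect_size_d) || any(!is.finite(effect_size_d)))
    stop_config("effect_size_d", "must be finite numeric")
  check_number(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  need <- c("age", "sex", "batch", "cell", "smoking", "bmi", "alcohol")
  if (!all(need %in% names(confounder_sd)))
    stop_config("confounder_sd",
                paste("must name", paste(need, collapse = ", ")))
  n_block_probes <- n_dmr_blocks * dmr_block_size
  if (n_causal + n_block_probes + 1 > n_probes_shared)
    stop_config("n_causal", "exceeds the shared probe set")
  structure(list(
    n_cohorts = as.integer(n_cohorts), n_samples = n_samples,
    case_prevalence = case_prevalence, array = array,
    n_probes_shared = as.integer(n_probes_shared),
    n_probes_epic_only = as.integer(n_probes_epic_only),
    n_causal = as.integer(n_causal), effect_size_d = effect_size_d,
    n_dmr_blocks = as.integer(n_dmr_blocks),
    dmr_block_size = as.integer(dmr_block_size),
    dmr_block_d = dmr_block_d, dmr_gap = as.integer(dmr_gap),
    confounder_sd = confounder_sd, noise_sd = noise_sd,
    mean_age = rep_len(mean_age, n_cohorts),
    seed = as.integer(seed)), class = "sim_config")
}

CELL_TYPES <- c("CD8T", "CD4T", "NK", "Bcell", "Gran")
SMOKING_PROBE <- "cg05575921"

# Probe universe shared by every cohort: ids, manifest (chr, 1-based pos,
# gene, island relation, array membership), causal assignment, per-probe
# baselines and confounder loadings. Deterministic given config.
build_probe_universe <- function(config) {
  with_seed(spawn_seed(config$seed, 0L), {
    n_sh <- config$n_probes_shared
    n_ep <- config$n_probes_epic_only
    ids_shared <- c(SMOKING_PROBE, sprintf("cg1%06d", seq_len(n_sh - 1L)))
    ids_shared <- sample(ids_shared)
    ids_epic <- if (n_ep > 0) sprintf("cg2%06d", seq_len(n_ep)) else character()
    ids <- c(ids_shared, ids_epic)
    n <- length(ids)

    chr <- sort(rep_len(1:22, n))
    pos <- integer(n)
    gaps <- sample(300:5000, n, replace = TRUE)

    # Planted DMR blocks: runs of adjacent shared probes with small gaps.
    block_members <- vector("list", config$n_dmr_blocks)
    used <- which(ids == SMOKING_PROBE)
    if (config$n_dmr_blocks > 0) {
      bs <- config$dmr_block_size
      starts <- integer(0)
      cand <- seq_len(length(ids_shared) - bs)
      for (b in seq_len(config$n_dmr_blocks)) {
        ok <- cand[vapply(cand, function(s) {
          idx <- s:(s + bs - 1L)
          length(unique(chr[idx])) == 1L && !any(idx %in% used)
        }, logical(1))]
        s <- ok[sample.int(length(ok), 1L)]
        idx <- s:(s + bs - 1L)
        block_members[[b]] <- ids[idx]
        used <- c(used, idx)
        gaps[idx[-1]] <- config$dmr_gap
      }
    }
    for (c_ in unique(chr)) {
      i <- which(chr == c_)
      pos[i] <- cumsum(gaps[i]) + 10000L
    }

    shared_idx <- seq_len(n_sh)
    free <- setdiff(shared_idx, used)
    causal_idx <- if (config$n_causal > 0)
      sort(sample(free, config$n_causal)) else integer()
    d <- rep_len(config$effect_size_d, config$n_causal)
    true_effects <- stats::setNames(d, ids[causal_idx])
    for (b in seq_along(block_members))
      true_effects[block_members[[b]]] <- config$dmr_block_d

    manifest <- data.frame(
      probe = ids, chr = as.character(chr), pos = pos,
      gene = sprintf("GENE%04d", sample.int(500, n, replace = TRUE)),
      island_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                                 "S_Shelf", "OpenSea"), n, replace = TRUE,
                               prob = c(.15, .1, .1, .05, .05, .55)),
      array = ifelse(seq_len(n) <= n_sh, "Both", "EPIC"),
      stringsAsFactors = FALSE)

    n_conf <- 7L + 3L  # age, sex, batch, 4 cells, smoking, bmi, alcohol
    sds <- config$confounder_sd
    loading_sd <- c(sds["age"], sds["sex"], sds["batch"],
                    rep(sds["cell"], 4), sds["smoking"],
                    sds["bmi"], sds["alcohol"])
    loadings <- matrix(stats::rnorm(n * n_conf), n, n_conf) *
      rep(loading_sd, each = n)
    rownames(loadings) <- ids

    list(ids = ids, ids_shared = ids[shared_idx], manifest = manifest,
         baseline = stats::setNames(stats::rnorm(n, 0, 1.5), ids),
         loadings = loadings, true_effects = true_effects,
         causal_probe_ids = names(true_effects),
         dmr_blocks = block_members)
  })
}

#' Simulate a multi-cohort methylation consortium with planted effects
#'
#' Generates one case-control cohort per configured study: an M-value matrix
#' (probes x samples), a binary phenotype, and a covariate table (age, sex,
#' batch, five cell proportions summing to one, a smoking-proxy probe's M
#' values, BMI, alcohol). At causal probes the case-control M-value mean
#' differs by the planted Cohen's d (relative to the residual SD) before
#' confounding. Confounding is additive on the M scale through per-probe
#' loadings shared across cohorts, so it is recoverable by principal
#' components. The smoking-proxy probe mirrors the AHRR smoking covariate:
#' its M value tracks a latent smoking variable that is itself correlated
#' with case status.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohorts} (list of \code{cohort_dataset}) and
#'   \code{truth} (a \code{ground_truth} with \code{causal_probe_ids},
#'   \code{true_effects} and \code{dmr_blocks}).
#' @export
simulate_consortium <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  uni <- build_probe_universe(config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k)
    simulate_cohort(config, uni, k))
  truth <- structure(list(
    causal_probe_ids = uni$causal_probe_ids,
    true_effects = uni$true_effects,
    dmr_blocks = uni$dmr_blocks,
    manifest = uni$manifest,
    mqtl_truth = NULL, causal_cpg_to_trait = NULL, protein_truth = NULL),
    class = "ground_truth")
  list(cohorts = cohorts, truth = truth)
}

simulate_cohort <- function(config, uni, k) {
  with_seed(spawn_seed(config$seed, k), {
    n <- config$n_samples[k]
    n_case <- max(1L, min(n - 1L, round(config$case_prevalence[k] * n)))
    pheno <- sample(c(rep(1L, n_case), rep(0L, n - n_case)))
    ids <- if (config$array[k] == "EPIC") uni$ids else uni$ids_shared
    m_idx <- match(ids, uni$ids)
    samples <- sprintf("S%02d_%04d", k, seq_len(n))

    age <- stats::rnorm(n, config$mean_age[k], 8)
    sex <- stats::rbinom(n, 1L, 0.5)
    n_batch <- 2L + k %% 2L
    batch <- sample(paste0("b", seq_len(n_batch)), n, replace = TRUE)
    cells <- matrix(stats::rgamma(n * 5, shape = rep(c(2, 4, 1, 1, 10),
                                                     each = n)), n, 5)
    cells <- cells / rowSums(cells)
    colnames(cells) <- CELL_TYPES
    smoking_latent <- 0.3 * pheno + stats::rnorm(n)
    bmi <- stats::rnorm(n, 26, 4)
    alcohol <- pmax(0, stats::rnorm(n, 8, 5))

    # Covariate design driving confounder loadings (cells centered; the
    # 5th proportion is determined by the other four and carries no
    # independent loading).
    C <- cbind(scale(age)[, 1], sex - 0.5,
               as.numeric(factor(batch)) - mean(as.numeric(factor(batch))),
               scale(cells[, 1:4]),
               smoking_latent, scale(bmi)[, 1], scale(alcohol)[, 1])
    M <- uni$baseline[m_idx] +
      uni$loadings[m_idx, , drop = FALSE] %*% t(C) +
      matrix(stats::rnorm(length(ids) * n, 0, config$noise_sd),
             length(ids), n)

    eff <- uni$true_effects[intersect(names(uni$true_effects), ids)]
    if (length(eff))
      M[names(eff), ] <- M[names(eff), ] +
        outer(eff * config$noise_sd, as.numeric(pheno))
    # Smoking-proxy probe: dominated by the latent smoking signal.
    M[SMOKING_PROBE, ] <- -1.5 + 0.8 * smoking_latent + stats::rnorm(n, 0, 0.3)
    dimnames(M) <- list(ids, samples)

    covariates <- data.frame(age = age, sex = sex, batch = batch,
                             cells, smoking = M[SMOKING_PROBE, ],
                             bmi = bmi, alcohol = alcohol,
                             row.names = samples, stringsAsFactors = FALSE)
    cohort_dataset(m_values = M, phenotype = stats::setNames(pheno, samples),
                   covariates = covariates,
                   manifest = uni$manifest[match(ids, uni$manifest$probe), ],
                   study_id = sprintf("study%02d", k),
                   array = config$array[k],
                   smoking_probe = SMOKING_PROBE)
  })
}

#' Construct and validate a cohort dataset
#'
#' @param m_values numeric matrix, probes x samples, M-value scale.
#' @param phenotype binary vector (1 = case), one per sample.
#' @param covariates data.frame, one row per sample.
#' @param manifest probe annotation covering all matrix rows.
#' @param study_id,array study label and array membership.
#' @param smoking_probe id of the smoking-proxy probe, if present.
#' @return a \code{cohort_dataset}.
#' @export
cohort_dataset <- function(m_values, phenotype, covariates, manifest,
                           study_id, array = c("450K", "EPIC"),
                           smoking_probe = NULL) {
  array <- match.arg(array)
  if (anyNA(phenotype)) stop("phenotype contains missing values")
  if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  if (sum(phenotype == 1L) < 1L || sum(phenotype == 0L) < 1L)
    stop("need at least one case and one control")
  if (length(phenotype) != ncol(m_values))
    stop("phenotype length must equal the number of samples")
  if (nrow(covariates) != ncol(m_values))
    stop("covariate rows must equal the number of samples")
  if (anyDuplicated(rownames(m_values))) stop("probe ids must be unique")
  missing_probes <- setdiff(rownames(m_values), manifest$probe)
  if (length(missing_probes))
    stop("manifest does not cover probes: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  structure(list(m_values = m_values, phenotype = phenotype,
                 covariates = covariates, manifest = manifest,
                 study_id = study_id, array = array,
                 smoking_probe = smoking_probe),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s [%s]: %d probes x %d samples (%d cases / %d controls)\n",
              x$study_id, x$array, nrow(x$m_values), ncol(x$m_values),
              sum(x$phenotype == 1), sum(x$phenotype == 0)))
  invisible(x)
}

#' Simulate an mQTL study with a planted SNP -> CpG -> trait causal chain
#'
#' Genotypes are drawn binomial(2, MAF) under Hardy-Weinberg; each CpG's
#' M value is the configured mQTL slope times the dosage plus unit-variance
#' noise; the (liability-scale) trait is the configured CpG slope times the
#' CpG M value plus noise. Genomic positions place each SNP inside or
#' outside the 1 Mb cis window of its CpG, and the ground truth flags
#' non-cis pairs.
#'
#' @param n_samples samples (>= 10).
#' @param n_snps,n_cpgs numbers of SNPs and CpGs.
#' @param chain_spec list with \code{maf} (length \code{n_snps}, in
#'   (0.05, 0.5)), \code{snp_cpg} (data.frame: snp, cpg, slope),
#'   \code{cpg_trait} (data.frame: cpg, slope), and optional
#'   \code{snp_pos}, \code{cpg_pos} (1-based bp on one chromosome).
#' @param seed integer.
#' @return list: \code{genotypes} (samples x SNPs), \code{m_values}
#'   (CpGs x samples), \code{trait}, \code{snp_info} (snp, chr, pos, maf),
#'   \code{cpg_info} (cpg, chr, pos), \code{truth} (a \code{ground_truth}
#'   with \code{mqtl_truth} incl. cis flags and
#'   \code{causal_cpg_to_trait}).
#' @export
simulate_mqtl_study <- function(n_samples, n_snps, n_cpgs, chain_spec,
                                seed = 1L) {
  if (n_samples < 10)
    stop("n_samples must be >= 10 for downstream regression")
  maf <- chain_spec$maf %||% rep(0.3, n_snps)
  if (any(maf <= 0.05) || any(maf >= 0.5))
    stop_config("maf", "must lie in (0.05, 0.5)")
  sc <- chain_spec$snp_cpg
  ct <- chain_spec$cpg_trait
  if (!is.null(sc) && any(!is.finite(sc$slope)))
    stop_config("snp_cpg", "slopes must be finite")
  if (!is.null(ct) && any(!is.finite(ct$slope)))
    stop_config("cpg_trait", "slopes must be finite")
  snps <- sprintf("rs%05d", seq_len(n_snps))
  cpgs <- sprintf("cg9%06d", seq_len(n_cpgs))
  snp_pos <- chain_spec$snp_pos %||% (1e6 + seq_len(n_snps) * 5e4)
  cpg_pos <- chain_spec$cpg_pos %||% (1e6 + seq_len(n_cpgs) * 5e4 + 500)

  with_seed(seed, {
    G <- sapply(maf, function(f) stats::rbinom(n_samples, 2L, f))
    dimnames(G) <- list(sprintf("I%04d", seq_len(n_samples)), snps)
    M <- matrix(stats::rnorm(n_cpgs * n_samples), n_cpgs, n_samples,
                dimnames = list(cpgs, rownames(G)))
    if (!is.null(sc))
      for (i in seq_len(nrow(sc)))
        M[sc$cpg[i], ] <- M[sc$cpg[i], ] + sc$slope[i] * G[, sc$snp[i]]
    trait <- stats::rnorm(n_samples)
    if (!is.null(ct))
      for (i in seq_len(nrow(ct)))
        trait <- trait + ct$slope[i] * M[ct$cpg[i], ]

    mqtl_truth <- NULL
    if (!is.null(sc)) {
      mqtl_truth <- sc
      mqtl_truth$cis <- abs(snp_pos[match(sc$snp, snps)] -
                              cpg_pos[match(sc$cpg, cpgs)]) <= 1e6
    }
    truth <- structure(list(
      causal_probe_ids = if (is.null(ct)) character() else ct$cpg,
      true_effects = NULL, dmr_blocks = NULL, mqtl_truth = mqtl_truth,
      causal_cpg_to_trait = if (is.null(ct)) NULL else
        stats::setNames(ct$slope, ct$cpg),
      protein_truth = NULL), class = "ground_truth")
    list(genotypes = G, m_values = M, trait = trait,
         snp_info = data.frame(snp = snps, chr = "1", pos = snp_pos,
                               maf = maf, stringsAsFactors = FALSE),
         cpg_info = data.frame(cpg = cpgs, chr = "1", pos = cpg_pos,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate a multiplex protein panel with a lower limit of detection
#'
#' Emulates a proximity-extension inflammation panel: each protein's
#' relative abundance is its configured slope times the (standardized)
#' methylation score plus unit noise. A configured subset of proteins fails
#' detection quality control: more than 40% of their values fall below the
#' lower limit of detection (LLOD) and are flagged in the mask.
#'
#' @param n_samples samples; must equal \code{length(score)}.
#' @param n_proteins panel size (92 for the emulated inflammation panel).
#' @param score per-sample methylation score driving true associations.
#' @param truth_slopes length-\code{n_proteins} slopes on the standardized
#'   score (0 = null protein).
#' @param lod_fail_fraction fraction of proteins that fail the 40% LLOD
#'   rule.
#' @param seed integer.
#' @return a \code{protein_panel}: \code{abundance} (samples x proteins),
#'   logical \code{below_llod} mask of the same shape, and \code{truth}
#'   with the planted slopes and failing proteins.
#' @export
simulate_protein_panel <- function(n_samples, n_proteins, score,
                                   truth_slopes = rep(0, n_proteins),
                                   lod_fail_fraction = 0,
                                   seed = 1L) {
  if (length(score) != n_samples)
    stop("score length must equal n_samples")
  if (length(truth_slopes) != n_proteins)
    stop(sprintf("truth_slopes has length %d but n_proteins is %d",
                 length(truth_slopes), n_proteins))
  check_number(lod_fail_fraction, "lod_fail_fraction", lower = 0, upper = 1)
  proteins <- sprintf("prot%03d", seq_len(n_proteins))
  with_seed(seed, {
    A <- scale(score)[, 1] %o% truth_slopes +
      matrix(stats::rnorm(n_samples * n_proteins), n_samples, n_proteins)
    dimnames(A) <- list(names(score) %||% sprintf("P%04d", seq_len(n_samples)),
                        proteins)
    n_fail <- round(lod_fail_fraction * n_proteins)
    failing <- sample(proteins, n_fail)
    below <- matrix(FALSE, n_samples, n_proteins, dimnames = dimnames(A))
    for (p in proteins) {
      frac <- if (p %in% failing) stats::runif(1, 0.45, 0.70)
              else stats::runif(1, 0, 0.30)
      llod <- stats::quantile(A[, p], frac)
      below[, p] <- A[, p] < llod
    }
    structure(list(abundance = A, below_llod = below,
                   truth = list(slopes = stats::setNames(truth_slopes,
                                                         proteins),
                                failing = failing)),
              class = "protein_panel")
  })
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("<protein_panel> %d proteins x %d samples; %d flagged >40%% below LLOD\n",
              ncol(x$abundance), nrow(x$abundance),
              sum(colMeans(x$below_llod) > 0.40)))
  invisible(x)
}
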