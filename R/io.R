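# TSV dialect: tab-separated, UTF-8, '.' for missing values, header row.

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]))
      df2[[j]] <- ifelse(is.na(df2[[j]]), ".",
                         format(df2[[j]], digits = 15, trim = TRUE,
                                scientific = NA))
    else df2[[j]] <- ifelse(is.na(df2[[j]]), ".", as.character(df2[[j]]))
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

SUMMARY_COLS <- c("probe", "chr", "pos", "beta", "se", "p", "n", "n_case",
                  "n_control", "study_id", "array", "model")

#' Read and write per-study summary statistics
#'
#' The TSV contract has fixed columns (order-insensitive): probe, chr,
#' pos, beta, se, p, n, n_case, n_control, study_id, array, model.
#' Unparseable numeric rows are rejected with their line numbers.
#'
#' @param path file path.
#' @return a \code{summary_stats} data.frame.
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(SUMMARY_COLS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- df[, SUMMARY_COLS]
  for (col in c("beta", "se", "p")) {
    bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(
      as.numeric(as.character(df[[col]])))))
    if (length(bad))
      stop(sprintf("non-numeric '%s' at line(s) %s", col,
                   paste(bad + 1L, collapse = ", ")))
    df[[col]] <- as.numeric(df[[col]])
  }
  df$chr <- as.character(df$chr)
  if (nrow(df) == 0) warning("empty summary-statistics file: ", path)
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param stats a \code{summary_stats} table.
#' @export
write_summary_stats <- function(stats, path) {
  write_tsv(as.data.frame(stats)[, SUMMARY_COLS], path)
}

#' Read and write a probe manifest
#'
#' Columns: probe, chr, pos (1-based), gene, island_relation, array.
#' Chromosome labels are normalized by stripping any "chr" prefix, so
#' "chr3" and "3" map to "3". Duplicate probe ids are rejected.
#'
#' @param path file path.
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path)
  need <- c("probe", "chr", "pos", "gene", "island_relation", "array")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  dup <- df$probe[duplicated(df$probe)]
  if (length(dup))
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  df$chr <- sub("^chr", "", as.character(df$chr))
  df$pos <- as.integer(df$pos)
  df[, need]
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(manifest, path)
}

#' Write a cohort dataset to a directory
#'
#' Three TSVs: the M-value matrix (probes as rows, first column
#' \code{probe}), the phenotype/covariate table (one row per sample), and
#' the manifest slice.
#'
#' @param cohort a \code{cohort_dataset}.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- data.frame(probe = rownames(cohort$m_values), cohort$m_values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(m, file.path(dir, "methylation.tsv"))
  ph <- data.frame(sample = colnames(cohort$m_values),
                   phenotype = cohort$phenotype, cohort$covariates,
                   stringsAsFactors = FALSE)
  write_tsv(ph, file.path(dir, "phenotype.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @param study_id,array study label and array of the cohort being read.
#' @param smoking_probe id of the smoking-proxy probe.
#' @export
read_cohort <- function(dir, study_id, array,
                        smoking_probe = SMOKING_PROBE) {
  m <- read_tsv(file.path(dir, "methylation.tsv"))
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$probe
  ph <- read_tsv(file.path(dir, "phenotype.tsv"))
  cov <- ph[, setdiff(names(ph), c("sample", "phenotype")), drop = FALSE]
  rownames(cov) <- ph$sample
  cohort_dataset(mat, stats::setNames(as.integer(ph$phenotype), ph$sample),
                 cov, read_manifest(file.path(dir, "manifest.tsv")),
                 study_id = study_id, array = array,
                 smoking_probe = if (smoking_probe %in% rownames(mat))
                   smoking_probe else NULL)
}

#' Export DMRs as a BED-compatible table
#'
#' Internally positions are 1-based inclusive; BED output converts to
#' 0-based half-open (start - 1, end).
#'
#' @param dmrs a \code{dmr_result} table.
#' @param path output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chr = dmrs$chr, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("DMR_%s_%d", dmrs$chr, dmrs$start),
                    score = dmrs$z, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order — simulate, per-cohort
#' MWAS, two-stage meta-analysis, then DMR calling, methylation-score
#' classification, heterogeneity diagnostics, and MR on a simulated mQTL
#' study — writing every artifact under \code{out_dir} along with a run
#' manifest (seed, configuration, input hashes).
#'
#' @param config list with elements \code{sim} (arguments for
#'   \code{\link{sim_config}}), \code{meta} (a \code{\link{meta_config}}),
#'   \code{stages} (character subset of \code{c("dmr", "score", "het",
#'   "mr")}), \code{model} (covariate model), and \code{seed}.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("dmr", "score", "het", "mr")
  model <- config$model %||% "ahrr"
  mcfg <- config$meta %||% meta_config()
  sim_args <- config$sim %||% list()
  if (inherits(sim_args, "sim_config")) sim_args <- unclass(sim_args)
  sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_consortium(scfg)
  for (co in sim$cohorts)
    write_cohort(co, file.path(out_dir, "cohorts", co$study_id))
  jsonlite::write_json(
    list(causal_probe_ids = sim$truth$causal_probe_ids,
         true_effects = as.list(sim$truth$true_effects),
         dmr_blocks = sim$truth$dmr_blocks),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)

  stats_by_study <- lapply(sim$cohorts, run_probe_regression, model = model)
  for (s in stats_by_study)
    write_summary_stats(s, file.path(out_dir,
                                     paste0("mwas_", s$study_id[1], ".tsv")))

  meta <- two_stage_meta(stats_by_study, mcfg)
  write_tsv(as.data.frame(meta), file.path(out_dir, "meta_result.tsv"))
  write_tsv(attr(meta, "filter_report"),
            file.path(out_dir, "filter_report.tsv"))
  results <- list(truth = sim$truth, meta = meta)

  if ("dmr" %in% stages) {
    dmrs <- call_dmrs(meta, sim$truth$manifest,
                      m_values = sim$cohorts[[1]]$m_values)
    write_tsv(as.data.frame(dmrs), file.path(out_dir, "dmr_result.tsv"))
    if (nrow(dmrs)) write_dmr_bed(dmrs, file.path(out_dir, "dmr.bed"))
    results$dmrs <- dmrs
  }
  if ("score" %in% stages) {
    # Hold-out evaluation: score the last cohort with weights built from
    # the remaining studies.
    test <- sim$cohorts[[length(sim$cohorts)]]
    meta_train <- two_stage_meta(stats_by_study[-length(stats_by_study)],
                                 mcfg)
    ws <- build_weights(meta_train)
    score_rows <- lapply(names(ws), function(th) {
      w <- ws[[th]]
      if (nrow(w) == 0 ||
          !any(w$probe %in% rownames(test$m_values))) return(NULL)
      raw <- compute_scores(test$m_values, w)
      resid <- residualize(raw, test$covariates[, c("age", "sex",
                                                    "smoking")])
      cls <- classify_case_control(resid, test$phenotype,
                                   test$covariates[, c("age", "sex",
                                                       "smoking")])
      data.frame(threshold = th, n_probes = nrow(w), beta = cls$beta,
                 se = cls$se, p = cls$p, auc = cls$auc,
                 cohens_d = cls$cohens_d, stringsAsFactors = FALSE)
    })
    score_tab <- do.call(rbind, score_rows)
    write_tsv(score_tab, file.path(out_dir, "score_classification.tsv"))
    results$score <- score_tab
  }
  if ("het" %in% stages) {
    top <- top_k_probes(meta, 50L)
    loo <- leave_one_out_meta(stats_by_study, probes = top)
    write_tsv(loo, file.path(out_dir, "leave_one_out.tsv"))
    pec <- pairwise_effect_correlation(stats_by_study,
                                       top_k_probes(stats_by_study[[1]],
                                                    200L))
    write_tsv(as.data.frame(pec$correlation),
              file.path(out_dir, "effect_correlation.tsv"))
    results$loo <- loo
    results$effect_correlation <- pec
  }
  if ("mr" %in% stages) {
    mr_sim <- simulate_mqtl_study(
      n_samples = 2000, n_snps = 5, n_cpgs = 5,
      chain_spec = list(
        maf = rep(0.3, 5),
        snp_cpg = data.frame(snp = sprintf("rs%05d", 1:5),
                             cpg = sprintf("cg9%06d", 1:5),
                             slope = rep(0.4, 5)),
        cpg_trait = data.frame(cpg = sprintf("cg9%06d", 1:5),
                               slope = rep(0.05, 5))),
      seed = spawn_seed(seed, 99L))
    sumry <- summarize_mqtl_study(mr_sim)
    fmr <- forward_mr(mr_sim$cpg_info, sumry$mqtl, sumry$gwas)
    write_tsv(as.data.frame(fmr), file.path(out_dir, "mr_forward.tsv"))
    results$mr <- fmr
  }

  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- setdiff(arts, file.path(out_dir, "run_manifest.json"))
  jsonlite::write_json(
    list(seed = seed, stages = stages, model = model,
         sim_config = scfg[setdiff(names(scfg), "confounder_sd")],
         meta_config = unclass(mcfg),
         package_version = as.character(utils::packageVersion("metamwas")),
         artifacts = as.list(stats::setNames(
           unname(tools::md5sum(arts)),
           sub(paste0("^", out_dir, "/?"), "", arts)))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(results)
}

#' Per-SNP summary statistics from an individual-level mQTL study
#'
#' Simple per-SNP regressions giving two-sample MR inputs: each SNP's
#' effect on its CpG (mQTL side) and on the trait (GWAS side).
#'
#' @param sim output of \code{\link{simulate_mqtl_study}}.
#' @return list of \code{mqtl} and \code{gwas} association tables.
#' @export
summarize_mqtl_study <- function(sim) {
  snps <- colnames(sim$genotypes)
  pairs <- sim$truth$mqtl_truth
  mqtl <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    g <- sim$genotypes[, pairs$snp[i]]
    fit <- summary(stats::lm(sim$m_values[pairs$cpg[i], ] ~ g))$coefficients
    data.frame(cpg = pairs$cpg[i], snp = pairs$snp[i], chr = "1",
               pos = sim$snp_info$pos[match(pairs$snp[i], snps)],
               a1 = "A", a2 = "G",
               freq = mean(g) / 2,
               beta = fit["g", 1], se = fit["g", 2], p = fit["g", 4],
               n = nrow(sim$genotypes), stringsAsFactors = FALSE)
  }))
  gwas <- do.call(rbind, lapply(snps, function(s) {
    g <- sim$genotypes[, s]
    fit <- summary(stats::lm(sim$trait ~ g))$coefficients
    data.frame(snp = s, chr = "1",
               pos = sim$snp_info$pos[match(s, snps)],
               a1 = "A", a2 = "G", freq = mean(g) / 2,
               beta = fit["g", 1], se = fit["g", 2], p = fit["g", 4],
               n = nrow(sim$genotypes), stringsAsFactors = FALSE)
  }))
  list(mqtl = mqtl, gwas = gwas)
}
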