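#' Select the cis instrument for a CpG
#'
#' Among the CpG's mQTL records within \code{window} base pairs of the CpG
#' and with p below \code{p_max}, returns the most significant record.
#' Ties on p are broken by larger absolute effect, then by SNP id.
#'
#' @param mqtls data.frame of association records for one CpG (snp, chr,
#'   pos, a1, a2, freq, beta, se, p, n).
#' @param cpg_position 1-based bp position of the CpG.
#' @param window cis window in bp (1 Mb default).
#' @param p_max instrument significance threshold.
#' @return the selected record (one-row data.frame) or \code{NULL}.
#' @export
select_cis_instrument <- function(mqtls, cpg_position, window = 1e6,
                                  p_max = 5e-8) {
  cand <- mqtls[abs(mqtls$pos - cpg_position) <= window &
                  mqtls$p < p_max, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand[order(cand$p, -abs(cand$beta), cand$snp), , drop = FALSE][1, ]
}

#' Greedy LD clumping
#'
#' Records are visited in order of ascending p (SNP id breaks ties); a
#' record is kept unless an already-kept record on the same chromosome
#' lies within \code{window} bp and is correlated above \code{r2_max}.
#' Output is invariant to the input row order.
#'
#' @param records association records (snp, chr, pos, p, ...).
#' @param ld square r-squared matrix with SNP ids as dimnames.
#' @param p_max records above this p are discarded first.
#' @param window clumping window in bp.
#' @param r2_max LD independence threshold.
#' @return the independent records, in selection order.
#' @export
clump <- function(records, ld, p_max = 5e-8, window = 1e6,
                  r2_max = 0.001) {
  rec <- records[records$p <= p_max, , drop = FALSE]
  rec <- rec[order(rec$p, rec$snp), , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    for (j in kept) {
      if (rec$chr[i] != rec$chr[j] ||
          abs(rec$pos[i] - rec$pos[j]) > window) next
      if (!(rec$snp[i] %in% rownames(ld)) ||
          !(rec$snp[j] %in% colnames(ld)))
        stop(sprintf("missing LD entry for pair %s:%s",
                     rec$snp[i], rec$snp[j]))
      r2 <- ld[rec$snp[i], rec$snp[j]]
      if (is.na(r2))
        stop(sprintf("missing LD entry for pair %s:%s",
                     rec$snp[i], rec$snp[j]))
      if (r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  rec[kept, , drop = FALSE]
}

PALINDROMIC <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Harmonize exposure and outcome alleles for one SNP
#'
#' If the outcome record's allele labels are swapped relative to the
#' exposure, the outcome effect sign is flipped and the labels swapped.
#' Palindromic SNPs (A/T or C/G) with effect-allele frequency in
#' [0.42, 0.58] are dropped as strand-ambiguous; mismatched allele sets
#' are dropped.
#'
#' @param exposure,outcome one-row association records with columns
#'   \code{snp, a1, a2, beta, se} and (outcome) \code{freq}.
#' @return list: \code{instrument} (list with harmonized \code{exposure}
#'   and \code{outcome}) or \code{NULL}, plus \code{status}
#'   (\code{"ok"}, \code{"flipped"}, \code{"dropped"}) and \code{reason}.
#' @export
harmonize_alleles <- function(exposure, outcome) {
  if (exposure$snp != outcome$snp) stop("records refer to different SNPs")
  pal <- any(vapply(PALINDROMIC, function(a)
    exposure$a1 == a[1] && exposure$a2 == a[2], logical(1)))
  if (pal) {
    f <- outcome$freq %||% NA_real_
    if (!is.na(f) && f >= 0.42 && f <= 0.58)
      return(list(instrument = NULL, status = "dropped",
                  reason = "palindromic SNP with ambiguous frequency"))
  }
  if (exposure$a1 == outcome$a1 && exposure$a2 == outcome$a2) {
    return(list(instrument = list(exposure = exposure, outcome = outcome),
                status = "ok", reason = NA_character_))
  }
  if (exposure$a1 == outcome$a2 && exposure$a2 == outcome$a1) {
    out2 <- outcome
    out2$beta <- -outcome$beta
    out2$a1 <- outcome$a2; out2$a2 <- outcome$a1
    if (!is.null(out2$freq)) out2$freq <- 1 - outcome$freq
    return(list(instrument = list(exposure = exposure, outcome = out2),
                status = "flipped", reason = NA_character_))
  }
  list(instrument = NULL, status = "dropped",
       reason = "mismatched allele sets")
}

#' Wald-ratio causal estimate
#'
#' \code{beta = b_outcome / b_exposure}; first-order delta-method standard
#' error \code{se = se_outcome / |b_exposure|} (the conventional
#' single-instrument form, ignoring exposure uncertainty); optionally the
#' second-order form including the exposure standard error. Two-sided
#' normal p.
#'
#' @param b_outcome,se_outcome outcome association and its se.
#' @param b_exposure exposure association (non-zero).
#' @param se_exposure exposure se, used only when
#'   \code{second_order = TRUE}.
#' @param second_order use the second-order delta-method se.
#' @return list with \code{beta}, \code{se}, \code{p}.
#' @export
wald_ratio <- function(b_outcome, se_outcome, b_exposure,
                       se_exposure = NULL, second_order = FALSE) {
  if (b_exposure == 0) stop("exposure effect must be non-zero")
  beta <- b_outcome / b_exposure
  se <- if (second_order) {
    if (is.null(se_exposure)) stop("second-order se requires se_exposure")
    sqrt(se_outcome^2 / b_exposure^2 +
           b_outcome^2 * se_exposure^2 / b_exposure^4)
  } else se_outcome / abs(b_exposure)
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Forward MR: methylation to trait
#'
#' For each CpG, selects the most significant cis mQTL as instrument,
#' harmonizes it against the trait GWAS, and computes the Wald ratio.
#' FDR is applied across all tested CpGs.
#'
#' @param cpg_list data.frame with \code{cpg} and \code{pos} (CpG
#'   positions).
#' @param mqtl_stats data.frame of mQTL records with a \code{cpg} column
#'   plus the association-record fields.
#' @param trait_gwas_stats trait GWAS records keyed by \code{snp}.
#' @param window,p_max instrument-selection parameters.
#' @return an \code{mr_result} data.frame (cpg, snp, chr, pos, a1, a2,
#'   freq, beta, se, p, q_fdr, direction); attribute \code{"untested"}
#'   lists CpGs without a usable instrument and the reason.
#' @export
forward_mr <- function(cpg_list, mqtl_stats, trait_gwas_stats,
                       window = 1e6, p_max = 5e-8) {
  if (nrow(cpg_list) == 0) stop("empty CpG list")
  untested <- list(); rows <- list()
  for (i in seq_len(nrow(cpg_list))) {
    cpg <- cpg_list$cpg[i]
    mq <- mqtl_stats[mqtl_stats$cpg == cpg, , drop = FALSE]
    inst <- select_cis_instrument(mq, cpg_list$pos[i], window, p_max)
    if (is.null(inst)) {
      untested[[cpg]] <- "no cis instrument at threshold"
      next
    }
    gw <- trait_gwas_stats[trait_gwas_stats$snp == inst$snp, , drop = FALSE]
    if (nrow(gw) == 0) {
      untested[[cpg]] <- "instrument absent from trait GWAS"
      next
    }
    h <- harmonize_alleles(inst, gw[1, ])
    if (h$status == "dropped") {
      untested[[cpg]] <- h$reason
      next
    }
    wr <- wald_ratio(h$instrument$outcome$beta, h$instrument$outcome$se,
                     h$instrument$exposure$beta)
    rows[[cpg]] <- data.frame(cpg = cpg, snp = inst$snp, chr = inst$chr,
                              pos = inst$pos, a1 = inst$a1, a2 = inst$a2,
                              freq = gw$freq[1] %||% NA_real_,
                              beta = wr$beta, se = wr$se, p = wr$p,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(cpg = character(), snp = character(), chr = character(),
                  pos = integer(), a1 = character(), a2 = character(),
                  freq = numeric(), beta = numeric(), se = numeric(),
                  p = numeric(), stringsAsFactors = FALSE)
  if (nrow(out)) out$q_fdr <- bh_fdr(out$p) else out$q_fdr <- numeric()
  out$direction <- rep("dnam_to_trait", nrow(out))
  class(out) <- c("mr_result", "data.frame")
  attr(out, "untested") <- untested
  out
}

#' Reverse MR: trait to methylation
#'
#' Clumps the trait GWAS to approximately independent genome-wide
#' significant instruments, then per CpG harmonizes each instrument
#' against the mQTL outcome statistics, computes per-SNP Wald ratios, and
#' pools them by fixed-effect IVW (a single instrument reduces to the
#' plain Wald ratio). FDR across CpGs.
#'
#' @param trait_gwas_stats trait GWAS association records.
#' @param ld square r-squared matrix for clumping.
#' @param mqtl_outcome_stats SNP-to-CpG association records with a
#'   \code{cpg} column (the outcome side).
#' @param cpg_list character vector of CpG ids to test.
#' @param p_max,window,r2_max clumping parameters.
#' @return an \code{mr_result} data.frame (cpg, n_snps, beta, se, p,
#'   q_fdr, direction).
#' @export
reverse_mr <- function(trait_gwas_stats, ld, mqtl_outcome_stats, cpg_list,
                       p_max = 5e-8, window = 1e6, r2_max = 0.001) {
  inst <- clump(trait_gwas_stats, ld, p_max, window, r2_max)
  if (nrow(inst) == 0) stop("no instruments left after clumping")
  rows <- lapply(cpg_list, function(cpg) {
    mo <- mqtl_outcome_stats[mqtl_outcome_stats$cpg == cpg, , drop = FALSE]
    wrs <- list()
    for (i in seq_len(nrow(inst))) {
      rec <- mo[mo$snp == inst$snp[i], , drop = FALSE]
      if (nrow(rec) == 0) next
      h <- harmonize_alleles(inst[i, ], rec[1, ])
      if (h$status == "dropped") next
      wrs[[length(wrs) + 1L]] <-
        wald_ratio(h$instrument$outcome$beta, h$instrument$outcome$se,
                   h$instrument$exposure$beta)
    }
    if (length(wrs) == 0) return(NULL)
    pool <- ivw_fixed_effect(vapply(wrs, `[[`, numeric(1), "beta"),
                             vapply(wrs, `[[`, numeric(1), "se"))
    data.frame(cpg = cpg, n_snps = length(wrs), beta = pool$beta,
               se = pool$se, p = pool$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no CpG could be tested with the clumped instruments")
  out$q_fdr <- bh_fdr(out$p)
  out$direction <- "trait_to_dnam"
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %d CpGs tested, %d at FDR < 0.05\n",
              if (nrow(x) && x$direction[1] == "trait_to_dnam")
                "trait -> DNAm" else "DNAm -> trait",
              nrow(x), sum(x$q_fdr < 0.05)))
  invisible(x)
}
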