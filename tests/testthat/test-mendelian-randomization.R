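mk_rec <- function(snp, pos, p, beta = 0.1, se = 0.02, a1 = "A",
                   a2 = "G", chr = "1", freq = 0.3) {
  data.frame(snp = snp, chr = chr, pos = pos, a1 = a1, a2 = a2,
             freq = freq, beta = beta, se = se, p = p, n = 10000,
             stringsAsFactors = FALSE)
}

test_that("cis-instrument selection applies window, threshold, argmin", {
  recs <- rbind(mk_rec("rs1", 1e6, 1e-9), mk_rec("rs2", 1.1e6, 1e-10))
  got <- select_cis_instrument(recs, cpg_position = 1e6)
  expect_equal(got$snp, "rs2")

  far <- mk_rec("rs3", 2.3e6, 1e-12)
  expect_null(select_cis_instrument(far, cpg_position = 1e6))
  weak <- mk_rec("rs4", 1e6, 1e-7)
  expect_null(select_cis_instrument(weak, cpg_position = 1e6))

  # p tie broken by larger |beta|, then snp id
  tie <- rbind(mk_rec("rs5", 1e6, 1e-9, beta = 0.1),
               mk_rec("rs6", 1e6, 1e-9, beta = -0.3))
  expect_equal(select_cis_instrument(tie, 1e6)$snp, "rs6")
})

test_that("greedy clumping keeps the independent record set", {
  ld2 <- matrix(c(1, 0.5, 0.5, 1), 2,
                dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  recs <- rbind(mk_rec("rs1", 1e6, 1e-10), mk_rec("rs2", 1.2e6, 1e-9))
  expect_equal(clump(recs, ld2)$snp, "rs1")

  apart <- rbind(mk_rec("rs1", 1e6, 1e-10), mk_rec("rs2", 3.5e6, 1e-9))
  expect_equal(clump(apart, ld2)$snp, c("rs1", "rs2"))

  # chained LD: keep 1, drop 2 (r2 with 1 = 0.9), keep 3 (r2 with 1 = 5e-4)
  ld3 <- matrix(c(1, .9, 5e-4, .9, 1, .9, 5e-4, .9, 1), 3,
                dimnames = list(paste0("rs", 1:3), paste0("rs", 1:3)))
  chain <- rbind(mk_rec("rs1", 1e6, 1e-12), mk_rec("rs2", 1.1e6, 1e-11),
                 mk_rec("rs3", 1.2e6, 1e-10))
  expect_equal(clump(chain, ld3)$snp, c("rs1", "rs3"))

  # output invariant to input order
  expect_equal(clump(chain[c(3, 1, 2), ], ld3)$snp, c("rs1", "rs3"))

  no_ld <- ld3[1:2, 1:2]
  expect_error(clump(chain, no_ld), "rs3")
})

test_that("allele harmonization flips, drops and reports reasons", {
  exp_rec <- mk_rec("rs1", 1e6, 1e-9, beta = 0.4)
  same <- harmonize_alleles(exp_rec, mk_rec("rs1", 1e6, 0.5, beta = 0.02))
  expect_equal(same$status, "ok")
  expect_equal(same$instrument$outcome$beta, 0.02)

  swapped <- harmonize_alleles(exp_rec,
                               mk_rec("rs1", 1e6, 0.5, beta = 0.02,
                                      a1 = "G", a2 = "A"))
  expect_equal(swapped$status, "flipped")
  expect_equal(swapped$instrument$outcome$beta, -0.02)
  expect_equal(swapped$instrument$outcome$a1, "A")

  pal <- harmonize_alleles(mk_rec("rs1", 1e6, 1e-9, a1 = "A", a2 = "T"),
                           mk_rec("rs1", 1e6, 0.5, a1 = "A", a2 = "T",
                                  freq = 0.5))
  expect_equal(pal$status, "dropped")
  expect_match(pal$reason, "palindromic")

  mism <- harmonize_alleles(exp_rec,
                            mk_rec("rs1", 1e6, 0.5, a1 = "C", a2 = "T"))
  expect_equal(mism$status, "dropped")
  expect_match(mism$reason, "mismatched")
})

test_that("the Wald ratio matches hand arithmetic and is flip-invariant", {
  ident <- wald_ratio(0.03, 0.01, 1)
  expect_equal(ident$beta, 0.03)
  expect_equal(ident$se, 0.01)

  hand <- wald_ratio(0.02, 0.005, 0.4)
  expect_equal(hand$beta, 0.05)
  expect_equal(hand$se, 0.0125)
  expect_equal(hand$beta / hand$se, 4)

  flip <- wald_ratio(-0.02, 0.005, -0.4)
  expect_equal(flip[c("beta", "se", "p")], hand[c("beta", "se", "p")])
  expect_error(wald_ratio(0.1, 0.01, 0), "non-zero")

  second <- wald_ratio(0.02, 0.005, 0.4, se_exposure = 0.05,
                       second_order = TRUE)
  expect_gt(second$se, hand$se)
})

test_that("forward MR recovers the planted causal slope and 2SLS oracle", {
  spec <- list(maf = rep(0.3, 2),
               snp_cpg = data.frame(snp = c("rs00001", "rs00002"),
                                    cpg = c("cg9000001", "cg9000002"),
                                    slope = c(0.4, 0.4)),
               cpg_trait = data.frame(cpg = c("cg9000001", "cg9000002"),
                                      slope = c(0.05, 0)))
  sim <- simulate_mqtl_study(5000, 2, 2, spec, seed = 77)
  sumry <- summarize_mqtl_study(sim)
  mr <- forward_mr(sim$cpg_info[1:2, c("cpg", "pos")], sumry$mqtl,
                   sumry$gwas)
  row <- mr[mr$cpg == "cg9000001", ]
  expect_lt(abs(row$beta - 0.05), 2 * row$se)

  # two-stage least squares on the individual-level data
  g <- sim$genotypes[, "rs00001"]
  stage1 <- fitted(lm(sim$m_values["cg9000001", ] ~ g))
  tsls <- coef(lm(sim$trait ~ stage1))[2]
  expect_equal(row$beta, unname(tsls), tolerance = 1e-8)

  # allele-orientation invariance of the full pipeline
  gwas_flip <- sumry$gwas
  gwas_flip$beta <- -gwas_flip$beta
  a1 <- gwas_flip$a1; gwas_flip$a1 <- gwas_flip$a2; gwas_flip$a2 <- a1
  gwas_flip$freq <- 1 - gwas_flip$freq
  mr2 <- forward_mr(sim$cpg_info[1:2, c("cpg", "pos")], sumry$mqtl,
                    gwas_flip)
  expect_equal(mr2$beta, mr$beta, tolerance = 1e-12)
  expect_equal(mr2$p, mr$p, tolerance = 1e-12)

  expect_error(forward_mr(sim$cpg_info[0, ], sumry$mqtl, sumry$gwas),
               "empty")
})

test_that("CpGs without usable instruments are reported untested", {
  mq <- mk_rec("rs1", 5e6, 1e-12)
  mq$cpg <- "cgX"
  gw <- mk_rec("rs9", 1e6, 0.5)
  got <- forward_mr(data.frame(cpg = "cgX", pos = 1e6), mq, gw)
  expect_equal(nrow(got), 0)
  expect_match(attr(got, "untested")$cgX, "no cis instrument")
})

test_that("reverse MR reduces to the Wald ratio for one instrument and
           recovers a planted trait-to-methylation slope", {
  set.seed(16)
  n <- 4000
  maf <- rep(0.3, 5)
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  colnames(G) <- paste0("rs", 1:5)
  trait <- G %*% rep(0.25, 5) + rnorm(n)
  cpg <- 0.1 * trait + rnorm(n)
  gwas <- do.call(rbind, lapply(1:5, function(i) {
    fit <- summary(lm(trait ~ G[, i]))$coefficients
    mk_rec(colnames(G)[i], 1e6 + i * 2.5e6, fit[2, 4], beta = fit[2, 1],
           se = fit[2, 2])
  }))
  mqtl_out <- do.call(rbind, lapply(1:5, function(i) {
    fit <- summary(lm(cpg ~ G[, i]))$coefficients
    r <- mk_rec(colnames(G)[i], 1e6 + i * 2.5e6, fit[2, 4],
                beta = fit[2, 1], se = fit[2, 2])
    r$cpg <- "cgY"
    r
  }))
  ld <- diag(5); dimnames(ld) <- list(colnames(G), colnames(G))

  got <- reverse_mr(gwas, ld, mqtl_out, "cgY")
  expect_equal(got$n_snps, 5)
  expect_lt(abs(got$beta - 0.1), 2 * got$se)

  one <- reverse_mr(gwas[1, ], ld[1, 1, drop = FALSE], mqtl_out, "cgY")
  wr <- wald_ratio(mqtl_out$beta[1], mqtl_out$se[1], gwas$beta[1])
  expect_equal(one$beta, wr$beta, tolerance = 1e-12)
  expect_equal(one$se, wr$se, tolerance = 1e-12)

  weak <- gwas; weak$p <- 0.5
  expect_error(reverse_mr(weak, ld, mqtl_out, "cgY"), "clumping")
})
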