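test_that("IVW pooling matches closed forms and the GLS oracle", {
  one <- ivw_fixed_effect(0.5, 0.1)
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)

  two <- ivw_fixed_effect(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(two$beta, 0.3)
  expect_equal(two$se, 0.2 / sqrt(2))

  hand <- ivw_fixed_effect(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(hand$beta, 0.24)
  expect_equal(hand$se, 1 / sqrt(125), tolerance = 1e-10)

  # brute-force diagonal-weight GLS solve, plus metafor as a second oracle
  set.seed(21)
  for (r in 1:10) {
    k <- sample(2:8, 1)
    b <- rnorm(k); s <- runif(k, 0.05, 0.5)
    W <- diag(1 / s^2)
    X <- matrix(1, k, 1)
    gls_beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% b)[1, 1]
    gls_se <- sqrt(solve(t(X) %*% W %*% X)[1, 1])
    got <- ivw_fixed_effect(b, s)
    expect_equal(got$beta, gls_beta, tolerance = 1e-10)
    expect_equal(got$se, gls_se, tolerance = 1e-10)
  }
  mf <- metafor::rma(yi = c(0.2, 0.4), sei = c(0.1, 0.2), method = "FE")
  expect_equal(hand$beta, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(hand$se, mf$se, tolerance = 1e-10)

  expect_error(ivw_fixed_effect(numeric(), numeric()), "empty")
  expect_error(ivw_fixed_effect(0.1, 0), "> 0")
})

test_that("probe filters apply the presence, sample-size and s.e. rules", {
  mk <- function(i, probes, n = 100)
    fake_stats(probes, rnorm(length(probes), 0, 0.05), n = n,
               study_id = paste0("s", i))
  # probe "a" in 3 of 5 studies -> presence rule (3/5 > 1/2)
  studies <- c(lapply(1:3, mk, probes = c("a", "b")),
               lapply(4:5, mk, probes = "b"))
  flt <- filter_probes(studies)
  ra <- flt$report[flt$report$probe == "a", ]
  expect_true(ra$retained)
  expect_equal(ra$rule, "presence")

  # probe in 2 of 5 studies but with 85% of the max n -> n rule
  big <- c(lapply(1:2, mk, probes = c("a", "b"), n = 850),
           lapply(3:5, mk, probes = "b", n = 100))
  fb <- filter_probes(big)
  rb <- fb$report[fb$report$probe == "a", ]
  expect_true(rb$retained)
  expect_equal(rb$rule, "n_rule")

  # strict reading of "more than half": 3 of 6 fails
  six <- c(lapply(1:3, mk, probes = c("a", "b")),
           lapply(4:6, mk, probes = "b"))
  rs <- filter_probes(six)$report
  expect_false(rs$retained[rs$probe == "a"])

  # records with s.e. > 0.5 are dropped before pooling
  noisy <- fake_stats("a", 0.1, ses = 0.6, study_id = "s9")
  fltn <- filter_probes(c(studies, list(noisy)))
  expect_equal(fltn$n_dropped_se, 1)
  expect_false("s9" %in% fltn$records$study_id)
})

test_that("two-stage pooling equals one-stage pooling (associativity)", {
  set.seed(31)
  probes <- sprintf("p%02d", 1:20)
  studies <- lapply(1:6, function(i)
    fake_stats(probes, rnorm(20, 0, 0.1), ses = runif(20, 0.05, 0.3),
               study_id = paste0("s", i),
               array = if (i <= 3) "450K" else "EPIC"))
  mt <- two_stage_meta(studies, permissive_config())
  rec <- do.call(rbind, studies)
  for (pr in c("p01", "p07", "p20")) {
    ri <- rec[rec$probe == pr, ]
    direct <- ivw_fixed_effect(ri$beta, ri$se)
    expect_equal(mt$beta[mt$probe == pr], direct$beta, tolerance = 1e-12)
    expect_equal(mt$se[mt$probe == pr], direct$se, tolerance = 1e-12)
  }
  # identical study duplicated on both arrays
  dup <- list(fake_stats("x", 0.3, ses = 0.1, study_id = "d1",
                         array = "450K"),
              fake_stats("x", 0.3, ses = 0.1, study_id = "d2",
                         array = "EPIC"))
  md <- two_stage_meta(dup, permissive_config())
  expect_equal(md$beta, 0.3, tolerance = 1e-12)
  expect_equal(md$se, 0.1 / sqrt(2), tolerance = 1e-12)
})

test_that("pooled se decreases as studies are added", {
  ses <- c(0.3, 0.25, 0.2, 0.15)
  pooled <- vapply(2:4, function(k)
    ivw_fixed_effect(rep(0.1, k), ses[1:k])$se, numeric(1))
  expect_true(all(diff(c(ses[1], pooled)) < 0))
})

test_that("direction strings follow the stable study order", {
  studies <- list(fake_stats("a", 0.2, study_id = "s1", array = "450K"),
                  fake_stats("a", -0.1, study_id = "s2", array = "EPIC"),
                  fake_stats("b", 0.1, study_id = "s3", array = "EPIC"))
  mt <- two_stage_meta(studies, permissive_config())
  expect_equal(mt$direction[mt$probe == "a"], "+-?")
  expect_equal(mt$direction[mt$probe == "b"], "??+")
})

test_that("Bonferroni arithmetic matches the closed forms", {
  expect_equal(bonferroni_adjust(0.5, 3), 1.0)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  expect_equal(round(bonferroni_threshold(0.05, 15), 5), 0.00333)
  expect_error(bonferroni_adjust(0.5, 0), "m")
  expect_error(bonferroni_adjust(0, 10), "p")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(4)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))  # order-preserving
  # independent step-up oracle on the sorted p-values
  ps <- sort(p)
  oracle <- pmin(rev(cummin(rev(ps * length(p) / seq_along(ps)))), 1)
  expect_equal(sort(q), oracle, tolerance = 1e-12)
  expect_error(bh_fdr(numeric()), "empty")
})

test_that("pooled estimates recover planted effects within 3 se", {
  hits <- 0L; total <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_cohorts = 3, n_samples = c(200, 300, 400),
                      case_prevalence = 0.4, n_probes_shared = 60,
                      n_probes_epic_only = 0, n_causal = 5,
                      effect_size_d = 0.4, seed = 500 + r)
    out <- simulate_consortium(cfg)
    # PCs are left out: on a 60-probe matrix with 5 strong planted
    # effects the leading components align with case status and would
    # soak up the very signal under test.
    stats <- lapply(out$cohorts, run_probe_regression, model = "ahrr",
                    n_pcs = 0)
    mt <- two_stage_meta(stats, permissive_config())
    idx <- match(out$truth$causal_probe_ids, mt$probe)
    ok <- abs(mt$beta[idx] - out$truth$true_effects) <= 3 * mt$se[idx]
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})
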