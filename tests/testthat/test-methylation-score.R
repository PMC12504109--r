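mk_meta_tab <- function(p, beta = rnorm(length(p))) {
  data.frame(probe = sprintf("q%03d", seq_along(p)), p = p, beta = beta,
             stringsAsFactors = FALSE)
}

test_that("score weights are threshold-filtered and nested", {
  set.seed(6)
  meta <- mk_meta_tab(c(1e-9, 1e-3, 0.5, 0.04))
  ws <- build_weights(meta, thresholds = c(1, 0.01, 5e-8))
  expect_equal(nrow(ws[[1]]), 4)
  expect_equal(nrow(ws[["5e-08"]]), 1)
  expect_true(all(ws[["5e-08"]]$probe %in% ws[["0.01"]]$probe))
  expect_true(all(ws[["0.01"]]$probe %in% ws[["1"]]$probe))
  expect_equal(ws[["0.01"]]$weight,
               meta$beta[meta$p <= 0.01])
  expect_error(build_weights(meta, thresholds = 0), "0, 1")
})

test_that("scores are weighted M-value sums, linear in the weights", {
  M <- matrix(c(2, 1), 2, 3, dimnames = list(c("a", "b"), NULL))
  w <- data.frame(probe = c("a", "b"), weight = c(0.5, -1))
  expect_equal(as.numeric(compute_scores(M, w)), rep(0, 3))

  set.seed(7)
  M2 <- matrix(rnorm(40), 4, 10,
               dimnames = list(letters[1:4], NULL))
  w1 <- data.frame(probe = letters[1:4], weight = rnorm(4))
  w2 <- data.frame(probe = letters[1:4], weight = rnorm(4))
  w12 <- data.frame(probe = letters[1:4], weight = w1$weight + w2$weight)
  expect_equal(as.numeric(compute_scores(M2, w12)),
               as.numeric(compute_scores(M2, w1)) +
                 as.numeric(compute_scores(M2, w2)), tolerance = 1e-12)

  # unknown probes are skipped with a count; zero overlap errors
  w3 <- rbind(w1, data.frame(probe = "zz", weight = 5))
  s3 <- compute_scores(M2, w3)
  expect_equal(attr(s3, "n_missing"), 1L)
  expect_equal(as.numeric(s3), as.numeric(compute_scores(M2, w1)))
  expect_error(compute_scores(M2, data.frame(probe = "zz", weight = 1)),
               "overlap")
})

test_that("residualization removes covariates and standardizes", {
  set.seed(8)
  n <- 200
  cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 2 + 0.5 * cov$age + rnorm(n)
  r <- residualize(y, cov)
  expect_equal(mean(r), 0, tolerance = 1e-9)
  expect_equal(sd(r), 1, tolerance = 1e-9)
  expect_lt(abs(cor(r, cov$age)), 1e-10)
  expect_lt(abs(cor(r, cov$sex)), 1e-10)

  # exact linear dependence is degenerate
  expect_error(residualize(3 * cov$age, cov["age"]), "degenerate")
  # rank-deficient covariates are rejected
  cov$age2 <- cov$age
  expect_error(residualize(y, cov), "rank-deficient")
})

test_that("Mann-Whitney AUC matches pair enumeration and the ROC oracle", {
  expect_equal(auc_mann_whitney(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_mann_whitney(c(2, 3, 1, 2), c(1, 1, 0, 0)), 0.875)

  # trapezoidal ROC integral as an independent oracle
  trap_auc <- function(s, y) {
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), numeric(1)), 1)
    fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), numeric(1)), 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(9)
  for (r in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(60), 1)  # ties included
    expect_equal(auc_mann_whitney(s, y), trap_auc(s, y),
                 tolerance = 1e-10)
  }
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "classes")
})

test_that("null-permutation AUC distribution centers on one half", {
  set.seed(10)
  s <- rnorm(300); y <- rbinom(300, 1, 0.3)
  aucs <- vapply(1:200, function(i) auc_mann_whitney(s, sample(y)),
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("RINT reproduces Blom scores and is rank-invariant", {
  got <- rank_inverse_normal(c(10, 40, 20))
  expect_equal(got, qnorm((c(1, 3, 2) - 3 / 8) / 3.25))
  expect_equal(round(sort(got), 4), c(-0.8694, 0, 0.8694))
  expect_equal(rank_inverse_normal(c(5, 9, 7))[3], 0)  # median maps to 0
  x <- rexp(50)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(log(x)))
  expect_error(rank_inverse_normal(rep(1, 5)), "tied")
  expect_error(rank_inverse_normal(1:2), "at least 3")
})

test_that("detection filter drops proteins strictly over 40% below LLOD", {
  ab <- matrix(rnorm(500), 100, 5,
               dimnames = list(NULL, paste0("pr", 1:5)))
  below <- matrix(FALSE, 100, 5, dimnames = dimnames(ab))
  below[1:40, 2] <- TRUE   # exactly 40%: retained
  below[1:41, 4] <- TRUE   # over 40%: dropped
  panel <- structure(list(abundance = ab, below_llod = below),
                     class = "protein_panel")
  flt <- filter_proteins_by_detection(panel)
  expect_setequal(colnames(flt$abundance), c("pr1", "pr2", "pr3", "pr5"))
  rep <- attr(flt, "report")
  expect_false(rep$retained[rep$protein == "pr4"])

  clean <- structure(list(abundance = ab,
                          below_llod = below & FALSE),
                     class = "protein_panel")
  expect_equal(ncol(filter_proteins_by_detection(clean)$abundance), 5)
})

test_that("classification beta sign tracks the score mean difference", {
  set.seed(11)
  y <- rbinom(400, 1, 0.4)
  s <- rnorm(400) + 0.4 * y
  cls <- classify_case_control(s, y)
  expect_gt(cls$beta, 0)
  expect_equal(sign(cls$beta),
               sign(mean(s[y == 1]) - mean(s[y == 0])))
  expect_gt(cls$auc, 0.5)
  expect_error(classify_case_control(s, rep(1, 400)), "classes")
})

test_that("PWAS recovers a planted protein association and its sign", {
  hits <- 0L
  for (r in 1:10) {
    set.seed(60000 + r)
    score <- rnorm(875)
    slopes <- rep(0, 30); slopes[7] <- -0.15
    panel <- simulate_protein_panel(875, 30, score, slopes,
                                    lod_fail_fraction = 0,
                                    seed = 600 + r)
    res <- pwas(score, panel)
    top <- res$protein[which.max(abs(res$beta))]
    if (top == "prot007" && res$beta[res$protein == "prot007"] < 0)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("an all-null panel yields no FDR discoveries in most runs", {
  fdr_hits <- vapply(1:10, function(r) {
    set.seed(70000 + r)
    score <- rnorm(300)
    panel <- simulate_protein_panel(300, 70, score, rep(0, 70),
                                    lod_fail_fraction = 0, seed = 700 + r)
    sum(pwas(score, panel)$q_fdr < 0.05)
  }, numeric(1))
  expect_gte(mean(fdr_hits == 0), 0.9)
})
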