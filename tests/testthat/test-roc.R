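test_that("empirical ROC enumerates unique cutoffs plus a sentinel", {
  curve <- empirical_roc(c(2, 6, 8), c(1, 3))
  expect_equal(nrow(curve), 6)  # 5 unique scores + sentinel
  at6 <- curve[curve$cutoff == 6, ]
  expect_equal(at6$sens, 2 / 3)
  expect_equal(at6$spec, 1)
  # endpoints always present
  expect_true(any(curve$sens == 1 & curve$spec == 0))
  expect_true(any(curve$sens == 0 & curve$spec == 1))
  # tie-only input degenerates to the two endpoint operating points
  tie <- empirical_roc(5, 5)
  expect_equal(tie$sens, c(1, 0))
  expect_equal(tie$spec, c(0, 1))
  expect_error(empirical_roc(numeric(), 1), "non-empty")
})

test_that("sens is non-increasing and spec non-decreasing along the curve", {
  set.seed(11)
  for (rep in 1:20) {
    pos <- sample(1:10, sample(1:15, 1), replace = TRUE)
    neg <- sample(1:10, sample(1:15, 1), replace = TRUE)
    curve <- empirical_roc(pos, neg)
    expect_true(all(diff(curve$sens) <= 1e-12))
    expect_true(all(diff(curve$spec) >= -1e-12))
  }
})

test_that("AUC is the tie-aware Mann-Whitney statistic", {
  expect_equal(roc_auc(c(3, 5, 7), c(1, 4))$auc, 5 / 6)
  expect_equal(roc_auc(rep(2, 5), rep(2, 7))$auc, 0.5)
  set.seed(12)
  for (rep in 1:30) {
    pos <- sample(1:8, sample(2:30, 1), replace = TRUE)
    neg <- sample(1:8, sample(2:30, 1), replace = TRUE)
    a <- roc_auc(pos, neg)$auc
    expect_equal(a, oracle_auc(pos, neg), tolerance = 1e-12)
    # trapezoidal area under the empirical curve equals the statistic
    expect_equal(a, oracle_trapezoid(empirical_roc(pos, neg)),
                 tolerance = 1e-12)
    # complement on tie-free data
    posu <- unique(stats::runif(10)); negu <- unique(stats::runif(10))
    expect_equal(roc_auc(posu, negu)$auc + roc_auc(negu, posu)$auc, 1,
                 tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE matches its closed form (AUC 0.8, n 50/50)", {
  pos <- c(rep(100, 40), rep(0, 10))
  neg <- rep(50, 50)
  res <- roc_auc(pos, neg)
  expect_equal(res$auc, 0.8)
  expect_equal(res$q1, 0.8 / 1.2, tolerance = 1e-12)
  expect_equal(res$q2, 2 * 0.64 / 1.8, tolerance = 1e-12)
  expect_equal(res$se, 0.04450, tolerance = 1e-4)
  expect_equal(res$ci95, pmin(1, pmax(0, 0.8 + c(-1, 1) * 1.96 * res$se)))
  expect_true(res$ci95[1] <= res$auc && res$auc <= res$ci95[2])
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (rep in 1:5) {
    pos <- rnorm(30, 1); neg <- rnorm(40)
    ref <- pROC::auc(pROC::roc(
      response = c(rep(1, 30), rep(0, 40)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE))
    expect_equal(roc_auc(pos, neg)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Youden cutoff matches exhaustive search and its tie-breaks", {
  res <- youden_cutoff(c(2, 6, 8), c(1, 3))
  expect_equal(res$cutoff, 6)
  expect_equal(res$youden_j, 2 / 3)
  expect_equal(res$youden_j, res$sens + res$spec - 1)
  # perfectly separated: J = 1 at the lowest achieving cutoff
  sep <- youden_cutoff(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$cutoff, 10)
  # identical distributions: J = 0
  expect_equal(youden_cutoff(c(1, 2, 3), c(1, 2, 3))$youden_j, 0)
  set.seed(14)
  for (rep in 1:30) {
    pos <- sample(1:12, sample(2:50, 1), replace = TRUE)
    neg <- sample(1:12, sample(2:50, 1), replace = TRUE)
    got <- youden_cutoff(pos, neg)
    want <- oracle_youden(pos, neg)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
  }
})

test_that("score shifts leave AUC, J and the operating point unchanged", {
  set.seed(15)
  pos <- rnorm(25, 0.8); neg <- rnorm(25)
  base_auc <- roc_auc(pos, neg)
  base_j <- youden_cutoff(pos, neg)
  for (shift in c(-5, 3.7, 100)) {
    expect_equal(roc_auc(pos + shift, neg + shift)$auc, base_auc$auc,
                 tolerance = 1e-12)
    shifted <- youden_cutoff(pos + shift, neg + shift)
    expect_equal(shifted$youden_j, base_j$youden_j, tolerance = 1e-12)
    expect_equal(shifted$sens, base_j$sens)
    expect_equal(shifted$spec, base_j$spec)
    expect_equal(shifted$cutoff, base_j$cutoff + shift, tolerance = 1e-9)
  }
})

test_that("paired AUC comparison: degenerate and symmetric cases", {
  set.seed(16)
  s <- rnorm(30)
  y <- rep(c(TRUE, FALSE), 15)
  self <- compare_auc_paired(s, s, y)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  # reflection on separable data: auc_b = 1 - auc_a
  pos <- 11:20; neg <- 1:10
  sa <- c(pos, neg); yy <- c(rep(TRUE, 10), rep(FALSE, 10))
  # degenerate variance (perfect separation both ways) is flagged
  expect_warning(refl <- compare_auc_paired(sa, -sa, yy), "zero variance")
  expect_equal(refl$auc_a, 1)
  expect_equal(refl$delta_auc, refl$auc_a - (1 - refl$auc_a))
  expect_error(compare_auc_paired(1:3, 1:4, c(TRUE, FALSE, TRUE)),
               "same length")
  expect_error(compare_auc_paired(1:3, 1:3, c(TRUE, TRUE, TRUE)), "classes")
})

test_that("placement covariance matches a first-principles oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 6
    sa <- rnorm(n); sb <- 0.5 * sa + rnorm(n)
    y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    got <- compare_auc_paired(sa, sb, y)
    expect_equal(got$cov_ab, oracle_paired_cov(sa, sb, y),
                 tolerance = 1e-10)
  }
})

test_that("paired z-test agrees with the reference DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  y <- c(rep(1, 40), rep(0, 40))
  x <- c(rnorm(40, 1), rnorm(40))
  sa <- x + rnorm(80, sd = 0.5)
  sb <- x + rnorm(80, sd = 1.5)
  got <- compare_auc_paired(sa, sb, y)
  ra <- pROC::roc(y, sa, direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, sb, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(abs(got$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-8)
})
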