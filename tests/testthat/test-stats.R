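test_that("percent display rounds half up on the exact rational", {
  expect_equal(round_percent(72, 104), 69.2)
  expect_equal(round_percent(91, 119), 76.5)
  expect_equal(round_percent(1, 3), 33.3)
  expect_equal(round_percent(1, 16), 6.3)    # 6.25% -> half up
  expect_equal(round_percent(1, 8), 12.5)    # exact one-decimal value
  expect_equal(round_percent(0, 5), 0)
  expect_equal(round_percent(5, 5), 100)
  expect_error(round_percent(1, 0), "positive")
})

test_that("confusion tables count (predicted, truth) pairs with malignant positive", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ct <- build_confusion(truth, truth)
  expect_identical(c(ct$fp, ct$fn), c(0L, 0L))
  ct0 <- build_confusion(rep(FALSE, 5), truth)
  expect_identical(c(ct0$tp, ct0$fp), c(0L, 0L))
  expect_error(build_confusion(TRUE, c(TRUE, FALSE)), "length")

  m <- confusion_metrics(confusion_table(tp = 72, fp = 28, fn = 32, tn = 91))
  expect_equal(m$percent[m$metric == "accuracy"], 73.1)
  expect_equal(m$value, c(72/104, 91/119, 163/223, 72/100, 91/123))

  # zero-denominator metrics are undefined, not zero
  m0 <- confusion_metrics(confusion_table(0, 0, 0, 10))
  expect_equal(m0$percent[m0$metric == "specificity"], 100)
  expect_true(is.na(m0$value[m0$metric == "sensitivity"]))
  expect_true(is.na(m0$value[m0$metric == "ppv"]))
})

test_that("ROC points follow the 'score > c' convention and bound the AUC", {
  # perfectly separated scores pass through (0, 1)
  r <- roc_points(c(1, 1, 5, 5), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  # all ties: only the two endpoints
  r2 <- roc_points(rep(3, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(nrow(r2), 3L)  # Inf, the single score, -Inf
  expect_equal(r2$fpr, c(0, 0, 1))
  expect_equal(r2$tpr, c(0, 0, 1))
  # hand-enumerated thresholds
  r3 <- roc_points(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  at2 <- r3[r3$threshold == 2, ]
  expect_equal(c(at2$fpr, at2$tpr), c(0, 0.5))
  expect_true(all(diff(r3$fpr) >= 0) && all(diff(r3$tpr) >= 0))
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Mann-Whitney AUC equals the pairwise oracle and the trapezoid", {
  expect_equal(auc_mann_whitney(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE)),
               0.875)
  expect_equal(auc_mann_whitney(c(1, 1, 9, 9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_mann_whitney(rep(4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(401)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:11, n, replace = TRUE)
    a <- auc_mann_whitney(scores, truth)
    expect_equal(a, auc_brute_force(scores, truth), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(roc_points(scores, truth)),
                 tolerance = 1e-12)
    # complement symmetry
    expect_equal(a + auc_mann_whitney(-scores, truth), 1, tolerance = 1e-12)
  }
})

test_that("DeLong structural components match the hand-computed example", {
  scores <- c(2, 3, 1, 2); truth <- c(TRUE, TRUE, FALSE, FALSE)
  d <- delong_components(scores, truth)
  expect_equal(d$auc, 0.875)
  expect_equal(sort(d$v10), c(0.75, 1))
  expect_equal(sort(d$v01), c(0.75, 1))
  expect_equal(d$var, 0.03125)
  # perfect separation: all components are 1, variance 0
  dp <- delong_components(c(9, 9, 1, 1), truth)
  expect_equal(dp$var, 0)
  expect_error(delong_components(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least 2")
})

test_that("the paired DeLong test is symmetric and degenerates gracefully", {
  set.seed(77)
  truth <- rep(c(TRUE, FALSE), each = 30)
  s1 <- ifelse(truth, sample(3:11, 60, TRUE), sample(1:8, 60, TRUE))
  s2 <- pmin(11, s1 + sample(0:2, 60, TRUE))
  same <- delong_paired_test(s1, s1, truth)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_paired_test(s1, s2, truth)
  ba <- delong_paired_test(s2, s1, truth)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$covariance, ba$covariance)
})

test_that("AUC, variance and paired p agree with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(42)
  co <- score_cohort(generate_cohort(default_cohort_spec(200L), ks_tree_t1(),
                                     seed = 42), ks_tree_t1())
  truth <- co$truth == "malignant"
  r1 <- pROC::roc(truth, co$ks, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(truth, co$ks_star, quiet = TRUE, direction = "<")
  expect_equal(auc_mann_whitney(co$ks, truth), as.numeric(pROC::auc(r1)),
               tolerance = 1e-12)
  expect_equal(delong_components(co$ks, truth)$var, pROC::var(r1),
               tolerance = 1e-10)
  ours <- delong_paired_test(co$ks_star, co$ks, truth)
  theirs <- pROC::roc.test(r2, r1, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(theirs$statistic)),
               tolerance = 1e-10)
  expect_equal(ours$p, as.numeric(theirs$p.value), tolerance = 1e-10)
})

test_that("the asymptotic DeLong p agrees with a pairing-permutation oracle", {
  set.seed(314)
  co <- score_cohort(generate_cohort(default_cohort_spec(200L), ks_tree_t1(),
                                     seed = 314), ks_tree_t1())
  truth <- co$truth == "malignant"
  obs <- delong_paired_test(co$ks_star, co$ks, truth)
  d_obs <- abs(obs$auc1 - obs$auc2)
  n <- nrow(co)
  perm <- replicate(5000, {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, co$ks, co$ks_star)
    b <- ifelse(swap, co$ks_star, co$ks)
    abs(auc_mann_whitney(a, truth) - auc_mann_whitney(b, truth))
  })
  p_perm <- mean(perm >= d_obs - 1e-12)
  expect_lt(abs(p_perm - obs$p), 0.01)
})

test_that("Cohen's kappa matches hand and reference computations", {
  r_from_table <- function(a, b, c, d) {
    list(r1 = rep(c("x", "x", "y", "y"), c(a, b, c, d)),
         r2 = rep(c("x", "y", "x", "y"), c(a, b, c, d)))
  }
  # identical ratings with both categories present
  k1 <- cohen_kappa(c("x", "x", "y"), c("x", "x", "y"))
  expect_equal(k1$kappa, 1)
  expect_identical(k1$band, "excellent")
  # independence: p_o = p_e = 0.5
  r <- r_from_table(25, 25, 25, 25)
  k0 <- cohen_kappa(r$r1, r$r2)
  expect_equal(k0$kappa, 0, tolerance = 1e-12)
  expect_identical(k0$band, "bad")
  # hand-applied formula: (0.85 - 0.51) / 0.49
  r <- r_from_table(50, 5, 10, 35)
  kg <- cohen_kappa(r$r1, r$r2)
  expect_equal(kg$kappa, (0.85 - 0.51) / 0.49, tolerance = 1e-12)
  expect_identical(kg$band, "good")
  # large-sample SE frozen from an independent implementation
  expect_equal(kg$se, 0.07241952039128227, tolerance = 1e-9)
  expect_equal(kg$ci, c(0.5519352910534949, 0.8358198109873214),
               tolerance = 1e-8)
  r2 <- r_from_table(70, 10, 5, 15)
  expect_equal(cohen_kappa(r2$r1, r2$r2)$se, 0.09795918367346947,
               tolerance = 1e-9)
  # symmetry and the constant-identical edge case
  expect_equal(cohen_kappa(r$r1, r$r2)$kappa, cohen_kappa(r$r2, r$r1)$kappa)
  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5))$kappa, 1)
  expect_error(cohen_kappa("x", c("x", "y")), "length")
})

test_that("kappa agreement bands follow the reader-study convention", {
  expect_identical(cohen_kappa(c("x","x","y","y"), c("y","y","x","x"))$band,
                   "bad")  # kappa = -1
  # band boundaries checked through the banding rule on synthetic kappas
  band_of <- function(k) if (k < 0.4) "bad" else if (k <= 0.7) "good" else "excellent"
  expect_identical(band_of(0.39), "bad")
  expect_identical(band_of(0.4), "good")
  expect_identical(band_of(0.7), "good")
  expect_identical(band_of(0.71), "excellent")
})

test_that("Pearson chi-square (uncorrected) matches the closed form", {
  eq <- chi2_2x2(c(10, 10, 10, 10))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # closed form N(ad-bc)^2 / (row and column products), independent route
  tab <- c(65, 14, 26, 14)
  got <- chi2_2x2(tab)
  a <- 65; b <- 14; c <- 26; d <- 14; N <- a + b + c + d
  hand <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got$chi2, hand, tolerance = 1e-12)
  # equals the squared two-proportion z statistic
  p1 <- a / (a + b); p2 <- c / (c + d); pp <- (a + c) / N
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c + d)))
  expect_equal(got$chi2, z^2, tolerance = 1e-12)
  # invariance under swapping rows together with columns
  swapped <- chi2_2x2(c(14, 26, 14, 65))
  expect_equal(swapped$chi2, got$chi2, tolerance = 1e-12)
  # Yates correction available but off by default
  expect_lt(chi2_2x2(tab, correct = TRUE)$chi2, got$chi2)
  expect_error(chi2_2x2(c(0, 0, 5, 5)), "marginal")
})
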