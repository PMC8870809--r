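rand_mask_pair <- function(d, p1 = 0.3, p2 = 0.3) {
  list(a = array(runif(prod(d)) < p1, d), b = array(runif(prod(d)) < p2, d))
}

test_that("dice handles the canonical cases", {
  d <- c(5, 5, 4)
  m <- array(runif(prod(d)) < 0.4, d)
  expect_equal(dice(m, m), 1)
  disj <- array(FALSE, d); disj[1, 1, 1] <- TRUE
  other <- array(FALSE, d); other[5, 5, 4] <- TRUE
  expect_equal(dice(disj, other), 0)
  # |a| = |b| = 100, overlap 50 -> 0.5
  a <- array(FALSE, c(20, 10, 1)); a[1:100] <- TRUE
  b <- array(FALSE, c(20, 10, 1)); b[51:150] <- TRUE
  expect_equal(dice(a, b), 0.5)
  # empty vs empty agrees on absence; empty vs non-empty does not
  e <- array(FALSE, d)
  expect_equal(dice(e, e), 1)
  expect_equal(dice(e, m), 0)
  expect_error(dice(m, array(FALSE, c(2, 2, 2))), "same grid")
})

test_that("jaccard equals dice/(2 - dice) on random mask pairs", {
  set.seed(33)
  for (i in 1:50) {
    p <- rand_mask_pair(c(6, 6, 6), runif(1, 0.05, 0.8), runif(1, 0.05, 0.8))
    dc <- dice(p$a, p$b)
    expect_equal(jaccard(p$a, p$b), dc / (2 - dc), tolerance = 1e-12)
    expect_equal(dice(p$a, p$b), dice(p$b, p$a))       # symmetry
    expect_gte(dc, 0); expect_lte(dc, 1)
  }
})

test_that("confusion metrics match voxel enumeration", {
  truth <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  pred <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$se, 0.5)
  expect_equal(cm$ppv, 1.0)
  expect_equal(cm$sp, 1.0)
  expect_equal(cm$npv, 0.5)
  # perfect prediction
  cmp <- confusion_metrics(truth, truth)
  expect_equal(unlist(cmp[c("se", "sp", "ppv", "npv")]),
               c(se = 1, sp = 1, ppv = 1, npv = 1))
  # complemented prediction has zero sensitivity and specificity
  cmx <- confusion_metrics(!truth, truth)
  expect_equal(cmx$se, 0); expect_equal(cmx$sp, 0)
  # undefined ratios are NA, not 0
  none <- array(FALSE, c(3, 1, 1))
  expect_true(is.na(confusion_metrics(none, truth)$ppv))
  expect_true(is.na(confusion_metrics(array(TRUE, c(3, 1, 1)),
                                      array(TRUE, c(3, 1, 1)))$sp))
})

test_that("Bland-Altman matches direct mean/sd computation", {
  x <- c(1, 2, 3); y <- x
  ba0 <- bland_altman(x, y)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_high - ba0$loa_low, 0)
  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, -5); expect_equal(ba5$loa_high - ba5$loa_low, 0)
  set.seed(12)
  a <- rnorm(100, 200, 80); b <- a + rnorm(100, 10, 25)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(77)
  x <- rnorm(2000, 100, 30)
  y <- x + rnorm(2000, 5, 12)
  ba <- bland_altman(x, y)
  d <- x - y
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(cover, 0.93); expect_lt(cover, 0.97)
})

test_that("spearman equals rank-then-Pearson, including ties", {
  expect_equal(spearman(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman(1:10, -(1:10)^3 + 5)$r, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(3, 1, 4, 4, 6, 2, 9, 9)
  expect_equal(spearman(x, y)$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$r))
})

test_that("paired t-test covers identity, shift and a textbook example", {
  expect_equal(paired_t(1:5, 1:5), 1)
  set.seed(4)
  x <- rnorm(30, 0, 0.1)
  expect_lt(paired_t(x, x + 10), 1e-10)
  # hand-checked 5-pair example: d = (2,1,3,2,2), mean 2, sd sqrt(0.5),
  # t = 2 / (sqrt(0.5)/sqrt(5)) = 6.3246, df 4 -> p = 0.0031982
  a <- c(12, 9, 14, 11, 10); b <- c(10, 8, 11, 9, 8)
  expect_equal(paired_t(a, b), 2 * pt(-2 / (sqrt(0.5) / sqrt(5)), 4),
               tolerance = 1e-12)
  expect_equal(paired_t(a, b), 0.0031982, tolerance = 1e-4)
  # constant nonzero shift: zero-variance differences, t is infinite
  expect_equal(paired_t(1:5, 1:5 + 3), 0)
})

test_that("cohort report reproduces per-method statistics", {
  set.seed(55)
  n <- 20
  manual <- runif(n, 50, 600)
  cases <- rbind(
    data.frame(case = 1:n, subtype = rep(c("HL", "DLBCL"), each = n / 2),
               method = "41pc", tmtv_manual = manual,
               tmtv_pred = manual * 0.9 + rnorm(n, 0, 15),
               dice = runif(n, 0.6, 0.95)),
    data.frame(case = 1:n, subtype = rep(c("HL", "DLBCL"), each = n / 2),
               method = "suv4", tmtv_manual = manual,
               tmtv_pred = manual + rnorm(n, 0, 5),
               dice = runif(n, 0.8, 0.98)))
  rep <- cohort_report(cases)
  expect_setequal(rep$per_method$method, c("41pc", "suv4"))
  row <- rep$per_method[rep$per_method$method == "41pc", ]
  sub <- cases[cases$method == "41pc", ]
  expect_equal(row$dice_median, median(sub$dice))
  expect_equal(row$spearman_r, spearman(sub$tmtv_manual, sub$tmtv_pred)$r)
  expect_equal(row$ba_bias, mean(sub$tmtv_manual - sub$tmtv_pred))
  expect_equal(row$t_p, paired_t(sub$tmtv_manual, sub$tmtv_pred))
  expect_equal(nrow(rep$per_subtype), 4)    # 2 subtypes x 2 methods
  # identical predictions give perfect agreement
  perfect <- cases; perfect$tmtv_pred <- perfect$tmtv_manual
  perfect$dice <- 1
  prep <- cohort_report(perfect)
  expect_true(all(prep$per_method$dice_median == 1))
  expect_true(all(prep$per_method$ba_bias == 0))
  expect_true(all(prep$per_method$spearman_r == 1))
  expect_true(all(prep$per_method$t_p == 1))
})

test_that("cohort report excludes cases missing a methodology", {
  cases <- data.frame(case = c(1, 2, 3, 1, 2),
                      method = c("a", "a", "a", "b", "b"),
                      tmtv_manual = c(10, 20, 30, 10, 20),
                      tmtv_pred = c(11, NA, 29, 10, 21),
                      dice = c(0.9, 0.8, 0.85, 0.95, 0.9))
  rep <- cohort_report(cases)
  expect_equal(rep$per_method$n[rep$per_method$method == "a"], 2)
  expect_equal(rep$per_method$n[rep$per_method$method == "b"], 2)
})
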