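test_that("confusion counts at the advice dichotomy match hand counts", {
  # worked-example counts: T2D rules, 42,978 participants with 1,005 cases,
  # 14,169 advised of whom 819 developed disease
  cc <- example_confusion_counts("t2d", "rules")
  expect_equal(cc$tp, 819)
  expect_equal(cc$fn, 186)
  expect_equal(cc$fp, 13350)
  expect_equal(cc$tn, 28623)
  expect_equal(cc$n, 42978)

  # all advised, all events
  cc2 <- confusion_at_high(rep(TRUE, 4), rep(TRUE, 4))
  expect_equal(c(cc2$tp, cc2$fn, cc2$fp, cc2$tn), c(4, 0, 0, 0))

  # 6-participant toy vector against an exhaustive hand count
  strata <- c("HIGH", "ELEVATED", "HIGH", "NOT_ELEVATED", "CLINICAL", "HIGH")
  ev <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  cc3 <- confusion_at_high(strata, ev)
  expect_equal(c(cc3$tp, cc3$fn, cc3$fp, cc3$tn), c(2, 2, 1, 1))

  # conservation over random vectors
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    cc4 <- confusion_at_high(runif(n) < 0.4, runif(n) < 0.2)
    expect_equal(cc4$tp + cc4$fn + cc4$fp + cc4$tn, n)
  }
  expect_error(confusion_at_high(c(TRUE, FALSE), TRUE), "length mismatch")
})

test_that("sensitivity and specificity follow their definitions with sane CIs", {
  ss <- sens_spec(confusion_counts(tp = 819, fn = 186, fp = 13350, tn = 28623))
  expect_equal(ss$point[ss$metric == "sensitivity"], 819 / 1005)
  expect_equal(round(100 * ss$point[ss$metric == "sensitivity"], 1), 81.5)
  expect_equal(ss$point[ss$metric == "specificity"], 28623 / 41973)
  ss2 <- sens_spec(confusion_counts(tp = 360, fn = 140, fp = 10, tn = 10))
  expect_equal(ss2$point[ss2$metric == "sensitivity"], 0.720)
  # undefined denominators are flagged, not silently NaN
  ss3 <- sens_spec(confusion_counts(tp = 5, fn = 2, fp = 0, tn = 0))
  expect_false(ss3$defined[ss3$metric == "specificity"])
  expect_true(is.na(ss3$point[ss3$metric == "specificity"]))
  # CIs contain their point estimates
  ok <- ss$defined
  expect_true(all(ss$ci_low[ok] <= ss$point[ok] &
                    ss$point[ok] <= ss$ci_high[ok]))
  # optional zero-cell floor keeps ratio statistics finite and defined
  ss4 <- sens_spec(confusion_counts(tp = 5, fn = 2, fp = 0, tn = 0),
                   floor_zero_cells = TRUE)
  expect_true(ss4$defined[ss4$metric == "specificity"])
  expect_equal(ss4$point[ss4$metric == "specificity"], 0.5)
})

test_that("AUROC equals brute-force pair counting, with midrank tie handling", {
  ev <- c(rep(TRUE, 3), rep(FALSE, 5))
  expect_equal(auroc(c(4, 5, 6, 1, 2, 3, 3.5, 0), ev, ci = FALSE)$point, 1)
  expect_equal(auroc(rep(2, 8), ev, ci = FALSE)$point, 0.5)
  set.seed(2)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    ev_i <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes present
    sc <- sample(1:4, n, replace = TRUE)        # heavy ties
    expect_equal(auroc(sc, ev_i, ci = FALSE)$point, pair_count_auc(sc, ev_i))
  }
  expect_error(auroc(1:4, rep(TRUE, 4)), "at least one")
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(3)
  ev <- runif(300) < 0.3
  ev[1:2] <- c(TRUE, FALSE)
  sc <- rnorm(300) + ev
  got <- auroc(sc, ev, B = 500, seed = 99)
  ref <- as.numeric(pROC::auc(pROC::roc(ev, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got$point, ref, tolerance = 1e-12)
  expect_true(got$ci_low <= got$point && got$point <= got$ci_high)
  # bootstrap is seeded-deterministic
  got2 <- auroc(sc, ev, B = 500, seed = 99)
  expect_identical(got, got2)
})

test_that("the DeLong comparison behaves as a paired test should", {
  set.seed(4)
  ev <- runif(200) < 0.25
  ev[1:2] <- c(TRUE, FALSE)
  a <- rnorm(200) + ev
  b <- 0.5 * a + rnorm(200)
  same <- delong_compare(a, a, ev)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  cmp <- delong_compare(a, b, ev)
  swapped <- delong_compare(b, a, ev)
  expect_equal(cmp$difference, -swapped$difference)
  expect_equal(cmp$p_value, swapped$p_value)
  ref <- pROC::roc.test(pROC::roc(ev, a, quiet = TRUE, direction = "<"),
                        pROC::roc(ev, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the DeLong variance is consistent with a bootstrap estimate", {
  set.seed(5)
  n <- 300
  ev <- runif(n) < 0.3
  ev[1:2] <- c(TRUE, FALSE)
  a <- rnorm(n) + ev
  b <- rnorm(n) + 0.5 * ev
  dl <- delong_compare(a, b, ev)
  i1 <- which(ev); i0 <- which(!ev)
  boots <- replicate(2000, {
    j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    delong_compare(a[j], b[j], ev[j])$difference
  })
  expect_lt(abs(dl$se / sd(boots) - 1), 0.2)
})

test_that("reclassification tables cross-tabulate movement by event status", {
  old <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  new <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  ev <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  tab <- build_reclassification(old, new, ev)
  # hand cross-tab: events rows 1,2,3,4,9 -> up 1 (row 3), down 1 (row 2),
  # same_high 2 (rows 1,9), same_low 1 (row 4)
  expect_equal(unname(tab$events), c(1, 1, 2, 1))
  expect_equal(unname(tab$nonevents), c(1, 1, 1, 2))
  # identical classifiers move no one
  tab0 <- build_reclassification(old, old, ev)
  expect_equal(unname(tab0$events[c("up", "down")]), c(0, 0))
  expect_equal(unname(tab0$nonevents[c("up", "down")]), c(0, 0))
  # worked-example marginals: the hypertension arm has 2,379 events
  tabh <- example_reclassification_table("htn")
  expect_equal(tabh$n_events, 1751 + 566 + 8 + 54)
  expect_equal(tabh$n_events, 2379)
  expect_equal(tabh$n_nonevents, 33541 - 2379)
})

test_that("the NRI is antisymmetric and zero for identical classifiers", {
  set.seed(6)
  old <- runif(300) < 0.4
  new <- runif(300) < 0.4
  ev <- runif(300) < 0.3
  a <- nri(build_reclassification(old, new, ev))
  b <- nri(build_reclassification(new, old, ev))
  expect_equal(a$point, -b$point)
  expect_equal(a$se, b$se)
  zero <- nri(build_reclassification(old, old, ev))
  expect_equal(zero$point, 0)
  expect_equal(zero$p_value, 1)
})
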