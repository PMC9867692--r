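test_that("auroc equals the exhaustive pair-counting oracle", {
  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)          # coarse scores force ties
    expect_equal(auroc(s, y), pair_count_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("auroc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  y <- rbinom(500, 1, 0.3)
  y[1:2] <- c(0, 1)
  s <- rnorm(500) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(s, y), ref, tolerance = 1e-12)
})

test_that("auroc handles perfect, reversed, and constant scores", {
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(c(1, 2, 3, 4), y), 1)
  expect_equal(auroc(c(4, 3, 2, 1), y), 0)
  expect_equal(auroc(c(1, 1, 1, 1), y), 0.5)
})

test_that("auprc matches hand-computed average precision", {
  # scores (desc): y = 1, 0, 1, 0 -> AP = 1/2 * (1 + 2/3)
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(auprc(s, y), 0.5 * (1 + 2 / 3), tolerance = 1e-12)
  # tied scores enter as one group: both at 0.5 -> precision 1/2 at recall 1
  expect_equal(auprc(c(0.5, 0.5), c(1, 0)), 0.5, tolerance = 1e-12)
  # perfect ranking
  expect_equal(auprc(c(3, 2, 1), c(1, 1, 0)), 1)
})

test_that("youden_threshold equals exhaustive search and favors low ties", {
  set.seed(33)
  for (r in 1:50) {
    n <- sample(4:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)
    thr <- youden_threshold(s, y)
    expect_equal(as.numeric(thr), exhaustive_youden(s, y))
  }
  # the rule is score >= threshold => positive
  thr <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "j"), 1)
})

test_that("compute_metrics matches a worked confusion matrix", {
  s <- c(0.9, 0.8, 0.3, 0.2, 0.7, 0.1)
  y <- c(1, 1, 0, 0, 0, 1)
  m <- compute_metrics(s, y, threshold = 0.7)
  # predicted positive: 0.9, 0.8, 0.7 -> tp = 2, fp = 1, fn = 1, tn = 2
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$accuracy, 4 / 6)
})

test_that("compute_metrics reports NA (not 0) for empty predicted classes", {
  s <- c(0.1, 0.2, 0.3, 0.4)
  y <- c(0, 0, 1, 1)
  m <- compute_metrics(s, y, threshold = 0.9)  # nobody predicted positive
  expect_true(is.na(m$ppv))
  expect_equal(m$sensitivity, 0)
  m2 <- compute_metrics(s, y, threshold = 0)   # everybody predicted positive
  expect_true(is.na(m2$npv))
})

test_that("bootstrap_ci is seeded, ordered, and brackets plausibly", {
  set.seed(44)
  y <- rbinom(300, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(300) + 1.2 * y
  ci1 <- bootstrap_ci(s, y, "auroc", n_resamples = 200, seed = 5L)
  ci2 <- bootstrap_ci(s, y, "auroc", n_resamples = 200, seed = 5L)
  expect_identical(ci1, ci2)
  expect_true(ci1[["lower"]] <= ci1[["upper"]])
  expect_true(ci1[["lower"]] <= auroc(s, y) && auroc(s, y) <= ci1[["upper"]])
})

test_that("bootstrap_ci redraws single-class resamples instead of failing", {
  y <- c(1, rep(0, 19))          # single positive: many resamples miss it
  s <- seq(0, 1, length.out = 20)
  expect_message(
    ci <- bootstrap_ci(s, y, "auroc", n_resamples = 50, seed = 2L),
    "redrew")
  expect_true(all(is.finite(ci)))
})

test_that("continuous NRI matches the definitional tally", {
  # 8 subjects: 4 events, 4 non-events
  ref <- c(0.2, 0.3, 0.4, 0.5, 0.2, 0.3, 0.4, 0.5)
  upd <- c(0.3, 0.4, 0.3, 0.6, 0.1, 0.2, 0.5, 0.4)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- nri(ref, upd, y)
  # events: up 3 (1,2,4), down 1 (3) -> 3/4 - 1/4 = 0.5
  # non-events: down 3 (5,6,8), up 1 (7) -> 3/4 - 1/4 = 0.5
  expect_equal(r$nri_events, 0.5)
  expect_equal(r$nri_nonevents, 0.5)
  expect_equal(r$nri, 1.0)
  expect_equal(r$overall_correct_pct, 100 * (3 + 3 - 1 - 1) / 8)
  # Pencina asymptotic z against a manual computation
  se <- sqrt((3 / 4 + 1 / 4 - 0.5^2) / 4 + (1 / 4 + 3 / 4 - 0.5^2) / 4)
  expect_equal(r$z, 1.0 / se, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-abs(1.0 / se)), tolerance = 1e-12)
})

test_that("categorical NRI respects supplied cutoffs", {
  # categories: <0.1, [0.1, 0.3), >=0.3
  ref <- c(0.05, 0.2, 0.2, 0.4)
  upd <- c(0.2, 0.05, 0.4, 0.4)
  y <- c(1, 1, 0, 0)
  r <- nri(ref, upd, y, categories = c(0.1, 0.3))
  # events: subject 1 up, subject 2 down -> 0
  expect_equal(r$nri_events, 0)
  # non-events: subject 3 up, subject 4 unchanged -> -1/2
  expect_equal(r$nri_nonevents, -0.5)
  expect_equal(r$nri, -0.5)
})

test_that("nri print method reports the headline numbers", {
  r <- nri(c(0.2, 0.8), c(0.4, 0.6), c(1, 0))
  expect_output(print(r), "NRI = ")
  expect_output(print(r), "reclassified")
})

test_that("auroc_ci_width implements the Hanley-McNeil closed form", {
  # independent recomputation at n = 1000, prevalence 0.2, AUROC 0.75
  a <- 0.75; n1 <- 200; n2 <- 800
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
    (n1 * n2)
  expect_equal(auroc_ci_width(1000, 0.2, 0.75), 2 * 1.96 * sqrt(v),
               tolerance = 1e-12)
  # monotone: more subjects -> narrower interval
  w <- vapply(c(500, 2000, 8000), auroc_ci_width, numeric(1),
              prevalence = 0.2, auroc = 0.8)
  expect_true(all(diff(w) < 0))
  expect_error(auroc_ci_width(10, 0.01, 0.8), "degenerate")
})
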