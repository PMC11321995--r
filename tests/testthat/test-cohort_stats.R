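test_that("1-D 2-means separates well-separated PSI groups deterministically", {
  x <- c(s1 = 0.1, s2 = 0.1, s3 = 0.9, s4 = 0.9)
  st <- kmeans_stratify(x)
  expect_identical(unname(st$strata), c("low", "low", "high", "high"))
  expect_equal(unname(st$centres), c(0.1, 0.9))
  expect_error(kmeans_stratify(c(a = 0.5, b = 0.5), exon_id = "ex6"),
               "degenerate.*ex6")
})

test_that("1-D 2-means attains the exhaustive threshold-cut optimum", {
  set.seed(12)
  for (i in 1:20) {
    x <- setNames(runif(sample(5:40, 1)), NULL)
    names(x) <- paste0("s", seq_along(x))
    if (length(unique(x)) < 2) next
    st <- kmeans_stratify(x)
    expect_equal(st$withinss, threshold_cut_wss(x), tolerance = 1e-10)
  }
})

test_that("stratification is invariant to sample order and duplication", {
  x <- c(a = 0.15, b = 0.8, c = 0.25, d = 0.9, e = 0.2)
  s1 <- kmeans_stratify(x)
  s2 <- kmeans_stratify(rev(x))
  expect_identical(s1$strata[names(x)], s2$strata[names(x)])
  x2 <- c(x, setNames(x, paste0(names(x), "2")))
  s3 <- kmeans_stratify(x2)
  expect_identical(s3$strata[names(x)], s1$strata)
  expect_equal(unname(s3$centres), unname(s1$centres))
})

test_that("chi-squared association matches direct computation", {
  # perfect independence
  r1 <- chisq_association(rep(c("high", "low"), each = 20),
                          rep(c("g3", "g4"), times = 20))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
  # perfect association: all expected cells are 10, statistic 4 * 100/10
  strata <- rep(c("high", "low"), each = 20)
  subtype <- rep(c("g3", "g4"), each = 20)
  r2 <- chisq_association(strata, subtype)
  expect_equal(r2$statistic, 40)
  expect_true(all(r2$expected == 10))
  expect_error(chisq_association(rep("high", 10), rep(c("a", "b"), 5)),
               ">= 2 strata")
})

test_that("chi-squared p-values are calibrated under label permutation", {
  set.seed(31)
  strata <- rep(c("high", "low"), each = 30)
  ps <- replicate(400, {
    chisq_association(strata, sample(rep(c("a", "b"), 30)))$p_value
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(mean(ps < 0.1), 0.04)
  expect_lt(mean(ps < 0.1), 0.18)
})

test_that("log-rank of identical groups is exactly null", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(1, 8)
  strata <- rep(c("A", "B"), each = 4)
  lr <- km_logrank(times, events, strata)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank matches the risk-table enumeration oracle", {
  cases <- list(
    list(times = c(1, 2, 3, 4, 5, 6), events = rep(1, 6),
         strata = rep(c("A", "B"), each = 3)),
    list(times = c(2, 3, 3, 5, 8, 9, 10, 12), events = c(1, 1, 0, 1, 1, 0, 1, 1),
         strata = rep(c("A", "B"), each = 4)),
    list(times = c(1, 1, 4, 6, 2, 3, 7, 7, 9), events = c(1, 0, 1, 1, 1, 1, 0, 1, 1),
         strata = c(rep("A", 4), rep("B", 5))))
  for (cs in cases) {
    lr <- km_logrank(cs$times, cs$events, cs$strata)
    oracle <- logrank_enum(cs$times, cs$events, cs$strata)
    expect_equal(lr$statistic, oracle$statistic, tolerance = 1e-6)
    expect_equal(lr$observed[1], oracle$observed, tolerance = 1e-6)
    expect_equal(lr$expected[1], oracle$expected, tolerance = 1e-6)
  }
})

test_that("KM estimate equals the empirical survival function without censoring", {
  times <- c(1, 3, 3, 7, 9)
  lr <- km_logrank(c(times, 2, 4, 6, 8, 10), rep(1, 10),
                   rep(c("A", "B"), each = 5))
  ca <- lr$curves[lr$curves$stratum == "A", ]
  emp <- vapply(ca$time, function(t) mean(times > t), numeric(1))
  expect_equal(ca$survival, emp)
  expect_true(all(diff(ca$survival) <= 0))
})

test_that("a strong hazard contrast is detected in a synthetic cohort", {
  cfg <- synthetic_config(n_events = 20, n_samples_per_group = 100,
                          hazard_ratio = 3, seed = 41)
  co <- generate_cohort(cfg)
  md <- co$metadata
  strat <- co$truth$stratum_labels[md$sample_id]
  lr <- km_logrank(md$surv_time, md$surv_event, strat)
  expect_lt(lr$p_value, 0.05)
  expect_error(km_logrank(md$surv_time, md$surv_event, rep("A", nrow(md))),
               "exactly two strata")
})

test_that("expected overlap and hypergeometric tail behave exactly", {
  r <- hypergeom_overlap(100, 50, 1000, 20)
  expect_equal(r$expected, 5)
  expect_equal(hypergeom_overlap(10, 10, 10, 10)$p_value, 1)
  expect_equal(hypergeom_overlap(5, 5, 10, 5)$p_value, 1 / choose(10, 5))
  expect_error(hypergeom_overlap(5, 5, 10, 6), "exceeds")
  # p non-increasing in the observed overlap
  ps <- vapply(0:5, function(k) hypergeom_overlap(5, 5, 10, k)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("joint exon signatures combine per-exon strata", {
  s1 <- c(a = "high", b = "high", c = "low")
  s2 <- c(a = "low", b = "high", c = "low")
  sig <- combine_strata(s1, s2)
  expect_identical(unname(sig), c("signature", "other", "other"))
  expect_error(combine_strata(c(x = "high"), c(y = "low")), "in common")
})
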