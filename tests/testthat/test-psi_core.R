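test_that("PSI estimator follows the length-normalized inclusion ratio", {
  expect_identical(estimate_psi(0, 20, 2, 1), 0)
  expect_identical(estimate_psi(20, 0, 2, 1), 1)
  expect_equal(estimate_psi(10, 10, 2, 1), 1 / 3)
  expect_true(is.na(estimate_psi(0, 0, 2, 1)))
  expect_error(estimate_psi(-1, 2), "non-negative")
  expect_error(estimate_psi(1, 2, 0, 1), ">= 1")
})

test_that("PSI is invariant under joint scaling of the counts", {
  for (k in c(2, 10, 1000)) {
    expect_equal(estimate_psi(7 * k, 13 * k, 2, 1), estimate_psi(7, 13, 2, 1))
    expect_equal(estimate_psi(7 * k, 13 * k, 2, 2), estimate_psi(7, 13, 2, 2))
  }
})

test_that("psi_matrix marks zero-support cells as missing", {
  x <- tiny_counts(I = rbind(c(0L, 4L), c(6L, 0L), c(0L, 0L)),
                   S = rbind(c(0L, 4L), c(2L, 0L), c(0L, 9L)))
  pm <- psi_matrix(x)
  expect_true(is.na(pm$psi[1, "s1"]))
  expect_false(is.na(pm$psi[1, "s2"]))
  expect_identical(pm$support, x$I + x$S)
  expect_identical(is.na(pm$psi), pm$support == 0L)
})

test_that("expression calls use an inclusive 15-read threshold", {
  x <- tiny_counts(I = rbind(c(7L, 7L)), S = rbind(c(8L, 7L)))
  det <- call_expressed(x)
  expect_true(det[1, "s1"])    # 7 + 8 = 15, inclusive
  expect_false(det[1, "s2"])   # 14 < 15
  z <- tiny_counts(I = matrix(0L, 2, 2, dimnames = list(NULL, c("s1", "s2"))),
                   S = matrix(0L, 2, 2, dimnames = list(NULL, c("s1", "s2"))))
  expect_false(any(call_expressed(z)))
  expect_error(call_expressed(x, min_reads = 0), ">= 1")
})

test_that("identical groups give delta PSI 0 and p = 1", {
  co <- generate_cohort(synthetic_config(n_events = 50, n_samples_per_group = 2,
                                         seed = 5))
  counts <- co$counts
  # mirror group A's counts into group B
  counts$I[, 3:4] <- counts$I[, 1:2]
  counts$S[, 3:4] <- counts$S[, 1:2]
  rec <- diff_splice(counts, counts$samples[1:2], counts$samples[3:4])
  expect_true(all(abs(rec$delta_psi) < 1e-12, na.rm = TRUE))
  expect_true(all(rec$p_value == 1, na.rm = TRUE))
})

test_that("swapping group labels negates delta PSI and preserves p", {
  co <- generate_cohort(synthetic_config(n_events = 100, seed = 11))
  a <- co$metadata$sample_id[co$metadata$group == "control"]
  b <- co$metadata$sample_id[co$metadata$group == "knockdown"]
  r1 <- diff_splice(co$counts, a, b)
  r2 <- diff_splice(co$counts, b, a)
  expect_equal(r2$delta_psi, -r1$delta_psi)
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$fdr, r1$fdr)
})

test_that("the pooled LRT matches brute-force likelihood maximization (1 vs 1)", {
  set.seed(42)
  cases <- data.frame(ia = rpois(25, 60) + 1L, sa = rpois(25, 40) + 1L,
                      ib = rpois(25, 30) + 1L, sb = rpois(25, 70) + 1L)
  ev <- tiny_events(1, "SE")
  for (i in seq_len(nrow(cases))) {
    I <- matrix(c(cases$ia[i], cases$ib[i]), 1,
                dimnames = list(NULL, c("a", "b")))
    S <- matrix(c(cases$sa[i], cases$sb[i]), 1,
                dimnames = list(NULL, c("a", "b")))
    rec <- diff_splice(event_count_matrix(ev, I, S), "a", "b")
    oracle <- brute_lrt_1v1(cases$ia[i], cases$sa[i], cases$ib[i], cases$sb[i])
    expect_equal(rec$statistic, oracle, tolerance = 1e-4)
  }
})

test_that("beta-binomial model reduces to binomial with one sample per group", {
  ev <- tiny_events(1, "SE")
  I <- matrix(c(30L, 10L), 1, dimnames = list(NULL, c("a", "b")))
  S <- matrix(c(20L, 40L), 1, dimnames = list(NULL, c("a", "b")))
  x <- event_count_matrix(ev, I, S)
  r1 <- diff_splice(x, "a", "b", model = "binomial")
  r2 <- diff_splice(x, "a", "b", model = "betabinomial")
  expect_equal(r1$statistic, r2$statistic)
})

test_that("events without support are excluded from the FDR denominator", {
  x <- tiny_counts(I = rbind(c(30L, 2L), c(0L, 0L), c(10L, 9L)),
                   S = rbind(c(5L, 40L), c(0L, 0L), c(11L, 10L)))
  rec <- diff_splice(x, "s1", "s2")
  expect_true(is.na(rec$p_value[2]))
  expect_true(is.na(rec$fdr[2]))
  # BH over the two testable events only
  expect_equal(rec$fdr[!is.na(rec$fdr)],
               p.adjust(rec$p_value[!is.na(rec$p_value)], "BH"))
})

test_that("group overlap and unknown samples are validation errors", {
  x <- tiny_counts()
  expect_error(diff_splice(x, "s1", "s1"), "disjoint")
  expect_error(diff_splice(x, "s1", "nope"), "unknown sample")
  expect_error(diff_splice(x, character(0), "s2"), "non-empty")
})

test_that("the filter triple uses strict delta/FDR and the support flag", {
  rec <- data.frame(event_id = c("a", "b", "c", "d"),
                    event_type = "SE",
                    psi_a = c(0.5, 0.9, 0.6, 0.8),
                    psi_b = c(0.41, 0.4, 0.4, 0.4),
                    delta_psi = c(0.09, 0.5, 0.2, 0.4),
                    statistic = 10, p_value = c(0.001, 0.001, 0.01, 0.001),
                    fdr = c(0.001, 0.01, 0.04, 0.05),
                    supported = c(TRUE, FALSE, TRUE, TRUE))
  sig <- apply_significance_filters(rec)
  # a: |dPSI| = 0.09 <= 0.10; b: unsupported (14 reads); d: fdr not < 0.05
  expect_identical(sig$event_id, "c")
  expect_identical(sig$direction, "inclusion-up")
  expect_identical(unname(attr(sig, "funnel")["significant"]), 1L)
})

test_that("the significant set never grows as max_fdr decreases", {
  co <- generate_cohort(synthetic_config(n_events = 400, seed = 9))
  md <- co$metadata
  rec <- diff_splice(co$counts, md$sample_id[md$group == "knockdown"],
                     md$sample_id[md$group == "control"])
  prev <- NULL
  for (q in c(0.2, 0.1, 0.05, 0.01, 0.001)) {
    cur <- apply_significance_filters(rec, max_fdr = q)$event_id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
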