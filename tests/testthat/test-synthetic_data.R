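test_that("the generator is fully reproducible from its seed", {
  cfg <- synthetic_config(n_events = 40, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts$I, b$counts$I)
  expect_identical(a$counts$S, b$counts$S)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$true_psi, b$truth$true_psi)
  c <- generate_cohort(synthetic_config(n_events = 40, seed = 124))
  expect_false(identical(a$counts$I, c$counts$I))
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  invisible(generate_cohort(synthetic_config(n_events = 10, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_events = 0), ">= 1")
  expect_error(synthetic_config(depth_mean = 0), "> 0")
  expect_error(synthetic_config(overdispersion = 1), "\\[0,1\\)")
  expect_error(synthetic_config(planted_diff = list(fraction = 0.1, delta = 1.2)),
               "\\(0,1\\)")
  expect_error(synthetic_config(event_type_mix = c(SE = 0.5)), "summing to 1")
  expect_error(synthetic_config(motif_plant = list(pattern = "TGXATG",
                                                   region = "downstream_intron",
                                                   offset = 100)),
               "non-IUPAC")
})

test_that("with nothing planted, group PSI differences are binomial noise", {
  cfg <- synthetic_config(n_events = 1000,
                          planted_diff = list(fraction = 0, delta = 0.4),
                          planted_corr = list(fraction = 0, slope = 2),
                          seed = 21)
  co <- generate_cohort(cfg)
  md <- co$metadata
  a <- md$sample_id[md$group == "control"]
  b <- md$sample_id[md$group == "knockdown"]
  li <- co$counts$events$eff_len_inclusion
  ls <- co$counts$events$eff_len_skipping
  ia <- rowSums(co$counts$I[, a]); sa <- rowSums(co$counts$S[, a])
  ib <- rowSums(co$counts$I[, b]); sb <- rowSums(co$counts$S[, b])
  dpsi <- estimate_psi(ia, sa, li, ls) - estimate_psi(ib, sb, li, ls)
  # delta-method standard error of the pooled delta-PSI estimate
  p <- (ia + ib) / (ia + sa + ib + sb)
  dfdp <- (1 / (li * ls)) / (p / li + (1 - p) / ls)^2
  se <- abs(dfdp) * sqrt(p * (1 - p) * (1 / (ia + sa) + 1 / (ib + sb)))
  expect_gt(mean(abs(dpsi) < 3 * se), 0.95)
})

test_that("planted delta PSI is recovered with small error across seeds", {
  errs <- unlist(lapply(1:20, function(i) {
    cfg <- synthetic_config(n_events = 1000, seed = 500 + i)
    co <- generate_cohort(cfg)
    md <- co$metadata
    a <- md$sample_id[md$group == "knockdown"]
    b <- md$sample_id[md$group == "control"]
    rec <- diff_splice(co$counts, a, b)
    truth <- co$truth$true_delta
    est <- rec$delta_psi[match(names(truth), rec$event_id)]
    abs(est - truth)
  }))
  expect_lt(mean(errs), 0.1)
})

test_that("the count link is the exact inverse of the PSI estimator", {
  # analytically: with I = n*p and S = n*(1-p) for p = psi*lI/(psi*lI+(1-psi)*lS),
  # estimate_psi returns exactly psi, for every event geometry
  for (ty in c("SE", "MXE", "RI", "A3SS", "A5SS")) {
    el <- effective_lengths(ty)
    li <- el$eff_len_inclusion; ls <- el$eff_len_skipping
    for (psi in c(0, 0.1, 1 / 3, 0.5, 0.9, 1)) {
      p <- (psi * li) / (psi * li + (1 - psi) * ls)
      n <- 1e6
      expect_equal(estimate_psi(n * p, n * (1 - p), li, ls), psi)
    }
  }
})

test_that("the PSI estimator converges to truth at high depth", {
  res <- psi_consistency_error(depth_mean = 1e5, n_events = 300, seed = 2)
  expect_lt(res$max_abs_error, 0.01)
})

test_that("flank sequences carry the motif exactly at the planted offset", {
  cfg <- synthetic_config(n_events = 30, seed = 8)
  co <- generate_cohort(cfg)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  planted <- names(co$truth$motif_offsets)
  expect_gt(length(planted), 0)
  for (id in planted) {
    s <- fl[[id]][["downstream_intron"]]
    expect_identical(substr(s, 100, 105), "TGCATG")
  }
  # unplanted background and planted sequences share region lengths
  lay <- region_layout()
  for (id in names(fl))
    expect_identical(unname(nchar(fl[[id]])),
                     unname(lay$regions[names(fl[[id]])]))
})

test_that("with nothing planted no offsets are recorded and planting is skipped", {
  cfg <- synthetic_config(n_events = 20,
                          planted_diff = list(fraction = 0, delta = 0.4),
                          seed = 8)
  co <- generate_cohort(cfg)
  expect_length(co$truth$motif_offsets, 0)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  expect_length(fl, 20)
})

test_that("planted motif density exceeds background at the planted offset", {
  cfg <- synthetic_config(n_events = 600, seed = 31)
  co <- generate_cohort(cfg)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  prof <- motif_score_profile(fl, motif_spec("RBFOX", "TGCATG"))
  pos <- attr(prof, "positions")
  at <- which(pos$region == "downstream_intron" & pos$pos == 100)
  planted <- names(co$truth$motif_offsets)
  bg <- setdiff(names(fl), co$truth$diff_event_ids)
  expect_gt(mean(prof[planted, at]), median(prof[bg, at]))
})

test_that("FASTA round trip preserves flank sequences and region labels", {
  cfg <- synthetic_config(n_events = 6, seed = 4)
  co <- generate_cohort(cfg)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_flanks_fasta(fl, path)
  rd <- read_flanks_fasta(path)
  expect_identical(names(rd), names(fl))
  for (id in names(fl)) expect_identical(rd[[id]], fl[[id]])
})

test_that("reference cohort plants subtype-specific deviation sets", {
  cfg <- synthetic_config(n_events = 200, seed = 17)
  ref <- generate_reference_cohort(cfg, c(still = 0L, near = 10L, far = 100L),
                                   n_tumours_per_subtype = 3)
  tr <- ref$truth
  md <- ref$metadata
  expect_identical(sum(md$group == "reference"), 4L)
  for (s in md$sample_id[md$group == "still"]) {
    expect_length(tr$deviating_events[[s]], 0)
    expect_equal(unname(tr$true_psi[, s]), unname(tr$base_psi))
  }
  for (s in md$sample_id[md$group == "near"])
    expect_length(tr$deviating_events[[s]], 10)
  for (s in md$sample_id[md$group == "far"])
    expect_length(tr$deviating_events[[s]], 100)
  expect_true(all(tr$true_psi >= 0 & tr$true_psi <= 1))
  expect_error(generate_reference_cohort(cfg, c(a = 5L, b = 10L),
                                         n_reference = 1),
               "reference samples")
  expect_error(generate_reference_cohort(cfg, c(a = 5L)), "two named subtypes")
})
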