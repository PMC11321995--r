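# build a flank set from explicit per-region sequences
manual_flanks <- function(...) {
  structure(list(...), class = "flank_sequences")
}

blank_regions <- function(layout = region_layout(), base = "A") {
  vapply(layout$regions, function(L) strrep(base, L), character(1))
}

test_that("a motif absent from the sequence scores zero density everywhere", {
  fl <- manual_flanks(e1 = blank_regions())
  prof <- motif_score_profile(fl, motif_spec("RBFOX", "TGCATG"))
  expect_identical(dim(prof), c(1L, 700L))
  expect_true(all(prof == 0))
})

test_that("a single planted match reproduces the brute-force window density", {
  lay <- region_layout()
  regs <- blank_regions(lay)
  s <- regs[["downstream_intron"]]
  substr(s, 100, 105) <- "TGCATG"
  regs[["downstream_intron"]] <- s
  fl <- manual_flanks(ev = regs)
  prof <- motif_score_profile(fl, motif_spec("RBFOX", "TGCATG"), lay)
  pos <- attr(prof, "positions")
  di <- pos$region == "downstream_intron"
  oracle <- window_density_enum(100, L = 250, w = 50)
  expect_equal(unname(prof[1, di]), oracle)
  # all other regions stay at zero
  expect_true(all(prof[1, !di] == 0))
  # sanity on the oracle itself: windows overlapping position 100 score 1/50
  expect_equal(oracle[100], 1 / 50)
  expect_equal(oracle[60], 0)
})

test_that("matching is case-insensitive and treats U as T", {
  lay <- region_layout()
  regs <- blank_regions(lay)
  s <- regs[["upstream_intron"]]
  substr(s, 30, 35) <- "tgcatg"
  regs[["upstream_intron"]] <- s
  fl <- manual_flanks(ev = regs)
  p1 <- motif_score_profile(fl, motif_spec("m", "TGCATG"), lay)
  p2 <- motif_score_profile(fl, motif_spec("m", "UGCAUG"), lay)
  expect_identical(p1[1, ], p2[1, ])
  expect_gt(max(p1), 0)
})

test_that("overlapping degenerate matches all count", {
  lay <- region_layout()
  regs <- blank_regions(lay)
  s <- regs[["downstream_intron"]]
  substr(s, 101, 110) <- "TTTTTTTTTT"   # poly-U run
  regs[["downstream_intron"]] <- s
  fl <- manual_flanks(ev = regs)
  prof <- motif_score_profile(fl, motif_spec("HNRNPC", "UUUUU"), lay)
  pos <- attr(prof, "positions")
  at <- which(pos$region == "downstream_intron" & pos$pos == 105)
  expect_equal(unname(prof[1, at]), 6 / 50)  # 6 start sites of a 5-mer in a 10-run
})

test_that("motifs longer than the window are rejected", {
  fl <- manual_flanks(e1 = blank_regions())
  expect_error(motif_score_profile(fl, motif_spec("m", strrep("A", 51))),
               "longer than the scanning window")
})

test_that("identical target and background sets give p = 1 everywhere", {
  cfg <- synthetic_config(n_events = 20, seed = 6)
  co <- generate_cohort(cfg)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  prof <- motif_score_profile(fl, motif_spec("RBFOX", "TGCATG"))
  ids <- names(fl)
  map <- compare_profiles(prof, up_ids = character(0), down_ids = ids,
                          bg_ids = ids)
  expect_true(all(map$p_down == 1))
  expect_true(all(is.na(map$p_up)))
  expect_equal(map$mean_down, map$mean_bg)
})

test_that("maps depend on set membership, not event order or duplication", {
  cfg <- synthetic_config(n_events = 60, seed = 13)
  co <- generate_cohort(cfg)
  fl <- generate_flank_sequences(co$counts, co$truth, cfg)
  prof <- motif_score_profile(fl, motif_spec("RBFOX", "TGCATG"))
  ids <- names(fl)
  tg <- ids[1:10]; bg <- ids[11:60]
  m1 <- compare_profiles(prof, character(0), tg, bg)
  m2 <- compare_profiles(prof, character(0), rev(tg), sample(bg))
  expect_equal(m1$mean_down, m2$mean_down)
  expect_equal(m1$p_down, m2$p_down)
  # duplicating every background event leaves the mean curve unchanged
  prof2 <- rbind(prof, prof[bg, ])
  rownames(prof2) <- c(rownames(prof), paste0(bg, "_dup"))
  attr(prof2, "positions") <- attr(prof, "positions")
  m3 <- compare_profiles(prof2, character(0), tg,
                         c(bg, paste0(bg, "_dup")))
  expect_equal(m3$mean_bg, m1$mean_bg)
})

test_that("missing regions yield NA densities that means exclude", {
  lay <- region_layout()
  full <- blank_regions(lay)
  partial <- full[names(full) != "downstream_intron"]
  fl <- manual_flanks(a = full, b = partial)
  prof <- motif_score_profile(fl, motif_spec("m", "TGCATG"), lay)
  pos <- attr(prof, "positions")
  di <- pos$region == "downstream_intron"
  expect_true(all(is.na(prof["b", di])))
  expect_true(all(!is.na(prof["a", di])))
  map <- compare_profiles(prof, character(0), "b", "a")
  expect_true(all(is.na(map$mean_down[di]) | map$mean_down[di] == 0))
})

test_that("the enrichment peak localizes to the planted downstream motif", {
  res <- sim_rna_map_localization(n_seeds = 1, n_events = 400, n_bg = 200,
                                  base_seed = 2)
  expect_identical(res$hits, 1L)
})
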