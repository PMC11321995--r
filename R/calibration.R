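# Simulation-based calibration experiments. Each function runs one of the
# package's validation studies on freshly generated synthetic cohorts and
# returns the measured operating characteristic; the tests and the analysis
# scripts consume these directly. All randomness flows from `base_seed`.

#' Type-I error of the differential-splicing test under the null
#'
#' Generates knockdown cohorts with no planted structure (binomial counts,
#' no group difference, no regulator link) and measures the fraction of raw
#' LRT p-values below `alpha`.
#'
#' @param n_seeds Number of replicate cohorts (default 20).
#' @param n_events,depth_mean,n_per_group Cohort dimensions
#'   (defaults 1000 / 100 / 3).
#' @param alpha Nominal level (default 0.05).
#' @param base_seed Seed of the first replicate; replicate i uses
#'   `base_seed + i - 1`.
#' @return List: `rate` (observed fraction), `n` (p-values pooled).
#' @export
sim_type1_error <- function(n_seeds = 20L, n_events = 1000L,
                            depth_mean = 100, n_per_group = 3L,
                            alpha = 0.05, base_seed = 1L) {
  ps <- unlist(lapply(seq_len(n_seeds), function(i) {
    cfg <- synthetic_config(n_events = n_events,
                            n_samples_per_group = n_per_group,
                            depth_mean = depth_mean,
                            planted_diff = list(fraction = 0, delta = 0.4),
                            planted_corr = list(fraction = 0, slope = 2),
                            overdispersion = 0,
                            seed = stage_seed(base_seed, i))
    co <- generate_cohort(cfg)
    md <- co$metadata
    rec <- diff_splice(co$counts, md$sample_id[md$group == "knockdown"],
                       md$sample_id[md$group == "control"])
    rec$p_value
  }))
  ps <- ps[!is.na(ps)]
  list(rate = mean(ps < alpha), n = length(ps))
}

#' Power of the filter triple on planted differential events
#'
#' Plants |delta PSI| = `delta` at `fraction` of events and measures the
#' fraction of planted events that pass the full significance filter triple
#' (|delta PSI| > `min_delta`, read support, FDR < `max_fdr`) with the
#' correct direction of change.
#'
#' @inheritParams sim_type1_error
#' @param fraction,delta Planted fraction and |delta PSI|
#'   (defaults 0.1 / 0.4).
#' @param min_delta,min_reads,max_fdr Filter thresholds.
#' @return List: `rate` (recovered fraction), `n` (planted events pooled).
#' @export
sim_power_recovery <- function(n_seeds = 20L, n_events = 1000L,
                               depth_mean = 100, n_per_group = 3L,
                               fraction = 0.1, delta = 0.4,
                               min_delta = 0.10, min_reads = 15L,
                               max_fdr = 0.05, base_seed = 1L) {
  hits <- total <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_events = n_events,
                            n_samples_per_group = n_per_group,
                            depth_mean = depth_mean,
                            planted_diff = list(fraction = fraction,
                                                delta = delta),
                            planted_corr = list(fraction = 0, slope = 2),
                            seed = stage_seed(base_seed, 100L + i))
    co <- generate_cohort(cfg)
    md <- co$metadata
    rec <- diff_splice(co$counts, md$sample_id[md$group == "knockdown"],
                       md$sample_id[md$group == "control"],
                       min_reads = min_reads)
    sig <- apply_significance_filters(rec, min_delta = min_delta,
                                      max_fdr = max_fdr)
    truth <- co$truth$true_delta
    found <- sig[sig$event_id %in% names(truth), ]
    ok <- sign(found$delta_psi) == sign(truth[found$event_id])
    hits <- hits + sum(ok)
    total <- total + length(truth)
  }
  list(rate = hits / total, n = total)
}

#' Recovery and false-positive rate of the regulator-correlation screen
#'
#' Generates cohorts where a planted exon subset follows a logistic link to
#' the regulator covariate, applies the cohort detection filters, runs the
#' screen, and measures the fraction of planted exons called significant
#' (adjusted p < `adj_p_max`) and the fraction of null exons falsely called.
#'
#' @inheritParams sim_type1_error
#' @param n_samples Cohort size (default 200).
#' @param fraction,slope Planted fraction and logistic slope
#'   (defaults 0.1 / 2).
#' @param adj_p_max Screen significance cut-off (default 0.01).
#' @return List: `recovery`, `fpr`, `n_planted`, `n_null`.
#' @export
sim_correlation_recovery <- function(n_seeds = 10L, n_events = 1000L,
                                     n_samples = 200L, depth_mean = 100,
                                     fraction = 0.1, slope = 2,
                                     adj_p_max = 0.01, base_seed = 1L) {
  rec_hit <- rec_tot <- fp <- null_tot <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_events = n_events,
                            n_samples_per_group = as.integer(n_samples / 2),
                            depth_mean = depth_mean,
                            planted_diff = list(fraction = 0, delta = 0.4),
                            planted_corr = list(fraction = fraction,
                                                slope = slope),
                            seed = stage_seed(base_seed, 200L + i))
    co <- generate_cohort(cfg)
    det <- call_expressed(co$counts)
    flt <- filter_cohort(det)
    pm <- psi_matrix(subset_events(co$counts, events = flt$events,
                                   samples = flt$samples))
    sc <- correlate_exons(pm, co$metadata, adj_p_max = adj_p_max)
    planted <- co$truth$corr_event_ids
    rec_hit <- rec_hit + sum(sc$significant & sc$event_id %in% planted)
    rec_tot <- rec_tot + length(planted)
    is_null <- !(sc$event_id %in% planted) & !sc$untestable
    fp <- fp + sum(sc$significant & is_null)
    null_tot <- null_tot + sum(is_null)
  }
  list(recovery = rec_hit / rec_tot, fpr = fp / null_tot,
       n_planted = rec_tot, n_null = null_tot)
}

#' Localization of the RNA-map enrichment peak at a planted motif
#'
#' Per replicate cohort, plants the configured motif in the downstream
#' introns of the inclusion-down differential events, builds the RNA map of
#' those events against a background of unregulated events, and checks
#' whether the position of maximum -log10 p falls within half a window of
#' the planted offset inside the planted region.
#'
#' @inheritParams sim_type1_error
#' @param n_bg Background events per replicate (default 500).
#' @return List: `hits`, `n_seeds`, `rate`.
#' @export
sim_rna_map_localization <- function(n_seeds = 10L, n_events = 1000L,
                                     n_bg = 500L, base_seed = 1L) {
  layout <- region_layout()
  hits <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_events = n_events,
                            seed = stage_seed(base_seed, 300L + i))
    co <- generate_cohort(cfg)
    truth <- co$truth
    down <- names(truth$motif_offsets)
    bg <- sample(setdiff(co$counts$events$event_id, truth$diff_event_ids),
                 n_bg)
    ev_sub <- co$counts$events[co$counts$events$event_id %in% c(down, bg), ]
    flanks <- generate_flank_sequences(ev_sub, truth, cfg, layout)
    prof <- motif_score_profile(flanks,
                                motif_spec("planted",
                                           cfg$motif_plant$pattern),
                                layout)
    map <- compare_profiles(prof, up_ids = character(0), down_ids = down,
                            bg_ids = bg)
    peak <- map_peak(map, "down")
    if (peak$region == cfg$motif_plant$region &&
        abs(peak$pos - cfg$motif_plant$offset) <= layout$window / 2)
      hits <- hits + 1L
  }
  list(hits = hits, n_seeds = n_seeds, rate = hits / n_seeds)
}

#' Ordering of subtype divergence medians by planted distance
#'
#' Per replicate, generates a reference cohort with subtypes at graded
#' splicing distances from the reference, scores every tumour's divergence,
#' and checks that the subtype ranking matches the planted distance order.
#'
#' @inheritParams sim_type1_error
#' @param distances Named per-tumour deviating-event counts
#'   (default near = 0, mid = 30, far = 100).
#' @param depth_mean Junction depth (default 100).
#' @return List: `hits`, `n_seeds`, `rate`.
#' @export
sim_divergence_ordering <- function(n_seeds = 10L, n_events = 1000L,
                                    depth_mean = 100,
                                    distances = c(near = 0L, mid = 30L,
                                                  far = 100L),
                                    base_seed = 1L) {
  expected <- names(distances)[order(distances, names(distances))]
  hits <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_events = n_events, depth_mean = depth_mean,
                            seed = stage_seed(base_seed, 400L + i))
    ref <- generate_reference_cohort(cfg, distances)
    prof <- divergence_profile(ref$counts, ref$metadata)
    if (identical(rank_subtypes(prof), expected)) hits <- hits + 1L
  }
  list(hits = hits, n_seeds = n_seeds, rate = hits / n_seeds)
}

#' Consistency of the PSI estimator at high depth
#'
#' Generates one cohort at very high junction depth across all five event
#' types and returns the maximum absolute difference between estimated and
#' true PSI over every event x sample cell.
#'
#' @param depth_mean Mean junction depth (default 1e5).
#' @param n_events Events (default 500, mixed across all five types).
#' @param seed Seed.
#' @return List: `max_abs_error`, `n` (cells).
#' @export
psi_consistency_error <- function(depth_mean = 1e5, n_events = 500L,
                                  seed = 1L) {
  cfg <- synthetic_config(n_events = n_events, depth_mean = depth_mean,
                          event_type_mix = c(SE = 0.2, MXE = 0.2, RI = 0.2,
                                             A3SS = 0.2, A5SS = 0.2),
                          planted_diff = list(fraction = 0, delta = 0.4),
                          planted_corr = list(fraction = 0, slope = 2),
                          seed = seed)
  co <- generate_cohort(cfg)
  pm <- psi_matrix(co$counts)
  err <- abs(pm$psi - co$truth$true_psi)
  list(max_abs_error = max(err, na.rm = TRUE), n = sum(!is.na(err)))
}
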