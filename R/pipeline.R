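PIPELINE_STAGES <- c("simulate", "diff", "correlate", "rnamap", "diverge",
                     "stratify")
STAGE_DEPS <- list(simulate = character(0),
                   diff = "simulate",
                   correlate = "simulate",
                   rnamap = "diff",
                   diverge = "diff",
                   stratify = "simulate")

#' Configuration of a full pipeline run
#'
#' Bundles the synthetic-cohort configuration, the stage toggles, the
#' significance thresholds and the output directory. One seed drives every
#' stochastic stage (sub-seeds are derived deterministically from it), so a
#' rerun with an identical config is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param synthetic A [synthetic_config()] for the knockdown cohort; its
#'   seed is overridden by `seed`.
#' @param stages Stages to run, a subset of
#'   `simulate, diff, correlate, rnamap, diverge, stratify`.
#' @param min_delta,min_reads,max_fdr Differential-splicing filter triple
#'   (defaults 0.10 / 15 / 0.05).
#' @param corr_adj_p Correlation-screen adjusted-p cut-off (default 0.01).
#' @param n_tumour_samples Size of the tumour cohort used by the
#'   correlation and stratification stages (default 60).
#' @param subtype_distances Named vector of per-tumour deviating-event
#'   counts for the divergence stage's reference cohort.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       synthetic = synthetic_config(),
                       stages = PIPELINE_STAGES,
                       min_delta = 0.10, min_reads = 15L, max_fdr = 0.05,
                       corr_adj_p = 0.01,
                       n_tumour_samples = 60L,
                       subtype_distances = c(gamma = 10L, alpha = 60L,
                                             beta = 120L)) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (v in c(min_delta, max_fdr, corr_adj_p))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0,1)", call. = FALSE)
  if (min_reads < 1) stop("'min_reads' must be >= 1", call. = FALSE)
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, stages = stages,
                 min_delta = min_delta, min_reads = as.integer(min_reads),
                 max_fdr = max_fdr, corr_adj_p = corr_adj_p,
                 n_tumour_samples = as.integer(n_tumour_samples),
                 subtype_distances = subtype_distances),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The schema is versioned (`schema_version: 1`); unknown keys are errors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != 1)
    stop("config must declare schema_version: 1", call. = FALSE)
  known <- c("schema_version", "out_dir", "seed", "stages", "min_delta",
             "min_reads", "max_fdr", "corr_adj_p", "n_tumour_samples",
             "subtype_distances", "synthetic")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  syn <- if (is.null(y$synthetic)) synthetic_config()
         else do.call(synthetic_config, y$synthetic)
  args <- y[setdiff(names(y), c("schema_version", "synthetic"))]
  if (!is.null(args$subtype_distances))
    args$subtype_distances <- unlist(args$subtype_distances)
  do.call(run_config, c(args, list(synthetic = syn)))
}

.write_stage_tsv <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full splicing-analysis pipeline on synthetic cohorts
#'
#' Executes the enabled stages in dependency order
#' (simulate -> diff -> correlate / rnamap / diverge / stratify), writing
#' each stage's table under `config$out_dir` with a provenance header
#' (seed + config hash) and a closing `manifest.json` listing every
#' artifact with its md5 checksum plus the filter funnel counts. Disabling
#' a stage that a later enabled stage depends on is a dependency error.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  for (st in stages) {
    need <- setdiff(STAGE_DEPS[[st]], stages)
    if (length(need))
      stop("stage '", st, "' requires disabled stage '", need[1], "'",
           call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  cfg_json <- out("run_config.json")
  cfg_plain <- unclass(config)
  cfg_plain$synthetic <- unclass(cfg_plain$synthetic)
  cfg_plain$out_dir <- NULL   # hash the scientific config, not the path
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  seed <- config$seed
  files <- c("run_config.json")
  funnel <- list()

  kd <- tumour <- NULL
  diff_rec <- sig <- NULL

  if ("simulate" %in% stages) {
    kd <- generate_cohort(config$synthetic)
    write_event_table(kd$counts, out("knockdown_counts.tsv"),
                      header = sprintf("seed=%d config=%s", seed, cfg_hash))
    write_metadata(kd$metadata, out("knockdown_metadata.tsv"))
    write_truth_json(kd$truth, out("knockdown_truth.json"))

    tum_cfg <- config$synthetic
    tum_cfg$n_samples_per_group <- as.integer(config$n_tumour_samples / 2)
    tum_cfg$seed <- stage_seed(seed, 2L)
    tumour <- generate_cohort(tum_cfg)
    write_event_table(tumour$counts, out("tumour_counts.tsv"),
                      header = sprintf("seed=%d config=%s", seed, cfg_hash))
    write_metadata(tumour$metadata, out("tumour_metadata.tsv"))
    files <- c(files, "knockdown_counts.tsv", "knockdown_metadata.tsv",
               "knockdown_truth.json", "tumour_counts.tsv",
               "tumour_metadata.tsv")
  }

  if ("diff" %in% stages) {
    md <- kd$metadata
    diff_rec <- diff_splice(kd$counts,
                            md$sample_id[md$group == "knockdown"],
                            md$sample_id[md$group == "control"],
                            min_reads = config$min_reads)
    sig <- apply_significance_filters(diff_rec, min_delta = config$min_delta,
                                      max_fdr = config$max_fdr)
    .write_stage_tsv(diff_rec, out("diff_splice.tsv"), seed, cfg_hash)
    .write_stage_tsv(sig, out("diff_significant.tsv"), seed, cfg_hash)
    funnel$diff <- as.list(attr(sig, "funnel"))
    files <- c(files, "diff_splice.tsv", "diff_significant.tsv")
  }

  if ("correlate" %in% stages) {
    det <- call_expressed(tumour$counts, min_reads = config$min_reads)
    flt <- filter_cohort(det)
    pm <- psi_matrix(subset_events(tumour$counts, events = flt$events,
                                   samples = flt$samples))
    cs <- correlate_exons(pm, tumour$metadata, adj_p_max = config$corr_adj_p)
    .write_stage_tsv(cs, out("correlation_screen.tsv"), seed, cfg_hash)
    funnel$correlate <- list(events_in = nrow(det),
                             events_kept = length(flt$events),
                             samples_kept = length(flt$samples),
                             significant = sum(cs$significant))
    files <- c(files, "correlation_screen.tsv")
  }

  if ("rnamap" %in% stages) {
    flanks <- generate_flank_sequences(kd$counts, kd$truth, config$synthetic)
    write_flanks_fasta(flanks, out("flanks.fasta"))
    prof <- motif_score_profile(flanks,
                                motif_spec("planted",
                                           config$synthetic$motif_plant$pattern))
    bg_ids <- setdiff(kd$counts$events$event_id, kd$truth$diff_event_ids)
    map <- compare_profiles(prof,
                            up_ids = sig$event_id[sig$direction == "inclusion-up"],
                            down_ids = sig$event_id[sig$direction == "inclusion-down"],
                            bg_ids = bg_ids)
    .write_stage_tsv(as.data.frame(map), out("rna_map.tsv"), seed, cfg_hash)
    files <- c(files, "flanks.fasta", "rna_map.tsv")
  }

  if ("diverge" %in% stages) {
    ref_cfg <- config$synthetic
    ref_cfg$seed <- stage_seed(seed, 3L)
    ref <- generate_reference_cohort(ref_cfg, config$subtype_distances)
    prof <- divergence_profile(ref$counts, ref$metadata,
                               min_delta = config$min_delta,
                               min_reads = config$min_reads,
                               max_fdr = config$max_fdr)
    .write_stage_tsv(prof, out("divergence_profile.tsv"), seed, cfg_hash)
    med <- attr(prof, "subtype_medians")
    .write_stage_tsv(data.frame(subtype = names(med),
                                median_score = as.numeric(med)),
                     out("divergence_subtypes.tsv"), seed, cfg_hash)
    funnel$diverge <- list(shared_exons = length(attr(prof, "shared")),
                           outliers = sum(prof$outlier))
    files <- c(files, "divergence_profile.tsv", "divergence_subtypes.tsv")
  }

  if ("stratify" %in% stages) {
    pm <- psi_matrix(tumour$counts)
    ex <- tumour$truth$signature_event
    strat <- kmeans_stratify(pm$psi[ex, ], exon_id = ex)
    md <- tumour$metadata
    chisq <- chisq_association(strat$strata[md$sample_id], md$group)
    lr <- km_logrank(md$surv_time, md$surv_event,
                     strat$strata[md$sample_id])
    .write_stage_tsv(data.frame(sample_id = names(strat$strata),
                                stratum = unname(strat$strata)),
                     out("stratification.tsv"), seed, cfg_hash)
    .write_stage_tsv(lr$curves, out("km_curves.tsv"), seed, cfg_hash)
    jsonlite::write_json(list(exon = ex,
                              centres = strat$centres,
                              chisq_statistic = chisq$statistic,
                              chisq_p = chisq$p_value,
                              logrank_statistic = lr$statistic,
                              logrank_p = lr$p_value),
                         out("stratification_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "stratification.tsv", "km_curves.tsv",
               "stratification_summary.json")
  }

  manifest <- list(seed = seed, config_hash = cfg_hash, stages = stages,
                   funnel = funnel,
                   artifacts = lapply(files, function(f)
                     list(file = f,
                          md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
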