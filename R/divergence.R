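#' Drop samples with outlying numbers of expressed events
#'
#' Box-plot whisker rule on per-sample detected-event counts: with quartiles
#' Q1 and Q3 computed by linear interpolation between order statistics
#' (`stats::quantile` type 7) and IQR = Q3 - Q1, a sample is an outlier when
#' its count lies outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\].
#'
#' @param detected_counts Named numeric vector: sample -> number of
#'   expressed events. At least 4 samples (quartiles are unstable below).
#' @return Character vector of kept sample ids (original order).
#' @export
remove_outlier_samples <- function(detected_counts) {
  if (length(detected_counts) < 4)
    stop("at least 4 samples are required for the whisker rule", call. = FALSE)
  if (is.null(names(detected_counts)))
    stop("'detected_counts' must be named by sample", call. = FALSE)
  q <- stats::quantile(detected_counts, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  names(detected_counts)[detected_counts >= lo & detected_counts <= hi]
}

#' Minimal set of events expressed across all samples
#'
#' Intersection of the per-sample expressed-event sets: the events detected
#' in every kept sample, making downstream per-sample significance counts
#' comparable regardless of coverage.
#'
#' @param detection Logical events x samples matrix (kept samples only).
#' @return Character vector of event ids (possibly empty, with a warning).
#' @export
minimal_shared_exons <- function(detection) {
  detection <- as.matrix(detection)
  if (!ncol(detection)) stop("no samples in detection matrix", call. = FALSE)
  shared <- rownames(detection)[rowSums(detection) == ncol(detection)]
  if (!length(shared))
    warning("no events are expressed across all samples", call. = FALSE)
  shared
}

#' Splicing divergence of one tumour from a pooled reference
#'
#' Runs the differential-splicing test with the single tumour as group A and
#' the pooled reference samples as group B, restricted to the shared event
#' set, applies the significance filter triple, and returns the number of
#' significantly spliced events. `NA` when no shared event is supported.
#'
#' @param counts An `event_counts` object.
#' @param tumour One sample id (not in `reference`).
#' @param reference Character vector of reference sample ids.
#' @param shared Event ids to restrict to (from [minimal_shared_exons()]).
#' @param min_delta,min_reads,max_fdr Filter thresholds
#'   (defaults 0.10 / 15 / 0.05).
#' @param model LRT model, see [diff_splice()].
#' @return Non-negative integer count, or `NA`.
#' @export
divergence_score <- function(counts, tumour, reference, shared,
                             min_delta = 0.10, min_reads = 15L,
                             max_fdr = 0.05, model = "binomial") {
  if (tumour %in% reference)
    stop("tumour must not be part of the reference", call. = FALSE)
  if (!length(shared)) return(NA_integer_)
  sub <- subset_events(counts, events = shared)
  rec <- diff_splice(sub, tumour, reference, model = model,
                     min_reads = min_reads)
  if (!any(rec$supported)) return(NA_integer_)
  nrow(apply_significance_filters(rec, min_delta = min_delta,
                                  max_fdr = max_fdr))
}

#' Per-tumour divergence profile against a developmental reference
#'
#' The full reference-comparison procedure: (1) call expressed events
#' (>= `min_reads` reads); (2) flag and drop tumours with outlying numbers
#' of expressed events (whisker rule, tumours only — the pooled reference is
#' always retained); (3) intersect the kept tumours' expressed-event lists
#' into the minimal shared set; (4) score every kept tumour by its number of
#' significant events versus the pooled reference.
#'
#' @param counts An `event_counts` object containing reference and tumour
#'   samples.
#' @param metadata Metadata data.frame (`sample_id`, `group`); rows with
#'   `group == reference_group` form the pooled reference, all other groups
#'   are tumour subtypes.
#' @param reference_group Label of the reference samples
#'   (default `"reference"`).
#' @param min_delta,min_reads,max_fdr Filter thresholds.
#' @param model LRT model.
#' @return data.frame of class `divergence_profile`: `sample_id, subtype,
#'   n_detected, outlier, score`; subtype medians in
#'   `attr(, "subtype_medians")`, the shared set in `attr(, "shared")`.
#' @export
divergence_profile <- function(counts, metadata,
                               reference_group = "reference",
                               min_delta = 0.10, min_reads = 15L,
                               max_fdr = 0.05, model = "binomial") {
  stopifnot(inherits(counts, "event_counts"))
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must have 'sample_id' and 'group'", call. = FALSE)
  ref <- metadata$sample_id[metadata$group == reference_group]
  if (length(ref) < 2) stop("need >= 2 reference samples", call. = FALSE)
  tum <- metadata$sample_id[metadata$group != reference_group]
  if (!length(tum)) stop("no tumour samples", call. = FALSE)

  det <- call_expressed(counts, min_reads = min_reads)
  n_det <- colSums(det[, tum, drop = FALSE])
  kept <- remove_outlier_samples(n_det)
  shared <- minimal_shared_exons(det[, kept, drop = FALSE])

  score <- rep(NA_integer_, length(tum))
  names(score) <- tum
  for (s in kept)
    score[s] <- divergence_score(counts, s, ref, shared,
                                 min_delta = min_delta,
                                 min_reads = min_reads, max_fdr = max_fdr,
                                 model = model)
  subtype <- metadata$group[match(tum, metadata$sample_id)]
  out <- data.frame(sample_id = tum, subtype = subtype,
                    n_detected = as.integer(n_det),
                    outlier = !(tum %in% kept),
                    score = as.integer(score),
                    stringsAsFactors = FALSE)
  med <- tapply(out$score[!out$outlier], out$subtype[!out$outlier],
                stats::median, na.rm = TRUE)
  class(out) <- c("divergence_profile", "data.frame")
  attr(out, "subtype_medians") <- med
  attr(out, "shared") <- shared
  out
}

#' Order subtypes by median divergence from the reference
#'
#' Ascending median score (least divergent, i.e. closest to the reference,
#' first); ties broken alphabetically. Subtypes with no scored sample are
#' omitted with a warning.
#'
#' @param profile A `divergence_profile`.
#' @return Character vector of subtype names.
#' @export
rank_subtypes <- function(profile) {
  stopifnot(inherits(profile, "divergence_profile"))
  ok <- !profile$outlier & !is.na(profile$score)
  if (!any(ok)) stop("no scored samples", call. = FALSE)
  med <- tapply(profile$score[ok], profile$subtype[ok], stats::median)
  all_st <- unique(profile$subtype)
  missing <- setdiff(all_st, names(med))
  if (length(missing))
    warning("subtype(s) with no scored samples omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  names(med)[order(unname(med), names(med))]
}
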