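#' Cohort-level detection filters for the correlation screen
#'
#' Applies the two cohort filters in a fixed order: first the
#' `floor(drop_sample_frac * n_samples)` samples with the fewest detected
#' events are dropped (ties broken by sample-id order), then only events
#' detected in at least `min_sample_frac` of the *remaining* samples are
#' kept (inclusive threshold). Dropping samples first makes the event
#' detection fraction well defined on the final cohort.
#'
#' @param detection Logical events x samples matrix from [call_expressed()].
#' @param min_sample_frac Minimum detection fraction per event (default 0.25).
#' @param drop_sample_frac Fraction of samples to drop (default 0.05).
#' @return List with `events` (kept event ids) and `samples`
#'   (kept sample ids).
#' @export
filter_cohort <- function(detection, min_sample_frac = 0.25,
                          drop_sample_frac = 0.05) {
  detection <- as.matrix(detection)
  if (!nrow(detection) || !ncol(detection))
    stop("empty detection matrix", call. = FALSE)
  if (is.null(rownames(detection)) || is.null(colnames(detection)))
    stop("detection matrix must carry event and sample ids", call. = FALSE)
  n_drop <- floor(drop_sample_frac * ncol(detection))
  n_det <- colSums(detection)
  ord <- order(n_det, colnames(detection))
  drop_idx <- if (n_drop > 0) ord[seq_len(n_drop)] else integer(0)
  kept_samples <- colnames(detection)[setdiff(seq_len(ncol(detection)),
                                              drop_idx)]
  frac <- rowMeans(detection[, kept_samples, drop = FALSE])
  kept_events <- rownames(detection)[frac >= min_sample_frac]
  list(events = kept_events, samples = kept_samples)
}

#' Correlate per-exon PSI with regulator expression across a cohort
#'
#' For each event, rank (Spearman, default) or linear (Pearson) correlation
#' between the samples' PSI values and the regulator's expression, using
#' only samples with defined PSI. Two-sided p-values are
#' Benjamini-Hochberg-adjusted across the testable events; an event is
#' `significant` when its adjusted p is below `adj_p_max` (default 0.01).
#' Events with fewer than `min_samples` defined values or constant PSI are
#' flagged `untestable` and excluded from the FDR denominator.
#'
#' @param psi A `psi_matrix` or a plain events x samples PSI matrix
#'   (typically already restricted via [filter_cohort()]).
#' @param metadata Metadata data.frame with `sample_id` and
#'   `regulator_expr`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param adj_p_max Significance cut-off on the adjusted p (default 0.01).
#' @param min_samples Minimum samples with defined PSI (default 3).
#' @return data.frame of class `correlation_screen`: `event_id, n_used, rho,
#'   p_value, adj_p, untestable, significant`.
#' @export
correlate_exons <- function(psi, metadata, method = c("spearman", "pearson"),
                            adj_p_max = 0.01, min_samples = 3L) {
  method <- match.arg(method)
  m <- if (inherits(psi, "psi_matrix")) psi$psi else as.matrix(psi)
  if (is.null(colnames(m)) || is.null(rownames(m)))
    stop("PSI matrix must carry event and sample ids", call. = FALSE)
  if (!all(c("sample_id", "regulator_expr") %in% names(metadata)))
    stop("metadata must have 'sample_id' and 'regulator_expr'", call. = FALSE)
  ix <- match(colnames(m), metadata$sample_id)
  if (anyNA(ix))
    stop("metadata missing sample(s): ",
         paste(colnames(m)[is.na(ix)], collapse = ", "), call. = FALSE)
  expr <- metadata$regulator_expr[ix]

  n_ev <- nrow(m)
  rho <- p <- rep(NA_real_, n_ev)
  n_used <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    ok <- !is.na(m[i, ]) & !is.na(expr)
    n_used[i] <- sum(ok)
    if (n_used[i] < min_samples) next
    x <- m[i, ok]; y <- expr[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- if (method == "spearman")
      suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                       exact = FALSE))
    else stats::cor.test(x, y, method = "pearson")
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  untestable <- is.na(p)
  adj_p <- rep(NA_real_, n_ev)
  adj_p[!untestable] <- stats::p.adjust(p[!untestable], method = "BH")
  out <- data.frame(event_id = rownames(m), n_used = n_used, rho = rho,
                    p_value = p, adj_p = adj_p, untestable = untestable,
                    significant = !untestable & !is.na(adj_p) &
                      adj_p < adj_p_max,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_screen", "data.frame")
  out
}
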