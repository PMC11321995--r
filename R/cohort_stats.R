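#' Stratify samples by exon inclusion with one-dimensional k-means
#'
#' Partitions the per-sample PSI values of a single exon into k clusters.
#' In one dimension an optimal k-means partition is always a set of
#' contiguous intervals of the sorted values, so for the default k = 2 the
#' global optimum is found exactly and deterministically by scanning every
#' threshold cut of the sorted values (prefix-sum evaluation of the
#' within-cluster sum of squares); iterative Lloyd refinement, whose result
#' can depend on initialization and stop at a local optimum, is only used
#' for k > 2 (evenly spaced initial centres, deterministic). Strata are
#' labelled so that `high` has the larger centre. Ties exactly at the
#' optimal threshold resolve by stable sort order.
#'
#' @param psi_values Named numeric vector of PSI values (sample -> psi);
#'   `NA` samples are left unassigned.
#' @param k Number of clusters (default 2).
#' @param exon_id Optional exon name, used in error messages.
#' @return An object of class `stratification`: `strata` (named character
#'   vector, `"high"`/`"low"` when k = 2), `centres` (sorted ascending),
#'   `withinss` (total within-cluster sum of squares).
#' @export
kmeans_stratify <- function(psi_values, k = 2L, exon_id = NULL) {
  x <- psi_values[!is.na(psi_values)]
  what <- if (is.null(exon_id)) "input" else paste0("exon '", exon_id, "'")
  if (length(unique(x)) < k)
    stop("degenerate PSI distribution for ", what,
         ": fewer than ", k, " distinct values", call. = FALSE)
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  if (k == 2L) {
    ord <- order(x)          # stable
    xs <- x[ord]
    n <- length(xs)
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    kk <- seq_len(n - 1)
    wss_left <- cs2[kk] - cs[kk]^2 / kk
    wss_right <- (cs2[n] - cs2[kk]) - (cs[n] - cs[kk])^2 / (n - kk)
    tot <- wss_left + wss_right
    best <- which.min(tot)
    lab <- rep(c("low", "high"), c(best, n - best))
    strata <- stats::setNames(lab, names(xs))[names(x)]
    centres <- unname(c(cs[best] / best, (cs[n] - cs[best]) / (n - best)))
    return(structure(list(strata = strata, centres = centres,
                          withinss = unname(tot[best])),
                     class = "stratification"))
  }
  centers <- matrix(seq(min(x), max(x), length.out = k), ncol = 1)
  km <- stats::kmeans(matrix(x, ncol = 1), centers = centers,
                      algorithm = "Lloyd", iter.max = 100L)
  ord <- order(km$centers[, 1])
  lab_of_cluster <- character(k)
  lab_of_cluster[ord] <- paste0("c", seq_len(k))
  strata <- stats::setNames(lab_of_cluster[km$cluster], names(x))
  structure(list(strata = strata,
                 centres = sort(km$centers[, 1]),
                 withinss = sum(km$withinss)),
            class = "stratification")
}

#' Chi-squared association between strata and subtype labels
#'
#' Pearson chi-squared on the strata x subtype contingency table,
#' df = (r-1)(c-1), without continuity correction by default.
#'
#' @param strata,subtypes Parallel label vectors (same samples, same order).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List: `statistic`, `p_value`, `df`, `table`, `expected`.
#' @export
chisq_association <- function(strata, subtypes, correct = FALSE) {
  if (length(strata) != length(subtypes))
    stop("'strata' and 'subtypes' must have equal length", call. = FALSE)
  tab <- table(strata, subtypes)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 strata and >= 2 subtype levels", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), table = tab, expected = ct$expected)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per stratum (with Greenwood standard
#' errors) and the unweighted (Mantel-Haenszel) log-rank test; the two-sided
#' p comes from the chi-squared distribution with 1 df.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param strata Stratum labels with exactly two levels, each non-empty.
#' @return An object of class `logrank_result`: `curves` (data.frame:
#'   stratum, time, n_risk, n_event, survival, std_err), `statistic`,
#'   `p_value`, `observed`, `expected`.
#' @export
km_logrank <- function(times, events, strata) {
  if (any(times < 0, na.rm = TRUE)) stop("times must be >= 0", call. = FALSE)
  strata <- as.character(strata)
  lev <- unique(strata)
  if (length(lev) != 2)
    stop("exactly two strata are required (got ", length(lev), ")",
         call. = FALSE)
  if (any(table(factor(strata, levels = lev)) == 0))
    stop("each stratum must contain at least one subject", call. = FALSE)
  df <- data.frame(times = times, events = events, strata = strata)
  fit <- survival::survfit(survival::Surv(times, events) ~ strata, data = df)
  sm <- summary(fit)
  curves <- data.frame(stratum = sub("^strata=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       std_err = sm$std.err, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ strata, data = df,
                           rho = 0)
  stat <- unname(sd$chisq)
  structure(list(curves = curves, statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = unname(sd$obs), expected = unname(sd$exp)),
            class = "logrank_result")
}

#' Expected overlap and hypergeometric enrichment of two sets
#'
#' For two sets of sizes `n1` and `n2` drawn from a universe of size `N`,
#' the expected overlap under independence is `n1 * n2 / N`, and the
#' enrichment p-value is the upper-tail hypergeometric probability
#' `P(X >= observed)`.
#'
#' @param n1,n2 Set sizes.
#' @param N Universe size.
#' @param observed Observed overlap (<= min(n1, n2)).
#' @return List of class `overlap_result`: `n1, n2, N, observed, expected,
#'   p_value`.
#' @export
hypergeom_overlap <- function(n1, n2, N, observed) {
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N)
    stop("need 0 <= n1, n2 <= N", call. = FALSE)
  if (observed > min(n1, n2))
    stop("observed overlap exceeds min(n1, n2)", call. = FALSE)
  if (observed < max(0, n1 + n2 - N))
    stop("observed overlap below the feasible minimum", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, N = N, observed = observed,
                 expected = n1 * n2 / N,
                 p_value = stats::phyper(observed - 1, n1, N - n1, n2,
                                         lower.tail = FALSE)),
            class = "overlap_result")
}

#' Combine two per-exon stratifications into a joint signature
#'
#' Samples in the first exon's `first_level` stratum *and* the second
#' exon's `second_level` stratum form the signature-positive group
#' (e.g. high inclusion of one exon with low inclusion of another).
#'
#' @param strat1,strat2 `stratification` objects (or named stratum vectors).
#' @param first_level,second_level Stratum levels defining the signature
#'   (defaults `"high"` and `"low"`).
#' @return Named character vector: `"signature"` / `"other"` per sample
#'   present in both stratifications.
#' @export
combine_strata <- function(strat1, strat2, first_level = "high",
                           second_level = "low") {
  s1 <- if (inherits(strat1, "stratification")) strat1$strata else strat1
  s2 <- if (inherits(strat2, "stratification")) strat2$strata else strat2
  common <- intersect(names(s1), names(s2))
  if (!length(common)) stop("no samples in common", call. = FALSE)
  sig <- s1[common] == first_level & s2[common] == second_level
  stats::setNames(ifelse(sig, "signature", "other"), common)
}
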