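# Small fixtures and independent brute-force oracles used across test files.
# The oracles deliberately avoid the package's own code paths (and, where a
# dual route is required, the library call the implementation uses).

tiny_events <- function(n = 3, types = c("SE", "MXE", "A3SS")[seq_len(n)]) {
  el <- effective_lengths(types)
  data.frame(event_id = paste0("e", seq_len(n)),
             gene_id = paste0("g", seq_len(n)),
             event_type = types,
             chrom = rep("chr1", n),
             start = 100L * seq_len(n),
             end = 100L * seq_len(n) + 60L,
             strand = rep("+", n),
             eff_len_inclusion = el$eff_len_inclusion,
             eff_len_skipping = el$eff_len_skipping,
             stringsAsFactors = FALSE)
}

tiny_counts <- function(I = rbind(c(10L, 20L), c(5L, 8L), c(0L, 3L)),
                        S = rbind(c(12L, 2L), c(9L, 4L), c(7L, 1L)),
                        samples = c("s1", "s2")) {
  colnames(I) <- colnames(S) <- samples
  event_count_matrix(tiny_events(nrow(I)), I, S)
}

# Brute-force binomial LRT for a 1-vs-1 comparison: numerical maximization
# of the binomial log-likelihood over the inclusion probability, per group
# and shared.
brute_lrt_1v1 <- function(ia, sa, ib, sb) {
  ll <- function(i, s) function(p) i * log(p) + s * log(1 - p)
  mx <- function(f) stats::optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE,
                                    tol = 1e-12)$objective
  2 * (mx(ll(ia, sa)) + mx(ll(ib, sb)) - mx(ll(ia + ib, sa + sb)))
}

# Risk-table enumeration of the two-group log-rank test. Walks the distinct
# event times, accumulating observed minus expected events and the
# hypergeometric variance in group 1.
logrank_enum <- function(times, events, strata) {
  g1 <- unique(strata)[1]
  o <- e <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & strata == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & strata == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(observed = o, expected = e, variance = v,
       statistic = (o - e)^2 / v)
}

# Exhaustive threshold-cut 1-D 2-means: minimum within-cluster sum of
# squares over every split of the sorted values.
threshold_cut_wss <- function(x) {
  x <- sort(x)
  n <- length(x)
  best <- Inf
  for (k in seq_len(n - 1)) {
    a <- x[1:k]; b <- x[(k + 1):n]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best <- min(best, wss)
  }
  best
}

# Direct window enumeration of positional motif-start density in one region.
window_density_enum <- function(starts, L, w = 50) {
  vapply(seq_len(L), function(t) {
    lo <- max(1, t - floor((w - 1) / 2))
    hi <- min(L, t + ceiling((w - 1) / 2))
    sum(starts >= lo & starts <= hi) / w
  }, numeric(1))
}

# Exact expected overlap of a fixed set of size n1 with all subsets of size
# n2 from a universe of size N, by explicit subset enumeration.
overlap_expectation_enum <- function(n1, n2, N) {
  if (n2 == 0 || n1 == 0) return(0)
  subsets <- utils::combn(N, n2)
  mean(colSums(subsets <= n1))
}
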