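# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards: all generator randomness flows from the one seed passed
# in, with no lasting effect on the session.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage sub-seed, kept below 2^31.
stage_seed <- function(seed, k) as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)

#' Configuration of the synthetic splicing cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort
#' sizes, sequencing depth, event-type composition, the planted differential
#' and regulator-correlated event structure, between-replicate
#' overdispersion, the planted RNA-map motif, and the survival hazard
#' contrast between PSI strata.
#'
#' @param n_events Number of splicing events (default 1000).
#' @param n_samples_per_group Samples per condition group (default 3, the
#'   typical replicate count of a knockdown experiment).
#' @param depth_mean Mean total junction reads per event per sample
#'   (default 100); per-cell depths are Poisson around this mean, floored
#'   at 1.
#' @param event_type_mix Named proportions over the five event types;
#'   default is cassette-exon dominated
#'   (SE .70, MXE .10, RI .10, A3SS .05, A5SS .05).
#' @param planted_diff `list(fraction=, delta=)`: fraction of events with a
#'   true group difference and its |delta PSI| magnitude
#'   (default 10% of events at 0.4). Signs are random and recorded.
#' @param planted_corr `list(fraction=, slope=)`: fraction of events whose
#'   PSI follows a logistic link to the regulator covariate, and the slope
#'   on the logit scale (default 10% at slope 2).
#' @param overdispersion Beta-binomial intra-class correlation rho in
#'   \[0, 1); 0 (default) is exactly binomial.
#' @param motif_plant `list(pattern=, region=, offset=)`: IUPAC motif planted
#'   (one concrete instance, match starting at 1-based `offset` within
#'   `region`) in the flanks of inclusion-down differential events; default
#'   the RBFOX hexamer TGCATG at offset 100 of the downstream intron.
#' @param hazard_ratio Exponential-hazard multiplier of the `high` PSI
#'   stratum relative to `low` (default 3).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_events = 1000L,
                             n_samples_per_group = 3L,
                             depth_mean = 100,
                             event_type_mix = c(SE = 0.70, MXE = 0.10,
                                                RI = 0.10, A3SS = 0.05,
                                                A5SS = 0.05),
                             planted_diff = list(fraction = 0.10, delta = 0.4),
                             planted_corr = list(fraction = 0.10, slope = 2),
                             overdispersion = 0,
                             motif_plant = list(pattern = "TGCATG",
                                                region = "downstream_intron",
                                                offset = 100L),
                             hazard_ratio = 3,
                             seed = 1L) {
  if (n_events < 1) stop("'n_events' must be >= 1", call. = FALSE)
  if (n_samples_per_group < 1) stop("'n_samples_per_group' must be >= 1",
                                    call. = FALSE)
  if (depth_mean <= 0) stop("'depth_mean' must be > 0", call. = FALSE)
  if (!all(names(event_type_mix) %in% EVENT_TYPES) ||
      abs(sum(event_type_mix) - 1) > 1e-8 || any(event_type_mix < 0))
    stop("'event_type_mix' must be non-negative proportions over SE/MXE/RI/A3SS/A5SS summing to 1",
         call. = FALSE)
  for (pl in list(planted_diff["fraction"], planted_corr["fraction"])) {
    v <- pl[[1]]
    if (v < 0 || v > 1) stop("planted fractions must be in [0,1]", call. = FALSE)
  }
  if (planted_diff$delta <= 0 || planted_diff$delta >= 1)
    stop("planted delta PSI must be in (0,1)", call. = FALSE)
  if (overdispersion < 0 || overdispersion >= 1)
    stop("'overdispersion' must be in [0,1)", call. = FALSE)
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be > 0", call. = FALSE)
  .check_iupac(motif_plant$pattern)
  structure(list(n_events = as.integer(n_events),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 depth_mean = depth_mean,
                 event_type_mix = event_type_mix,
                 planted_diff = planted_diff,
                 planted_corr = planted_corr,
                 overdispersion = overdispersion,
                 motif_plant = motif_plant,
                 hazard_ratio = hazard_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.check_iupac <- function(pattern) {
  pattern <- toupper(gsub("U", "T", toupper(pattern)))
  letters <- strsplit(pattern, "")[[1]]
  ok <- letters %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!length(letters) || !all(ok))
    stop("motif contains non-IUPAC letter(s): ",
         paste(unique(letters[!ok]), collapse = ", "), call. = FALSE)
  pattern
}

# Random event metadata table.
.make_events <- function(n, mix) {
  types <- sample(names(mix), n, replace = TRUE, prob = mix)
  el <- effective_lengths(types)
  start <- sample.int(2e8, n)
  len <- sample(30:300, n, replace = TRUE)
  data.frame(event_id = sprintf("ev%05d", seq_len(n)),
             gene_id = sprintf("gene%05d", seq_len(n)),
             event_type = types,
             chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             eff_len_inclusion = el$eff_len_inclusion,
             eff_len_skipping = el$eff_len_skipping,
             stringsAsFactors = FALSE)
}

# Beta-binomial draw with intra-class correlation rho (binomial at rho = 0).
.rbetabinom <- function(size, prob, rho) {
  if (rho == 0) return(stats::rbinom(length(size), size, prob))
  p <- prob
  inner <- p
  mid <- p > 0 & p < 1
  if (any(mid)) {
    nu <- (1 - rho) / rho
    inner[mid] <- stats::rbeta(sum(mid), p[mid] * nu, (1 - p[mid]) * nu)
  }
  stats::rbinom(length(size), size, inner)
}

# psi -> per-read inclusion probability under the junction-length geometry
# (the exact inverse of estimate_psi on expected counts).
.psi_to_prob <- function(psi, li, ls) (psi * li) / (psi * li + (1 - psi) * ls)

# Draw I/S junction counts for a true-PSI matrix.
.draw_counts <- function(true_psi, li, ls, depth_mean, rho) {
  n_ev <- nrow(true_psi); n_s <- ncol(true_psi)
  depth <- matrix(pmax(1L, stats::rpois(n_ev * n_s, depth_mean)), n_ev, n_s)
  p <- .psi_to_prob(true_psi, li, ls)
  I <- matrix(.rbetabinom(as.vector(depth), as.vector(p), rho), n_ev, n_s)
  list(I = I, S = depth - I)
}

#' Generate a two-condition knockdown cohort with planted splicing structure
#'
#' Emulates a regulator-knockdown experiment: `n_samples_per_group` control
#' and knockdown samples each, junction counts drawn per event and sample as
#' `I ~ (Beta-)Binomial(n, p)` with `n ~ Poisson(depth_mean)` and
#' `p = psi * l_I / (psi * l_I + (1 - psi) * l_S)` — the exact inverse of the
#' PSI estimator — and `S = n - I`.
#'
#' Planted structure (all recorded in the returned truth object):
#' * a `planted_diff$fraction` subset of events whose true PSI differs
#'   between the groups by `planted_diff$delta` with random sign;
#' * a disjoint `planted_corr$fraction` subset whose true PSI follows
#'   `logit(psi) = logit(base) + slope * regulator_expr`, with
#'   `regulator_expr ~ N(0, 1)` per sample;
#' * survival times exponential with hazard multiplied by `hazard_ratio` in
#'   the `high` stratum (samples split at the median true PSI of the first
#'   planted event), administratively censored at the 80th percentile of the
#'   drawn event times.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts` (`event_counts`), `metadata` (data.frame:
#'   sample_id, group, regulator_expr, surv_time, surv_event) and `truth`
#'   (class `synthetic_truth`: `true_psi`, `diff_event_ids`, `true_delta`,
#'   `corr_event_ids`, `motif_offsets`, `stratum_labels`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(config$seed, {
    n <- config$n_events
    m <- config$n_samples_per_group
    events <- .make_events(n, config$event_type_mix)
    samples <- c(sprintf("ctrl_%02d", seq_len(m)),
                 sprintf("kd_%02d", seq_len(m)))
    group <- rep(c("control", "knockdown"), each = m)
    regulator_expr <- stats::rnorm(2 * m)

    n_diff <- round(config$planted_diff$fraction * n)
    n_corr <- round(config$planted_corr$fraction * n)
    ids <- events$event_id
    diff_ids <- sort(sample(ids, n_diff))
    corr_ids <- sort(sample(setdiff(ids, diff_ids), n_corr))

    delta <- config$planted_diff$delta
    slope <- config$planted_corr$slope

    base <- stats::runif(n, 0.05, 0.95)
    true_psi <- matrix(base, n, 2 * m)
    dimnames(true_psi) <- list(ids, samples)

    true_delta <- numeric(0)
    if (n_diff > 0) {
      di <- match(diff_ids, ids)
      lo <- stats::runif(n_diff, 0.05, 0.95 - delta)
      sign <- sample(c(-1, 1), n_diff, replace = TRUE)
      psi_ctrl <- ifelse(sign > 0, lo, lo + delta)
      psi_kd <- ifelse(sign > 0, lo + delta, lo)
      true_psi[di, group == "control"] <- psi_ctrl
      true_psi[di, group == "knockdown"] <- psi_kd
      true_delta <- stats::setNames(psi_kd - psi_ctrl, diff_ids)
    }
    if (n_corr > 0) {
      ci <- match(corr_ids, ids)
      cbase <- stats::runif(n_corr, 0.2, 0.8)
      eta <- outer(stats::qlogis(cbase), rep(1, 2 * m)) +
        outer(rep(slope, n_corr), regulator_expr)
      true_psi[ci, ] <- stats::plogis(eta)
    }

    cs <- .draw_counts(true_psi, events$eff_len_inclusion,
                       events$eff_len_skipping, config$depth_mean,
                       config$overdispersion)
    colnames(cs$I) <- colnames(cs$S) <- samples
    counts <- event_count_matrix(events, cs$I, cs$S)

    sig_event <- if (n_corr > 0) corr_ids[1] else if (n_diff > 0) diff_ids[1] else ids[1]
    sig_psi <- true_psi[sig_event, ]
    stratum <- ifelse(sig_psi >= stats::median(sig_psi), "high", "low")
    rate <- 0.1 * ifelse(stratum == "high", config$hazard_ratio, 1)
    t_event <- stats::rexp(2 * m, rate)
    cens <- stats::quantile(t_event, 0.8)
    surv_time <- pmin(t_event, cens)
    surv_event <- as.integer(t_event <= cens)

    metadata <- data.frame(sample_id = samples, group = group,
                           regulator_expr = regulator_expr,
                           surv_time = surv_time, surv_event = surv_event,
                           stringsAsFactors = FALSE)

    motif_ids <- names(true_delta)[true_delta < 0]
    motif_offsets <- stats::setNames(rep(as.integer(config$motif_plant$offset),
                                         length(motif_ids)), motif_ids)

    truth <- structure(list(true_psi = true_psi,
                            diff_event_ids = diff_ids,
                            true_delta = true_delta,
                            corr_event_ids = corr_ids,
                            motif_offsets = motif_offsets,
                            stratum_labels = stats::setNames(stratum, samples),
                            signature_event = sig_event),
                       class = "synthetic_truth")
    list(counts = counts, metadata = metadata, truth = truth)
  })
}

#' Generate flanking sequences with a planted motif
#'
#' Produces, for every event, random uniform-ACGT sequences covering each
#' region of the RNA-map layout. Events listed in `truth$motif_offsets`
#' additionally carry one concrete instance of the configured motif whose
#' match starts at the configured 1-based offset within the configured
#' region (chance matches elsewhere are possible, as in real sequence).
#'
#' @param events Events data.frame (or `event_counts`).
#' @param truth A `synthetic_truth` (its `motif_offsets` drive the planting);
#'   may be `NULL` for a pure background set.
#' @param config A [synthetic_config()]; `motif_plant` and `seed` are used.
#' @param layout A [region_layout()].
#' @return Named list (by event id) of named character vectors (by region):
#'   class `flank_sequences`.
#' @export
generate_flank_sequences <- function(events, truth, config,
                                     layout = region_layout()) {
  if (inherits(events, "event_counts")) events <- events$events
  pattern <- .check_iupac(config$motif_plant$pattern)
  region <- config$motif_plant$region
  if (!region %in% names(layout$regions))
    stop("motif_plant region '", region, "' is not in the layout", call. = FALSE)
  offsets <- if (is.null(truth)) integer(0) else truth$motif_offsets
  with_rng(stage_seed(config$seed, 7L), {
    out <- lapply(events$event_id, function(id) {
      seqs <- vapply(layout$regions, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1))
      if (id %in% names(offsets)) {
        off <- offsets[[id]]
        L <- layout$regions[[region]]
        inst <- .realize_iupac(pattern)
        if (off < 1 || off + nchar(inst) - 1 > L)
          stop("motif offset ", off, " does not fit region '", region, "'",
               call. = FALSE)
        s <- seqs[[region]]
        substr(s, off, off + nchar(inst) - 1) <- inst
        seqs[[region]] <- s
      }
      seqs
    })
    names(out) <- events$event_id
    structure(out, class = "flank_sequences")
  })
}

# One concrete DNA realization of an IUPAC pattern.
.realize_iupac <- function(pattern) {
  letters <- strsplit(pattern, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Write / read flank sequences as FASTA
#'
#' Records are named `<event_id>|<region>`.
#'
#' @param flanks A `flank_sequences` list.
#' @param path FASTA file path.
#' @return `path` invisibly (write); a `flank_sequences` list (read).
#' @export
write_flanks_fasta <- function(flanks, path) {
  seqs <- unlist(lapply(names(flanks), function(id)
    stats::setNames(as.character(flanks[[id]]),
                    paste0(id, "|", names(flanks[[id]])))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_flanks_fasta
#' @export
read_flanks_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  regions <- vapply(parts, `[`, character(1), 2)
  out <- lapply(split(seq_along(ss), ids), function(ix)
    stats::setNames(as.character(ss[ix]), regions[ix]))
  structure(out[unique(ids)], class = "flank_sequences")
}

#' Generate a reference-plus-tumour cohort at graded splicing distances
#'
#' Emulates the developmental-reference comparison: a pooled set of
#' reference samples shares one base PSI vector; each tumour of a subtype
#' deviates from that vector at a subtype-specific number of events
#' (resampled per tumour and recorded in the truth), by `deviation_delta`
#' in whichever direction keeps PSI in \[0, 1\]. A distance of 0 leaves a
#' subtype's true PSI identical to the reference.
#'
#' @param config A [synthetic_config()] (`n_events`, `depth_mean`,
#'   `overdispersion`, `event_type_mix`, `seed`).
#' @param subtype_distances Named integer vector: subtype -> number of
#'   deviating events per tumour. At least two subtypes.
#' @param n_reference Number of reference samples (default 4, >= 2).
#' @param n_tumours_per_subtype Tumours per subtype (default 8).
#' @param deviation_delta |delta PSI| of each deviating event (default 0.5).
#' @return A list with `counts`, `metadata` (group = subtype or
#'   `"reference"`) and `truth` (`base_psi`, `deviating_events`: named list
#'   per tumour, `true_psi`).
#' @export
generate_reference_cohort <- function(config, subtype_distances,
                                      n_reference = 4L,
                                      n_tumours_per_subtype = 8L,
                                      deviation_delta = 0.5) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(subtype_distances) < 2 || is.null(names(subtype_distances)))
    stop("at least two named subtypes are required", call. = FALSE)
  if (n_reference < 2)
    stop("at least 2 reference samples are required", call. = FALSE)
  if (any(subtype_distances < 0) || any(subtype_distances > config$n_events))
    stop("subtype distances must be in [0, n_events]", call. = FALSE)
  with_rng(stage_seed(config$seed, 11L), {
    n <- config$n_events
    events <- .make_events(n, config$event_type_mix)
    ids <- events$event_id
    subtypes <- names(subtype_distances)
    tum_ids <- unlist(lapply(subtypes, function(st)
      sprintf("%s_t%02d", st, seq_len(n_tumours_per_subtype))))
    samples <- c(sprintf("ref_%02d", seq_len(n_reference)), tum_ids)
    group <- c(rep("reference", n_reference),
               rep(subtypes, each = n_tumours_per_subtype))

    base <- stats::runif(n, 0.15, 0.85)
    true_psi <- matrix(base, n, length(samples),
                       dimnames = list(ids, samples))
    deviating <- stats::setNames(vector("list", length(tum_ids)), tum_ids)
    for (j in seq_along(samples)) {
      if (group[j] == "reference") next
      k <- subtype_distances[[group[j]]]
      dev <- if (k > 0) sort(sample(ids, k)) else character(0)
      deviating[[samples[j]]] <- dev
      if (k > 0) {
        di <- match(dev, ids)
        dir <- ifelse(base[di] < 0.5, 1, -1)
        true_psi[di, j] <- base[di] + dir * deviation_delta
      }
    }
    true_psi <- pmin(pmax(true_psi, 0), 1)

    cs <- .draw_counts(true_psi, events$eff_len_inclusion,
                       events$eff_len_skipping, config$depth_mean,
                       config$overdispersion)
    colnames(cs$I) <- colnames(cs$S) <- samples
    counts <- event_count_matrix(events, cs$I, cs$S)
    metadata <- data.frame(sample_id = samples, group = group,
                           stringsAsFactors = FALSE)
    truth <- structure(list(base_psi = stats::setNames(base, ids),
                            deviating_events = deviating,
                            true_psi = true_psi),
                       class = "synthetic_truth")
    list(counts = counts, metadata = metadata, truth = truth)
  })
}

#' Serialize a synthetic-truth object to JSON
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$true_psi)) {
    x$true_psi <- as.data.frame(x$true_psi)
  }
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}
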