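#' Genomic interval (0-based, half-open)
#'
#' Coordinates follow the 0-based half-open convention (as in BED and the
#' rMATS `exonStart_0base` columns), so the length of an interval is simply
#' `end - start`. Under this reading the printed coordinates of the two
#' morpholino-targeted cassette exons give lengths of 57 nt and 63 nt, both
#' divisible by three.
#'
#' @param chrom Chromosome name, e.g. `"chr12"`.
#' @param start 0-based inclusive start (non-negative integer).
#' @param end Exclusive end; must satisfy `end >= start`.
#' @param strand One of `"+"`, `"-"` or `"*"` (unknown). Unknown strand is
#'   treated as `"+"` wherever an orientation is needed.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr12", 42778741, 42778798)
#' exon_length(iv)  # 57
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("'chrom' must be a non-empty string", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("'start' and 'end' must be single numbers", call. = FALSE)
  if (start < 0) stop("'start' must be >= 0", call. = FALSE)
  if (end < start) stop("'end' must be >= 'start'", call. = FALSE)
  if (start != floor(start) || end != floor(end))
    stop("coordinates must be integers", call. = FALSE)
  if (!strand %in% c("+", "-", "*"))
    stop("'strand' must be one of '+', '-', '*'", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Parse a region string such as "chr12:42778741-42778798"
#'
#' Accepts hyphen or en-dash separators. The coordinates are taken as
#' 0-based half-open, matching [genomic_interval()].
#'
#' @param region A single string `"<chrom>:<start>-<end>"`.
#' @param strand Optional strand, default `"*"`.
#' @return A `genomic_interval`.
#' @export
parse_region <- function(region, strand = "*") {
  if (!is.character(region) || length(region) != 1L)
    stop("'region' must be a single string", call. = FALSE)
  region <- gsub("–", "-", region)          # tolerate en-dash
  region <- gsub(",", "", region, fixed = TRUE)  # tolerate thousand separators
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string '", region, "'", call. = FALSE)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]), strand = strand)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s) [%d nt]\n", x$chrom, x$start, x$end, x$strand,
              exon_length(x)))
  invisible(x)
}

#' Exon / interval length
#'
#' Length of a 0-based half-open interval: `end - start`.
#'
#' @param iv A `genomic_interval`.
#' @return Integer length in nucleotides.
#' @export
exon_length <- function(iv) {
  if (!inherits(iv, "genomic_interval"))
    stop("'iv' must be a genomic_interval", call. = FALSE)
  as.integer(iv$end - iv$start)
}

#' Is an exon length frame-preserving?
#'
#' A skipped exon leaves the downstream open reading frame intact exactly
#' when its length is divisible by three; this is the arithmetic used to
#' check that a splice-blocking morpholino will not introduce a frameshift.
#'
#' @param length Non-negative integer length in nucleotides.
#' @return `TRUE` iff `length %% 3 == 0`.
#' @export
frame_preserving <- function(length) {
  if (!is.numeric(length) || anyNA(length))
    stop("'length' must be numeric", call. = FALSE)
  if (any(length < 0)) stop("'length' must be >= 0", call. = FALSE)
  if (any(length != floor(length))) stop("'length' must be integer", call. = FALSE)
  length %% 3 == 0
}

EVENT_TYPES <- c("SE", "MXE", "RI", "A3SS", "A5SS")

#' Effective junction lengths by event type
#'
#' Number of distinct junctions supporting the inclusion and skipping
#' isoforms in junction-count mode: skipped exons and retained introns have
#' two inclusion junctions versus one skipping junction; mutually exclusive
#' exons have two of each; alternative 5'/3' splice sites have one of each.
#'
#' @param event_type Character vector of event types
#'   (`SE`, `MXE`, `RI`, `A3SS`, `A5SS`).
#' @return A data.frame with columns `eff_len_inclusion`, `eff_len_skipping`.
#' @export
effective_lengths <- function(event_type) {
  if (!all(event_type %in% EVENT_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(event_type, EVENT_TYPES), collapse = ", "),
         call. = FALSE)
  li <- c(SE = 2L, MXE = 2L, RI = 2L, A3SS = 1L, A5SS = 1L)
  ls <- c(SE = 1L, MXE = 2L, RI = 1L, A3SS = 1L, A5SS = 1L)
  data.frame(eff_len_inclusion = unname(li[event_type]),
             eff_len_skipping  = unname(ls[event_type]))
}

EVENT_META_COLS <- c("event_id", "gene_id", "event_type", "chrom", "start",
                     "end", "strand", "eff_len_inclusion", "eff_len_skipping")

#' Event count matrix: inclusion and skipping junction counts per event x sample
#'
#' The raw quantitative input of every downstream stage: per alternative
#' splicing event and per sample, the number of junction reads supporting the
#' inclusion isoform (`I`) and the skipping isoform (`S`).
#'
#' @param events data.frame of event metadata with columns
#'   `event_id, gene_id, event_type, chrom, start, end, strand,
#'   eff_len_inclusion, eff_len_skipping`.
#' @param I,S Integer matrices (events x samples) of non-negative junction
#'   read counts, with identical dimensions. Column names are sample ids.
#' @return An object of class `event_counts`.
#' @export
event_count_matrix <- function(events, I, S) {
  events <- as.data.frame(events)
  miss <- setdiff(EVENT_META_COLS, names(events))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(events$event_id))
    stop("duplicated event ids: ",
         paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(events$event_type %in% EVENT_TYPES))
    stop("invalid event types present", call. = FALSE)
  if (any(events$eff_len_inclusion < 1) || any(events$eff_len_skipping < 1))
    stop("effective lengths must be >= 1", call. = FALSE)
  I <- as.matrix(I); S <- as.matrix(S)
  if (!identical(dim(I), dim(S)))
    stop("I and S must have identical dimensions", call. = FALSE)
  if (nrow(I) != nrow(events))
    stop("count matrices must have one row per event", call. = FALSE)
  .check_counts(I, "I"); .check_counts(S, "S")
  samples <- colnames(I)
  if (is.null(samples)) stop("count matrices must carry sample ids as colnames",
                             call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicated sample ids", call. = FALSE)
  storage.mode(I) <- "integer"; storage.mode(S) <- "integer"
  rownames(I) <- rownames(S) <- events$event_id
  structure(list(events = events, samples = samples, I = I, S = S),
            class = "event_counts")
}

.check_counts <- function(m, what) {
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    r <- bad[1, 1]; c <- bad[1, 2]
    cn <- if (!is.null(colnames(m))) colnames(m)[c] else as.character(c)
    stop(sprintf("invalid %s count %s at row %d, column '%s': counts must be non-negative integers",
                 what, format(m[r, c]), r, cn), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("event_counts: %d events x %d samples\n",
              nrow(x$I), ncol(x$I)))
  cat("event types:", paste(sprintf("%s=%d", names(table(x$events$event_type)),
                                    table(x$events$event_type)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.event_counts <- function(x) dim(x$I)

#' Write an event count table (TSV dialect)
#'
#' One event per row: the metadata columns, then paired per-sample count
#' columns named `<sample>__I` and `<sample>__S`. Tab-separated, lossless
#' and diff-friendly. Optional `#`-prefixed provenance header lines.
#'
#' @param x An `event_counts` object.
#' @param path Output file path.
#' @param header Optional character vector of provenance lines, written as
#'   `# <line>` before the table.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "event_counts"))
  df <- x$events[, EVENT_META_COLS]
  for (s in x$samples) {
    df[[paste0(s, "__I")]] <- x$I[, s]
    df[[paste0(s, "__S")]] <- x$S[, s]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event count table (TSV dialect)
#'
#' Reads the dialect written by [write_event_table()]: event metadata columns
#' followed by `<sample>__I` / `<sample>__S` count column pairs. Lines
#' starting with `#` are ignored.
#'
#' @param path Input file path.
#' @return An `event_counts` object; row order is preserved.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(EVENT_META_COLS, names(df))
  if (length(miss))
    stop("malformed event table, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  count_cols <- grep("__[IS]$", names(df), value = TRUE)
  samples <- unique(sub("__[IS]$", "", count_cols))
  if (!length(samples)) stop("no per-sample count columns found", call. = FALSE)
  for (s in samples) {
    for (suf in c("__I", "__S")) {
      cn <- paste0(s, suf)
      if (!cn %in% names(df))
        stop("unpaired count column for sample '", s, "': missing ", cn,
             call. = FALSE)
      if (!is.numeric(df[[cn]]))
        stop("non-numeric counts in column '", cn, "'", call. = FALSE)
    }
  }
  I <- as.matrix(df[, paste0(samples, "__I"), drop = FALSE])
  S <- as.matrix(df[, paste0(samples, "__S"), drop = FALSE])
  colnames(I) <- colnames(S) <- samples
  event_count_matrix(df[, EVENT_META_COLS], I, S)
}

#' Export event target intervals as BED6
#'
#' @param x An `event_counts` object or an events data.frame.
#' @param path Output BED file path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(x, path) {
  ev <- if (inherits(x, "event_counts")) x$events else as.data.frame(x)
  strand <- ifelse(ev$strand %in% c("+", "-"), ev$strand, "+")
  bed <- data.frame(ev$chrom, ev$start, ev$end, ev$event_id, 0L, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sample metadata (TSV)
#'
#' @param metadata data.frame with columns `sample_id`, `group` and
#'   optionally `regulator_expr`, `surv_time`, `surv_event`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (TSV)
#'
#' Validates that sample ids are unique and that a survival event indicator
#' accompanies every recorded survival time.
#'
#' @param path Input file path.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have 'sample_id' and 'group' columns", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids", call. = FALSE)
  if ("surv_time" %in% names(df)) {
    if (!"surv_event" %in% names(df))
      stop("'surv_event' required when 'surv_time' is present", call. = FALSE)
    bad <- !is.na(df$surv_time) & is.na(df$surv_event)
    if (any(bad))
      stop("surv_event missing for sample(s) with surv_time: ",
           paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  df
}

# Subset an event_counts object by event ids and/or sample ids.
#' Subset an event count matrix
#' @param x An `event_counts` object.
#' @param events Event ids to keep (default all).
#' @param samples Sample ids to keep (default all).
#' @return An `event_counts` object.
#' @export
subset_events <- function(x, events = NULL, samples = NULL) {
  stopifnot(inherits(x, "event_counts"))
  ei <- if (is.null(events)) seq_len(nrow(x$I)) else {
    idx <- match(events, x$events$event_id)
    if (anyNA(idx)) stop("unknown event id(s)", call. = FALSE)
    idx
  }
  si <- if (is.null(samples)) seq_along(x$samples) else {
    idx <- match(samples, x$samples)
    if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
    idx
  }
  event_count_matrix(x$events[ei, , drop = FALSE],
                     x$I[ei, si, drop = FALSE],
                     x$S[ei, si, drop = FALSE])
}
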