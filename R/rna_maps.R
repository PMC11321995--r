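#' Positional layout of an RNA map around a cassette exon
#'
#' The standard RNA-map geometry: 50 nt of upstream-exon edge, 250 nt of
#' upstream intron, the 5' and 3' edges of the target exon (50 nt each),
#' 250 nt of downstream intron and 50 nt of downstream-exon edge, scanned
#' with a sliding window (50 nt wide, 1-nt step). All lengths are
#' configurable; each must be at least the window width.
#'
#' @param upstream_exon,upstream_intron,exon_5p,exon_3p,downstream_intron,downstream_exon
#'   Region lengths in nucleotides.
#' @param window Sliding-window width (default 50).
#' @param step Window step (default 1).
#' @return An object of class `region_layout` with `regions` (named integer
#'   vector in map order), `window` and `step`.
#' @export
region_layout <- function(upstream_exon = 50L, upstream_intron = 250L,
                          exon_5p = 50L, exon_3p = 50L,
                          downstream_intron = 250L, downstream_exon = 50L,
                          window = 50L, step = 1L) {
  regions <- c(upstream_exon = upstream_exon,
               upstream_intron = upstream_intron,
               exon_5p = exon_5p, exon_3p = exon_3p,
               downstream_intron = downstream_intron,
               downstream_exon = downstream_exon)
  if (any(regions < window))
    stop("every region must be at least as long as the window", call. = FALSE)
  if (window < 1 || step < 1) stop("window and step must be >= 1", call. = FALSE)
  regions <- stats::setNames(as.integer(regions), names(regions))
  structure(list(regions = regions, window = as.integer(window),
                 step = as.integer(step)),
            class = "region_layout")
}

#' Motif specification (IUPAC)
#'
#' @param name Motif name (e.g. `"RBFOX"`).
#' @param pattern IUPAC nucleotide string; `U` is treated as `T` and case is
#'   ignored.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec("RBFOX", "UGCAUG")  # normalized to TGCATG
#' @export
motif_spec <- function(name, pattern) {
  pattern <- .check_iupac(pattern)
  structure(list(name = name, pattern = pattern), class = "motif_spec")
}

#' Read a motif table (TSV: name, pattern)
#' @param path TSV path with columns `name` and `pattern`.
#' @return List of `motif_spec` objects.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(df)))
    stop("motif table needs 'name' and 'pattern' columns", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) motif_spec(df$name[i], df$pattern[i]))
}

# Flatten a layout into a per-position annotation data.frame.
.layout_positions <- function(layout) {
  data.frame(region = rep(names(layout$regions), layout$regions),
             pos = unlist(lapply(layout$regions, seq_len), use.names = FALSE),
             position = seq_len(sum(layout$regions)),
             stringsAsFactors = FALSE)
}

# Windowed density of match-start indicators within one region:
# density(t) = #starts in [t - floor((w-1)/2), t + ceiling((w-1)/2)] / w,
# the window truncated at the region edges, denominator fixed at w.
.window_density <- function(starts, L, w) {
  m <- if (length(starts)) tabulate(starts, nbins = L) else numeric(L)
  cs <- c(0, cumsum(m))
  t <- seq_len(L)
  lo <- pmax(1L, t - floor((w - 1) / 2))
  hi <- pmin(L, t + ceiling((w - 1) / 2))
  (cs[hi + 1] - cs[lo]) / w
}

#' Per-event positional motif-density profiles
#'
#' For every event and every position of the layout, the motif-match density
#' in the 50-nt window centred at that position: the number of motif match
#' *start sites* inside the window divided by the window width. Matching is
#' IUPAC-degenerate and overlap-counting (every match start counts, so a
#' poly-U run contains many poly-U matches); windows are confined to their
#' region and truncated at region edges. Regions absent from an event (or
#' shorter than the layout) yield `NA` densities, which downstream means and
#' tests exclude.
#'
#' @param flanks A `flank_sequences` list (event -> region -> sequence).
#' @param motif A [motif_spec()] (or IUPAC string).
#' @param layout A [region_layout()].
#' @return Numeric matrix events x positions with the per-position layout in
#'   `attr(, "positions")`.
#' @export
motif_score_profile <- function(flanks, motif, layout = region_layout()) {
  if (is.character(motif)) motif <- motif_spec(motif, motif)
  stopifnot(inherits(motif, "motif_spec"), inherits(layout, "region_layout"))
  if (nchar(motif$pattern) > layout$window)
    stop("motif is longer than the scanning window", call. = FALSE)
  ids <- names(flanks)
  posinfo <- .layout_positions(layout)
  total <- nrow(posinfo)
  out <- matrix(NA_real_, length(ids), total,
                dimnames = list(ids, NULL))
  k <- nchar(motif$pattern)
  offset <- 0L
  for (rg in names(layout$regions)) {
    L <- layout$regions[[rg]]
    seqs <- vapply(flanks, function(f) {
      if (!rg %in% names(f)) return("")
      s <- f[[rg]]
      if (is.null(s) || is.na(s)) "" else toupper(gsub("U", "T", toupper(s)))
    }, character(1))
    has <- nchar(seqs) >= L
    if (any(has)) {
      ss <- Biostrings::DNAStringSet(substr(seqs[has], 1L, L))
      hits <- Biostrings::vmatchPattern(motif$pattern, ss, fixed = FALSE)
      starts <- Biostrings::startIndex(hits)
      dens <- t(vapply(starts, function(st) {
        st <- st[st <= L - k + 1L]
        .window_density(st, L, layout$window)
      }, numeric(L)))
      out[which(has), offset + seq_len(L)] <- dens
    }
    offset <- offset + L
  }
  attr(out, "positions") <- posinfo
  attr(out, "motif") <- motif
  attr(out, "layout") <- layout
  out
}

#' RNA map: positional motif enrichment of regulated exon sets vs background
#'
#' Builds the positional profile of mean motif density for the
#' inclusion-up set, the inclusion-down set and the background set, and at
#' every position runs a two-sided Wilcoxon rank-sum test of the per-event
#' densities of each regulated set against the background. Positions where
#' the combined densities are constant (e.g. no matches anywhere) get
#' p = 1. No correction across positions is applied; the map reports raw
#' per-position p curves (flagged in the object's metadata).
#'
#' @param profiles Density matrix from [motif_score_profile()] containing
#'   all events referenced below.
#' @param up_ids,down_ids Event ids of the inclusion-up / inclusion-down
#'   regulated sets (either may be empty: its curves are `NA`).
#' @param bg_ids Background event ids (non-empty).
#' @return data.frame of class `rna_map`: `region, pos, position, mean_up,
#'   mean_down, mean_bg, p_up, p_down`; set sizes, motif and the
#'   multiple-testing note are attributes.
#' @export
compare_profiles <- function(profiles, up_ids, down_ids, bg_ids) {
  if (!length(bg_ids)) stop("background set must be non-empty", call. = FALSE)
  posinfo <- attr(profiles, "positions")
  if (is.null(posinfo)) stop("profiles must come from motif_score_profile()",
                             call. = FALSE)
  miss <- setdiff(c(up_ids, down_ids, bg_ids), rownames(profiles))
  if (length(miss))
    stop("events missing from profiles: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  bg <- profiles[bg_ids, , drop = FALSE]
  one_side <- function(ids) {
    if (!length(ids))
      return(list(mean = rep(NA_real_, ncol(profiles)),
                  p = rep(NA_real_, ncol(profiles))))
    tg <- profiles[ids, , drop = FALSE]
    mean_curve <- colMeans(tg, na.rm = TRUE)
    p <- vapply(seq_len(ncol(profiles)), function(j) {
      x <- tg[, j]; x <- x[!is.na(x)]
      y <- bg[, j]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NA_real_)
      if (length(unique(c(x, y))) == 1L) return(1)
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }, numeric(1))
    list(mean = mean_curve, p = p)
  }
  up <- one_side(up_ids)
  down <- one_side(down_ids)
  out <- data.frame(posinfo,
                    mean_up = up$mean, mean_down = down$mean,
                    mean_bg = colMeans(bg, na.rm = TRUE),
                    p_up = up$p, p_down = down$p,
                    stringsAsFactors = FALSE)
  class(out) <- c("rna_map", "data.frame")
  attr(out, "n_up") <- length(up_ids)
  attr(out, "n_down") <- length(down_ids)
  attr(out, "n_bg") <- length(bg_ids)
  attr(out, "motif") <- attr(profiles, "motif")
  attr(out, "note") <- "per-position p-values are unadjusted across positions"
  out
}

#' Peak of an RNA map
#'
#' Position of the strongest enrichment signal (minimum p, i.e. maximum
#' -log10 p) for one direction; ties resolved to the first position.
#'
#' @param map An `rna_map`.
#' @param direction `"down"` (default) or `"up"`.
#' @return One-row data.frame (`region`, `pos`, `position`, `p`).
#' @export
map_peak <- function(map, direction = c("down", "up")) {
  direction <- match.arg(direction)
  p <- if (direction == "down") map$p_down else map$p_up
  if (all(is.na(p))) stop("no p-values for direction '", direction, "'",
                          call. = FALSE)
  i <- which.min(p)
  data.frame(region = map$region[i], pos = map$pos[i],
             position = map$position[i], p = p[i])
}
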