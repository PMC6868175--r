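#' Inter-mutation distance series for one chromosome
#'
#' Sorts the SNV positions of one chromosome, collapses duplicates at the
#' same position, and forms consecutive inter-mutation distances together
#' with their log10 transform (the series the segmentation is fitted to).
#'
#' @param chrom Chromosome name.
#' @param positions SNV positions (bp), any order; ties collapsed.
#' @return A list of class `imd_series` with `chrom`, `positions`
#'   (sorted, unique), `imd` (raw bp distances) and `log_imd`.
#' @export
imd_series <- function(chrom, positions) {
  positions <- sort(unique(as.numeric(positions)))
  imd <- diff(positions)
  structure(list(chrom = chrom, positions = positions, imd = imd,
                 log_imd = log10(imd)),
            class = "imd_series")
}

#' Globally optimal piecewise-constant segmentation
#'
#' Fits a piecewise-constant profile with exactly `S = min(max_segments,
#' length(series))` segments to the log10 inter-mutation distances,
#' minimizing the total within-segment sum of squared deviations.  The fit
#' is a layered dynamic program over (point index, segment count) with
#' cumulative-sum cost evaluation and is globally optimal; ties break to
#' the earliest breakpoint.
#'
#' @param series An [imd_series()], or a bare numeric vector.
#' @param max_segments Maximum segment count (>= 1).
#' @return A list with `ends` (right endpoint index of each segment),
#'   `means` (per-segment mean of the fitted values), `cost` (total SSE at
#'   `S` segments) and `cost_by_s` (optimal SSE for 1..S segments,
#'   non-increasing).  An empty list-of-zero-length components when the
#'   series has fewer than one distance (under two SNVs).
#' @export
segment_series <- function(series, max_segments) {
  stopifnot(max_segments >= 1)
  x <- if (inherits(series, "imd_series")) series$log_imd else as.numeric(series)
  if (length(x) < 1) {
    return(list(ends = integer(), means = numeric(), cost = NA_real_,
                cost_by_s = numeric()))
  }
  .dp_segment_cpp(x, as.integer(min(max_segments, length(x))))
}

# Segment count used per chromosome: one segment per five consecutive
# SNVs, capped at 5000.
kataegis_n_segments <- function(n_distances) {
  min(5000L, max(1L, n_distances %/% 5L))
}

#' Call kataegis events in one sample
#'
#' Per chromosome, the log10 inter-mutation distances of the sample's
#' SNVs are segmented into `min(5000, max(1, floor(m/5)))` pieces (m =
#' number of distances).  A segment qualifies as kataegis when its
#' raw-scale mean inter-mutation distance is at most `max_mean_imd` bp
#' and it involves at least `min_snvs` SNVs (member distances + 1).
#' Maximal runs of adjacent segments satisfying the mean-IMD criterion
#' are merged into a single candidate before the SNV-count criterion is
#' applied (`merge = FALSE` scores every segment separately instead);
#' merging first makes the call robust to the segmentation splitting a
#' tight focus across tied zero-cost segments.  A sample with more than
#' `max_events` distinct
#' events genome-wide is treated as globally hypermutated rather than
#' locally: its event list is emptied and the `hypermutated` attribute
#' set.
#'
#' @param sample A [sample_data()] object (only SNVs are used).
#' @param max_mean_imd Mean inter-mutation distance ceiling, bp
#'   (default 2000).
#' @param min_snvs Minimum SNVs per event (default 5).
#' @param max_events Hypermutator guard (default 200, strict: more than
#'   this many events resets the sample to zero).
#' @param merge Merge adjacent qualifying segments (default `TRUE`).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `n_snvs`,
#'   `mean_imd`; attribute `hypermutated` (logical).
#' @export
call_kataegis <- function(sample, max_mean_imd = 2000, min_snvs = 5L,
                          max_events = 200L, merge = TRUE) {
  stopifnot(inherits(sample, "sample_data"))
  snvs <- sample$variants[sample$variants$vclass == "SNV", , drop = FALSE]
  out <- list()
  for (chrom in unique(snvs$chrom)) {
    ser <- imd_series(chrom, snvs$pos[snvs$chrom == chrom])
    m <- length(ser$log_imd)
    if (m < 1) next
    fit <- segment_series(ser, kataegis_n_segments(m))
    starts <- c(1L, head(fit$ends, -1L) + 1L)
    seg_mean <- vapply(seq_along(fit$ends), function(s) {
      mean(ser$imd[starts[s]:fit$ends[s]])
    }, numeric(1))
    seg_n <- fit$ends - starts + 2L  # member distances + 1 SNV
    imd_ok <- seg_mean <= max_mean_imd
    if (!any(imd_ok)) next
    # maximal runs of adjacent IMD-qualifying segments form candidates;
    # the SNV-count criterion applies to the (merged) candidate
    grp <- if (merge) cumsum(c(TRUE, diff(which(imd_ok)) > 1L))
           else seq_along(which(imd_ok))
    for (g in split(which(imd_ok), grp)) {
      a <- starts[g[1]]; b <- fit$ends[g[length(g)]]
      if (b - a + 2L < min_snvs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = ser$positions[a],
        end = ser$positions[b + 1L],
        n_snvs = b - a + 2L,
        mean_imd = mean(ser$imd[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snvs = integer(), mean_imd = numeric(),
               stringsAsFactors = FALSE)
  hyper <- nrow(events) > max_events
  if (hyper) events <- events[0, , drop = FALSE]
  attr(events, "hypermutated") <- hyper
  events
}
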