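#' Chromothripsis calling criteria
#'
#' The five criteria a per-chromosome SV cluster must satisfy to be
#' called a chromothripsis-like event: (a) at least `min_sv`
#' intrachromosomal SVs in the event; (b) a run of at least `min_osc2`
#' copy-number segments oscillating between two states, or `min_osc3`
#' between at most three states; (c) event span at least `min_size_bp`;
#' (d) the four intrachromosomal SV types (DEL, DUP, INV_HH, INV_TT)
#' compatible with an equal distribution (p > `equal_type_p_gt`); (e)
#' breakpoints non-uniformly placed along the chromosome
#' (p <= `nonrandom_p_le`).
#'
#' @param min_sv Minimum intrachromosomal SV count (default 25).
#' @param min_osc2 Minimum 2-state oscillation run (default 7).
#' @param min_osc3 Minimum 3-state oscillation run (default 14).
#' @param min_size_bp Minimum event span (default 20 Mbp).
#' @param equal_type_p_gt Equal-type test threshold (default 0.05).
#' @param nonrandom_p_le Non-random placement threshold (default 0.05).
#' @return A list of class `chromothripsis_criteria`.
#' @export
chromothripsis_criteria <- function(min_sv = 25L, min_osc2 = 7L,
                                    min_osc3 = 14L, min_size_bp = 2e7,
                                    equal_type_p_gt = 0.05,
                                    nonrandom_p_le = 0.05) {
  structure(list(min_sv = as.integer(min_sv),
                 min_osc2 = as.integer(min_osc2),
                 min_osc3 = as.integer(min_osc3),
                 min_size_bp = as.numeric(min_size_bp),
                 equal_type_p_gt = equal_type_p_gt,
                 nonrandom_p_le = nonrandom_p_le),
            class = "chromothripsis_criteria")
}

#' Longest oscillating copy-number runs
#'
#' Over the rounded CN states of one chromosome's consecutive segments
#' (optionally restricted to a region), computes the longest run whose
#' states strictly alternate between exactly two distinct integers
#' (`osc2`), and the longest run in which every adjacent pair differs and
#' at most three distinct states occur (`osc3`).  Run lengths are counted
#' in segments; a single segment is a run of length 1.
#'
#' @param segments Segment `data.frame` for one chromosome, sorted.
#' @param region Optional `c(start, end)`; only overlapping segments are
#'   considered.
#' @return `c(osc2 = ..., osc3 = ...)`.
#' @export
oscillation_runs <- function(segments, region = NULL) {
  segments <- segments[!is_y_chrom(segments$chrom), , drop = FALSE]
  if (length(unique(segments$chrom)) > 1) {
    stop("oscillation_runs expects segments of a single chromosome")
  }
  if (!is.null(region)) {
    keep <- segments$end >= region[1] & segments$start <= region[2]
    segments <- segments[keep, , drop = FALSE]
  }
  st <- segments$cn_round
  n <- length(st)
  if (n == 0L) return(c(osc2 = 0L, osc3 = 0L))
  osc2 <- osc3 <- 1L
  for (i in seq_len(n)) {
    # longest alternating (two-state) run starting at i
    j <- i
    while (j + 1L <= n && st[j + 1L] != st[j] &&
           (j == i || st[j + 1L] == st[j - 1L])) {
      j <- j + 1L
    }
    osc2 <- max(osc2, j - i + 1L)
    # longest <=3-state run with all adjacent pairs distinct starting at i
    j <- i
    while (j + 1L <= n && st[j + 1L] != st[j] &&
           length(unique(st[i:(j + 1L)])) <= 3L) {
      j <- j + 1L
    }
    osc3 <- max(osc3, j - i + 1L)
  }
  c(osc2 = osc2, osc3 = osc3)
}

#' Test of equal distribution of SV types
#'
#' Chi-square goodness of fit of the DEL/DUP/INV_HH/INV_TT counts against
#' equal proportions; when any expected count is below 5 the p-value is
#' computed by Monte-Carlo resampling (1e5 draws).  High p is compatible
#' with the balanced type mixture expected of chromothripsis.
#'
#' @param sv_type_counts Counts over the 4 intrachromosomal classes.
#' @param mc_draws Monte-Carlo draws when expected counts are small.
#' @return p-value.
#' @export
equal_type_test <- function(sv_type_counts, mc_draws = 1e5) {
  x <- as.numeric(sv_type_counts)
  if (sum(x) == 0) stop("equal_type_test needs a non-zero total")
  expected <- sum(x) / length(x)
  if (expected < 5) {
    suppressWarnings(
      chisq.test(x, simulate.p.value = TRUE, B = mc_draws)$p.value)
  } else {
    suppressWarnings(chisq.test(x)$p.value)
  }
}

#' Test of non-random breakpoint placement
#'
#' One-sample two-sided Kolmogorov-Smirnov test of the breakpoint
#' positions against the uniform distribution over the chromosome; a
#' small p-value evidences clustering.
#'
#' @param breakpoints Breakpoint positions (bp); at least 5.
#' @param chrom_length Chromosome length (bp).
#' @return p-value, or `NA` when fewer than 5 breakpoints are supplied
#'   (the criterion then fails).
#' @export
nonrandom_breakpoint_test <- function(breakpoints, chrom_length) {
  bp <- as.numeric(breakpoints)
  if (length(bp) < 5) return(NA_real_)
  # jitter-free exact KS needs distinct points; breakpoints are discrete,
  # ties get the asymptotic statistic
  suppressWarnings(
    ks.test(bp, "punif", 0, chrom_length)$p.value)
}

#' Call chromothripsis-like events
#'
#' Per chromosome carrying intrachromosomal SVs, the candidate region is
#' the breakpoint footprint (min to max breakend of SVs with both ends on
#' the chromosome).  All five criterion statistics are evaluated and
#' reported without short-circuiting; `passed` is their conjunction.
#' Inputs are expected BAF-filtered (SVs) and rounded (CN); the Y
#' chromosome is excluded.
#'
#' @param sample A [sample_data()] object.
#' @param criteria A [chromothripsis_criteria()].
#' @param genome A [genome_spec()] supplying chromosome lengths for the
#'   placement test.
#' @param seed Seed for the Monte-Carlo equal-type p-value.
#' @return `data.frame` with one row per evaluated chromosome: `chrom`,
#'   `start`, `end`, `n_sv`, `osc2_run`, `osc3_run`, the four type
#'   counts, `p_equal_types`, `p_nonrandom`, and `passed`.
#' @export
call_chromothripsis <- function(sample,
                                criteria = chromothripsis_criteria(),
                                genome = mini_genome(), seed = 1L) {
  stopifnot(inherits(sample, "sample_data"))
  svs <- sample$svs
  intra <- svs[svs$svtype %in% c("DEL", "DUP", "INV_HH", "INV_TT") &
                 !is_y_chrom(svs$chrom1), , drop = FALSE]
  segs <- sample$segments[!is_y_chrom(sample$segments$chrom), ,
                          drop = FALSE]
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  rows <- lapply(unique(intra$chrom1), function(chrom) {
    sv <- intra[intra$chrom1 == chrom, , drop = FALSE]
    bp <- c(sv$pos1, sv$pos2)
    region <- c(min(bp), max(bp))
    counts <- vapply(c("DEL", "DUP", "INV_HH", "INV_TT"),
                     function(t) sum(sv$svtype == t), integer(1))
    osc <- oscillation_runs(segs[segs$chrom == chrom, , drop = FALSE],
                            region)
    p_eq <- if (sum(counts) > 0) equal_type_test(counts) else NA_real_
    chrom_len <- genome$chrom_lengths[[chrom]]
    p_nr <- if (!is.null(chrom_len))
      nonrandom_breakpoint_test(bp, chrom_len) else NA_real_
    span <- region[2] - region[1]
    passed <- nrow(sv) >= criteria$min_sv &&
      (osc["osc2"] >= criteria$min_osc2 ||
         osc["osc3"] >= criteria$min_osc3) &&
      span >= criteria$min_size_bp &&
      !is.na(p_eq) && p_eq > criteria$equal_type_p_gt &&
      !is.na(p_nr) && p_nr <= criteria$nonrandom_p_le
    data.frame(chrom = chrom, start = region[1], end = region[2],
               n_sv = nrow(sv),
               osc2_run = unname(osc["osc2"]),
               osc3_run = unname(osc["osc3"]),
               n_del = counts[["DEL"]], n_dup = counts[["DUP"]],
               n_inv_hh = counts[["INV_HH"]],
               n_inv_tt = counts[["INV_TT"]],
               p_equal_types = p_eq, p_nonrandom = p_nr,
               passed = passed, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sv = integer(),
                      osc2_run = integer(), osc3_run = integer(),
                      n_del = integer(), n_dup = integer(),
                      n_inv_hh = integer(), n_inv_tt = integer(),
                      p_equal_types = numeric(), p_nonrandom = numeric(),
                      passed = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
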