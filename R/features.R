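#' SV clustering categories
#'
#' The seven structural-variant categories used in the per-sample feature
#' vector: translocations, inversions (orientation classes merged),
#' insertions, and tandem duplications and deletions each split at
#' 100 kbp.
#' @return Character vector of category labels.
#' @export
sv_categories <- function() {
  c("translocation", "inversion", "insertion",
    "dup_small", "dup_large", "del_small", "del_large")
}

#' Categorize one or more SVs
#'
#' `TRA` maps to translocation, `INS` to insertion, `INV_HH`/`INV_TT`
#' merge into inversion, and `DUP`/`DEL` split on size at `size_cut`
#' (ties at exactly the cut are "small": the split is printed only as
#' strictly larger / smaller than 100 kbp).
#'
#' @param svs SV `data.frame` (or a single-row one).
#' @param size_cut Size threshold in bp (default 100,000).
#' @return Character vector of category labels, one per SV.
#' @export
categorize_sv <- function(svs, size_cut = 1e5) {
  svs <- validate_svs(svs)
  type <- svs$svtype
  out <- character(nrow(svs))
  out[type == "TRA"] <- "translocation"
  out[type == "INS"] <- "insertion"
  out[type %in% c("INV_HH", "INV_TT")] <- "inversion"
  dup <- type == "DUP"; del <- type == "DEL"
  out[dup] <- ifelse(svs$size[dup] > size_cut, "dup_large", "dup_small")
  out[del] <- ifelse(svs$size[del] > size_cut, "del_large", "del_small")
  out
}

#' Length-weighted mean genome-wide ploidy
#'
#' @param segments Segment `data.frame`; Y-chromosome rows are excluded.
#' @return `sum(cn * len) / sum(len)` over the remaining segments.
#' @export
mean_ploidy <- function(segments) {
  segments <- validate_segments(segments)
  segments <- segments[!is_y_chrom(segments$chrom), , drop = FALSE]
  if (!nrow(segments)) stop("mean_ploidy needs at least one non-Y segment")
  len <- segments$end - segments$start + 1
  sum(segments$cn * len) / sum(len)
}

#' Names of the per-sample scar features
#' @param reduced Drop the ploidy and MNV columns (the reduced mode used
#'   when comparing against cohorts lacking those annotations).
#' @return Character vector of feature names.
#' @export
scar_feature_names <- function(reduced = FALSE) {
  base <- c("tmb_snv", "tmb_indel", "tmb_mnv", "mean_ploidy", "n_sv",
            paste0("freq_", sv_categories()))
  if (reduced) setdiff(base, c("tmb_mnv", "mean_ploidy")) else base
}

#' Per-sample genomic-scar feature vector
#'
#' The whole-genome characteristics used for genotype clustering:
#' per-Mbp genome-wide burden of SNVs, InDels and MNVs, length-weighted
#' mean ploidy, total SV count, and the relative frequencies of the seven
#' SV categories (summing to 1; all zero for a sample without SVs).
#'
#' @param sample A [sample_data()] object.
#' @param genome A [genome_spec()] for the TMB denominators.
#' @param size_cut DUP/DEL size split (bp).
#' @return Named numeric vector in [scar_feature_names()] order.
#' @export
scar_features <- function(sample, genome = mini_genome(), size_cut = 1e5) {
  stopifnot(inherits(sample, "sample_data"))
  counts <- count_mutations(sample$variants)
  mb <- genome$callable_genomic_bases / 1e6
  ploidy <- if (nrow(sample$segments)) mean_ploidy(sample$segments)
            else NA_real_
  n_sv <- nrow(sample$svs)
  freqs <- setNames(numeric(length(sv_categories())),
                    paste0("freq_", sv_categories()))
  if (n_sv > 0) {
    tab <- table(factor(categorize_sv(sample$svs, size_cut),
                        levels = sv_categories()))
    freqs[] <- as.numeric(tab) / n_sv
  } else {
    warning(sprintf("sample %s has no SVs; frequency block is all zero",
                    sample$sample_id))
  }
  c(tmb_snv = counts$snv_g / mb, tmb_indel = counts$indel_g / mb,
    tmb_mnv = counts$mnv_g / mb, mean_ploidy = ploidy, n_sv = n_sv,
    freqs)
}

#' Cohort feature matrix
#'
#' Stacks [scar_features()] over a cohort, rows ordered by sample id.
#' In `reduced` mode the ploidy and MNV columns are dropped (for
#' comparisons against cohorts where those are unavailable).
#'
#' @param cohort List of [sample_data()] objects (>= 2).
#' @param genome A [genome_spec()].
#' @param size_cut DUP/DEL size split (bp).
#' @param reduced Drop `tmb_mnv` and `mean_ploidy`.
#' @return Numeric matrix, samples x features, rownames = sample ids.
#' @export
build_feature_matrix <- function(cohort, genome = mini_genome(),
                                 size_cut = 1e5, reduced = FALSE) {
  if (length(cohort) < 2) stop("need >= 2 samples")
  ids <- vapply(cohort, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  cohort <- cohort[order(ids)]
  rows <- t(vapply(cohort, scar_features, numeric(12), genome = genome,
                   size_cut = size_cut))
  rownames(rows) <- sort(ids)
  if (reduced) rows <- rows[, scar_feature_names(reduced = TRUE),
                            drop = FALSE]
  rows
}
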