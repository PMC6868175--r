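#' Heuristic post-filter thresholds
#'
#' Thresholds of the heuristic somatic post-filters.  A small variant is
#' removed when its supporting read count is at or below
#' `max_alt_reads_remove`, or its gnomAD exome (ALL) allele frequency is at
#' or above `gnomad_exome_af`, or its gnomAD genome (ALL) frequency is at
#' or above `gnomad_genome_af`.  Structural variants are kept when their
#' junction BAF is at least `sv_min_baf`.
#'
#' @param max_alt_reads_remove Remove variants with `alt_reads` at or below
#'   this count (default 3).
#' @param gnomad_exome_af Removal cut-off on gnomAD exome AF (default 0.001,
#'   removal at equality).
#' @param gnomad_genome_af Removal cut-off on gnomAD genome AF (default
#'   0.005, removal at equality).
#' @param sv_min_baf Minimum SV junction BAF retained (default 0.1,
#'   retained at equality).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_alt_reads_remove = 3L,
                              gnomad_exome_af = 0.001,
                              gnomad_genome_af = 0.005,
                              sv_min_baf = 0.1) {
  stopifnot(max_alt_reads_remove >= 0,
            gnomad_exome_af >= 0, gnomad_exome_af <= 1,
            gnomad_genome_af >= 0, gnomad_genome_af <= 1,
            sv_min_baf >= 0, sv_min_baf <= 1)
  structure(list(max_alt_reads_remove = as.integer(max_alt_reads_remove),
                 gnomad_exome_af = gnomad_exome_af,
                 gnomad_genome_af = gnomad_genome_af,
                 sv_min_baf = sv_min_baf),
            class = "filter_thresholds")
}

#' Apply the heuristic somatic post-filters
#'
#' Removes small variants supported by too few reads or too common in
#' gnomAD.  Missing gnomAD frequencies are treated as 0 (the variant is
#' retained by the frequency criteria): absence of population evidence
#' must not discard a somatic call.  Missing `alt_reads` likewise does not
#' trigger the read-support criterion.
#'
#' @param variants Variant `data.frame`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `retained` (the surviving rows), `removed` (the
#'   rest) and `report`, a named integer vector counting removals per
#'   criterion (`low_alt_reads`, `gnomad_exome`, `gnomad_genome`,
#'   `removed_total`); a variant failing several criteria counts once per
#'   criterion but is removed once.
#' @export
apply_heuristic_filters <- function(variants,
                                    thresholds = filter_thresholds()) {
  variants <- validate_variants(variants)
  ar <- variants$alt_reads
  ex <- variants$gnomad_exome_af
  wg <- variants$gnomad_genome_af
  ex[is.na(ex)] <- 0
  wg[is.na(wg)] <- 0
  low_reads <- !is.na(ar) & ar <= thresholds$max_alt_reads_remove
  common_ex <- ex >= thresholds$gnomad_exome_af
  common_wg <- wg >= thresholds$gnomad_genome_af
  if (!nrow(variants)) {
    low_reads <- common_ex <- common_wg <- logical()
  }
  drop <- low_reads | common_ex | common_wg
  retained <- variants[!drop, , drop = FALSE]
  removed <- variants[drop, , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained,
       removed = removed,
       report = c(low_alt_reads = sum(low_reads),
                  gnomad_exome = sum(common_ex),
                  gnomad_genome = sum(common_wg),
                  removed_total = sum(drop)))
}

#' Filter structural variants on junction BAF
#'
#' SVs with BAF below the threshold are removed; records with missing BAF
#' are retained (no evidence against them).
#'
#' @param svs SV `data.frame`.
#' @param thresholds A [filter_thresholds()] object.
#' @return The retained SV rows.
#' @export
filter_svs_by_baf <- function(svs, thresholds = filter_thresholds()) {
  svs <- validate_svs(svs)
  keep <- is.na(svs$baf) | svs$baf >= thresholds$sv_min_baf
  svs[keep, , drop = FALSE]
}

# Consequence severity ranking, most deleterious first.  Unknown labels
# rank after every known one.
EFFECT_SEVERITY <- c("nonsense", "frameshift", "splice", "missense",
                     "inframe_indel", "synonymous", "noncoding")

effect_rank <- function(effect) {
  r <- match(effect, EFFECT_SEVERITY)
  r[is.na(r) & !is.na(effect)] <- length(EFFECT_SEVERITY) + 1L
  r
}

#' Most deleterious consequence per gene
#'
#' Per gene overlapping at least one annotated variant, retains the single
#' most deleterious consequence under the severity order
#' nonsense/frameshift > splice > missense/inframe InDel > synonymous >
#' non-coding.  Unknown effect labels rank last, with a warning.
#'
#' @param variants Variant `data.frame` carrying `gene` and `effect`.
#' @return Named character vector, gene to worst effect, sorted by gene.
#' @export
most_deleterious_per_gene <- function(variants) {
  variants <- validate_variants(variants)
  ann <- variants[!is.na(variants$gene) & !is.na(variants$effect), ,
                  drop = FALSE]
  if (!nrow(ann)) return(setNames(character(), character()))
  unknown <- setdiff(unique(ann$effect), EFFECT_SEVERITY)
  if (length(unknown)) {
    warning("unknown effect label(s) ranked last: ",
            paste(unknown, collapse = ", "))
  }
  ranks <- effect_rank(ann$effect)
  picks <- vapply(split(seq_len(nrow(ann)), ann$gene),
                  function(idx) ann$effect[idx[which.min(ranks[idx])]],
                  character(1))
  picks[order(names(picks))]
}
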