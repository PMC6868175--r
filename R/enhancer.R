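#' A gene/enhancer locus pair
#'
#' @param name Pair name (e.g. `"AR"`).
#' @param gene_region,enhancer_region Lists or vectors
#'   `c(chrom, start, end)` (coordinates 1-based inclusive).
#' @return A list of class `locus_pair`.
#' @export
locus_pair <- function(name, gene_region, enhancer_region) {
  as_region <- function(r) {
    list(chrom = as.character(r[[1]]), start = as.numeric(r[[2]]),
         end = as.numeric(r[[3]]))
  }
  g <- as_region(gene_region); e <- as_region(enhancer_region)
  if (g$start > g$end || e$start > e$end) stop("empty region")
  structure(list(name = name, gene = g, enhancer = e),
            class = "locus_pair")
}

#' Default gene/enhancer locus pairs (GRCh37, approximate)
#'
#' AR with its upstream enhancer (~66.13 Mb on chromosome X) and MYC with
#' the PCAT1 enhancer region.  Boundaries are approximate and editable:
#' the packaged table `extdata/locus_pairs.tsv` can be replaced by any
#' TSV with columns `name chrom_gene start_gene end_gene chrom_enh
#' start_enh end_enh`.
#'
#' @param path Optional TSV overriding the packaged table.
#' @return List of [locus_pair()] objects.
#' @export
default_locus_pairs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "locus_pairs.tsv", package = "scarscape")
  }
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    locus_pair(df$name[i],
               c(df$chrom_gene[i], df$start_gene[i], df$end_gene[i]),
               c(df$chrom_enh[i], df$start_enh[i], df$end_enh[i]))
  })
}

#' Copy number of a genomic region
#'
#' The maximum copy-number value over the segments overlapping the
#' region.
#'
#' @param segments Segment `data.frame`.
#' @param region List or vector `c(chrom, start, end)`.
#' @return Maximum `cn`, or `NA` (with a warning) when no segment
#'   overlaps.
#' @export
region_cn <- function(segments, region) {
  if (!is.list(region)) {
    region <- list(chrom = region[[1]], start = as.numeric(region[[2]]),
                   end = as.numeric(region[[3]]))
  }
  hit <- segments$chrom == region$chrom &
    segments$end >= region$start & segments$start <= region$end
  if (!any(hit)) {
    warning(sprintf("no segment overlaps %s:%.0f-%.0f", region$chrom,
                    region$start, region$end))
    return(NA_real_)
  }
  max(segments$cn[hit])
}

#' Classify samples as enhancer- or gene-enriched
#'
#' Per sample, the log2 ratio `r = log2(cn_enhancer) - log2(cn_gene)` is
#' formed; the null model is a strict 1:1 enhancer-to-gene ratio (mean 0,
#' no fitted parameters).  Each sample's ratio is studentized externally:
#' `t_i = r_i / s_(-i)` where `s_(-i)` is the root mean square of the
#' other samples' ratios.  `t > 1` flags enhancer-enriched, `t < -1`
#' gene-enriched, otherwise balanced.
#'
#' @param cohort List of [sample_data()] objects (>= 3 usable).
#' @param pair A [locus_pair()].
#' @return `data.frame` with `sample_id`, `cn_enhancer`, `cn_gene`,
#'   `log2_ratio`, `t`, `category`; samples without overlapping segments
#'   or with zero copy number are excluded with a warning.
#' @export
classify_enhancer_gene <- function(cohort, pair) {
  stopifnot(inherits(pair, "locus_pair"))
  ids <- vapply(cohort, function(s) s$sample_id, character(1))
  cn_e <- vapply(cohort, function(s) region_cn(s$segments, pair$enhancer),
                 numeric(1))
  cn_g <- vapply(cohort, function(s) region_cn(s$segments, pair$gene),
                 numeric(1))
  usable <- !is.na(cn_e) & !is.na(cn_g) & cn_e > 0 & cn_g > 0
  if (any(!usable)) {
    warning(sprintf("excluded %d sample(s) without positive copy number at both loci",
                    sum(!usable)))
  }
  if (sum(usable) < 3) stop("need >= 3 samples with both region CNs > 0")
  r <- log2(cn_e[usable]) - log2(cn_g[usable])
  n <- length(r)
  ss <- sum(r^2)
  # leave-one-out RMS of the other samples' ratios
  s_loo <- sqrt((ss - r^2) / (n - 1L))
  t <- ifelse(r == 0, 0, r / s_loo)
  category <- ifelse(t > 1, "enhancer-enriched",
                     ifelse(t < -1, "gene-enriched", "balanced"))
  data.frame(sample_id = ids[usable], cn_enhancer = cn_e[usable],
             cn_gene = cn_g[usable], log2_ratio = r, t = t,
             category = category, stringsAsFactors = FALSE)
}
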