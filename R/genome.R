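#' Genome specification
#'
#' A genome specification carries the chromosome names and lengths used by
#' the simulator and the per-chromosome stages, together with the two
#' callable-base denominators of the tumor mutational burden formulas:
#' the number of callable (ACTG) nucleotides genome-wide and the summed
#' length of distinct non-overlapping coding regions.
#'
#' The defaults are the hg19 callable constants used throughout:
#' 2,858,674,662 genomic and 28,711,682 coding bases.  Both are
#' overridable, e.g. for a reduced test genome.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param callable_genomic_bases Callable genome-wide bases (denominator of
#'   genomic TMB).
#' @param callable_coding_bases Summed non-overlapping coding bases
#'   (denominator of coding TMB).
#' @return An object of class `genome_spec`.
#' @examples
#' g <- genome_spec(c(chr1 = 1e6), callable_genomic_bases = 1e6)
#' g$callable_coding_bases
#' @export
genome_spec <- function(chrom_lengths = hg19_chrom_lengths(),
                        callable_genomic_bases = 2858674662,
                        callable_coding_bases = 28711682) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(nzchar(names(chrom_lengths))), all(chrom_lengths >= 1))
  if (callable_genomic_bases <= 0 || callable_coding_bases <= 0) {
    stop("callable base counts must be positive")
  }
  structure(
    list(chrom_lengths = chrom_lengths,
         callable_genomic_bases = as.numeric(callable_genomic_bases),
         callable_coding_bases = as.numeric(callable_coding_bases)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %.0f callable genomic bp, %.0f callable coding bp\n",
              length(x$chrom_lengths), x$callable_genomic_bases,
              x$callable_coding_bases))
  invisible(x)
}

#' hg19 chromosome lengths
#'
#' Lengths of the 24 hg19 chromosomes (chr1..chr22, chrX, chrY), in bp.
#' @return Named integer vector.
#' @export
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Miniature three-chromosome genome for simulation and testing
#'
#' A compact genome (three chromosomes of 150, 120 and 100 Mbp) used as the
#' default by the synthetic-cohort generator so that per-sample variant sets
#' stay small.  The TMB denominators are scaled to the miniature genome:
#' the callable genomic fraction and the coding fraction of the full-genome
#' defaults are applied to the reduced total length.
#'
#' @return A `genome_spec`.
#' @export
mini_genome <- function() {
  lens <- c(chr1 = 150e6, chr2 = 120e6, chr3 = 100e6)
  total <- sum(lens)
  full <- 2858674662
  genome_spec(lens,
              callable_genomic_bases = total,
              callable_coding_bases = round(total * 28711682 / full))
}

#' Is a chromosome name the Y chromosome?
#'
#' Copy-number based statistics (ploidy, oscillation runs) exclude the Y
#' chromosome.
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_y_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "Y"
}
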