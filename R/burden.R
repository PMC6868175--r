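#' Per-class mutation counts
#'
#' Genome-wide and coding counts of SNVs, InDels and MNVs, the numerators
#' of the two tumor mutational burden formulas.
#'
#' @param snv_g,indel_g,mnv_g Genome-wide counts.
#' @param snv_c,indel_c,mnv_c Coding counts (each at most its genome-wide
#'   counterpart).
#' @return A list of class `mutation_counts`.
#' @export
mutation_counts <- function(snv_g = 0L, indel_g = 0L, mnv_g = 0L,
                            snv_c = 0L, indel_c = 0L, mnv_c = 0L) {
  vals <- c(snv_g = snv_g, indel_g = indel_g, mnv_g = mnv_g,
            snv_c = snv_c, indel_c = indel_c, mnv_c = mnv_c)
  if (any(vals < 0)) stop("mutation counts must be >= 0")
  if (snv_c > snv_g || indel_c > indel_g || mnv_c > mnv_g) {
    stop("coding counts cannot exceed genome-wide counts")
  }
  structure(as.list(vals), class = "mutation_counts")
}

#' Count mutations in a variant table
#'
#' @param variants Variant `data.frame`; rows with `coding = TRUE`
#'   contribute to the coding counts.
#' @return A [mutation_counts()] object.
#' @export
count_mutations <- function(variants) {
  variants <- validate_variants(variants)
  cls <- variants$vclass
  coding <- !is.na(variants$coding) & variants$coding
  mutation_counts(
    snv_g = sum(cls == "SNV"), indel_g = sum(cls == "InDel"),
    mnv_g = sum(cls == "MNV"),
    snv_c = sum(cls == "SNV" & coding),
    indel_c = sum(cls == "InDel" & coding),
    mnv_c = sum(cls == "MNV" & coding))
}

#' Tumor mutational burden (mutations per Mbp)
#'
#' Genomic TMB is the total genome-wide count of SNVs, MNVs and InDels
#' divided by the callable genome length in Mbp; coding TMB is the coding
#' analogue with the summed non-overlapping coding length.  TMB is linear
#' in the counts.
#'
#' @param counts A [mutation_counts()] object.
#' @param genome A [genome_spec()] supplying the callable denominators.
#' @param scope `"genomic"` or `"coding"`.
#' @return Mutations per Mbp (numeric scalar).
#' @examples
#' tmb(mutation_counts(snv_g = 6621, indel_g = 1008, mnv_g = 55))
#' @export
tmb <- function(counts, genome = genome_spec(),
                scope = c("genomic", "coding")) {
  scope <- match.arg(scope)
  stopifnot(inherits(counts, "mutation_counts"))
  if (scope == "genomic") {
    (counts$snv_g + counts$mnv_g + counts$indel_g) /
      (genome$callable_genomic_bases / 1e6)
  } else {
    (counts$snv_c + counts$mnv_c + counts$indel_c) /
      (genome$callable_coding_bases / 1e6)
  }
}

# Count of genomic InDels that qualify for the MSI rule: event length
# <= 50 bp and either a repeat unit of 2-4 bp repeated >= 4 times, or a
# homopolymer (unit 1 bp) repeated >= 5 times.
msi_qualifying <- function(variants) {
  indel <- variants[variants$vclass == "InDel", , drop = FALSE]
  if (!nrow(indel)) return(0L)
  ul <- indel$repeat_unit_len
  rc <- indel$repeat_count
  if (anyNA(ul) || anyNA(rc)) {
    stop("InDels lack repeat annotations (repeat_unit_len/repeat_count); ",
         "annotate them or supply a reference via annotate_repeats()")
  }
  qual <- (ul >= 2L & ul <= 4L & rc >= 4L) | (ul == 1L & rc >= 5L)
  sum(qual)
}

#' Classify microsatellite instability from genomic InDels
#'
#' A sample is called MSI when it carries more than `threshold` qualifying
#' genomic InDels.  An InDel qualifies when its event length is at most
#' 50 bp and it sits in a tandem repeat with unit length 2-4 bp repeated
#' at least 4 times, or in a homopolymer (unit length 1) repeated at least
#' 5 times.  Repeat annotations (`repeat_unit_len`, `repeat_count`) must be
#' present on the InDel rows; [annotate_repeats()] computes them from a
#' reference sequence.
#'
#' @param variants Variant `data.frame`.
#' @param threshold Qualifying-InDel count above which the sample is MSI
#'   (default 11,436; the call is strict: a count equal to the threshold
#'   is microsatellite-stable).
#' @return A list of class `msi_call` with `qualifying_indels`, `is_msi`
#'   and `threshold`.
#' @export
classify_msi <- function(variants, threshold = 11436L) {
  variants <- validate_variants(variants)
  q <- msi_qualifying(variants)
  structure(list(qualifying_indels = q,
                 is_msi = q > threshold,
                 threshold = as.integer(threshold)),
            class = "msi_call")
}

#' @export
print.msi_call <- function(x, ...) {
  cat(sprintf("<msi_call> %d qualifying InDels (threshold %d): %s\n",
              x$qualifying_indels, x$threshold,
              if (x$is_msi) "MSI" else "MSS"))
  invisible(x)
}

#' Annotate InDels with tandem-repeat context from a reference
#'
#' For each InDel, takes the inserted or deleted unit and extends it by
#' maximal perfect tandem repetition to the left and right of the event on
#' the reference sequence; `repeat_unit_len` is the unit length and
#' `repeat_count` the total number of adjacent unit copies (including the
#' event's own copy for insertions).
#'
#' @param variants Variant `data.frame`.
#' @param ref_seqs Named character vector (or list) of chromosome
#'   sequences.
#' @return The variant table with `repeat_unit_len`/`repeat_count` filled
#'   on InDel rows.
#' @export
annotate_repeats <- function(variants, ref_seqs) {
  variants <- validate_variants(variants)
  idx <- which(variants$vclass == "InDel")
  for (i in idx) {
    chrom <- variants$chrom[i]
    if (is.null(ref_seqs[[chrom]])) next
    seq <- ref_seqs[[chrom]]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    # unit: the inserted (alt longer) or deleted (ref longer) bases after
    # the shared anchor base
    unit <- if (nchar(alt) > nchar(ref)) substring(alt, nchar(ref) + 1L)
            else substring(ref, nchar(alt) + 1L)
    k <- nchar(unit)
    if (k == 0L) next
    # position just after the anchor base on the reference
    at <- variants$pos[i] + 1L
    count <- 0L
    p <- at
    while (p + k - 1L <= nchar(seq) && substring(seq, p, p + k - 1L) == unit) {
      count <- count + 1L
      p <- p + k
    }
    p <- at - k
    while (p >= 1L && substring(seq, p, p + k - 1L) == unit) {
      count <- count + 1L
      p <- p - k
    }
    if (nchar(alt) > nchar(ref)) count <- count + 1L  # the inserted copy
    variants$repeat_unit_len[i] <- k
    variants$repeat_count[i] <- count
  }
  variants
}

#' Correlate per-class mutation counts with tumor purity
#'
#' Spearman correlation of the absolute SNV, InDel, MNV and SV counts
#' against the in-silico estimated tumor cell fraction, across the
#' samples of a cohort.
#'
#' @param cohort List of [sample_data()] objects (at least 3 with
#'   non-missing purity).
#' @return `data.frame` with columns `class`, `n`, `rho`, `p`; `rho` and
#'   `p` are `NA` when the correlation is undefined (e.g. all counts
#'   tied).
#' @export
purity_burden_correlation <- function(cohort) {
  purity <- vapply(cohort, function(s) s$purity, numeric(1))
  keep <- !is.na(purity)
  if (sum(keep) < 3) stop("need >= 3 samples with purity")
  cohort <- cohort[keep]; purity <- purity[keep]
  counts <- list(
    SNV = vapply(cohort, function(s) sum(s$variants$vclass == "SNV"),
                 numeric(1)),
    InDel = vapply(cohort, function(s) sum(s$variants$vclass == "InDel"),
                   numeric(1)),
    MNV = vapply(cohort, function(s) sum(s$variants$vclass == "MNV"),
                 numeric(1)),
    SV = vapply(cohort, function(s) nrow(s$svs), numeric(1)))
  rows <- lapply(names(counts), function(cls) {
    x <- counts[[cls]]
    if (sd(x) == 0 || sd(purity) == 0) {
      return(data.frame(class = cls, n = length(x), rho = NA_real_,
                        p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, purity, method = "spearman",
                                    alternative = "two.sided", exact = FALSE))
    data.frame(class = cls, n = length(x), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}
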