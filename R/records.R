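#' @useDynLib scarscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist as.hclust chisq.test cophenetic cor cor.test
#'   cutree fisher.test hclust ks.test median p.adjust prcomp quantile
#'   rbinom rnbinom rnorm rpois runif sd setNames wilcox.test rlnorm
#' @importFrom utils read.delim write.table head tail packageVersion
"_PACKAGE"

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "vclass", "alt_reads",
                  "gnomad_exome_af", "gnomad_genome_af", "trinucleotide",
                  "coding", "gene", "effect", "repeat_unit_len",
                  "repeat_count")

SV_COLS <- c("svtype", "chrom1", "pos1", "chrom2", "pos2", "baf", "size")

SEG_COLS <- c("chrom", "start", "end", "cn", "cn_round")

SV_TYPES <- c("TRA", "INV_HH", "INV_TT", "DUP", "DEL", "INS")

# Maximum InDel length accepted by the somatic catalog (50 bp event, i.e.
# max(len(ref), len(alt)) <= 51 with the shared anchor base).
INDEL_MAX_LEN <- 51L

#' Classify a ref/alt allele pair
#'
#' Equal-length single-base substitutions are SNVs, equal-length multi-base
#' substitutions are MNVs, and length-changing events are InDels.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector with values `"SNV"`, `"MNV"` or `"InDel"`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr != la, "InDel", ifelse(lr == 1L, "SNV", "MNV"))
}

#' Build a somatic small-variant table
#'
#' Assembles and validates the canonical variant table used by every
#' downstream stage.  One row per ALT allele.  Optional annotation columns
#' default to `NA` (absent): population allele frequencies, trinucleotide
#' context (SNVs only, pyrimidine-normalized), gene/effect annotation and
#' the InDel repeat annotation (`repeat_unit_len`, `repeat_count`).
#'
#' @param chrom,pos,ref,alt Required core fields; `pos` is 1-based.
#' @param alt_reads Supporting read count (default `NA`).
#' @param gnomad_exome_af,gnomad_genome_af Population allele fractions.
#' @param trinucleotide 3-mer pyrimidine-strand context, e.g. `"ACA"`.
#' @param coding Logical: overlaps coding sequence.
#' @param gene,effect Gene symbol and coding consequence.
#' @param repeat_unit_len,repeat_count InDel tandem-repeat annotation.
#' @return A `data.frame` with the documented columns, `vclass` derived
#'   from the allele lengths.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          alt_reads = NA_integer_,
                          gnomad_exome_af = NA_real_,
                          gnomad_genome_af = NA_real_,
                          trinucleotide = NA_character_,
                          coding = NA, gene = NA_character_,
                          effect = NA_character_,
                          repeat_unit_len = NA_integer_,
                          repeat_count = NA_integer_) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    vclass = if (n) variant_class(ref, alt) else character(),
    alt_reads = rep_len(as.integer(alt_reads), n),
    gnomad_exome_af = rep_len(as.numeric(gnomad_exome_af), n),
    gnomad_genome_af = rep_len(as.numeric(gnomad_genome_af), n),
    trinucleotide = rep_len(as.character(trinucleotide), n),
    coding = rep_len(as.logical(coding), n),
    gene = rep_len(as.character(gene), n),
    effect = rep_len(as.character(effect), n),
    repeat_unit_len = rep_len(as.integer(repeat_unit_len), n),
    repeat_count = rep_len(as.integer(repeat_count), n),
    stringsAsFactors = FALSE)
  validate_variants(df)
}

validate_variants <- function(df) {
  stopifnot(all(VARIANT_COLS %in% names(df)))
  df <- df[VARIANT_COLS]
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("variant positions must be >= 1")
    bad_reads <- !is.na(df$alt_reads) & df$alt_reads < 0L
    if (any(bad_reads)) stop("alt_reads must be >= 0")
    indel <- df$vclass == "InDel"
    too_long <- indel & pmax(nchar(df$ref), nchar(df$alt)) > INDEL_MAX_LEN
    if (any(too_long)) {
      warning(sprintf("rejected %d InDel(s) longer than 50 bp", sum(too_long)))
      df <- df[!too_long, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Build a structural-variant table
#'
#' One row per SV junction.  Types: `TRA` (interchromosomal translocation),
#' `INV_HH`/`INV_TT` (head-to-head and tail-to-tail inversion breakends),
#' `DUP` (tandem duplication), `DEL` (deletion), `INS` (insertion).
#' `size` is `|pos2 - pos1|` for intrachromosomal records and `NA` for
#' translocations.
#'
#' @param svtype Character vector of SV types.
#' @param chrom1,pos1,chrom2,pos2 Breakend coordinates, 1-based.
#' @param baf Variant allele fraction of the junction (`NA` allowed).
#' @return A validated `data.frame`.
#' @export
sv_table <- function(svtype = character(), chrom1 = character(),
                     pos1 = integer(), chrom2 = character(),
                     pos2 = integer(), baf = NA_real_) {
  n <- length(svtype)
  df <- data.frame(
    svtype = as.character(svtype),
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
    baf = rep_len(as.numeric(baf), n),
    stringsAsFactors = FALSE)
  df$size <- ifelse(df$chrom1 == df$chrom2, abs(df$pos2 - df$pos1),
                    NA_integer_)
  validate_svs(df)
}

validate_svs <- function(df) {
  stopifnot(all(SV_COLS %in% names(df)))
  df <- df[SV_COLS]
  if (nrow(df)) {
    unknown <- !df$svtype %in% SV_TYPES
    if (any(unknown)) {
      stop("unknown svtype(s): ", paste(unique(df$svtype[unknown]),
                                        collapse = ", "))
    }
    inter <- df$chrom1 != df$chrom2
    if (any(df$svtype == "TRA" & !inter)) {
      stop("TRA records must have chrom1 != chrom2")
    }
    if (any(df$svtype != "TRA" & inter)) {
      stop("intrachromosomal SV types require chrom1 == chrom2")
    }
    bad_size <- df$svtype != "TRA" & (is.na(df$size) | df$size < 1L)
    if (any(bad_size)) stop("intrachromosomal SVs must have size >= 1")
    df$size[df$svtype == "TRA"] <- NA_integer_
  }
  rownames(df) <- NULL
  df
}

#' Round a copy number to its integer state
#'
#' Banker's rounding (ties to even), matching the rounded absolute
#' copy-number states used by the chromothripsis caller.
#' @param cn Numeric vector of absolute copy numbers.
#' @return Integer vector.
#' @export
round_cn <- function(cn) as.integer(round(cn))

#' Build an absolute copy-number segment table
#'
#' Segments are 1-based inclusive.  `cn_round` is the nearest-integer state
#' (ties to even).  Rows are sorted by (chrom, start).
#'
#' @param chrom,start,end Segment coordinates.
#' @param cn Absolute total copy number (non-negative real).
#' @return A validated, sorted `data.frame`.
#' @export
cn_table <- function(chrom = character(), start = integer(),
                     end = integer(), cn = numeric()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   cn = as.numeric(cn), stringsAsFactors = FALSE)
  df$cn_round <- round_cn(df$cn)
  validate_segments(df)
}

validate_segments <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(df)))
  if (is.null(df$cn_round)) df$cn_round <- round_cn(df$cn)
  df <- df[SEG_COLS]
  if (nrow(df)) {
    if (any(df$start > df$end)) stop("segment start must be <= end")
    if (any(df$cn < 0)) stop("copy number must be >= 0")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    ov <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
      if (length(idx) < 2) return(integer())
      s <- df$start[idx]; e <- df$end[idx]
      idx[which(s[-1] <= e[-length(e)]) + 1L]
    }))
    if (length(ov)) {
      stop("overlapping segments on one chromosome at rows: ",
           paste(sort(ov), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Bundle one sample's somatic catalogs
#'
#' @param sample_id Unique sample identifier.
#' @param variants Variant table (see [variant_table()]).
#' @param svs SV table (see [sv_table()]).
#' @param segments Copy-number segment table (see [cn_table()]).
#' @param purity In-silico tumor cell fraction in (0, 1], or `NA`.
#' @param chord_score Externally supplied HR-deficiency score in [0, 1],
#'   or `NA` (consumed, never computed here).
#' @param metadata Named list of sample annotations (biopsy site,
#'   treatment group, ...).
#' @return An object of class `sample_data`.
#' @export
sample_data <- function(sample_id, variants = variant_table(),
                        svs = sv_table(), segments = cn_table(),
                        purity = NA_real_, chord_score = NA_real_,
                        metadata = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            nzchar(sample_id))
  if (!is.na(purity) && (purity <= 0 || purity > 1)) {
    stop("purity must be in (0, 1]")
  }
  if (!is.na(chord_score) && (chord_score < 0 || chord_score > 1)) {
    stop("chord_score must be in [0, 1]")
  }
  structure(list(sample_id = sample_id,
                 variants = validate_variants(variants),
                 svs = validate_svs(svs),
                 segments = validate_segments(segments),
                 purity = purity, chord_score = chord_score,
                 metadata = metadata),
            class = "sample_data")
}

#' @export
print.sample_data <- function(x, ...) {
  cat(sprintf("<sample_data> %s: %d variants, %d SVs, %d CN segments\n",
              x$sample_id, nrow(x$variants), nrow(x$svs), nrow(x$segments)))
  invisible(x)
}
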