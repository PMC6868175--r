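# Readers/writers for the plain-text interchange formats (TSV variant
# table, VCF, SEG, BEDPE).  All writers emit a header line; gzip is
# supported transparently (reading any .gz, writing when the path ends in
# .gz).

out_conn <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

write_tsv <- function(df, path) {
  con <- out_conn(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

read_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", "."),
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s %s lacks required column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
  }
  df
}

coerce_col <- function(x, fn, col, path) {
  out <- suppressWarnings(fn(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    # +1 for the header line
    stop(sprintf("malformed %s in %s at line %d", col, path, bad[1] + 1L))
  }
  out
}

warn_unknown_chroms <- function(chrom, genome) {
  if (is.null(genome)) return(invisible())
  unknown <- setdiff(unique(chrom), names(genome$chrom_lengths))
  if (length(unknown)) {
    warning("unknown chromosome(s) kept: ", paste(unknown, collapse = ", "))
  }
  invisible()
}

#' Read a somatic small-variant catalog
#'
#' Reads either the package's tab-separated variant table (columns
#' `chrom pos ref alt` plus any of the optional annotation columns of
#' [variant_table()]) or a VCF 4.x file.  For VCF input, per-variant
#' annotations are taken from INFO keys `ALT_READS`, `GNOMAD_EX`,
#' `GNOMAD_WG`, `TNC`, `CODING`, `GENE`, `EFFECT`, `REP_UL` and `REP_CT`;
#' multi-allelic records are split into one row per ALT allele.
#'
#' `vclass` is always rederived from the allele lengths; InDels longer
#' than 50 bp are rejected with a warning giving their count.  If a
#' `genome` is supplied, records on chromosomes it does not know are kept
#' with a warning.
#'
#' @param path File path (`.gz` allowed).
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @param genome Optional [genome_spec()] used to flag unknown chromosomes.
#' @return A validated variant `data.frame`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") return(read_variants_vcf(path, genome))
  df <- read_tsv(path, c("chrom", "pos", "ref", "alt"), "variant table")
  n <- nrow(df)
  get <- function(col, fn, default) {
    if (col %in% names(df)) coerce_col(df[[col]], fn, col, path)
    else rep(default, n)
  }
  out <- data.frame(
    chrom = as.character(df$chrom),
    pos = coerce_col(df$pos, as.integer, "pos", path),
    ref = as.character(df$ref), alt = as.character(df$alt),
    stringsAsFactors = FALSE)
  out$vclass <- if (n) variant_class(out$ref, out$alt) else character()
  out$alt_reads <- get("alt_reads", as.integer, NA_integer_)
  out$gnomad_exome_af <- get("gnomad_exome_af", as.numeric, NA_real_)
  out$gnomad_genome_af <- get("gnomad_genome_af", as.numeric, NA_real_)
  out$trinucleotide <- if ("trinucleotide" %in% names(df))
    as.character(df$trinucleotide) else rep(NA_character_, n)
  out$coding <- get("coding", as.logical, NA)
  out$gene <- if ("gene" %in% names(df)) as.character(df$gene)
    else rep(NA_character_, n)
  out$effect <- if ("effect" %in% names(df)) as.character(df$effect)
    else rep(NA_character_, n)
  out$repeat_unit_len <- get("repeat_unit_len", as.integer, NA_integer_)
  out$repeat_count <- get("repeat_count", as.integer, NA_integer_)
  warn_unknown_chroms(out$chrom, genome)
  validate_variants(out)
}

info_field <- function(info, key) {
  m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
  out <- rep(NA_character_, length(info))
  hit <- m > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
  out
}

read_variants_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(variant_table())
  # split multi-allelic ALT into one row per allele
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  info <- fix$INFO[idx]
  num <- function(key) suppressWarnings(as.numeric(info_field(info, key)))
  int <- function(key) suppressWarnings(as.integer(info_field(info, key)))
  out <- data.frame(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    stringsAsFactors = FALSE)
  out$vclass <- variant_class(out$ref, out$alt)
  out$alt_reads <- int("ALT_READS")
  out$gnomad_exome_af <- num("GNOMAD_EX")
  out$gnomad_genome_af <- num("GNOMAD_WG")
  out$trinucleotide <- info_field(info, "TNC")
  out$coding <- !is.na(info_field(info, "CODING")) &
    info_field(info, "CODING") %in% c("1", "TRUE", "true")
  out$gene <- info_field(info, "GENE")
  out$effect <- info_field(info, "EFFECT")
  out$repeat_unit_len <- int("REP_UL")
  out$repeat_count <- int("REP_CT")
  warn_unknown_chroms(out$chrom, genome)
  validate_variants(out)
}

#' Write a variant table to TSV
#' @param variants Variant `data.frame`.
#' @param path Output path (`.gz` for gzip).
#' @return The path, invisibly.
#' @export
write_variants <- function(variants, path) {
  write_tsv(validate_variants(variants), path)
}

#' Read absolute copy-number segments (SEG/TSV)
#'
#' Expects columns `chrom`, `start`, `end`, `cn` (1-based inclusive
#' coordinates).  Rows are sorted by (chrom, start), `cn_round` is
#' populated (ties to even) and overlapping segments on one chromosome
#' raise an error listing the offending rows.
#'
#' @param path File path.
#' @return A validated segment `data.frame`.  Y-chromosome rows are kept
#'   here; downstream CN statistics exclude them.
#' @export
read_cn_segments <- function(path) {
  df <- read_tsv(path, c("chrom", "start", "end", "cn"), "SEG file")
  out <- data.frame(
    chrom = as.character(df$chrom),
    start = coerce_col(df$start, as.numeric, "start", path),
    end = coerce_col(df$end, as.numeric, "end", path),
    cn = coerce_col(df$cn, as.numeric, "cn", path),
    stringsAsFactors = FALSE)
  validate_segments(out)
}

#' Write copy-number segments to SEG/TSV
#' @param segments Segment `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cn_segments <- function(segments, path) {
  write_tsv(validate_segments(segments), path)
}

#' Read structural variants (BEDPE or TSV)
#'
#' BEDPE input (`chrom1 start1 end1 chrom2 start2 end2 name score strand1
#' strand2` with a `type` column and optionally `baf`) is converted from
#' half-open 0-based starts to the internal 1-based breakend positions
#' (`pos = start + 1`).  Inversions are split by orientation: strands
#' `+/+` give `INV_HH`, `-/-` give `INV_TT` (an explicit `INV_HH`/`INV_TT`
#' type is also accepted).  A TSV with the internal columns
#' (`svtype chrom1 pos1 chrom2 pos2 baf`) is read as-is.
#'
#' @param path File path.
#' @return A validated SV `data.frame`.
#' @export
read_svs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  probe <- read.delim(path, sep = "\t", header = TRUE, nrows = 1,
                      stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("svtype", "pos1", "pos2") %in% names(probe))) {
    df <- read_tsv(path, c("svtype", "chrom1", "pos1", "chrom2", "pos2"),
                   "SV table")
    out <- data.frame(
      svtype = as.character(df$svtype),
      chrom1 = as.character(df$chrom1),
      pos1 = coerce_col(df$pos1, as.integer, "pos1", path),
      chrom2 = as.character(df$chrom2),
      pos2 = coerce_col(df$pos2, as.integer, "pos2", path),
      baf = if ("baf" %in% names(df))
        coerce_col(df$baf, as.numeric, "baf", path) else NA_real_,
      stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path, c("chrom1", "start1", "chrom2", "start2", "type"),
                   "BEDPE file")
    type <- toupper(as.character(df$type))
    s1 <- if ("strand1" %in% names(df)) as.character(df$strand1) else NA
    s2 <- if ("strand2" %in% names(df)) as.character(df$strand2) else NA
    inv <- type == "INV"
    type[inv & s1 == "+" & s2 == "+"] <- "INV_HH"
    type[inv & s1 == "-" & s2 == "-"] <- "INV_TT"
    if (any(type == "INV")) {
      stop("INV records need strand orientation (+/+ or -/-) or an ",
           "explicit INV_HH/INV_TT type")
    }
    out <- data.frame(
      svtype = type,
      chrom1 = as.character(df$chrom1),
      pos1 = coerce_col(df$start1, as.integer, "start1", path) + 1L,
      chrom2 = as.character(df$chrom2),
      pos2 = coerce_col(df$start2, as.integer, "start2", path) + 1L,
      baf = if ("baf" %in% names(df))
        coerce_col(df$baf, as.numeric, "baf", path) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out$size <- ifelse(out$chrom1 == out$chrom2, abs(out$pos2 - out$pos1),
                     NA_integer_)
  validate_svs(out)
}

#' Write structural variants as BEDPE
#'
#' Emits 0-based half-open breakend intervals of width 1, a `type` column
#' (`INV_HH`/`INV_TT` encoded via the strand columns as `INV` `+/+` and
#' `-/-`), and `baf`.  [read_svs()] inverts this exactly.
#'
#' @param svs SV `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_svs_bedpe <- function(svs, path) {
  svs <- validate_svs(svs)
  strand1 <- ifelse(svs$svtype == "INV_TT", "-", "+")
  strand2 <- ifelse(svs$svtype == "INV_HH", "+",
                    ifelse(svs$svtype == "INV_TT", "-", "."))
  type <- ifelse(svs$svtype %in% c("INV_HH", "INV_TT"), "INV", svs$svtype)
  bed <- data.frame(
    chrom1 = svs$chrom1, start1 = svs$pos1 - 1L, end1 = svs$pos1,
    chrom2 = svs$chrom2, start2 = svs$pos2 - 1L, end2 = svs$pos2,
    name = sprintf("sv%d", seq_len(nrow(svs))), score = ".",
    strand1 = strand1, strand2 = strand2,
    type = type, baf = svs$baf, stringsAsFactors = FALSE)
  write_tsv(bed, path)
}
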