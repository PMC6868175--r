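test_that("variant classes follow allele lengths and long InDels are rejected", {
  expect_equal(variant_class("A", "T"), "SNV")
  expect_equal(variant_class("AT", "GC"), "MNV")
  expect_equal(variant_class("A", "AT"), "InDel")
  long_alt <- paste(rep("A", 60), collapse = "")
  expect_warning(
    v <- variant_table(chrom = c("chr1", "chr1"), pos = c(100L, 200L),
                       ref = c("A", "A"), alt = c("AT", long_alt)),
    "50 bp")
  expect_equal(nrow(v), 1L)
  expect_equal(v$vclass, "InDel")
})

test_that("copy-number states round ties to even and segments sort", {
  expect_equal(round_cn(c(2.0, 2.5, 3.5, 1.4)), c(2L, 2L, 4L, 1L))
  seg <- cn_table(chrom = c("chr2", "chr1", "chr1"),
                  start = c(5e6, 2e6, 1e5), end = c(6e6, 3e6, 1e6),
                  cn = c(2.5, 3.1, 2.0))
  expect_equal(seg$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(seg$start, c(1e5, 2e6, 5e6))
  expect_equal(seg$cn_round, c(2L, 3L, 2L))
  expect_error(
    cn_table(chrom = c("chr1", "chr1"), start = c(1, 500),
             end = c(1000, 900), cn = c(2, 3)),
    "overlapping")
})

test_that("SV records derive size and enforce the TRA contract", {
  sv <- sv_table(svtype = "DEL", chrom1 = "chr1", pos1 = 1000000L,
                 chrom2 = "chr1", pos2 = 1050000L)
  expect_equal(sv$size, 50000L)
  tra <- sv_table(svtype = "TRA", chrom1 = "chr1", pos1 = 100L,
                  chrom2 = "chr5", pos2 = 200L)
  expect_true(is.na(tra$size))
  expect_error(
    sv_table(svtype = "TRA", chrom1 = "chr1", pos1 = 1L,
             chrom2 = "chr1", pos2 = 2L),
    "chrom1 != chrom2")
})

test_that("variant TSV round trip is lossless, including gzip", {
  set.seed(11)
  n <- 50
  v <- variant_table(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample.int(1e6, n), ref = rep("C", n),
    alt = sample(c("A", "T", "G"), n, TRUE),
    alt_reads = sample.int(60, n),
    gnomad_exome_af = ifelse(runif(n) < 0.3, NA, runif(n, 0, 1e-3)),
    gnomad_genome_af = NA_real_,
    trinucleotide = sample(c("ACA", "TCT", NA), n, TRUE),
    coding = runif(n) < 0.1,
    gene = sample(c("TP53", NA), n, TRUE),
    effect = sample(c("missense", NA), n, TRUE),
    repeat_unit_len = NA_integer_, repeat_count = NA_integer_)
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_variants(v, path)
    expect_equal(read_variants(path), v)
  }
})

test_that("empty variant table with valid header reads as empty", {
  path <- tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt", path)
  v <- read_variants(path)
  expect_equal(nrow(v), 0L)
})

test_that("malformed rows and unknown chromosomes are reported", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tT",
               "chr1\toops\tA\tG"), path)
  expect_error(read_variants(path), "line 3")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chrUn\t100\tA\tT"), path2)
  expect_warning(v <- read_variants(path2, genome = test_genome()),
                 "unknown chromosome")
  expect_equal(nrow(v), 1L)
})

test_that("SEG round trip preserves segments and shuffled input sorts", {
  set.seed(12)
  seg <- rand_segments(20)
  path <- tempfile(fileext = ".seg")
  write_cn_segments(seg[sample.int(20), ], path)
  expect_equal(read_cn_segments(path), seg)
})

test_that("BEDPE round trip is exactly invertible, orientations included", {
  set.seed(13)
  n <- 20
  types <- c(rep("DEL", 4), rep("DUP", 4), rep("INV_HH", 4),
             rep("INV_TT", 4), rep("INS", 2), rep("TRA", 2))
  p1 <- sample.int(1e7, n)
  sv <- sv_table(svtype = types,
                 chrom1 = "chr1", pos1 = p1,
                 chrom2 = ifelse(types == "TRA", "chr2", "chr1"),
                 pos2 = ifelse(types == "TRA", sample.int(1e7, n),
                               p1 + sample.int(1e5, n)),
                 baf = round(runif(n), 3))
  path <- tempfile(fileext = ".bedpe")
  write_svs_bedpe(sv, path)
  back <- read_svs(path)
  expect_equal(back[order(back$pos1), ], sv[order(sv$pos1), ],
               ignore_attr = TRUE)
})

test_that("VCF input maps INFO annotations onto the variant table", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ALT_READS,Number=1,Type=Integer,Description=\"alt\">",
    "##INFO=<ID=GNOMAD_EX,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"ctx\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\t.\tC\tT\t.\tPASS\tALT_READS=12;GNOMAD_EX=0.0002;TNC=ACA",
    "chr2\t2000\t.\tG\tA,C\t.\tPASS\tALT_READS=7"), path)
  v <- read_variants(path, format = "vcf")
  expect_equal(nrow(v), 3L)  # multi-allelic split
  expect_equal(v$alt_reads, c(12L, 7L, 7L))
  expect_equal(v$gnomad_exome_af, c(2e-4, NA, NA))
  expect_equal(v$trinucleotide, c("ACA", NA, NA))
  expect_equal(v$vclass, rep("SNV", 3))
})
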