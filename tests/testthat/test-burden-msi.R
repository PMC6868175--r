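test_that("TMB follows the callable-base formulas and is linear in counts", {
  expect_equal(tmb(mutation_counts()), 0)
  c1 <- mutation_counts(snv_g = 100, indel_g = 50, mnv_g = 10,
                        snv_c = 20, indel_c = 5, mnv_c = 1)
  g <- genome_spec()
  expect_equal(tmb(c1, g, "genomic"), 160 / (2858674662 / 1e6))
  expect_equal(tmb(c1, g, "coding"), 26 / (28711682 / 1e6))
  c2 <- mutation_counts(snv_g = 200, indel_g = 100, mnv_g = 20,
                        snv_c = 40, indel_c = 10, mnv_c = 2)
  expect_equal(tmb(c2, g, "genomic"), 2 * tmb(c1, g, "genomic"))
  expect_equal(tmb(c2, g, "coding"), 2 * tmb(c1, g, "coding"))
  # denominators are overridable
  g2 <- genome_spec(c(chr1 = 1e6), callable_genomic_bases = 1e6,
                    callable_coding_bases = 5e5)
  expect_equal(tmb(c1, g2, "genomic"), 160)
  expect_equal(tmb(c1, g2, "coding"), 52)
})

test_that("the cohort-median worked example lands on the printed TMB", {
  counts <- mutation_counts(snv_g = 6621, indel_g = 1008, mnv_g = 55)
  expect_equal(round(tmb(counts, genome_spec(), "genomic"), 1), 2.7)
})

test_that("MSI call is strict at the threshold and monotone", {
  expect_false(classify_msi(qualifying_indels(11436))$is_msi)
  expect_true(classify_msi(qualifying_indels(11437))$is_msi)
  expect_false(classify_msi(variant_table())$is_msi)
  expect_equal(classify_msi(qualifying_indels(500))$qualifying_indels,
               500L)
})

test_that("the qualifying-InDel rule needs unit 2-4 x4 or homopolymer x5", {
  mk <- function(ul, rc) {
    variant_table(chrom = "chr1", pos = 100L, ref = "A", alt = "AT",
                  alt_reads = 10L, repeat_unit_len = ul,
                  repeat_count = rc)
  }
  qual <- function(ul, rc) classify_msi(mk(ul, rc))$qualifying_indels
  expect_equal(qual(1L, 4L), 0L)   # homopolymer needs >= 5 copies
  expect_equal(qual(1L, 5L), 1L)
  expect_equal(qual(2L, 3L), 0L)   # unit 2-4 needs >= 4 copies
  expect_equal(qual(2L, 4L), 1L)
  expect_equal(qual(4L, 4L), 1L)
  expect_equal(qual(5L, 10L), 0L)  # unit > 4 bp never qualifies
  expect_error(classify_msi(
    variant_table(chrom = "chr1", pos = 1L, ref = "A", alt = "AT")),
    "repeat annotations")
})

test_that("repeat annotation extends maximal tandem runs from a reference", {
  #              1234567890123456789
  ref_seqs <- c(chr1 = "GGACACACACTTTTTTGGA")
  # deletion of "AC" anchored at pos 2 ("GA" -> "G"? use pos 2 ref GAC->G)
  v <- variant_table(chrom = c("chr1", "chr1"), pos = c(2L, 10L),
                     ref = c("GAC", "CT"), alt = c("G", "C"),
                     alt_reads = 10L)
  out <- annotate_repeats(v, ref_seqs)
  # AC repeats 4x starting at pos 3 (ACACACAC)
  expect_equal(out$repeat_unit_len[1], 2L)
  expect_equal(out$repeat_count[1], 4L)
  # T homopolymer of length 6 following position 10
  expect_equal(out$repeat_unit_len[2], 1L)
  expect_equal(out$repeat_count[2], 6L)
  # an insertion's own copy counts toward the run
  ins <- annotate_repeats(
    variant_table(chrom = "chr1", pos = 10L, ref = "C", alt = "CT",
                  alt_reads = 10L), ref_seqs)
  expect_equal(ins$repeat_count, 7L)
})

test_that("purity correlations recover monotone and null structure", {
  mk_sample <- function(id, purity, n_snv) {
    sample_data(id, variants = tiny_snvs(seq_len(n_snv) * 50L),
                purity = purity)
  }
  mono <- lapply(1:6, function(i) mk_sample(paste0("m", i), i / 10,
                                            10 * i))
  tab <- purity_burden_correlation(mono)
  expect_equal(tab$rho[tab$class == "SNV"], 1)
  # independence: |rho| small on a seeded null cohort
  set.seed(31)
  null <- lapply(1:500, function(i) {
    mk_sample(paste0("n", i), runif(1, .2, .9), sample(50:150, 1))
  })
  tabn <- purity_burden_correlation(null)
  expect_lt(abs(tabn$rho[tabn$class == "SNV"]), 0.1)
  # all-tied counts: undefined, reported absent
  tied <- lapply(1:5, function(i) mk_sample(paste0("t", i), i / 10, 10))
  expect_true(is.na(
    purity_burden_correlation(tied)$rho[1]))
  expect_error(purity_burden_correlation(mono[1:2]), ">= 3")
})
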