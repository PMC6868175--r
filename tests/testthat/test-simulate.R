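test_that("simulation is deterministic per seed", {
  p <- default_profiles(n_total = 10)$E
  s1 <- simulate_sample(p, seed = 7)
  s2 <- simulate_sample(p, seed = 7)
  expect_equal(s1$sample$variants, s2$sample$variants)
  expect_equal(s1$sample$svs, s2$sample$svs)
  expect_equal(s1$sample$segments, s2$sample$segments)
  expect_equal(s1$truth$n_sv, s2$truth$n_sv)
  s3 <- simulate_sample(p, seed = 8)
  expect_false(identical(s1$sample$variants, s3$sample$variants))
})

test_that("cohort files are byte-identical across reruns of one seed", {
  profs <- default_profiles(n_total = 6)
  profs <- profs[c("E", "H")]
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_cohort(profs, seed = 5, out_dir = d1)
  simulate_cohort(profs, seed = 5, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and written files round-trip to the in-memory tables
  sim <- simulate_cohort(profs, seed = 5)
  s <- sim$cohort[[1]]
  expect_equal(read_variants(file.path(d1, paste0(s$sample_id,
                                                  ".variants.tsv"))),
               s$variants)
  expect_equal(read_cn_segments(file.path(d1, paste0(s$sample_id,
                                                     ".seg"))),
               s$segments, tolerance = 1e-9)
  sv_back <- read_svs(file.path(d1, paste0(s$sample_id, ".bedpe")))
  expect_equal(sv_back[order(sv_back$pos1, sv_back$svtype), ],
               s$svs[order(s$svs$pos1, s$svs$svtype), ],
               ignore_attr = TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("MSI genotypes classify MSI and others stay stable", {
  pA <- default_profiles(n_total = 20)$A
  for (seed in 1:20) {
    s <- simulate_sample(pA, seed = seed)
    expect_true(classify_msi(s$sample$variants)$is_msi)
  }
  pE <- default_profiles(n_total = 20)$E
  for (seed in 1:5) {
    s <- simulate_sample(pE, seed = seed)
    expect_false(classify_msi(s$sample$variants)$is_msi)
  }
})

test_that("planted chromothripsis is recovered on its chromosome", {
  p <- default_profiles(n_total = 20)$F
  p$chromothripsis_prob <- 1
  hits <- 0L
  for (seed in 1:10) {
    s <- simulate_sample(p, seed = seed)
    expect_true(s$truth$chromothripsis)
    ev <- call_chromothripsis(s$sample, seed = seed)
    chrom <- s$truth$chromothripsis_region$chrom
    if (any(ev$passed[ev$chrom == chrom])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("zero-rate profiles produce empty catalogs", {
  p <- genotype_profile(
    name = "null", n_samples = 1, snv_rate = 0, indel_rate = 0,
    mnv_rate = 0, n_sv_mean = 0, sv_mix = rep(1 / 7, 7),
    ploidy_mean = 2, kataegis_prob = 0, ets_prob = 0,
    signature_mix = c(flat = 1),
    driver_probs = c(TP53 = 0))
  s <- simulate_sample(p, seed = 1)
  expect_equal(nrow(s$sample$variants), 0L)
  expect_equal(nrow(s$sample$svs), 0L)
})

test_that("profile validation rejects inconsistent chromothripsis settings", {
  expect_error(
    genotype_profile(name = "bad", n_samples = 1, snv_rate = 1,
                     indel_rate = 1, n_sv_mean = 10,
                     sv_mix = rep(1 / 7, 7), ploidy_mean = 2,
                     chromothripsis_prob = 0.5,
                     signature_mix = c(flat = 1)),
    "inconsistent")
})

test_that("realized per-genotype medians concentrate near planted values", {
  p <- default_profiles(n_total = 20)$G
  truths <- lapply(1:20, function(seed) {
    simulate_sample(p, seed = seed)$truth
  })
  med <- function(f) median(vapply(truths, f, numeric(1)))
  g <- test_genome()
  mb <- sum(g$chrom_lengths) / 1e6
  expect_lt(abs(med(function(t) t$n_sv) - p$n_sv_mean),
            0.25 * p$n_sv_mean)
  expect_lt(abs(med(function(t) t$mean_ploidy) - p$ploidy_mean),
            0.25 * p$ploidy_mean)
  expect_lt(abs(med(function(t) t$n_snv) / mb - p$snv_rate),
            0.25 * p$snv_rate)
})

test_that("empty profiles are dropped with a warning", {
  profs <- default_profiles(n_total = 6)[c("E", "H")]
  profs$E$n_samples <- 0L
  expect_warning(sim <- simulate_cohort(profs, seed = 2), "n_samples = 0")
  expect_true(all(sim$truth_table$genotype == "H"))
  expect_error(simulate_cohort(profs["E"]), ">= 2")
})

test_that("default profile sizes scale the cohort proportions exactly", {
  profs <- default_profiles(n_total = 200)
  sizes <- vapply(profs, `[[`, integer(1), "n_samples")
  expect_equal(sum(sizes), 200L)
  expect_equal(unname(sizes[c("A", "B", "C", "D")]), c(13L, 13L, 15L, 22L))
  base <- c(13, 13, 15, 22, 55, 20, 34, 25)
  expect_true(all(abs(sizes - base / 197 * 200) < 1))
})
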