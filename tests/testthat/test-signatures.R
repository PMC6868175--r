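test_that("spectra count pyrimidine-normalized trinucleotide classes", {
  v <- tiny_snvs(100L, tnc = "ACA")  # C>T at ACA
  sp <- build_spectrum(v)
  expect_equal(sum(sp), 1L)
  expect_equal(unname(sp["A[C>T]A"]), 1L)
  # purine-strand G>A at TGT reverse-complements to A[C>T]A
  vp <- variant_table(chrom = "chr1", pos = 500L, ref = "G", alt = "A",
                      alt_reads = 10L, trinucleotide = "TGT")
  expect_equal(unname(build_spectrum(vp)["A[C>T]A"]), 1L)
  # context can come from a reference sequence
  ref_seqs <- c(chr1 = "TTACATT")
  vr <- variant_table(chrom = "chr1", pos = 4L, ref = "C", alt = "G",
                      alt_reads = 10L)
  expect_equal(unname(build_spectrum(vr, ref_seqs)["A[C>G]A"]), 1L)
  # contextless SNVs are excluded and counted
  expect_equal(attr(build_spectrum(vr), "n_excluded"), 1L)
})

test_that("a simulated draw is recovered exactly by the spectrum", {
  set.seed(51)
  classes <- sample(contexts_96(), 1000, replace = TRUE,
                    prob = runif(96))
  tnc <- paste0(substring(classes, 1, 1), substring(classes, 3, 3),
                substring(classes, 7, 7))
  v <- variant_table(chrom = rep("chr1", 1000), pos = seq_len(1000),
                     ref = substring(classes, 3, 3),
                     alt = substring(classes, 5, 5),
                     alt_reads = 10L, trinucleotide = tnc)
  sp <- build_spectrum(v)
  expect_equal(as.vector(sp),
               as.vector(table(factor(classes, levels = contexts_96()))))
})

test_that("NNLS refitting recovers exact mixtures and degenerate cases", {
  catalog <- default_signature_catalog()
  # pure column
  fit <- fit_signatures(1000 * catalog[, 2], catalog)
  expect_equal(unname(fit$relative_contributions[2]), 1, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
  # noise-free two-signature mixture
  m <- 600 * catalog[, 1] + 400 * catalog[, 4]
  fit2 <- fit_signatures(m, catalog)
  expect_equal(unname(fit2$relative_contributions[1]), 0.6,
               tolerance = 1e-6)
  expect_equal(unname(fit2$relative_contributions[4]), 0.4,
               tolerance = 1e-6)
  # spectrum orthogonal to the catalog: residual equals its norm
  A <- diag(96)[, 1:3]
  cat2 <- signature_catalog(A)
  m2 <- numeric(96); m2[50] <- 5
  fit3 <- fit_signatures(m2, cat2)
  expect_equal(fit3$residual_norm, sqrt(sum(m2^2)))
  # zero spectrum: zero weights, contributions reported absent
  fit4 <- fit_signatures(numeric(96), catalog)
  expect_true(all(fit4$weights == 0))
  expect_true(all(is.na(fit4$relative_contributions)))
})

test_that("the active-set NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(52)
  for (i in 1:10) {
    A <- matrix(runif(40 * 6), 40, 6)
    b <- runif(40)
    ours <- nnls(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(ours$x, ref$x, tolerance = 1e-8)
  }
})

test_that("adding a catalog column never increases the NNLS residual", {
  set.seed(53)
  A <- matrix(runif(96 * 5), 96, 5)
  b <- runif(96)
  r5 <- nnls(A, b)$residual_norm
  r6 <- nnls(cbind(A, runif(96)), b)$residual_norm
  expect_lte(r6, r5 + 1e-12)
})

test_that("cosine similarity matches the direct formula", {
  expect_equal(cosine_similarity(1:5, 1:5), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  set.seed(54)
  a <- runif(96); b <- runif(96)
  expect_equal(cosine_similarity(a, b),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 1e-12)
  expect_error(cosine_similarity(numeric(96), a), "zero")
})

test_that("NMF recovers a planted 3-signature cohort and is deterministic", {
  catalog <- default_signature_catalog()
  set.seed(55)
  W <- unclass(catalog)[, c("aging", "apobec", "msi_like")]
  H <- matrix(rgamma(3 * 20, 2), 3, 20) * 500
  V <- W %*% H
  res <- denovo_nmf(V, ranks = 2:4, n_runs = 6, seed = 9,
                    chosen_rank = 3, max_iter = 300)
  m3 <- res$metrics[res$metrics$rank == 3, ]
  expect_gte(m3$cophenetic, 0.95)
  expect_lt(m3$rss, 0.01 * sum(V^2))
  # objective is non-increasing across multiplicative updates
  expect_true(all(diff(res$objective) <= 1e-6))
  # recovered signatures match the planted ones
  match_cos <- apply(W, 2, function(w) {
    max(apply(res$W, 2, cosine_similarity, w))
  })
  expect_true(all(match_cos > 0.95))
  # fixed seed -> identical output
  res2 <- denovo_nmf(V, ranks = 2:4, n_runs = 6, seed = 9,
                     chosen_rank = 3, max_iter = 300)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$W, res2$W)
  expect_error(denovo_nmf(V, ranks = 25, n_runs = 3), "rank")
})
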