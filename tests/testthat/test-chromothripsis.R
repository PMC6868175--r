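osc_seg <- function(states, chrom = "chr1", seg_len = 1e6,
                    start = 1e6) {
  n <- length(states)
  cn_table(chrom = rep(chrom, n),
           start = start + (seq_len(n) - 1) * seg_len,
           end = start + seq_len(n) * seg_len - 1,
           cn = states)
}

test_that("oscillation runs follow their definitions", {
  expect_equal(unname(oscillation_runs(osc_seg(c(2, 1, 2, 1, 2, 1, 2)))),
               c(7L, 7L))
  expect_equal(unname(oscillation_runs(osc_seg(c(2, 2, 2)))["osc2"]), 1L)
  # three-state run counts adjacent-distinct with <= 3 values
  r <- oscillation_runs(osc_seg(c(1, 2, 3, 1, 2, 3)))
  expect_equal(unname(r["osc2"]), 2L)
  expect_equal(unname(r["osc3"]), 6L)
  expect_equal(unname(oscillation_runs(osc_seg(2)["x" == "y", ])),
               c(0L, 0L))
})

test_that("oscillation runs match the brute-force scan on random states", {
  set.seed(61)
  for (i in 1:200) {
    states <- sample(1:4, sample(1:12, 1), replace = TRUE)
    expect_equal(oscillation_runs(osc_seg(states)),
                 brute_osc_runs(states))
  }
})

test_that("equal-type test is exact for balanced and degenerate counts", {
  expect_equal(equal_type_test(c(10, 10, 10, 10)), 1.0)
  # chi-square 75 on df 3
  expect_lt(equal_type_test(c(25, 0, 0, 0)), 1e-3)
  expect_error(equal_type_test(c(0, 0, 0, 0)), "non-zero")
})

test_that("Monte-Carlo p agrees with exact multinomial enumeration", {
  set.seed(62)
  for (counts in list(c(5, 3, 2, 2), c(8, 1, 1, 1), c(3, 3, 3, 3),
                      c(6, 4, 1, 0))) {
    p_mc <- equal_type_test(counts)
    p_exact <- multinom_equal_p(counts)
    expect_lt(abs(p_mc - p_exact), 0.01)
  }
})

test_that("breakpoint uniformity test flags clustering, not uniformity", {
  len <- 1.5e8
  set.seed(63)
  over_05 <- sum(vapply(1:100, function(i) {
    nonrandom_breakpoint_test(runif(50, 1, len), len) > 0.05
  }, logical(1)))
  expect_gte(over_05, 95)
  # 50 breakpoints inside the central 5%
  p_tight <- nonrandom_breakpoint_test(runif(50, 0.475 * len, 0.525 * len),
                                       len)
  expect_lt(p_tight, 1e-6)
  # all at one position: as small as KS allows for this n
  expect_lt(nonrandom_breakpoint_test(rep(1000, 50), len), 1e-10)
  expect_true(is.na(nonrandom_breakpoint_test(c(1, 2, 3, 4), len)))
})

test_that("a planted event passes; each criterion fails at its boundary", {
  crit <- chromothripsis_criteria()
  ev <- call_chromothripsis(planted_event_sample(), crit, seed = 3)
  expect_true(ev$passed)
  expect_gte(ev$n_sv, 25)
  expect_gte(ev$osc2_run, 7)
  expect_gte(ev$end - ev$start, 2e7)
  # criterion (a): 24 SVs fails the count alone
  ev24 <- call_chromothripsis(planted_event_sample(n_sv = 24L), crit,
                              seed = 3)
  expect_false(ev24$passed)
  expect_equal(ev24$n_sv, 24L)
  expect_gte(ev24$osc2_run, 7)
  expect_gte(ev24$end - ev24$start, 2e7)
  expect_gt(ev24$p_equal_types, 0.05)
  expect_lte(ev24$p_nonrandom, 0.05)
  # criterion (b): oscillation below both thresholds
  ev_osc <- call_chromothripsis(planted_event_sample(n_osc = 6L), crit,
                                seed = 3)
  expect_false(ev_osc$passed)
  expect_lt(ev_osc$osc2_run, 7)
  # criterion (c): span below 20 Mbp
  ev_small <- call_chromothripsis(
    planted_event_sample(span = 1.8e7, n_osc = 25L), crit, seed = 3)
  expect_false(ev_small$passed)
  expect_lt(ev_small$end - ev_small$start, 2e7)
})

test_that("scattered structural variants do not produce an event", {
  svs <- sv_table(svtype = c("DEL", "DUP", "INV_HH"),
                  chrom1 = "chr1", pos1 = c(1e7L, 6e7L, 1.2e8L),
                  chrom2 = "chr1", pos2 = c(1.1e7L, 6.1e7L, 1.21e8L),
                  baf = 0.5)
  s <- sample_data("q", svs = svs,
                   segments = cn_table("chr1", 1, 1.5e8, 2))
  ev <- call_chromothripsis(s, seed = 3)
  expect_false(any(ev$passed))
})

test_that("adding qualifying SVs inside the region never breaks a pass", {
  crit <- chromothripsis_criteria()
  base <- planted_event_sample()
  expect_true(call_chromothripsis(base, crit, seed = 3)$passed)
  for (extra in c(4L, 8L, 16L)) {
    grown <- planted_event_sample(n_sv = 32L + extra)
    expect_true(call_chromothripsis(grown, crit, seed = 3)$passed)
  }
})
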