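# Independent oracles used across the suite.  Each is a brute-force or
# closed-form recomputation that shares no code with the implementation
# it checks.

# exhaustive least-squares segmentation: try every placement of S-1
# breakpoints among the m-1 gaps
brute_force_segmentation <- function(x, n_seg) {
  m <- length(x)
  n_seg <- min(n_seg, m)
  sse <- function(v) sum((v - mean(v))^2)
  if (n_seg == 1) return(list(cost = sse(x), ends = m))
  best <- Inf
  best_ends <- NULL
  for (cut in utils::combn(m - 1, n_seg - 1, simplify = FALSE)) {
    ends <- c(cut, m)
    starts <- c(1, head(ends, -1) + 1)
    cost <- sum(vapply(seq_along(ends),
                       function(s) sse(x[starts[s]:ends[s]]),
                       numeric(1)))
    if (cost < best - 1e-12) {
      best <- cost
      best_ends <- ends
    }
  }
  list(cost = best, ends = best_ends)
}

# hand Lance-Williams recursion with the classic ward.D coefficients
# (alpha_i = (n_i + n_k) / (n_i + n_j + n_k), beta = -n_k / (...),
# gamma = 0) applied to the unsquared dissimilarities
hand_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- numeric(0)
  merges <- list()
  idx <- seq_len(n)          # current cluster ids; negative = singleton
  ids <- -seq_len(n)
  while (length(ids) > 1) {
    k <- length(ids)
    best <- Inf; bi <- bj <- NA
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (d[i, j] < best - 1e-12) {
        best <- d[i, j]; bi <- i; bj <- j
      }
    }
    heights <- c(heights, best)
    merges[[length(merges) + 1]] <- sort(c(ids[bi], ids[bj]))
    ni <- sizes[bi]; nj <- sizes[bj]
    newrow <- vapply(seq_len(k), function(l) {
      if (l == bi || l == bj) return(NA_real_)
      nk <- sizes[l]
      ((ni + nk) * d[bi, l] + (nj + nk) * d[bj, l] - nk * best) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    ids <- c(ids[keep], length(merges))
  }
  list(heights = heights, merges = merges)
}

# every leaf ordering consistent with an hclust tree (flip enumeration)
all_tree_orders <- function(tree) {
  expand <- function(id) {
    if (id < 0) return(list(-id))
    l <- expand(tree$merge[id, 1])
    r <- expand(tree$merge[id, 2])
    out <- list()
    for (a in l) for (b in r) {
      out[[length(out) + 1]] <- c(a, b)
      out[[length(out) + 1]] <- c(b, a)
    }
    out
  }
  expand(nrow(tree$merge))
}

adjacent_cost <- function(ord, d) {
  d <- as.matrix(d)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# exact multinomial goodness-of-fit p against equal proportions
multinom_equal_p <- function(counts) {
  n <- sum(counts)
  k <- length(counts)
  stat <- function(x) sum((x - n / k)^2 / (n / k))
  obs <- stat(counts)
  total <- 0
  rec <- function(prefix, left, pos) {
    if (pos == k) {
      x <- c(prefix, left)
      if (stat(x) >= obs - 1e-9) {
        total <<- total + dmultinom(x, prob = rep(1 / k, k))
      }
      return(invisible())
    }
    for (v in 0:left) rec(c(prefix, v), left - v, pos + 1)
  }
  rec(integer(), n, 1)
  total
}

# brute-force maximum CN over segments overlapping a region
brute_region_cn <- function(segments, region) {
  best <- NA_real_
  for (i in seq_len(nrow(segments))) {
    if (segments$chrom[i] != region$chrom) next
    if (segments$end[i] < region$start || segments$start[i] > region$end)
      next
    best <- max(best, segments$cn[i], na.rm = TRUE)
  }
  best
}

# brute-force longest oscillation runs over all sub-runs
brute_osc_runs <- function(states) {
  n <- length(states)
  if (!n) return(c(osc2 = 0L, osc3 = 0L))
  osc2 <- osc3 <- 1L
  for (i in 1:n) for (j in i:n) {
    run <- states[i:j]
    len <- j - i + 1L
    if (len >= 2) {
      adj_diff <- all(run[-1] != run[-len])
      if (adj_diff && length(unique(run)) == 2 &&
          all(run == rep(run[1:2], length.out = len))) {
        osc2 <- max(osc2, len)
      }
      if (adj_diff && length(unique(run)) <= 3) osc3 <- max(osc3, len)
    }
  }
  c(osc2 = osc2, osc3 = osc3)
}

# small deterministic variant/sv/segment builders
tiny_snvs <- function(pos, chrom = "chr1", tnc = "ACA") {
  variant_table(chrom = rep(chrom, length(pos)), pos = pos,
                ref = rep("C", length(pos)), alt = rep("T", length(pos)),
                alt_reads = 10L, trinucleotide = tnc)
}

qualifying_indels <- function(n, chrom = "chr1") {
  variant_table(chrom = rep(chrom, n), pos = seq_len(n) * 100L,
                ref = rep("A", n), alt = rep("AT", n), alt_reads = 10L,
                repeat_unit_len = 1L, repeat_count = 6L)
}

test_genome <- function() mini_genome()

# random non-overlapping segments on one chromosome
rand_segments <- function(n, chrom = "chr1") {
  lens <- sample.int(4e4, n) + 1e3
  gaps <- sample.int(6e4, n) + 1e3
  starts <- cumsum(gaps + lens) - lens
  cn_table(chrom = chrom, start = starts, end = starts + lens - 1,
           cn = runif(n, 0, 10))
}

# a clean constructed chromothripsis event: n_sv balanced SVs, an
# oscillating 2-state block, breakpoints confined to the region
planted_event_sample <- function(n_sv = 32L, n_osc = 25L, span = 4e7,
                                 start = 3e7, id = "ct") {
  region <- list(chrom = "chr1", start = start, end = start + span)
  types <- rep(c("DEL", "DUP", "INV_HH", "INV_TT"), length.out = n_sv)
  # breakpoint footprint spans the region exactly
  p1 <- as.integer(seq(region$start, region$end - 1500000L,
                       length.out = n_sv))
  svs <- sv_table(svtype = types, chrom1 = "chr1", pos1 = p1,
                  chrom2 = "chr1", pos2 = p1 + 1500000L, baf = 0.5)
  states <- rep(c(2, 3), length.out = n_osc)
  bounds <- round(seq(region$start, region$end, length.out = n_osc + 1))
  segs <- cn_table(chrom = rep("chr1", n_osc),
                   start = bounds[-(n_osc + 1)] + c(0, rep(1, n_osc - 1)),
                   end = bounds[-1], cn = states)
  sample_data(id, svs = svs, segments = segs)
}
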