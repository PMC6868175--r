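# blobs with shape-distinct centers, so both Euclidean and
# correlation-based distances see the planted structure
blobs <- function(n_per = 20, centers = list(c(1, 5, 10), c(10, 1, 5),
                                             c(5, 10, 1)), sd = 0.5,
                  seed = 81) {
  set.seed(seed)
  m <- do.call(rbind, lapply(centers, function(ce) {
    matrix(rnorm(n_per * length(ce), mean = rep(ce, each = n_per),
                 sd = sd), n_per)
  }))
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  m
}

test_that("RMS scaling normalizes columns without centering", {
  set.seed(82)
  m <- matrix(runif(60, 1, 5), 10, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  sc <- scale_features(m)
  rms <- sqrt(colSums(sc^2) / (nrow(sc) - 1))
  expect_equal(unname(rms), rep(1, 6), tolerance = 1e-12)
  expect_equal(scale_features(sc), sc, tolerance = 1e-12)
  expect_equal(sc, sweep(m, 2, sqrt(colSums(m^2) / 9), "/"),
               tolerance = 1e-12)
  m2 <- cbind(m, bad = 0)
  expect_error(scale_features(m2), "bad")
})

test_that("Pearson dissimilarity is 1 - r with the documented edge cases", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  d <- pearson_dissimilarity(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  set.seed(83)
  r <- matrix(rnorm(50), 5, 10, dimnames = list(letters[1:5], NULL))
  expect_equal(pearson_dissimilarity(r)["a", "b"],
               1 - cor(r["a", ], r["b", ]), tolerance = 1e-12)
  expect_error(pearson_dissimilarity(rbind(a = c(1, 1, 1))), "a")
})

leafsets <- function(merges_children, n) {
  sets <- vector("list", length(merges_children))
  for (v in seq_along(merges_children)) {
    get <- function(id) if (id < 0) -id else sets[[id]]
    sets[[v]] <- sort(c(get(merges_children[[v]][1]),
                        get(merges_children[[v]][2])))
  }
  sets
}

test_that("ward.D linkage reproduces the hand Lance-Williams recursion", {
  # two identical samples merge first at height 0
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4),
             d = c(2, 8, 1))
  d0 <- as.matrix(dist(m))
  tree <- ward_linkage(d0)
  expect_equal(tree$height[1], 0)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  set.seed(84)
  for (i in 1:10) {
    pts <- matrix(rnorm(6 * 4), 6)
    d <- as.matrix(dist(pts))
    ours <- ward_linkage(d)
    ref <- hand_ward(d)
    expect_equal(ours$height, ref$heights, tolerance = 1e-9)
    ours_sets <- leafsets(split(ours$merge, row(ours$merge)), 6)
    ref_sets <- leafsets(ref$merges, 6)
    expect_equal(ours_sets, ref_sets)
  }
  dn <- as.matrix(dist(pts)); dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(ward_linkage(dn), "NA")
})

test_that("duplicating a sample preserves the partition of the others", {
  m <- blobs(n_per = 8, seed = 85)
  part <- cutree(ward_linkage(as.matrix(dist(m))), k = 3)
  m2 <- rbind(m, dup = m[1, ])
  part2 <- cutree(ward_linkage(as.matrix(dist(m2))), k = 3)
  # same partition up to label names
  expect_equal(length(unique(paste(part, part2[rownames(m)]))), 3L)
  expect_equal(part2[["dup"]], part2[[rownames(m)[1]]])
})

test_that("optimal leaf ordering matches exhaustive enumeration", {
  set.seed(86)
  for (n in c(3, 5, 8)) {
    for (i in 1:5) {
      pts <- matrix(rnorm(n * 3), n)
      d <- as.matrix(dist(pts))
      tree <- ward_linkage(d)
      ord <- optimal_leaf_order(tree, d)
      expect_setequal(ord, seq_len(n))
      best <- min(vapply(all_tree_orders(tree), adjacent_cost,
                         numeric(1), d = d))
      expect_equal(adjacent_cost(ord, d), best, tolerance = 1e-12)
      expect_equal(attr(ord, "cost"), best, tolerance = 1e-12)
    }
  }
  # points on a line come out in monotone order
  x <- matrix(c(1, 2, 4, 8, 16, 32), ncol = 1)
  d <- as.matrix(dist(x))
  ordl <- optimal_leaf_order(ward_linkage(d), d)
  expect_true(all(diff(ordl) > 0) || all(diff(ordl) < 0))
})

test_that("the elbow finds planted blob structure and warns on noise", {
  m <- blobs(n_per = 15, sd = 0.4, seed = 87)
  sc <- scale_features(m)
  tree <- ward_linkage(pearson_dissimilarity(sc))
  k <- choose_k_elbow(sc, tree, k_max = 10)
  expect_equal(as.integer(k), 3L)
  set.seed(88)
  noise <- matrix(runif(200, 1, 2), 20)
  scn <- scale_features(noise)
  treen <- ward_linkage(pearson_dissimilarity(scn))
  expect_warning(choose_k_elbow(scn, treen, k_max = 10,
                                curvature_warn = 0.45),
                 "weak elbow")
})

test_that("bootstrap support is high for real splits and deterministic", {
  m <- blobs(n_per = 10,
             centers = list(c(1, 8, 2, 9, 1, 8, 2, 9),
                            c(9, 2, 8, 1, 9, 2, 8, 1)),
             sd = 0.4, seed = 89)
  colnames(m) <- paste0("f", 1:8)
  sup <- bootstrap_support(m, n_boot = 100, seed = 5)
  expect_true(all(sup >= 0 & sup <= 1))
  tree <- attr(sup, "tree")
  # the two top-level children (last merge's inputs) are stable
  top_children <- tree$merge[nrow(tree$merge), ]
  expect_true(all(sup[top_children[top_children > 0]] >= 0.95))
  sup2 <- bootstrap_support(m, n_boot = 100, seed = 5)
  expect_identical(as.numeric(sup), as.numeric(sup2))
})

test_that("cluster enrichment reproduces the exact hypergeometric test", {
  labels <- setNames(rep(1:2, c(13, 184)), sprintf("s%03d", 1:197))
  trait <- c(rep(TRUE, 11), rep(FALSE, 2),      # 11/13 in cluster 1
             rep(TRUE, 5), rep(FALSE, 179))     # 5/184 outside
  traits <- matrix(trait, dimnames = list(names(labels), "geneX"))
  tab <- cluster_enrichment(labels, traits)
  row1 <- tab[tab$cluster == 1, ]
  expect_equal(row1$in_freq, 11 / 13)
  expect_equal(row1$out_freq, 5 / 184)
  oracle <- fisher_enum_p(matrix(c(11, 2, 5, 179), 2))
  expect_equal(row1$p, oracle, tolerance = 1e-9)
  expect_true(row1$significant)
  # equal frequencies give p = 1
  labels2 <- setNames(rep(1:2, each = 10), sprintf("t%02d", 1:20))
  traits2 <- matrix(rep(c(TRUE, FALSE), 10),
                    dimnames = list(names(labels2), "flat"))
  expect_true(all(cluster_enrichment(labels2, traits2)$p == 1))
  # all-negative trait emits p = 1 rows
  traits3 <- matrix(FALSE, 20, 1,
                    dimnames = list(names(labels2), "empty"))
  expect_true(all(cluster_enrichment(labels2, traits3)$p == 1))
})

test_that("the supervised mutually-exclusive scheme follows precedence", {
  flags <- rbind(
    s1 = c(ERG = FALSE, ETV1 = FALSE, ETV4 = FALSE, FLI1 = FALSE,
           SPOP = TRUE, FOXA1 = FALSE, IDH1 = FALSE),
    s2 = c(ERG = TRUE, ETV1 = FALSE, ETV4 = FALSE, FLI1 = FALSE,
           SPOP = TRUE, FOXA1 = FALSE, IDH1 = FALSE),
    s3 = rep(FALSE, 7))
  out <- classify_tcga(flags)
  expect_equal(unname(out$class), c("SPOP", "ERG", "unclassified"))
  expect_equal(out$classified_fraction, 2 / 3)
})

test_that("cohort comparison detects planted frequency and TMB shifts", {
  a <- matrix(FALSE, 200, 2, dimnames = list(NULL, c("g1", "g2")))
  b <- a
  identical_cmp <- compare_cohorts(a, b)
  expect_true(all(identical_cmp$genes$q == 1))
  expect_true(all(identical_cmp$genes$freq_diff == 0))
  set.seed(91)
  a[, "g1"] <- runif(200) < 0.30
  b[, "g1"] <- runif(200) < 0.05
  a[, "g2"] <- runif(200) < 0.10
  b[, "g2"] <- runif(200) < 0.10
  tmb_a <- rlnorm(200, log(8), 0.3)
  tmb_b <- rlnorm(200, log(8 / 3), 0.3)
  cmp <- compare_cohorts(a, b, tmb_a, tmb_b)
  expect_lte(cmp$genes$q[cmp$genes$gene == "g1"], 0.05)
  expect_lt(cmp$tmb$p.value, 1e-3)
  expect_error(compare_cohorts(a[0, ], b), "empty")
})

test_that("per-feature cos2 sums to one and matches an SVD recomputation", {
  set.seed(92)
  m <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  pc <- pca_cos2(m)
  expect_equal(unname(rowSums(pc$cos2)), rep(1, 6), tolerance = 1e-10)
  # independent recomputation via svd of the standardized matrix
  z <- scale(m, center = TRUE, scale = TRUE)
  sv <- svd(z)
  coord <- sv$v %*% diag(sv$d / sqrt(nrow(m) - 1))
  cos2 <- coord^2 / rowSums(coord^2)
  expect_equal(unname(pc$cos2), unname(cos2), tolerance = 1e-10)
  # rank-1 data loads everything on the first component
  r1 <- outer(seq_len(10), c(1, 2, 3)) +
    matrix(rnorm(30, sd = 1e-8), 10)
  pr <- pca_cos2(r1, scale. = FALSE)
  expect_true(all(pr$cos2[, 1] > 0.999))
  expect_error(pca_cos2(m[1, , drop = FALSE]), ">= 2")
})

test_that("cluster_scars is deterministic end to end", {
  m <- blobs(n_per = 10, sd = 0.6, seed = 93)
  colnames(m) <- paste0("f", 1:3)
  r1 <- cluster_scars(m, k = 3, n_boot = 50, seed = 11)
  r2 <- cluster_scars(m, k = 3, n_boot = 50, seed = 11)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$leaf_order, r2$leaf_order)
  expect_identical(as.numeric(r1$bootstrap_support),
                   as.numeric(r2$bootstrap_support))
  expect_equal(sort(unique(r1$labels)), 1:3)
  expect_setequal(r1$leaf_order, seq_len(nrow(m)))
})
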