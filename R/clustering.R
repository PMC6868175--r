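#' Root-mean-square feature scaling (no centering)
#'
#' Divides each feature column by its root mean square
#' `sqrt(sum(x^2) / (n - 1))`, without centering, prior to the Pearson
#' dissimilarity.  Idempotent up to the RMS of an already-scaled column
#' being 1.
#'
#' @param m Numeric samples x features matrix.
#' @return Scaled matrix.
#' @export
scale_features <- function(m) {
  m <- as.matrix(m)
  rms <- sqrt(colSums(m^2, na.rm = TRUE) / (nrow(m) - 1L))
  zero <- rms == 0
  if (any(zero)) {
    stop("all-zero feature column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, rms, "/")
}

#' Pearson dissimilarity between samples
#'
#' `d = 1 - r` where `r` is the Pearson correlation between sample rows.
#'
#' @param m Numeric samples x features matrix (>= 2 features).
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
pearson_dissimilarity <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need >= 2 features per sample")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("constant feature row(s), correlation undefined: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- 1 - cor(t(m))
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the classic Ward criterion applied to
#' the supplied dissimilarities without squaring (the `"ward.D"`
#' contract, Lance-Williams updates).
#'
#' @param d Symmetric dissimilarity matrix or `dist`.
#' @return An `hclust` tree.
#' @export
ward_linkage <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  if (anyNA(d)) stop("dissimilarity matrix contains NA/NaN")
  hclust(d, method = "ward.D")
}

min_plus <- function(X, Y) {
  # Z[i, j] = min_k X[i, k] + Y[k, j]
  Z <- matrix(Inf, nrow(X), ncol(Y))
  for (j in seq_len(ncol(Y))) {
    Z[, j] <- do.call(pmin, lapply(seq_len(ncol(X)),
                                   function(k) X[, k] + Y[k, j]))
  }
  Z
}

#' Optimal leaf ordering of a dendrogram
#'
#' Among the `2^(n-1)` leaf orderings consistent with the tree, finds one
#' minimizing the summed dissimilarity between adjacent leaves
#' (bottom-up dynamic program over subtree endpoint pairs).
#'
#' @param tree An `hclust` tree over the same samples.
#' @param d Dissimilarity matrix (matrix or `dist`).
#' @return Integer permutation of the leaves (indices into the original
#'   sample order), with attribute `cost`, the minimized adjacent-leaf
#'   dissimilarity sum.
#' @export
optimal_leaf_order <- function(tree, d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- length(tree$order)
  merge <- tree$merge
  leaves <- vector("list", n - 1L)   # leaf indices per internal node
  M <- vector("list", n - 1L)        # endpoint-pair cost matrices
  kids <- vector("list", n - 1L)
  node_leaves <- function(id) if (id < 0) -id else leaves[[id]]
  node_M <- function(id) {
    if (id < 0) matrix(0, 1, 1, dimnames = list(-id, -id)) else M[[id]]
  }
  for (v in seq_len(n - 1L)) {
    l <- merge[v, 1]; r <- merge[v, 2]
    ll <- node_leaves(l); rl <- node_leaves(r)
    Ml <- node_M(l); Mr <- node_M(r)
    # cost of ordering with left endpoint u in ll, right endpoint w in rl:
    # min over adjacent pair (m in ll, k in rl)
    cross <- min_plus(min_plus(Ml, d[ll, rl, drop = FALSE]), Mr)
    dimnames(cross) <- list(ll, rl)
    full <- matrix(Inf, length(ll) + length(rl), length(ll) + length(rl),
                   dimnames = list(c(ll, rl), c(ll, rl)))
    full[seq_along(ll), length(ll) + seq_along(rl)] <- cross
    full[length(ll) + seq_along(rl), seq_along(ll)] <- t(cross)
    leaves[[v]] <- c(ll, rl)
    M[[v]] <- full
    kids[[v]] <- c(l, r)
  }
  root <- n - 1L
  best <- which(M[[root]] == min(M[[root]]), arr.ind = TRUE)[1, ]
  u <- leaves[[root]][best[1]]; w <- leaves[[root]][best[2]]
  # reconstruct the order achieving cost M[[v]][u, w]
  reconstruct <- function(id, u, w) {
    if (id < 0) return(-id)
    l <- kids[[id]][1]; r <- kids[[id]][2]
    ll <- node_leaves(l); rl <- node_leaves(r)
    if (u %in% rl) {  # mirrored orientation
      return(rev(reconstruct(id, w, u)))
    }
    Ml <- node_M(l); Mr <- node_M(r)
    iu <- match(u, ll); iw <- match(w, rl)
    cand <- outer(Ml[iu, ], Mr[, iw], "+") + d[ll, rl, drop = FALSE]
    hit <- which(cand == min(cand), arr.ind = TRUE)[1, ]
    m <- ll[hit[1]]; k <- rl[hit[2]]
    c(reconstruct(l, u, m), reconstruct(r, k, w))
  }
  ord <- reconstruct(root, u, w)
  attr(ord, "cost") <- min(M[[root]])
  ord
}

order_cost <- function(ord, d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

#' Within-cluster sum of squares for tree cuts
#'
#' @param m Samples x features matrix (typically RMS-scaled).
#' @param tree `hclust` tree over the rows of `m`.
#' @param k_max Largest cut evaluated.
#' @return Numeric vector `wss[k]`, k = 1..k_max.
#' @export
wss_curve <- function(m, tree, k_max = 15L) {
  m <- as.matrix(m)
  k_max <- min(k_max, nrow(m))
  vapply(seq_len(k_max), function(k) {
    labels <- cutree(tree, k = k)
    sum(vapply(split(seq_len(nrow(m)), labels), function(idx) {
      x <- m[idx, , drop = FALSE]
      sum(sweep(x, 2, colMeans(x))^2)
    }, numeric(1)))
  }, numeric(1))
}

#' Choose the cluster count by the elbow criterion
#'
#' Computes the total within-cluster sum of squares for cuts k =
#' 1..`k_max` and picks the k whose point on the (normalized) curve lies
#' furthest from the chord joining the endpoints.  When the curve is
#' nearly straight (maximum normalized distance below `curvature_warn`)
#' the choice carries little evidence and a warning is raised.
#'
#' @param m Samples x features matrix (scaled).
#' @param tree `hclust` tree over the rows.
#' @param k_max Largest cut considered (default 15, below `nrow(m)`).
#' @param curvature_warn Weak-elbow warning threshold on the normalized
#'   maximum chord distance (default 0.1).
#' @return Chosen k, with attributes `wss` (the curve) and `strength`
#'   (normalized maximum chord distance).
#' @export
choose_k_elbow <- function(m, tree, k_max = 15L, curvature_warn = 0.1) {
  m <- as.matrix(m)
  if (k_max >= nrow(m)) k_max <- nrow(m) - 1L
  wss <- wss_curve(m, tree, k_max)
  ks <- seq_len(k_max)
  # normalize both axes to [0, 1] so the chord distance is scale-free
  x <- (ks - 1) / (k_max - 1)
  span <- max(wss) - min(wss)
  y <- if (span > 0) (wss - min(wss)) / span else rep(0, k_max)
  # signed distance to the chord from (0, y1) to (1, y_kmax)
  dist_chord <- abs((y[k_max] - y[1]) * x - (1 - 0) * y +
                      y[1]) / sqrt((y[k_max] - y[1])^2 + 1)
  k <- ks[which.max(dist_chord)]
  strength <- max(dist_chord)
  if (strength < curvature_warn) {
    warning(sprintf(
      "weak elbow (normalized curvature %.3f < %.3f); k = %d is poorly determined",
      strength, curvature_warn, k))
  }
  structure(k, wss = wss, strength = strength)
}

node_leafsets <- function(tree, labels) {
  n <- length(labels)
  sets <- vector("list", n - 1L)
  for (v in seq_len(n - 1L)) {
    l <- tree$merge[v, 1]; r <- tree$merge[v, 2]
    get <- function(id) if (id < 0) labels[-id] else sets[[id]]
    sets[[v]] <- sort(c(get(l), get(r)))
  }
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Bootstrap support of dendrogram nodes
#'
#' Resamples the feature columns with replacement, re-runs the scaling /
#' Pearson-dissimilarity / Ward pipeline, and scores each internal node
#' of the original tree by the fraction of replicates whose tree contains
#' an identical leaf set (ordinary bootstrap probability).
#'
#' @param m Samples x features matrix (unscaled; scaling is applied
#'   inside each replicate).
#' @param n_boot Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of per-node support in [0, 1] (ordered as the
#'   original tree's merge rows), with the original tree attached as
#'   attribute `tree`.
#' @export
bootstrap_support <- function(m, n_boot = 1000L, seed = 1L) {
  m <- as.matrix(m)
  if (n_boot < 2) stop("n_boot must be >= 2")
  tree <- ward_linkage(pearson_dissimilarity(scale_features(m)))
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  orig <- node_leafsets(tree, labels)
  hits <- numeric(length(orig))
  used <- 0L
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_tree <- tryCatch(
      ward_linkage(pearson_dissimilarity(scale_features(
        m[, cols, drop = FALSE]))),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    used <- used + 1L
    hits <- hits + orig %in% node_leafsets(rep_tree, labels)
  }
  if (used == 0L) stop("all bootstrap replicates failed")
  structure(hits / used, tree = tree, n_used = used)
}

#' Unsupervised scar-genotype clustering
#'
#' End-to-end clustering of a cohort feature matrix: RMS scaling (no
#' centering), Pearson dissimilarity (1 - r), Ward (`ward.D`) linkage,
#' optimal leaf ordering, elbow-based cluster count (unless `k` is
#' given), cluster labels, and optionally bootstrap node support.
#'
#' @param features Samples x features matrix (raw, unscaled).
#' @param k Cluster count, or `"auto"` for the elbow choice.
#' @param k_max Largest k considered by the elbow.
#' @param n_boot Bootstrap replicates (0 to skip).
#' @param seed Integer seed (bootstrap only; the rest is deterministic).
#' @return An object of class `cluster_result`: `tree`, `leaf_order`,
#'   `k`, `labels` (named integer vector; cluster ids are 1..k in leaf
#'   order of first appearance), `bootstrap_support`, `wss`,
#'   `elbow_strength`, `scaled` (the scaled matrix).
#' @export
cluster_scars <- function(features, k = "auto", k_max = 15L,
                          n_boot = 0L, seed = 1L) {
  m <- as.matrix(features)
  scaled <- scale_features(m)
  d <- pearson_dissimilarity(scaled)
  tree <- ward_linkage(d)
  leaf_order <- optimal_leaf_order(tree, d)
  wss <- NULL; strength <- NA_real_
  if (identical(k, "auto")) {
    kk <- choose_k_elbow(scaled, tree, k_max)
    wss <- attr(kk, "wss"); strength <- attr(kk, "strength")
    k <- as.integer(kk)
  } else {
    k <- as.integer(k)
    wss <- wss_curve(scaled, tree, k_max)
  }
  raw_labels <- cutree(tree, k = k)
  # renumber clusters by order of appearance along the optimally ordered
  # leaves, so cluster 1 is leftmost in the dendrogram
  first_seen <- unique(raw_labels[leaf_order])
  labels <- match(raw_labels, first_seen)
  names(labels) <- rownames(m)
  support <- if (n_boot > 0) bootstrap_support(m, n_boot, seed) else NULL
  structure(list(tree = tree, leaf_order = as.integer(leaf_order),
                 olo_cost = attr(leaf_order, "cost"),
                 k = k, labels = labels,
                 bootstrap_support = support, wss = wss,
                 elbow_strength = strength, scaled = scaled),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d samples, k = %d clusters\n",
              length(x$labels), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cluster-trait enrichment testing
#'
#' For every (cluster, binary trait) pair, builds the 2x2 in-cluster /
#' out-of-cluster by trait-positive / trait-negative table, tests it with
#' a two-sided Fisher's exact test, and corrects all tests jointly by
#' Benjamini-Hochberg.
#'
#' @param labels Named cluster labels per sample.
#' @param traits Samples x traits logical (or 0/1) matrix or data.frame,
#'   rows matching `names(labels)`.
#' @param q_cut Flag threshold on q (default 0.05).
#' @return `data.frame` with `cluster`, `trait`, `n_in`, `in_freq`,
#'   `out_freq`, `odds_ratio`, `p`, `q`, `significant`.
#' @export
cluster_enrichment <- function(labels, traits, q_cut = 0.05) {
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) && !is.null(names(labels))) {
    traits <- traits[names(labels), , drop = FALSE]
  }
  stopifnot(nrow(traits) == length(labels))
  mode(traits) <- "logical"
  rows <- list()
  for (cl in sort(unique(labels))) {
    inside <- labels == cl
    for (tr in colnames(traits)) {
      x <- traits[, tr]
      tab <- matrix(c(sum(inside & x), sum(inside & !x),
                      sum(!inside & x), sum(!inside & !x)), 2)
      ft <- fisher.test(tab, alternative = "two.sided")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, trait = tr, n_in = sum(inside),
        in_freq = sum(inside & x) / sum(inside),
        out_freq = sum(!inside & x) / sum(!inside),
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_cut
  out
}

TCGA_CLASSES <- c("ERG", "ETV1", "ETV4", "FLI1", "SPOP", "FOXA1", "IDH1")

#' Supervised mutually-exclusive classification (TCGA scheme)
#'
#' Assigns each sample the first matching class in the precedence order
#' ERG, ETV1, ETV4, FLI1 (genomic breaks of the ETS partner), then SPOP,
#' FOXA1, IDH1 (gene aberrations); samples matching none are
#' `"unclassified"`.
#'
#' @param flags Samples x flags logical matrix/data.frame with columns
#'   named after the seven classes.
#' @return List with `class` (character per sample) and
#'   `classified_fraction`.
#' @export
classify_tcga <- function(flags) {
  flags <- as.matrix(flags)
  missing <- setdiff(TCGA_CLASSES, colnames(flags))
  if (length(missing)) {
    stop("missing flag column(s): ", paste(missing, collapse = ", "))
  }
  mode(flags) <- "logical"
  cls <- apply(flags[, TCGA_CLASSES, drop = FALSE], 1, function(x) {
    hit <- which(x)
    if (length(hit)) TCGA_CLASSES[hit[1]] else "unclassified"
  })
  list(class = cls,
       classified_fraction = mean(cls != "unclassified"))
}

#' Compare gene-aberration frequencies and TMB between two cohorts
#'
#' Genes are compared by two-sided Fisher's exact test on the per-cohort
#' aberrant-sample counts (multiple aberrations per gene and sample must
#' already be collapsed to one event, i.e. the inputs are binary),
#' jointly BH-corrected; the TMB distributions are compared by a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param aber_a,aber_b Samples x genes logical matrices over the same
#'   gene universe.
#' @param tmb_a,tmb_b Optional per-sample TMB vectors.
#' @return List with `genes` (`data.frame`: gene, freq_a, freq_b,
#'   freq_diff, odds_ratio, p, q) and `tmb` (`htest` or `NULL`).
#' @export
compare_cohorts <- function(aber_a, aber_b, tmb_a = NULL, tmb_b = NULL) {
  aber_a <- as.matrix(aber_a); aber_b <- as.matrix(aber_b)
  if (!nrow(aber_a) || !nrow(aber_b)) stop("empty cohort")
  genes <- colnames(aber_a)
  if (!identical(sort(genes), sort(colnames(aber_b)))) {
    stop("cohorts must share one gene universe")
  }
  aber_b <- aber_b[, genes, drop = FALSE]
  mode(aber_a) <- "logical"; mode(aber_b) <- "logical"
  na <- nrow(aber_a); nb <- nrow(aber_b)
  rows <- lapply(genes, function(g) {
    ca <- sum(aber_a[, g]); cb <- sum(aber_b[, g])
    ft <- fisher.test(matrix(c(ca, na - ca, cb, nb - cb), 2))
    data.frame(gene = g, freq_a = ca / na, freq_b = cb / nb,
               freq_diff = ca / na - cb / nb,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  tmb_test <- if (!is.null(tmb_a) && !is.null(tmb_b)) {
    suppressWarnings(wilcox.test(tmb_a, tmb_b, alternative = "two.sided"))
  }
  list(genes = out, tmb = tmb_test)
}

#' Feature importance per principal component (cos-squared)
#'
#' Principal component analysis (with centering and scaling by default)
#' of the feature matrix; for each feature, the squared coordinate on
#' each component normalized so the per-feature cos-squared values sum to
#' 1 across all components.
#'
#' @param m Samples x features matrix (>= 2 rows).
#' @param center,scale. Passed to [stats::prcomp()].
#' @return List with `cos2` (features x components), `loadings`
#'   (rotation), `sdev`.
#' @export
pca_cos2 <- function(m, center = TRUE, scale. = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 samples")
  pc <- prcomp(m, center = center, scale. = scale.)
  coord <- sweep(pc$rotation, 2, pc$sdev, "*")
  cos2 <- coord^2 / rowSums(coord^2)
  list(cos2 = cos2, loadings = pc$rotation, sdev = pc$sdev)
}
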