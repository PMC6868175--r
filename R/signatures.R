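#' The 96 trinucleotide substitution classes
#'
#' Canonical class order used by every spectrum and catalog in the
#' package: substitutions alphabetically (C>A, C>G, C>T, T>A, T>C, T>G),
#' then the flanking context alphabetically (A, C, G, T on each side).
#' Labels are in `"A[C>A]A"` style, pyrimidine-normalized.
#'
#' @return Character vector of 96 class labels.
#' @export
contexts_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(l, r) {
      paste0(l, "[", s, "]", r)
    })))
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(unname(REVCOMP[ch])), collapse = "")
  }, character(1))
}

#' Build a 96-class mutational spectrum
#'
#' Counts a sample's SNVs into the 96 trinucleotide substitution classes.
#' SNVs whose reference base is a purine are reverse-complemented
#' (reference base, alternate base and context) onto the pyrimidine
#' strand.  The context comes from the `trinucleotide` column or, when
#' absent, from `ref_seqs`; SNVs with neither are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param variants Variant `data.frame` (non-SNV rows are ignored).
#' @param ref_seqs Optional named character vector of chromosome
#'   sequences used to look up missing contexts.
#' @return Named integer vector of length 96 (class `spectrum96`), in
#'   [contexts_96()] order, summing to the number of usable SNVs.
#' @export
build_spectrum <- function(variants, ref_seqs = NULL) {
  variants <- validate_variants(variants)
  snv <- variants[variants$vclass == "SNV", , drop = FALSE]
  ctx <- toupper(snv$trinucleotide)
  if (!is.null(ref_seqs) && nrow(snv)) {
    need <- which(is.na(ctx))
    for (i in need) {
      seq <- ref_seqs[[snv$chrom[i]]]
      p <- snv$pos[i]
      if (!is.null(seq) && p >= 2 && p + 1 <= nchar(seq)) {
        ctx[i] <- toupper(substring(seq, p - 1, p + 1))
      }
    }
  }
  ref <- toupper(snv$ref); alt <- toupper(snv$alt)
  usable <- !is.na(ctx) & nchar(ctx) == 3L &
    !grepl("[^ACGT]", ctx) & substring(ctx, 2, 2) == ref
  n_excluded <- sum(!usable)
  ctx <- ctx[usable]; ref <- ref[usable]; alt <- alt[usable]
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ctx[pur] <- revcomp(ctx[pur])
    ref[pur] <- unname(REVCOMP[ref[pur]])
    alt[pur] <- unname(REVCOMP[alt[pur]])
  }
  labels <- paste0(substring(ctx, 1, 1), "[", ref, ">", alt, "]",
                   substring(ctx, 3, 3))
  lv <- contexts_96()
  counts <- table(factor(labels, levels = lv))
  out <- setNames(as.integer(counts), lv)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- "spectrum96"
  out
}

#' Load or build a signature catalog
#'
#' A catalog is a 96 x K matrix of signature probability columns (each
#' summing to 1) with rows in [contexts_96()] order.  `read_signature_catalog`
#' reads a COSMIC-style TSV whose first column holds `"A[C>A]A"`-style
#' context labels and whose remaining columns are signatures; rows are
#' reordered to the canonical context order.
#'
#' @param mat Numeric matrix, 96 rows.
#' @param names Optional column names.
#' @return A validated matrix of class `signature_catalog`.
#' @export
signature_catalog <- function(mat, names = colnames(mat)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 96L) stop("a signature catalog needs 96 rows")
  if (any(mat < 0)) stop("signature probabilities must be >= 0")
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("signature column(s) do not sum to 1: ",
         paste(which(abs(sums - 1) > 1e-6), collapse = ", "))
  }
  if (is.null(names)) names <- sprintf("Signature.%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(contexts_96(), names)
  class(mat) <- c("signature_catalog", class(mat))
  mat
}

#' @rdname signature_catalog
#' @param path TSV path for `read_signature_catalog`.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1]]
  mat <- as.matrix(df[-1])
  idx <- match(contexts_96(), labels)
  if (anyNA(idx)) stop("catalog is missing context rows")
  signature_catalog(mat[idx, , drop = FALSE], colnames(mat))
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the active-set
#' method.  Deterministic.
#'
#' @param A Design matrix.
#' @param b Response vector.
#' @param tol Dual-feasibility tolerance (default scaled machine eps).
#' @return List with `x`, `residual_norm`.
#' @export
nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A); b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  passive <- rep(FALSE, n)
  x <- numeric(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[passive] > 0)) break
      viol <- passive & s <= 0
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)))
}

#' Refit a spectrum against a signature catalog
#'
#' Expresses a 96-class spectrum as a constrained (non-negative) linear
#' combination of the catalog's signature columns via non-negative least
#' squares.
#'
#' @param spectrum A [build_spectrum()] result or bare 96-vector.
#' @param catalog A [signature_catalog()].
#' @return A list of class `signature_fit` with `weights` (K non-negative
#'   loadings, named), `relative_contributions` (weights normalized to
#'   sum 1; all-`NA` for a zero spectrum) and `residual_norm`.
#' @export
fit_signatures <- function(spectrum, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  m <- as.numeric(spectrum)
  if (length(m) != 96L) stop("spectrum must have 96 entries")
  fit <- nnls(unclass(catalog), m)
  w <- setNames(fit$x, colnames(catalog))
  rel <- if (sum(w) > 0) w / sum(w) else setNames(rep(NA_real_, length(w)),
                                                  names(w))
  structure(list(weights = w, relative_contributions = rel,
                 residual_norm = fit$residual_norm),
            class = "signature_fit")
}

#' Cosine similarity between spectra or signatures
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return `dot(a, b) / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

nmf_kl_run <- function(V, rank, max_iter, eps = 1e-12) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  obj <- numeric(max_iter)
  kl <- function(WH) sum(V * log((V + eps) / (WH + eps)) - V + WH)
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (crossprod(W, V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) / rep(rowSums(H) + eps,
                                               each = n)
    obj[it] <- kl(W %*% H)
    if (it > 1 && abs(obj[it - 1] - obj[it]) <
        1e-10 * (abs(obj[it]) + 1)) {
      obj <- obj[seq_len(it)]
      break
    }
  }
  list(W = W, H = H, objective = obj)
}

#' De novo signature extraction by NMF with rank diagnostics
#'
#' Factorizes a cohort spectrum matrix (96 x samples) with
#' Kullback-Leibler multiplicative-update NMF, using `n_runs` random
#' restarts per candidate rank.  Sample-to-signature assignments (argmax
#' of the loading matrix) across runs define a consensus matrix per rank,
#' from which the cophenetic correlation coefficient and mean silhouette
#' width are computed; the residual sum of squares comes from the best
#' run (lowest KL divergence).  The factorization returned is the best
#' run at `chosen_rank`.
#'
#' @param spectra Numeric matrix, 96 rows, one column per sample (at
#'   least 2).
#' @param ranks Candidate ranks (default 2:15, bounded below
#'   `min(dim(spectra))`).
#' @param n_runs Random restarts per rank (default 50).
#' @param seed Integer seed; run r at rank k uses a deterministic
#'   derivative so results are reproducible.
#' @param chosen_rank Rank of the returned factorization (default 5,
#'   clipped into `ranks`).
#' @param max_iter Multiplicative-update iterations per run.
#' @return List with `metrics` (`data.frame`: rank, cophenetic, rss,
#'   silhouette), `rank` (the chosen rank), `W` (96 x rank signatures,
#'   columns scaled to sum 1), `H` (rank x samples exposures), and
#'   `objective` (KL trace of the returned run, non-increasing).
#' @export
denovo_nmf <- function(spectra, ranks = 2:15, n_runs = 50L, seed = 1L,
                       chosen_rank = 5L, max_iter = 400L) {
  V <- as.matrix(spectra)
  if (ncol(V) < 2) stop("need >= 2 samples")
  if (any(V < 0)) stop("spectra must be non-negative")
  ranks <- ranks[ranks < min(dim(V))]
  if (!length(ranks)) stop("no candidate rank below min(dim(spectra))")
  if (n_runs < 2) stop("n_runs must be >= 2")
  chosen_rank <- if (chosen_rank %in% ranks) chosen_rank else
    ranks[which.min(abs(ranks - chosen_rank))]
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  metrics <- data.frame(rank = ranks, cophenetic = NA_real_,
                        rss = NA_real_, silhouette = NA_real_)
  best_fit <- NULL
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    consensus <- matrix(0, ncol(V), ncol(V))
    best <- NULL
    for (run in seq_len(n_runs)) {
      set.seed(seed * 1000L + r * 100L + run)
      fit <- nmf_kl_run(V, r, max_iter)
      assign_ <- apply(fit$H, 2, which.max)
      consensus <- consensus + outer(assign_, assign_, "==")
      if (is.null(best) || min(fit$objective) < min(best$objective)) {
        best <- fit
      }
    }
    consensus <- consensus / n_runs
    d <- as.dist(1 - consensus)
    metrics$rss[ri] <- sum((V - best$W %*% best$H)^2)
    if (max(d) < .Machine$double.eps) {
      warning(sprintf(
        "rank %d: degenerate consensus (all runs agree on one cluster); cophenetic/silhouette undefined",
        r))
    } else {
      hc <- hclust(d, method = "average")
      metrics$cophenetic[ri] <- suppressWarnings(
        cor(d, cophenetic(hc)))
      cl <- cutree(hc, k = min(r, ncol(V) - 1L))
      if (length(unique(cl)) > 1) {
        sil <- cluster::silhouette(cl, d)
        metrics$silhouette[ri] <- mean(sil[, "sil_width"])
      }
    }
    if (r == chosen_rank) best_fit <- best
  }
  Wn <- best_fit$W
  scale <- colSums(Wn)
  Wn <- sweep(Wn, 2, scale, "/")
  Hn <- best_fit$H * scale
  rownames(Wn) <- rownames(V)
  colnames(Hn) <- colnames(V)
  list(metrics = metrics, rank = chosen_rank, W = Wn, H = Hn,
       objective = best_fit$objective)
}
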