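# Synthetic mCRPC cohort generator.  Plants eight genotype profiles
# (burden levels, SV category mixtures, ploidy, MSI, kataegis foci,
# oscillating-CN chromothripsis, signature mixtures, driver-gene flags)
# with full truth labels, so every analysis stage is testable without
# controlled-access data.

#' A genotype simulation profile
#'
#' Parameters of one planted genotype.  Burdens are per-Mbp rates on the
#' simulation genome except for MSI genotypes, whose InDel burden is
#' planted at absolute-count level (`msi_indel_count`) because the MSI
#' rule is an absolute-count rule.
#'
#' @param name Genotype label.
#' @param n_samples Samples drawn from this profile by default.
#' @param snv_rate,indel_rate,mnv_rate Genome-wide mutations per Mbp.
#' @param msi Logical: plant microsatellite instability.
#' @param msi_indel_count Mean planted InDel count for MSI genotypes
#'   (drawn Normal, sd 5%, floored so the expected qualifying subset
#'   clears the MSI threshold by at least 10%).
#' @param msi_qualifying_frac Fraction of InDels given qualifying repeat
#'   annotations (0.9 for MSI, 0.35 otherwise).
#' @param n_sv_mean,n_sv_dispersion Negative-binomial SV count (mean,
#'   size).
#' @param sv_mix Probability vector over the seven [sv_categories()].
#' @param ploidy_mean,ploidy_sd Normal ploidy draw, truncated at 1.
#' @param kataegis_prob Probability of carrying at least one kataegis
#'   focus.
#' @param kataegis_foci_mean Mean focus count in carriers (>= 1).
#' @param chromothripsis_prob Probability of a planted chromothripsis
#'   event.
#' @param signature_mix Named weights over the signature catalog columns
#'   (normalized internally).
#' @param driver_probs Named per-gene aberration probabilities.
#' @param ets_prob Probability of an ETS-family fusion flag.
#' @param chord_high Draw a high HR-deficiency input score (BRCAness
#'   genotypes).
#' @return A list of class `genotype_profile`.
#' @export
genotype_profile <- function(name, n_samples,
                             snv_rate, indel_rate, mnv_rate = 0.0083 * snv_rate,
                             msi = FALSE, msi_indel_count = 14000,
                             msi_qualifying_frac = if (msi) 0.9 else 0.35,
                             n_sv_mean, n_sv_dispersion = 60,
                             sv_mix,
                             ploidy_mean, ploidy_sd = 0.08,
                             kataegis_prob = 0.15, kataegis_foci_mean = 1.5,
                             chromothripsis_prob = 0,
                             signature_mix,
                             driver_probs = numeric(),
                             ets_prob = 0.3, chord_high = FALSE) {
  sv_mix <- sv_mix / sum(sv_mix)
  if (is.null(names(sv_mix))) names(sv_mix) <- sv_categories()
  stopifnot(setequal(names(sv_mix), sv_categories()))
  if (any(c(snv_rate, indel_rate, mnv_rate) < 0)) {
    stop("burden rates must be >= 0")
  }
  if (chromothripsis_prob > 0 && n_sv_mean < 25) {
    stop("inconsistent profile: chromothripsis planted but n_sv_mean < 25")
  }
  structure(list(name = name, n_samples = as.integer(n_samples),
                 snv_rate = snv_rate, indel_rate = indel_rate,
                 mnv_rate = mnv_rate, msi = msi,
                 msi_indel_count = msi_indel_count,
                 msi_qualifying_frac = msi_qualifying_frac,
                 n_sv_mean = n_sv_mean,
                 n_sv_dispersion = n_sv_dispersion,
                 sv_mix = sv_mix[sv_categories()],
                 ploidy_mean = ploidy_mean, ploidy_sd = ploidy_sd,
                 kataegis_prob = kataegis_prob,
                 kataegis_foci_mean = kataegis_foci_mean,
                 chromothripsis_prob = chromothripsis_prob,
                 signature_mix = signature_mix,
                 driver_probs = driver_probs, ets_prob = ets_prob,
                 chord_high = chord_high),
            class = "genotype_profile")
}

# aberration probabilities shared by every genotype
COMMON_DRIVERS <- c(TP53 = 0.50, AR = 0.55, PTEN = 0.35, RB1 = 0.22)
BACKGROUND_DRIVER_P <- 0.04
CLUSTER_DRIVERS <- list(
  A = c(MSH6 = 0.692, JAK1 = 0.692, CIC = 0.583),
  B = c(CDK12 = 0.846, FGF3 = 0.692, FGF4 = 0.692),
  D = c(BRCA2 = 0.682))

driver_universe <- function() {
  sort(unique(c(names(COMMON_DRIVERS),
                unlist(lapply(CLUSTER_DRIVERS, names)))))
}

profile_driver_probs <- function(cluster) {
  probs <- setNames(rep(BACKGROUND_DRIVER_P, length(driver_universe())),
                    driver_universe())
  probs[names(COMMON_DRIVERS)] <- COMMON_DRIVERS
  own <- CLUSTER_DRIVERS[[cluster]]
  if (!is.null(own)) probs[names(own)] <- own
  probs
}

#' The default eight-genotype profile set
#'
#' Eight metastatic prostate cancer genotypes: an MSI genotype with very
#' high InDel-rich burden (A), a large-tandem-duplication genotype with
#' CDK12 loss (B), a small-tandem-duplication genotype (C), an
#' HRD/BRCAness genotype rich in deletions (D), a chromothripsis
#' genotype (F), an insertion-enriched genotype (H) and two genotypes
#' without a dominant SV category (E, G).  Sizes scale the cohort
#' proportions 13:13:15:22:55:20:34:25 to `n_total` samples by largest
#' remainder.
#'
#' @param n_total Total cohort size (default 200).
#' @return Named list of [genotype_profile()] objects.
#' @export
default_profiles <- function(n_total = 200L) {
  base_n <- c(A = 13, B = 13, C = 15, D = 22, E = 55, F = 20, G = 34,
              H = 25)
  exact <- base_n / sum(base_n) * n_total
  n <- floor(exact)
  extra <- order(exact - n, decreasing = TRUE)[seq_len(n_total - sum(n))]
  n[extra] <- n[extra] + 1L
  mix <- function(...) {
    v <- c(...)
    setNames(v, sv_categories())
  }
  # order: translocation, inversion, insertion, dup_small, dup_large,
  #        del_small, del_large
  mixes <- list(
    A = mix(.20, .28, .05, .12, .05, .22, .08),
    B = mix(.12, .18, .04, .12, .32, .16, .06),
    C = mix(.13, .18, .04, .35, .05, .19, .06),
    D = mix(.12, .16, .04, .08, .03, .37, .20),
    E = mix(.28, .18, .05, .12, .05, .24, .08),
    F = mix(.20, .28, .05, .12, .05, .22, .08),
    G = mix(.12, .40, .05, .10, .04, .21, .08),
    H = mix(.15, .20, .25, .10, .04, .20, .06))
  sigs <- list(
    A = c(aging = 0.25, msi_like = 0.60, flat = 0.15),
    B = c(aging = 0.55, flat = 0.35, apobec = 0.10),
    C = c(aging = 0.50, flat = 0.30, apobec = 0.20),
    D = c(aging = 0.25, brca_like = 0.60, flat = 0.15),
    E = c(aging = 0.55, flat = 0.30, apobec = 0.15),
    F = c(aging = 0.50, flat = 0.35, smoking_like = 0.15),
    G = c(aging = 0.60, flat = 0.25, apobec = 0.15),
    H = c(aging = 0.55, flat = 0.30, smoking_like = 0.15))
  # (total per-Mbp burden, SNV/InDel ratio) per genotype; A is planted at
  # count level to satisfy the absolute MSI rule on the compact genome
  tmb <- c(A = 36.88, B = 2.44, C = 3.00, D = 4.39, E = 2.12, F = 2.51,
           G = 2.12, H = 2.30)
  ratio <- c(A = 0.99, B = 7.07, C = 6.73, D = 7.28, E = 7.13, F = 6.15,
             G = 6.13, H = 5.81)
  n_sv <- c(A = 149, B = 669, C = 237, D = 323, E = 178, F = 400,
            G = 222, H = 201)
  ploidy <- c(A = 1.92, B = 2.39, C = 3.19, D = 2.16, E = 3.24, F = 3.35,
              G = 2.98, H = 1.97)
  kat_p <- c(A = 6, B = 1, C = 2, D = 5, E = 13, F = 7, G = 5, H = 3) /
    base_n
  ct_p <- c(A = 1, B = 0, C = 1, D = 5, E = 8, F = 16, G = 8, H = 7) /
    base_n
  ets_p <- c(A = 3, B = 2, C = 7, D = 7, E = 25, F = 10, G = 23, H = 16) /
    base_n
  profs <- lapply(names(base_n), function(cl) {
    snv <- tmb[[cl]] * ratio[[cl]] / (1 + ratio[[cl]] + 0.0083 * ratio[[cl]])
    genotype_profile(
      name = cl, n_samples = n[[cl]],
      snv_rate = snv, indel_rate = snv / ratio[[cl]],
      msi = cl == "A",
      n_sv_mean = n_sv[[cl]], sv_mix = mixes[[cl]],
      ploidy_mean = ploidy[[cl]],
      kataegis_prob = kat_p[[cl]],
      chromothripsis_prob = ct_p[[cl]],
      signature_mix = sigs[[cl]],
      driver_probs = profile_driver_probs(cl),
      ets_prob = ets_p[[cl]],
      chord_high = cl == "D")
  })
  setNames(profs, names(base_n))
}

#' Packaged synthetic signature catalog
#'
#' Five synthetic, well-separated 96-class signatures (aging-, MSI-,
#' BRCA-, APOBEC- and smoking-like shapes) used by the simulator; no
#' external catalog download is needed.
#' @return A [signature_catalog()].
#' @export
default_signature_catalog <- function() {
  read_signature_catalog(system.file("extdata", "synthetic_signatures.tsv",
                                     package = "scarscape"))
}

#' Packaged signature-to-etiology grouping
#'
#' Editable mapping from catalog signature names to proposed etiologies,
#' used to summarize refit contributions per etiology.
#' @return `data.frame` with columns `signature`, `etiology`.
#' @export
default_etiology_map <- function() {
  read.delim(system.file("extdata", "etiology_map.tsv",
                         package = "scarscape"),
             stringsAsFactors = FALSE)
}

#' Summarize signature contributions per proposed etiology
#'
#' @param fit A [fit_signatures()] result.
#' @param map `data.frame` with `signature` and `etiology` columns.
#' @return Named numeric vector of summed relative contributions.
#' @export
etiology_contributions <- function(fit, map = default_etiology_map()) {
  rel <- fit$relative_contributions
  et <- map$etiology[match(names(rel), map$signature)]
  et[is.na(et)] <- "unknown"
  tapply(rel, et, sum)
}

sample_positions <- function(n, genome) {
  lens <- genome$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- floor(runif(n, 1, lens[chrom])) + 0
  data.frame(chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

class_to_snv <- function(classes) {
  # "A[C>T]G" -> trinucleotide ACG, ref C, alt T
  data.frame(
    trinucleotide = paste0(substring(classes, 1, 1),
                           substring(classes, 3, 3),
                           substring(classes, 7, 7)),
    ref = substring(classes, 3, 3),
    alt = substring(classes, 5, 5), stringsAsFactors = FALSE)
}

sim_snvs <- function(n_background, foci, profile, genome, catalog) {
  bg <- sample_positions(n_background, genome)
  if (nrow(foci)) {
    foci_pos <- do.call(rbind, lapply(seq_len(nrow(foci)), function(i) {
      gaps <- runif(foci$n_snvs[i] - 1L, 100, 1500)
      data.frame(chrom = foci$chrom[i],
                 pos = as.integer(foci$start[i] + cumsum(c(0, gaps))),
                 stringsAsFactors = FALSE)
    }))
    bg <- rbind(bg, foci_pos)
  }
  n <- nrow(bg)
  mixw <- setNames(rep(0, ncol(catalog)), colnames(catalog))
  mixw[names(profile$signature_mix)] <- profile$signature_mix
  class_p <- drop(unclass(catalog) %*% (mixw / sum(mixw)))
  classes <- sample(contexts_96(), n, replace = TRUE, prob = class_p)
  ctx <- class_to_snv(classes)
  variant_table(chrom = bg$chrom, pos = bg$pos, ref = ctx$ref,
                alt = ctx$alt,
                alt_reads = 4L + rpois(n, 20),
                trinucleotide = ctx$trinucleotide,
                coding = runif(n) <
                  genome$callable_coding_bases / genome$callable_genomic_bases)
}

sim_indels <- function(n, profile, genome) {
  if (n == 0) return(variant_table())
  at <- sample_positions(n, genome)
  ins <- runif(n) < 0.5
  unit_n <- sample(1:3, n, replace = TRUE, prob = c(.6, .25, .15))
  units <- vapply(unit_n, function(k) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
  anchor <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ref <- ifelse(ins, anchor, paste0(anchor, units))
  alt <- ifelse(ins, paste0(anchor, units), anchor)
  qual <- runif(n) < profile$msi_qualifying_frac
  homo <- unit_n == 1L
  rep_count <- integer(n)
  # qualifying: homopolymer run >= 5 or unit 2-4 repeated >= 4
  rep_count[qual & homo] <- sample(5:12, sum(qual & homo), replace = TRUE)
  rep_count[qual & !homo] <- sample(4:8, sum(qual & !homo), replace = TRUE)
  # non-qualifying: too few copies
  rep_count[!qual & homo] <- sample(1:4, sum(!qual & homo), replace = TRUE)
  rep_count[!qual & !homo] <- sample(1:3, sum(!qual & !homo),
                                     replace = TRUE)
  variant_table(chrom = at$chrom, pos = at$pos, ref = ref, alt = alt,
                alt_reads = 4L + rpois(n, 18),
                coding = runif(n) <
                  genome$callable_coding_bases / genome$callable_genomic_bases,
                repeat_unit_len = unit_n, repeat_count = rep_count)
}

sim_mnvs <- function(n, genome) {
  if (n == 0) return(variant_table())
  at <- sample_positions(n, genome)
  pair <- function() {
    b <- c("A", "C", "G", "T")
    r <- sample(b, 2, replace = TRUE)
    a <- vapply(r, function(x) sample(setdiff(b, x), 1), character(1))
    c(paste(r, collapse = ""), paste(a, collapse = ""))
  }
  ra <- t(vapply(seq_len(n), function(i) pair(), character(2)))
  variant_table(chrom = at$chrom, pos = at$pos, ref = ra[, 1],
                alt = ra[, 2], alt_reads = 4L + rpois(n, 18),
                coding = runif(n) <
                  genome$callable_coding_bases / genome$callable_genomic_bases)
}

sim_driver_variants <- function(genes, genome) {
  if (!length(genes)) return(variant_table())
  at <- sample_positions(length(genes), genome)
  n <- length(genes)
  variant_table(chrom = at$chrom, pos = at$pos,
                ref = rep("C", n), alt = rep("T", n),
                alt_reads = 4L + rpois(n, 20),
                trinucleotide = "ACA", coding = TRUE, gene = genes,
                effect = sample(c("missense", "nonsense", "frameshift"),
                                n, replace = TRUE,
                                prob = c(.6, .2, .2)))
}

sv_size_range <- function(category) {
  switch(category,
         dup_small = c(1e3, 1e5), del_small = c(1e3, 1e5),
         dup_large = c(1e5 + 1, 5e6), del_large = c(1e5 + 1, 5e6),
         inversion = c(1e3, 5e6), insertion = c(50, 1e4),
         stop("no size range for ", category))
}

sim_svs <- function(n, mix, genome, exclude_chrom = NULL) {
  if (n == 0) return(sv_table())
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  lens <- genome$chrom_lengths
  intra_lens <- lens
  if (!is.null(exclude_chrom)) {
    intra_lens <- lens[setdiff(names(lens), exclude_chrom)]
  }
  rows <- lapply(cats, function(cat) {
    if (cat == "translocation") {
      ch <- sample(names(lens), 2, replace = FALSE)
      return(data.frame(svtype = "TRA", chrom1 = ch[1],
                        pos1 = as.integer(runif(1, 1, lens[ch[1]])),
                        chrom2 = ch[2],
                        pos2 = as.integer(runif(1, 1, lens[ch[2]])),
                        stringsAsFactors = FALSE))
    }
    rng <- sv_size_range(cat)
    size <- floor(exp(runif(1, log(rng[1]), log(rng[2]))))
    ch <- sample(names(intra_lens), 1,
                 prob = intra_lens / sum(intra_lens))
    p1 <- as.integer(runif(1, 1, intra_lens[ch] - size))
    type <- switch(cat,
                   inversion = sample(c("INV_HH", "INV_TT"), 1),
                   insertion = "INS",
                   dup_small = , dup_large = "DUP",
                   del_small = , del_large = "DEL")
    data.frame(svtype = type, chrom1 = ch, pos1 = p1, chrom2 = ch,
               pos2 = as.integer(p1 + size), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sv_table(svtype = df$svtype, chrom1 = df$chrom1, pos1 = df$pos1,
           chrom2 = df$chrom2, pos2 = df$pos2,
           baf = round(runif(nrow(df), 0.15, 1), 3))
}

sim_segments <- function(ploidy, genome, ct_region = NULL,
                         ct_states = NULL) {
  rows <- lapply(names(genome$chrom_lengths), function(ch) {
    len <- genome$chrom_lengths[[ch]]
    n_seg <- sample(8:15, 1)
    cuts <- sort(sample.int(len - 1L, n_seg - 1L))
    start <- c(1, cuts + 1)
    end <- c(cuts, len)
    cn <- pmax(0, ploidy + rnorm(n_seg, 0, 0.35))
    df <- data.frame(chrom = ch, start = start, end = end, cn = cn,
                     stringsAsFactors = FALSE)
    if (!is.null(ct_region) && ch == ct_region$chrom) {
      # carve the oscillating chromothripsis block into the baseline
      keep <- df[df$end < ct_region$start | df$start > ct_region$end, ,
                 drop = FALSE]
      left <- df[df$start <= ct_region$start & df$end >= ct_region$start, ,
                 drop = FALSE]
      right <- df[df$start <= ct_region$end & df$end >= ct_region$end, ,
                  drop = FALSE]
      if (nrow(left)) left$end <- ct_region$start - 1
      if (nrow(right)) right$start <- ct_region$end + 1
      n_osc <- length(ct_states)
      bounds <- round(seq(ct_region$start, ct_region$end + 1,
                          length.out = n_osc + 1))
      osc <- data.frame(chrom = ch, start = bounds[-(n_osc + 1)],
                        end = bounds[-1] - 1,
                        cn = pmin(pmax(ct_states + rnorm(n_osc, 0, 0.05),
                                       ct_states - 0.4),
                                  ct_states + 0.4),
                        stringsAsFactors = FALSE)
      trim <- function(d) d[d$end >= d$start, , drop = FALSE]
      df <- rbind(trim(keep), trim(left), trim(right), osc)
    }
    df
  })
  df <- do.call(rbind, rows)
  cn_table(chrom = df$chrom, start = df$start, end = df$end, cn = df$cn)
}

sim_chromothripsis_svs <- function(region, n_sv) {
  types <- sample(rep(c("DEL", "DUP", "INV_HH", "INV_TT"),
                      length.out = n_sv))
  span <- region$end - region$start
  p1 <- as.integer(runif(n_sv, region$start, region$end - span * 0.02))
  size <- floor(exp(runif(n_sv, log(5e4), log(span * 0.3))))
  p2 <- pmin(p1 + size, region$end)
  sv_table(svtype = types, chrom1 = region$chrom, pos1 = p1,
           chrom2 = region$chrom, pos2 = as.integer(p2),
           baf = round(runif(n_sv, 0.2, 1), 3))
}

#' Simulate one sample from a genotype profile
#'
#' Draws a complete [sample_data()] realization (small variants with
#' contexts and repeat annotations, SVs, CN segments, purity, metadata)
#' together with its ground truth.  Deterministic per seed.
#'
#' @param profile A [genotype_profile()].
#' @param genome A [genome_spec()] (default [mini_genome()]).
#' @param seed Integer seed.
#' @param catalog Signature catalog for drawing SNV contexts.
#' @param sample_id Identifier (default derived from profile and seed).
#' @return List with `sample` (a `sample_data`) and `truth` (a list of
#'   planted and realized values).
#' @export
simulate_sample <- function(profile, genome = mini_genome(), seed = 1L,
                            catalog = default_signature_catalog(),
                            sample_id = NULL) {
  stopifnot(inherits(profile, "genotype_profile"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_seed%d", profile$name, seed)
  }
  mb <- sum(genome$chrom_lengths) / 1e6
  noise <- function(x) x * rlnorm(1, 0, 0.08)

  # burden counts
  n_indel <- if (profile$msi) {
    # floored so that even the qualifying subset (msi_qualifying_frac)
    # stays above the MSI threshold
    max(round(rnorm(1, profile$msi_indel_count,
                    0.05 * profile$msi_indel_count)),
        ceiling(1.1 * 11436 / profile$msi_qualifying_frac))
  } else {
    rpois(1, noise(profile$indel_rate) * mb)
  }
  n_snv_bg <- if (profile$msi) {
    rpois(1, n_indel * profile$snv_rate / max(profile$indel_rate, 1e-9))
  } else {
    rpois(1, noise(profile$snv_rate) * mb)
  }
  n_mnv <- rpois(1, noise(profile$mnv_rate) * mb)

  # kataegis foci
  foci <- data.frame(chrom = character(), start = numeric(),
                     n_snvs = integer(), stringsAsFactors = FALSE)
  if (runif(1) < profile$kataegis_prob) {
    n_foci <- 1L + rpois(1, max(profile$kataegis_foci_mean - 1, 0))
    lens <- genome$chrom_lengths
    foci <- data.frame(
      chrom = sample(names(lens), n_foci, replace = TRUE),
      start = NA_real_, n_snvs = sample(5:30, n_foci, replace = TRUE),
      stringsAsFactors = FALSE)
    foci$start <- floor(runif(n_foci, 1, lens[foci$chrom] - 5e4))
  }

  # ploidy and chromothripsis plan
  ploidy <- max(1, rnorm(1, profile$ploidy_mean, profile$ploidy_sd))
  ct_region <- NULL; ct_states <- NULL; ct_svs <- sv_table()
  has_ct <- runif(1) < profile$chromothripsis_prob
  if (has_ct) {
    ct_chrom <- names(genome$chrom_lengths)[
      min(2L, length(genome$chrom_lengths))]
    clen <- genome$chrom_lengths[[ct_chrom]]
    span <- min(4e7, 0.4 * clen)
    start <- floor(runif(1, 1, clen - span))
    ct_region <- list(chrom = ct_chrom, start = start,
                      end = start + span)
    base_state <- max(1L, round(ploidy))
    n_osc <- sample(21:31, 1)
    ct_states <- rep(c(base_state, base_state + 1L),
                     length.out = n_osc)
    ct_svs <- sim_chromothripsis_svs(ct_region, 25L + rpois(1, 10))
  }

  # variants
  variants <- rbind(
    sim_snvs(n_snv_bg, foci, profile, genome, catalog),
    sim_indels(n_indel, profile, genome),
    sim_mnvs(n_mnv, genome))
  driver_flags <- runif(length(profile$driver_probs)) <
    profile$driver_probs
  names(driver_flags) <- names(profile$driver_probs)
  variants <- rbind(variants,
                    sim_driver_variants(names(which(driver_flags)),
                                        genome))

  # structural variants; when chromothripsis is planted, baseline
  # intrachromosomal junctions are routed away from the shattered
  # chromosome, whose junction catalog the event dominates
  n_sv_base <- rnbinom(1, mu = profile$n_sv_mean,
                       size = profile$n_sv_dispersion)
  alpha <- profile$sv_mix * 150
  mix <- rgamma(length(alpha), alpha)
  mix <- setNames(mix / sum(mix), names(alpha))
  svs <- sim_svs(n_sv_base, mix, genome,
                 exclude_chrom = if (has_ct) ct_region$chrom else NULL)
  svs <- rbind(svs, ct_svs)

  segments <- sim_segments(ploidy, genome, ct_region, ct_states)

  ets <- runif(1) < profile$ets_prob
  tcga_flags <- c(ERG = FALSE, ETV1 = FALSE, ETV4 = FALSE, FLI1 = FALSE,
                  SPOP = runif(1) < 0.10, FOXA1 = runif(1) < 0.08,
                  IDH1 = runif(1) < 0.01)
  if (ets) {
    partner <- sample(c("ERG", "ETV1", "ETV4", "FLI1"), 1,
                      prob = c(.7, .15, .1, .05))
    tcga_flags[partner] <- TRUE
  }

  sample <- sample_data(
    sample_id = sample_id, variants = variants, svs = svs,
    segments = segments,
    purity = round(runif(1, 0.2, 0.95), 3),
    chord_score = if (profile$chord_high) round(runif(1, 0.7, 1), 3)
                  else round(runif(1, 0, 0.3), 3),
    metadata = list(
      genotype = profile$name,
      biopsy_site = sample(c("bone", "lymph_node", "liver",
                             "soft_tissue"), 1),
      ets_fusion = ets, tcga_flags = as.list(tcga_flags),
      driver_flags = as.list(driver_flags)))

  truth <- list(
    sample_id = sample_id, genotype = profile$name,
    n_snv = nrow(variants[variants$vclass == "SNV", ]),
    n_indel = nrow(variants[variants$vclass == "InDel", ]),
    n_mnv = nrow(variants[variants$vclass == "MNV", ]),
    n_sv = nrow(svs),
    sv_category_counts = table(factor(categorize_sv(svs),
                                      levels = sv_categories())),
    ploidy_drawn = ploidy,
    mean_ploidy = mean_ploidy(segments),
    msi = profile$msi, kataegis_foci = foci,
    chromothripsis = has_ct, chromothripsis_region = ct_region,
    driver_flags = driver_flags, ets_fusion = ets,
    tcga_flags = tcga_flags)
  list(sample = sample, truth = truth)
}

#' Simulate a full cohort
#'
#' Draws `n_samples` per profile (sample i of the cohort uses the
#' derived seed `(seed * 1009 + i) mod (2^31 - 1)`), optionally writing
#' per-sample variant TSV / SEG / BEDPE files plus cohort metadata and
#' truth tables.
#'
#' @param profiles List of [genotype_profile()] objects (>= 2), e.g.
#'   [default_profiles()].
#' @param seed Master seed.
#' @param genome A [genome_spec()].
#' @param catalog Signature catalog.
#' @param out_dir Output directory (created), or `NULL` for in-memory
#'   only.
#' @return List with `cohort` (list of `sample_data`), `truth` (list of
#'   per-sample truth), `truth_table` (`data.frame` summary) and
#'   `out_dir`.
#' @export
simulate_cohort <- function(profiles = default_profiles(), seed = 1L,
                            genome = mini_genome(),
                            catalog = default_signature_catalog(),
                            out_dir = NULL) {
  if (length(profiles) < 2) stop("need >= 2 profiles")
  empty <- vapply(profiles, function(p) p$n_samples == 0L, logical(1))
  if (any(empty)) {
    warning("dropping profile(s) with n_samples = 0: ",
            paste(vapply(profiles[empty], `[[`, "", "name"),
                  collapse = ", "))
    profiles <- profiles[!empty]
  }
  plan <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genotype = p$name, idx = seq_len(p$n_samples),
               stringsAsFactors = FALSE)
  }))
  ids <- sprintf("S%03d", seq_len(nrow(plan)))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  by_name <- setNames(profiles, vapply(profiles, `[[`, "", "name"))
  cohort <- vector("list", nrow(plan))
  truth <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- simulate_sample(by_name[[plan$genotype[i]]], genome,
                         seed = (seed * 1009L + i) %% 2147483647L,
                         catalog = catalog, sample_id = ids[i])
    cohort[[i]] <- s$sample
    truth[[i]] <- s$truth
  }
  truth_table <- do.call(rbind, lapply(truth, function(t) {
    data.frame(sample_id = t$sample_id, genotype = t$genotype,
               n_snv = t$n_snv, n_indel = t$n_indel, n_mnv = t$n_mnv,
               n_sv = t$n_sv, mean_ploidy = t$mean_ploidy,
               msi = t$msi, chromothripsis = t$chromothripsis,
               n_kataegis_foci = nrow(t$kataegis_foci),
               ets_fusion = t$ets_fusion, stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in cohort) {
      write_variants(s$variants,
                     file.path(out_dir, paste0(s$sample_id,
                                               ".variants.tsv")))
      write_cn_segments(s$segments,
                        file.path(out_dir, paste0(s$sample_id, ".seg")))
      write_svs_bedpe(s$svs,
                      file.path(out_dir, paste0(s$sample_id, ".bedpe")))
    }
    meta <- do.call(rbind, lapply(cohort, function(s) {
      data.frame(sample_id = s$sample_id, purity = s$purity,
                 chord_score = s$chord_score,
                 biopsy_site = s$metadata$biopsy_site,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(meta, file.path(out_dir, "metadata.tsv"))
    write_tsv(truth_table, file.path(out_dir, "truth.tsv"))
  }
  list(cohort = cohort, truth = truth, truth_table = truth_table,
       out_dir = out_dir)
}

#' Binary trait matrix of a simulated cohort
#'
#' Driver-gene flags, ETS fusion, planted chromothripsis and kataegis
#' presence per sample, for enrichment testing against cluster labels.
#'
#' @param sim A [simulate_cohort()] result.
#' @return Logical samples x traits matrix, rownames = sample ids.
#' @export
cohort_trait_matrix <- function(sim) {
  genes <- names(sim$truth[[1]]$driver_flags)
  rows <- t(vapply(sim$truth, function(t) {
    c(t$driver_flags[genes],
      ets_fusion = t$ets_fusion,
      chromothripsis = t$chromothripsis,
      kataegis = nrow(t$kataegis_foci) > 0)
  }, logical(length(genes) + 3L)))
  rownames(rows) <- vapply(sim$truth, `[[`, "", "sample_id")
  rows
}
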