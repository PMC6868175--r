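#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: input/output paths, the
#' filter thresholds, the MSI threshold, the chromothripsis criteria, the
#' DUP/DEL size split, and the clustering options.  Fully serializable to
#' YAML; the effective config is written next to the outputs of each
#' run.
#'
#' @param input_dir Directory with per-sample `<id>.variants.tsv`,
#'   `<id>.seg`, `<id>.bedpe` and a `metadata.tsv` (as written by
#'   [simulate_cohort()]).
#' @param out_dir Output directory.
#' @param thresholds [filter_thresholds()].
#' @param criteria [chromothripsis_criteria()].
#' @param msi_threshold MSI qualifying-InDel threshold.
#' @param size_cut DUP/DEL size split (bp).
#' @param k Cluster count or `"auto"`.
#' @param n_boot Bootstrap replicates for node support (0 to skip).
#' @param seed Run seed (all randomness derives from it).
#' @param genome `"mini"`, `"hg19"`, or a [genome_spec()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            thresholds = filter_thresholds(),
                            criteria = chromothripsis_criteria(),
                            msi_threshold = 11436L, size_cut = 1e5,
                            k = "auto", n_boot = 0L, seed = 1L,
                            genome = "mini") {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 thresholds = thresholds, criteria = criteria,
                 msi_threshold = as.integer(msi_threshold),
                 size_cut = size_cut, k = k, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), genome = genome),
            class = "pipeline_config")
}

resolve_genome <- function(genome) {
  if (inherits(genome, "genome_spec")) return(genome)
  switch(genome,
         mini = mini_genome(),
         hg19 = genome_spec(),
         stop("unknown genome: ", genome))
}

config_yaml <- function(config) {
  ser <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::as.yaml(lapply(ser, function(x)
    if (is.list(x) || is.null(x)) x else unclass(x)))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(config_yaml(config), tf)
  unname(tools::md5sum(tf))
}

write_result_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scarscape %s config %s",
                     as.character(packageVersion("scarscape")), hash),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

pipe_log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible()
}

stage <- function(name, sample_id = NA, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s'%s failed: %s", name,
                 if (is.na(sample_id)) "" else
                   sprintf(" (sample %s)", sample_id),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full scar-genotyping pipeline
#'
#' Executes, in order: heuristic filtering, burden/MSI, kataegis,
#' signature refitting, chromothripsis, feature extraction, clustering
#' and cluster enrichment, reading per-sample files from
#' `config$input_dir` and writing one TSV per stage (plus the effective
#' config, a dendrogram in Newick format and a run log) to
#' `config$out_dir`.  Every output table carries the package version and
#' the config hash in a leading comment line.
#'
#' @param config A [pipeline_config()].
#' @param catalog Signature catalog (default packaged catalog).
#' @return Invisibly, a list with the per-stage tables and the
#'   [cluster_scars()] result.
#' @export
run_pipeline <- function(config, catalog = default_signature_catalog()) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- resolve_genome(config$genome)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_con <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(log_con))
  writeLines(config_yaml(config),
             file.path(config$out_dir, "run_config.yaml"))
  t0 <- Sys.time()

  meta <- stage("load", NA, read_tsv(
    file.path(config$input_dir, "metadata.tsv"), "sample_id",
    "metadata"))
  ids <- as.character(meta$sample_id)
  pipe_log(log_con, "loading %d samples from %s", length(ids),
           config$input_dir)
  cohort <- lapply(ids, function(id) {
    stage("load", id, {
      paths <- file.path(config$input_dir,
                         paste0(id, c(".variants.tsv", ".seg", ".bedpe")))
      missing <- paths[!file.exists(paths)]
      if (length(missing)) stop("missing input file(s): ",
                                paste(basename(missing), collapse = ", "))
      sample_data(id, read_variants(paths[1], genome = genome),
                  read_svs(paths[3]), read_cn_segments(paths[2]),
                  purity = if ("purity" %in% names(meta))
                    meta$purity[meta$sample_id == id][1] else NA_real_)
    })
  })

  # 1: heuristic filters
  filter_report <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    stage("filter", ids[i], {
      f <- apply_heuristic_filters(cohort[[i]]$variants,
                                   config$thresholds)
      cohort[[i]]$variants <<- f$retained
      cohort[[i]]$svs <<- filter_svs_by_baf(cohort[[i]]$svs,
                                            config$thresholds)
      data.frame(sample_id = ids[i], t(f$report))
    })
  }))
  write_result_table(filter_report,
                     file.path(config$out_dir, "filter_report.tsv"), hash)
  pipe_log(log_con, "filter: removed %d variants cohort-wide",
           sum(filter_report$removed_total))

  # 2: burden + MSI
  burden <- do.call(rbind, lapply(cohort, function(s) {
    stage("burden", s$sample_id, {
      counts <- count_mutations(s$variants)
      msi <- classify_msi(s$variants, config$msi_threshold)
      data.frame(sample_id = s$sample_id,
                 tmb_genomic = tmb(counts, genome, "genomic"),
                 tmb_coding = tmb(counts, genome, "coding"),
                 n_snv = counts$snv_g, n_indel = counts$indel_g,
                 n_mnv = counts$mnv_g,
                 msi_qualifying = msi$qualifying_indels,
                 is_msi = msi$is_msi)
    })
  }))
  write_result_table(burden, file.path(config$out_dir, "burden.tsv"),
                     hash)
  pipe_log(log_con, "burden: median genomic TMB %.2f, %d MSI sample(s)",
           median(burden$tmb_genomic), sum(burden$is_msi))

  # 3: kataegis
  kat <- do.call(rbind, lapply(cohort, function(s) {
    stage("kataegis", s$sample_id, {
      ev <- call_kataegis(s)
      if (nrow(ev)) cbind(sample_id = s$sample_id, ev,
                          hypermutated = attr(ev, "hypermutated"))
      else data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snvs = integer(), mean_imd = numeric(),
                      hypermutated = logical())
    })
  }))
  write_result_table(kat, file.path(config$out_dir, "kataegis.tsv"),
                     hash)
  pipe_log(log_con, "kataegis: %d events in %d sample(s)", nrow(kat),
           length(unique(kat$sample_id)))

  # 4: mutational signatures (refit against the catalog)
  sig <- do.call(rbind, lapply(cohort, function(s) {
    stage("signatures", s$sample_id, {
      fit <- fit_signatures(build_spectrum(s$variants), catalog)
      data.frame(sample_id = s$sample_id,
                 t(fit$relative_contributions),
                 residual_norm = fit$residual_norm)
    })
  }))
  write_result_table(sig, file.path(config$out_dir, "signatures.tsv"),
                     hash)
  pipe_log(log_con, "signatures: refit %d samples against %d signatures",
           nrow(sig), ncol(catalog))

  # 5: chromothripsis
  ct <- do.call(rbind, lapply(cohort, function(s) {
    stage("chromothripsis", s$sample_id, {
      ev <- call_chromothripsis(s, config$criteria, genome,
                                seed = config$seed)
      if (nrow(ev)) cbind(sample_id = s$sample_id, ev) else NULL
    })
  }))
  if (is.null(ct)) {
    ct <- data.frame(sample_id = character(), passed = logical())
  }
  write_result_table(ct, file.path(config$out_dir, "chromothripsis.tsv"),
                     hash)
  pipe_log(log_con, "chromothripsis: %d passing event(s)",
           sum(ct$passed))

  # 6: scar features
  features <- stage("features", NA,
                    build_feature_matrix(cohort, genome,
                                         config$size_cut))
  write_result_table(data.frame(sample_id = rownames(features),
                                features, check.names = FALSE),
                     file.path(config$out_dir, "features.tsv"), hash)

  # 7: clustering
  result <- stage("cluster", NA,
                  cluster_scars(features, k = config$k,
                                n_boot = config$n_boot,
                                seed = config$seed))
  labels <- data.frame(sample_id = names(result$labels),
                       cluster = result$labels)
  write_result_table(labels, file.path(config$out_dir, "clusters.tsv"),
                     hash)
  write_result_table(data.frame(k = seq_along(result$wss),
                                wss = result$wss),
                     file.path(config$out_dir, "wss.tsv"), hash)
  writeLines(hclust_newick(result$tree, names(result$labels)),
             file.path(config$out_dir, "dendrogram.nwk"))
  pipe_log(log_con, "cluster: k = %d", result$k)

  # 8: enrichment of aberrations across clusters
  traits <- stage("enrichment", NA, {
    gene_flags <- pipeline_gene_traits(cohort)
    extra <- cbind(
      chromothripsis = rownames(gene_flags) %in%
        ct$sample_id[ct$passed],
      kataegis = rownames(gene_flags) %in% kat$sample_id,
      msi = rownames(gene_flags) %in% burden$sample_id[burden$is_msi])
    cbind(gene_flags, extra)
  })
  enrich <- stage("enrichment", NA, {
    usable <- colSums(traits) > 0
    cluster_enrichment(result$labels,
                       traits[names(result$labels), usable,
                              drop = FALSE])
  })
  write_result_table(enrich, file.path(config$out_dir, "enrichment.tsv"),
                     hash)
  pipe_log(log_con, "enrichment: %d significant (cluster, trait) pairs",
           sum(enrich$significant))
  pipe_log(log_con, "done in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(filter_report = filter_report, burden = burden,
                 kataegis = kat, signatures = sig, chromothripsis = ct,
                 features = features, clustering = result,
                 enrichment = enrich, traits = traits,
                 config_hash = hash))
}

# per-sample binary gene flags from annotated coding variants
pipeline_gene_traits <- function(cohort) {
  genes <- sort(unique(unlist(lapply(cohort, function(s) {
    v <- s$variants
    unique(v$gene[!is.na(v$gene) & !is.na(v$effect)])
  }))))
  flags <- t(vapply(cohort, function(s) {
    v <- s$variants
    genes %in% v$gene[!is.na(v$gene) & !is.na(v$effect)]
  }, logical(length(genes))))
  dimnames(flags) <- list(vapply(cohort, `[[`, "", "sample_id"), genes)
  flags
}

# minimal Newick serialization of an hclust tree
hclust_newick <- function(tree, labels = tree$labels) {
  build <- function(id) {
    if (id < 0) return(labels[-id])
    l <- tree$merge[id, 1]; r <- tree$merge[id, 2]
    sprintf("(%s,%s):%g", build(l), build(r), tree$height[id])
  }
  paste0("(", build(nrow(tree$merge)), ");")
}
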