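# Pipeline orchestration: one config in, every intermediate as TSV
# plus a JSON run manifest out. All randomness flows from the single
# config seed, so identical config + seed gives identical outputs.

#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Defaults follow
#' the analysis conventions of the dual-screen design: correlation
#' threshold 0.4 on both evidence channels, adjusted-p cutoff 0.05,
#' promoter window -2000/+500, summit flank 5 kb. Round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' @param screen path to a long-form screen TSV (optional stage input)
#' @param de_dir directory of per-knockdown DE tables `<kd>.tsv`
#' @param timecourse,timecourse_sets time-course matrix TSV
#'   (genes x timepoints) and 2-column `set gene` TSV
#' @param genes_bed,peaks_bed,coverage_bedgraph genomic inputs
#' @param coverage_total_reads library size for the coverage track
#' @param out_dir output directory (required)
#' @param threshold dual-evidence correlation cutoff (default 0.4)
#' @param alpha DE significance cutoff (default 0.05)
#' @param promoter_upstream,promoter_downstream promoter window (bp)
#' @param flank,n_bins summit-matrix window half-width and bin count
#' @param n_boot trajectory bootstrap resamples
#' @param k_clusters clusters for the log2FC heatmap partition
#' @param rank_feature optional screen feature to rank hits on
#' @param seed integer seed for all stochastic stages
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(screen = NULL, de_dir = NULL,
                            timecourse = NULL, timecourse_sets = NULL,
                            genes_bed = NULL, peaks_bed = NULL,
                            coverage_bedgraph = NULL,
                            coverage_total_reads = NULL,
                            out_dir = NULL,
                            threshold = 0.4, alpha = 0.05,
                            promoter_upstream = 2000,
                            promoter_downstream = 500,
                            flank = 5000, n_bins = 100,
                            n_boot = 1000, k_clusters = 3,
                            rank_feature = NULL, seed = 1L) {
  cfg <- list(screen = screen, de_dir = de_dir, timecourse = timecourse,
              timecourse_sets = timecourse_sets, genes_bed = genes_bed,
              peaks_bed = peaks_bed, coverage_bedgraph = coverage_bedgraph,
              coverage_total_reads = coverage_total_reads,
              out_dir = out_dir, threshold = threshold, alpha = alpha,
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream,
              flank = flank, n_bins = n_bins, n_boot = n_boot,
              k_clusters = k_clusters, rank_feature = rank_feature,
              seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop_config("config requires out_dir")
  paths <- c("screen", "de_dir", "timecourse", "timecourse_sets",
             "genes_bed", "peaks_bed", "coverage_bedgraph")
  for (p in paths) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop_config("input path for `%s` does not exist: %s", p, cfg[[p]])
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_config("alpha must be in (0, 1)")
  invisible(cfg)
}

write_tsv <- function(x, path, rowname_col = NULL) {
  if (!is.null(rowname_col)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rowname_col),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full dual-screen integration pipeline
#'
#' Executes, in order and as far as the configured inputs allow:
#' screen normalization and phenotype correlation; DE gene sets,
#' log2FC matrix and transcriptome correlation; the dual-evidence
#' network; overlap enrichment of DE sets with peak-mapped genes;
#' hierarchical clustering of the log2FC matrix; trajectory
#' summaries; and peak/coverage signal quantification. Every
#' intermediate is written as TSV under `out_dir`, plus
#' `manifest.json` recording parameters, seed, package version and
#' input/output checksums. A failing stage writes a `FAILED` marker
#' naming the stage and aborts; earlier outputs are retained.
#'
#' @param config a [pipeline_config()] or the path to a YAML config
#' @return invisibly, a list with the in-memory results per stage and
#'   `outputs` (named vector of written file paths)
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  ctx <- new.env(parent = emptyenv())
  ctx$outputs <- character()
  ctx$results <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
                 failed_marker)
      stop_config("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e))
    })
  }
  out <- function(name) file.path(cfg$out_dir, name)

  if (!is.null(cfg$screen)) stage("screen", function() {
    tab <- read_screen_table(cfg$screen)
    profiles <- aggregate_replicates(zscore_by_plate(tab))
    ctx$outputs["profiles"] <- write_tsv(profiles$z, out("profiles.tsv"),
                                         rowname_col = "knockdown")
    if (!is.null(cfg$rank_feature))
      ctx$outputs["hits"] <- write_tsv(rank_hits(profiles, cfg$rank_feature),
                                       out("ranked_hits.tsv"))
    ctx$corr_hc <- phenotype_correlation(profiles)
    ctx$outputs["corr_highcontent"] <-
      write_tsv(ctx$corr_hc, out("corr_highcontent.tsv"), "knockdown")
    ctx$results$profiles <- profiles
  })

  if (!is.null(cfg$de_dir)) stage("de", function() {
    files <- sort(list.files(cfg$de_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(files)) stop_config("no DE tables in %s", cfg$de_dir)
    tables <- lapply(files, read_de_table)
    names(tables) <- sub("\\.tsv$", "", basename(files))
    ctx$de_sets <- lapply(tables, de_gene_sets, alpha = cfg$alpha)
    summ <- do.call(rbind, lapply(names(tables), function(nm) {
      s <- de_summary(tables[[nm]], cfg$alpha)
      data.frame(knockdown = nm, n_deregulated = s$n_deregulated,
                 fraction_up = s$fraction_up,
                 mean_abs_log2fc = s$mean_abs_log2fc_of_significant)
    }))
    ctx$outputs["de_summary"] <- write_tsv(summ, out("de_summary.tsv"))
    ctx$universe <- sort(unique(unlist(lapply(ctx$de_sets, `[[`, "universe"))))
    sel <- sort(unique(unlist(lapply(ctx$de_sets,
                                     function(s) c(s$up, s$down)))))
    if (length(sel) < 3) sel <- ctx$universe
    ctx$lfc <- suppressWarnings(log2fc_matrix(tables, sel))
    ctx$outputs["log2fc_matrix"] <- write_tsv(ctx$lfc,
                                              out("log2fc_matrix.tsv"),
                                              "gene")
    if (length(tables) >= 2) {
      ctx$corr_rna <- transcriptome_correlation(ctx$lfc)
      ctx$outputs["corr_transcriptome"] <-
        write_tsv(ctx$corr_rna, out("corr_transcriptome.tsv"), "knockdown")
    }
    ctx$results$de_sets <- ctx$de_sets
  })

  if (!is.null(ctx$corr_hc) && !is.null(ctx$corr_rna)) stage("network",
                                                             function() {
    net <- dual_evidence_network(ctx$corr_hc, ctx$corr_rna,
                                 threshold = cfg$threshold)
    ctx$outputs["network_tsv"] <- export_network(net, out("network.tsv"),
                                                 "tsv")
    ctx$outputs["network_graphml"] <-
      export_network(net, out("network.graphml"), "graphml")
    ctx$outputs["network_sif"] <- export_network(net, out("network.sif"),
                                                 "sif")
    ctx$results$network <- net
  })

  if (!is.null(cfg$peaks_bed) && !is.null(cfg$genes_bed)) stage("genomics",
                                                                function() {
    genes <- read_bed(cfg$genes_bed)
    peaks <- read_peaks_bed(cfg$peaks_bed)
    mapping <- map_peaks_to_genes(peaks, genes, mode = "interval",
                                  upstream = cfg$promoter_upstream,
                                  downstream = cfg$promoter_downstream)
    ctx$peak_genes <- sort(unique(mapping$gene))
    ctx$outputs["peak_gene_map"] <- write_tsv(mapping,
                                              out("peak_gene_map.tsv"))
    if (!is.null(cfg$coverage_bedgraph)) {
      track <- read_bedgraph(cfg$coverage_bedgraph,
                             total_reads = cfg$coverage_total_reads)
      sig <- data.frame(peak = peaks$name %||%
                          sprintf("peak%03d", seq_along(peaks)),
                        rpm = region_signal(track, peaks, "rpm"))
      ctx$outputs["region_signal"] <- write_tsv(sig,
                                                out("region_signal.tsv"))
      sm <- suppressWarnings(
        summit_matrix(track, peaks, flank = cfg$flank,
                      n_bins = cfg$n_bins, norm = "rpkm"))
      ctx$outputs["summit_matrix"] <- write_tsv(sm, out("summit_matrix.tsv"),
                                                "peak")
      ctx$results$summit_matrix <- sm
    }
    ctx$results$peak_genes <- ctx$peak_genes
  })

  if (!is.null(ctx$de_sets) && !is.null(ctx$peak_genes)) stage("enrichment",
                                                               function() {
    pg <- intersect(norm_symbols(ctx$peak_genes), norm_symbols(ctx$universe))
    comparisons <- list()
    for (nm in names(ctx$de_sets)) {
      comparisons[[paste0(nm, "_up_vs_peak_genes")]] <-
        list(a = ctx$de_sets[[nm]]$up, b = pg)
      comparisons[[paste0(nm, "_down_vs_peak_genes")]] <-
        list(a = ctx$de_sets[[nm]]$down, b = pg)
    }
    if (length(ctx$de_sets) >= 2) {
      k1 <- names(ctx$de_sets)[1]; k2 <- names(ctx$de_sets)[2]
      dereg <- function(s) c(s$up, s$down)
      comparisons[[paste0(k1, "_vs_", k2, "_deregulated")]] <-
        list(a = dereg(ctx$de_sets[[k1]]), b = dereg(ctx$de_sets[[k2]]))
      venn <- venn3_counts(dereg(ctx$de_sets[[k1]]),
                           dereg(ctx$de_sets[[k2]]), pg)
      ctx$outputs["venn"] <- write_tsv(
        data.frame(region = names(venn), count = as.integer(venn)),
        out("venn_counts.tsv"))
    }
    enr <- enrichment_table(comparisons, ctx$universe)
    ctx$outputs["enrichment"] <- write_tsv(enr, out("enrichment.tsv"))
    ctx$results$enrichment <- enr
  })

  if (!is.null(ctx$lfc)) stage("clusters", function() {
    if (nrow(ctx$lfc) >= cfg$k_clusters && cfg$k_clusters >= 2) {
      cl <- hierarchical_clusters(ctx$lfc, k = cfg$k_clusters)
      ctx$outputs["clusters"] <- write_tsv(
        data.frame(gene = names(cl), cluster = as.integer(cl)),
        out("clusters.tsv"))
      ctx$results$clusters <- cl
    }
  })

  if (!is.null(cfg$timecourse)) stage("trajectories", function() {
    expr <- as.matrix(utils::read.delim(cfg$timecourse, row.names = 1,
                                        check.names = FALSE))
    sets <- if (!is.null(cfg$timecourse_sets))
      read_gene_sets(cfg$timecourse_sets)
    else list(all = rownames(expr))
    rows <- lapply(names(sets), function(nm) {
      ts <- trajectory_summary(expr, intersect(sets[[nm]], rownames(expr)),
                               n_boot = cfg$n_boot, seed = cfg$seed)
      cbind(set = nm, ts)
    })
    ctx$outputs["trajectories"] <- write_tsv(do.call(rbind, rows),
                                             out("trajectories.tsv"))
    ctx$results$trajectories <- rows
  })

  stage("manifest", function() {
    inputs <- unlist(cfg[c("screen", "de_dir", "timecourse",
                           "timecourse_sets", "genes_bed", "peaks_bed",
                           "coverage_bedgraph")])
    input_files <- unlist(lapply(inputs, function(p)
      if (dir.exists(p)) list.files(p, full.names = TRUE) else p))
    manifest <- list(
      package = "dualscreen",
      version = as.character(utils::packageVersion("dualscreen")),
      parameters = cfg[!vapply(cfg, is.null, logical(1))],
      seed = cfg$seed,
      input_checksums = as.list(tools::md5sum(input_files)),
      output_checksums = as.list(tools::md5sum(unname(ctx$outputs))))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ctx$outputs["manifest"] <- out("manifest.json")
  })

  res <- ctx$results
  res$outputs <- ctx$outputs
  invisible(res)
}

#' Write a complete synthetic demo input bundle plus config
#'
#' Generates, from one seed, a matched set of pipeline inputs: a
#' plate-structured screen with one planted 3-member module, per-
#' knockdown DE tables sharing the module's DE signature (computed by
#' [simple_de()] on synthetic NB counts), a time course with decay
#' and flat gene sets, and a small genome with promoter-targeted
#' peaks and coverage. Returns the path of a ready-to-run YAML config.
#'
#' @param dir directory to populate
#' @param seed integer seed
#' @return path to `config.yaml` in `dir`, invisibly
#' @export
write_demo_inputs <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  knockdowns <- sprintf("KD%03d", 1:12)
  modules <- list(knockdowns[1:3])
  scr <- generate_screen(12, n_features = 27, n_replicates = 4,
                         n_plates = 2,
                         truth = screen_truth(modules = modules,
                                              effect_size = 2,
                                              noise_sd = 1,
                                              plate_shift = 0.5),
                         seed = seed)
  screen_path <- file.path(dir, "screen.tsv")
  write_screen_table(scr$table, screen_path)

  de_dir <- file.path(dir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  studies <- generate_knockdown_studies(knockdowns, modules,
                                        n_genes = 300, seed = seed + 1L)
  for (kd in knockdowns) {
    st <- studies[[kd]]
    de <- simple_de(st$counts,
                    group_a = st$samples$sample[st$samples$group == kd],
                    group_b = st$samples$sample[st$samples$group == "ctrl"])
    write_de_table(de, file.path(de_dir, paste0(kd, ".tsv")))
  }

  tc <- generate_time_course(
    60, timepoints = c("d0", "d2", "d4", "d6"),
    decay_sets = list(decay = c(1, 0.6, 0.35, 0.25),
                      flat = c(1, 1, 1, 1)),
    seed = seed + 2L)
  tc_path <- file.path(dir, "timecourse.tsv")
  write_tsv(tc, tc_path, rowname_col = "gene")
  sets_path <- file.path(dir, "timecourse_sets.tsv")
  write_gene_sets(attr(tc, "gene_sets"), sets_path)

  # peaks target the module's up-regulated signature genes, so the
  # enrichment stage has real signal to find
  sig <- studies[[knockdowns[1]]]$truth$de_genes[[knockdowns[1]]]
  targets <- names(sig)[sig > 0]
  chrom_sizes <- c(chr1 = 1200000, chr2 = 900000)
  trk <- generate_genomic_tracks(300, chrom_sizes,
                                 target_genes = targets,
                                 frac_targeted = 0.8, flank = 1000,
                                 n_background_peaks = 5,
                                 seed = seed + 3L)
  genes_path <- file.path(dir, "genes.bed")
  write_bed(trk$genes, genes_path)
  peaks_path <- file.path(dir, "peaks.bed")
  write_peaks_bed(trk$peaks, peaks_path)
  cov_path <- file.path(dir, "coverage.bedgraph")
  write_bedgraph(trk$coverage, cov_path)

  cfg <- pipeline_config(
    screen = screen_path, de_dir = de_dir, timecourse = tc_path,
    timecourse_sets = sets_path, genes_bed = genes_path,
    peaks_bed = peaks_path, coverage_bedgraph = cov_path,
    coverage_total_reads = trk$coverage$total_reads,
    out_dir = file.path(dir, "out"),
    flank = 2000, n_bins = 40, n_boot = 200,
    rank_feature = "F01", seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_path)
  invisible(cfg_path)
}
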