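#' Pipeline configuration
#'
#' Collects every stage threshold with validation. Either supply input table
#' paths (`host_table`, `prophage_table`, optional `fasta`) or leave them
#' `NULL` to run on a freshly simulated catalog from `sim`.
#'
#' @param seed master seed; all stochastic stages draw named substreams from
#'   it.
#' @param out_dir run directory for stage outputs.
#' @param host_table,prophage_table,fasta input paths, or `NULL` to simulate.
#' @param sim a [simulation_config()] used when simulating.
#' @param stages character vector of stages to run, in dependency order,
#'   from: filter, summarize, enrich, bootstrap, pathogen, cluster, aai,
#'   kmer.
#' @param min_replicon_bp,keep_categories,drop_plasmid filtering thresholds.
#' @param rank,min_genomes,cap_trigger,cap_sample enrichment settings.
#' @param boot_n_genomes,boot_n_iter,boot_min_genus bootstrap settings.
#' @param pathogen_cap per-genus genome cap before the pathogen comparison.
#' @param id_threshold,cov_threshold clustering thresholds in (0, 1].
#' @param aai_max_prophages cap on the number of cluster representatives
#'   entering the all-vs-all AAI stage (it is quadratic in this number).
#' @param aai_threshold AAI edge threshold in [0, 100].
#' @param kmer_k word sizes profiled (subset of 1:4).
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("prophage_run_"),
                            host_table = NULL, prophage_table = NULL,
                            fasta = NULL, sim = simulation_config(seed = seed),
                            stages = c("filter", "summarize", "enrich",
                                       "bootstrap", "pathogen", "cluster",
                                       "aai", "kmer"),
                            min_replicon_bp = 10000, keep_categories = c(1, 2),
                            drop_plasmid = TRUE,
                            rank = "genus", min_genomes = 5L,
                            cap_trigger = 50L, cap_sample = 10L,
                            boot_n_genomes = 10L, boot_n_iter = 100L,
                            boot_min_genus = 50L, pathogen_cap = 100L,
                            id_threshold = 0.90, cov_threshold = 0.80,
                            aai_threshold = 80, aai_max_prophages = 10L,
                            kmer_k = c(2L, 3L)) {
  cfg <- as.list(environment())
  bad <- c(
    if (id_threshold <= 0 || id_threshold > 1) "id_threshold",
    if (cov_threshold <= 0 || cov_threshold > 1) "cov_threshold",
    if (aai_threshold < 0 || aai_threshold > 100) "aai_threshold",
    if (min_replicon_bp < 0) "min_replicon_bp",
    if (!all(kmer_k %in% 1:4)) "kmer_k",
    if (boot_n_genomes < 2) "boot_n_genomes",
    if (!all(stages %in% c("filter", "summarize", "enrich", "bootstrap",
                           "pathogen", "cluster", "aai", "kmer"))) "stages")
  if (length(bad))
    stop_input("invalid configuration value(s): %s", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Stages run in dependency order on the loaded or simulated catalog; every
#' stage writes its tables under `out_dir` and the run ends with a
#' machine-readable `summary.json` (stage list, thresholds, seeds, output
#' checksums) and a plain-text log. Outputs are byte-reproducible given the
#' same config and inputs. A stage failure aborts the run with the failing
#' stage named; partial outputs are kept next to a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("prophagecomp %s | seed %d\n",
              as.character(utils::packageVersion("prophagecomp")),
              config$seed),
      file = log_path)
  outputs <- character(0)
  done <- character(0)
  current <- "load"
  result <- tryCatch({
    if (is.null(config$host_table)) {
      current <- "simulate"
      simdir <- file.path(config$out_dir, "simulated")
      sim <- simulate_catalog(config$sim, dir = simdir)
      catalog <- sim$catalog
      host_seqs <- sim$host_seqs
      outputs <- c(outputs, list.files(simdir, full.names = TRUE))
      logf("simulate: %d genomes, %d prophages", nrow(catalog$hosts),
           nrow(catalog$prophages))
    } else {
      catalog <- load_catalog(config$prophage_table, config$host_table,
                              config$fasta)
      host_seqs <- character(0)
      logf("load: %d genomes, %d prophages", nrow(catalog$hosts),
           nrow(catalog$prophages))
    }
    done <- c(done, current)

    emit <- function(df, name) {
      p <- file.path(config$out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, p)
    }

    if ("filter" %in% config$stages) {
      current <- "filter"
      catalog <- filter_predictions(catalog, config$min_replicon_bp,
                                    config$keep_categories,
                                    config$drop_plasmid)
      logf("filter: %d prophages retained", nrow(catalog$prophages))
      emit(catalog$prophages[, setdiff(names(catalog$prophages), "sequence")],
           "filtered_prophages.tsv")
      done <- c(done, current)
    }
    if ("summarize" %in% config$stages) {
      current <- "summarize"
      s <- summarize_catalog(catalog)
      emit(data.frame(metric = names(unclass(s)),
                      value = unlist(lapply(unclass(s), format))),
           "catalog_summary.tsv")
      ld <- length_distribution(catalog)
      emit(ld$histogram, "length_histogram.tsv")
      logf("summarize: %.2f prophages per lysogen", s$mean_per_lysogen)
      done <- c(done, current)
    }
    if ("enrich" %in% config$stages) {
      current <- "enrich"
      enr <- rank_enrichment(catalog, rank = config$rank,
                             min_genomes = config$min_genomes,
                             cap_trigger = config$cap_trigger,
                             cap_sample = config$cap_sample,
                             seed = substream_seed(config$seed,
                                                   "enrichment.cap"))
      emit(enr, paste0("enrichment_", config$rank, ".tsv"))
      logf("enrich: %d taxa tested at rank %s", nrow(enr), config$rank)
      done <- c(done, current)
    }
    if ("bootstrap" %in% config$stages) {
      current <- "bootstrap"
      bt <- bootstrap_enrichment(catalog, config$boot_n_genomes,
                                 config$boot_n_iter,
                                 seed = substream_seed(config$seed,
                                                       "enrichment.bootstrap"),
                                 min_genus_genomes = config$boot_min_genus)
      emit(data.frame(genus = rownames(bt$p_matrix), bt$p_matrix,
                      check.names = FALSE), "bootstrap_p_matrix.tsv")
      logf("bootstrap: %d genera x %d iterations", nrow(bt$p_matrix),
           config$boot_n_iter)
      done <- c(done, current)
    }
    if ("pathogen" %in% config$stages) {
      current <- "pathogen"
      capped <- cap_per_genus(catalog, config$pathogen_cap,
                              seed = substream_seed(config$seed,
                                                    "pathogen.cap"))
      labels <- classify_pathogens(capped)
      emit(labels, "pathogen_labels.tsv")
      counts <- per_genome_counts(capped$hosts, capped$prophages)
      pa <- counts[labels$label == "pathogen"]
      un <- counts[labels$label == "unassigned"]
      if (length(pa) && length(un)) {
        ge <- group_enrichment(pa, un)
        loo <- loo_contribution(labels, capped)
        emit(loo$loo, "pathogen_loo.tsv")
        shared <- tryCatch(shared_genus_comparison(labels, capped),
                           error = function(e) NULL)
        if (!is.null(shared)) emit(shared, "pathogen_shared_genera.tsv")
        logf("pathogen: p = %.3g (pathogen > unassigned)", ge$p_value)
      } else logf("pathogen: skipped (a group is empty)")
      done <- c(done, current)
    }
    clusters <- NULL
    if ("cluster" %in% config$stages &&
        !any(is.na(catalog$prophages$sequence))) {
      current <- "cluster"
      clusters <- greedy_cluster(catalog, config$id_threshold,
                                 config$cov_threshold)
      emit(clusters$membership, "viral_clusters.tsv")
      ph <- stats::setNames(catalog$prophages$genome_id,
                            catalog$prophages$prophage_id)
      rep_report <- host_range_report(clusters, catalog$hosts, ph)
      emit(rep_report$vc_ranks, "host_range_ranks.tsv")
      emit(rep_report$multi_host_table, "multi_host_vcs.tsv")
      logf("cluster: %d VCs, %.1f%% same-genus",
           rep_report$n_vcs, 100 * rep_report$fraction_same_genus)
      done <- c(done, current)
    }
    if ("aai" %in% config$stages && !is.null(clusters)) {
      current <- "aai"
      reps <- unique(clusters$membership$representative)
      reps <- utils::head(reps, config$aai_max_prophages)
      seqs <- stats::setNames(catalog$prophages$sequence,
                              catalog$prophages$prophage_id)[reps]
      orfs <- lapply(seq_along(seqs), function(i)
        find_orfs(seqs[[i]], id = names(seqs)[i]))
      names(orfs) <- names(seqs)
      li <- cbind(prophage_id = names(seqs),
                  catalog$hosts[match(
                    catalog$prophages$genome_id[
                      match(names(seqs), catalog$prophages$prophage_id)],
                    catalog$hosts$genome_id),
                    c("phylum", "class", "order", "family", "genus")])
      net <- build_network(orfs, li, threshold = config$aai_threshold)
      write_network(net, file.path(config$out_dir, "aai_edges.tsv"),
                    file.path(config$out_dir, "aai_nodes.tsv"))
      outputs <- c(outputs, file.path(config$out_dir,
                                      c("aai_edges.tsv", "aai_nodes.tsv")))
      if (nrow(net$edges) > 0)
        emit(fraction_by_rank(net, li), "aai_fraction_by_rank.tsv")
      logf("aai: %d edges over %d dereplicated prophages",
           nrow(net$edges), length(orfs))
      done <- c(done, current)
    }
    if ("kmer" %in% config$stages &&
        !any(is.na(catalog$prophages$sequence))) {
      current <- "kmer"
      ids <- utils::head(catalog$prophages$prophage_id, 50)
      seqs <- stats::setNames(catalog$prophages$sequence,
                              catalog$prophages$prophage_id)[ids]
      prof <- lapply(names(seqs), function(id) {
        ps <- lapply(config$kmer_k, function(k)
          kmer_bias(seqs[[id]], k, id = id))
        if (length(ps) > 1) do.call(combine_bias_profiles, ps) else ps[[1]]
      })
      write_bias_matrix(prof, file.path(config$out_dir, "kmer_bias.tsv"))
      outputs <- c(outputs, file.path(config$out_dir, "kmer_bias.tsv"))
      logf("kmer: %d profiles at k = %s", length(prof),
           paste(config$kmer_k, collapse = "+"))
      done <- c(done, current)
    }

    checksums <- vapply(sort(unique(outputs)), function(p)
      as.character(tools::md5sum(p)), character(1))
    summary <- list(stages = done, seed = config$seed,
                    thresholds = config[c("min_replicon_bp", "id_threshold",
                                          "cov_threshold", "aai_threshold")],
                    outputs = as.list(checksums))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summary
  }, error = function(e) {
    writeLines(c(current, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop_input("pipeline stage '%s' failed: %s", current,
               conditionMessage(e))
  })
  invisible(result)
}
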