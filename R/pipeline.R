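# End-to-end orchestration: simulate/ingest -> ploidy -> haplotypes ->
# character matrices -> trees -> congruence, under one YAML-dialect config
# with deterministic per-stage seeds and a checksum manifest.

#' Default pipeline configuration
#'
#' Returns the runnable default configuration (a plain nested list; the
#' on-disk dialect is YAML).  Every stage draws its seed deterministically
#' from `seed`, so a rerun with the same config is bit-identical.
#'
#' @param seed master seed.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    markers = c("marker1", "marker2"),
    # either simulate (below) or provide inputs$<marker> = <path to NEXUS>
    simulate = list(n_taxa = 10L, locus_length = 400L,
                    mode = "congruent", branch_length = 0.08),
    accession = list(n_subgenomes = 3L, clones_per_subgenome = 12L,
                     subgenome_divergence = 0.05,
                     allelic_divergence = 0.002,
                     clone_error_rate = 0.001, locus_length = 800L),
    ploidy = list(relative_size = 3.0, published_size = 3.0,
                  n_readings = 4L, cv = 0.03),
    threshold = 0.01,
    distance_model = "TN93-composite",
    search = list(n_replicates = 5L, max_trees = 50L),
    bootstrap = list(n_replicates = 0L, search_effort = 1L),
    ild = list(n_permutations = 99L, search_effort = 1L)
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Unset keys fall back to [default_config()] values.
#'
#' @param path path to a YAML file.
#' @return A config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("config format error: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  modifyList(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' @param config a config list.
#' @return Character vector of problems (empty when runnable); each problem
#'   names the offending key and the violated constraint.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$seed) || !is.finite(as.numeric(config$seed)))
    add("seed: must be a finite integer")
  if (!is.null(config$threshold) &&
      (!is.numeric(config$threshold) || config$threshold <= 0))
    add("threshold: must be > 0")
  if (!is.null(config$inputs)) {
    for (mk in names(config$inputs))
      if (!file.exists(config$inputs[[mk]]))
        add(paste0("inputs$", mk, ": file not found (",
                   config$inputs[[mk]], ")"))
  } else if (is.null(config$simulate)) {
    add("inputs/simulate: one of them must be present")
  }
  if (!is.null(config$simulate) && is.null(config$inputs)) {
    if (config$simulate$n_taxa < 4)
      add("simulate$n_taxa: must be >= 4 for tree search")
  }
  if (!is.null(config$accession)) {
    acfg <- try(do.call(simulation_config,
                        c(list(seed = 1L), config$accession)), silent = TRUE)
    if (inherits(acfg, "try-error"))
      add(paste0("accession: ", attr(acfg, "condition")$message))
  }
  if (!is.null(config$ild) && config$ild$n_permutations < 1)
    add("ild$n_permutations: must be >= 1")
  problems
}

stage_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  writeLines(line, con)
  flush(con)
}

#' Run the full pipeline
#'
#' Stages: simulate or ingest marker alignments; simulate-and-classify
#' ploidy; separate haplotypes of a simulated polyploid accession per
#' marker (consensus FASTA + count table); site statistics per marker;
#' gap-coded parsimony search per marker (newick trees, optional bootstrap
#' supports); ILD test between the first two markers.  Every artifact is
#' listed with its md5 checksum in `manifest.tsv`; the config is echoed to
#' `config.yaml`.  A failing stage aborts with its name and leaves a
#' `FAILED` marker file.
#'
#' @param config a config list (see [default_config()], [read_config()]).
#' @param out_dir output directory (created; must be empty or absent).
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "w")
  on.exit(close(logf))
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  stage <- "setup"
  tryCatch({
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    emit(file.path(out_dir, "config.yaml"))
    seed <- config$seed

    stage <- "ingest"
    if (!is.null(config$inputs)) {
      alns <- lapply(config$inputs, read_nexus_alignment)
      markers <- names(alns)
      stage_log(logf, stage, paste("read", length(alns), "alignment(s)"))
    } else {
      panel <- simulate_marker_panel(
        n_taxa = config$simulate$n_taxa,
        locus_length = config$simulate$locus_length,
        mode = config$simulate$mode,
        seed = derive_seed(seed, "panel"),
        branch_length = config$simulate$branch_length,
        n_markers = length(config$markers))
      alns <- panel$alignments
      markers <- names(alns)
      for (mk in markers) {
        p <- file.path(out_dir, paste0(mk, ".nex"))
        write_nexus_alignment(alns[[mk]], p)
        emit(p)
      }
      stage_log(logf, stage, paste("simulated", length(alns), "marker(s),",
                                   config$simulate$mode, "mode"))
    }

    stage <- "ploidy"
    if (!is.null(config$ploidy)) {
      std <- flow_sample("standard",
                         simulate_flow_readings(1.0,
                           n_readings = config$ploidy$n_readings,
                           cv = config$ploidy$cv,
                           seed = derive_seed(seed, "flowstd")))
      smp <- flow_sample("sample",
                         simulate_flow_readings(config$ploidy$relative_size,
                           n_readings = config$ploidy$n_readings,
                           cv = config$ploidy$cv,
                           seed = derive_seed(seed, "flowsmp")))
      call <- classify_ploidy(relative_genome_size(smp, std),
                              config$ploidy$published_size,
                              sample_id = "sample")
      p <- file.path(out_dir, "ploidy.tsv")
      write.table(call, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      stage_log(logf, stage, paste("status:", call$status))
    }

    stage <- "haplotypes"
    if (!is.null(config$accession)) {
      params <- separation_params(threshold = config$threshold,
                                  model = config$distance_model)
      counts <- list()
      for (mi in seq_along(markers)) {
        mk <- markers[mi]
        acfg <- do.call(simulation_config,
                        c(list(seed = derive_seed(seed, paste0("acc", mi))),
                          config$accession))
        sim <- simulate_accession(acfg, accession_id = "sim_accession",
                                  locus_id = mk)
        groups <- separate_haplotypes(sim$clone_set, params)
        haps <- setNames(
          vapply(groups, `[[`, "", "consensus"),
          paste0("sim_accession__hap", seq_along(groups)))
        p <- file.path(out_dir, paste0("haplotypes_", mk, ".fasta"))
        write_fasta(haps, p)
        emit(p)
        counts[[mk]] <- haplotype_report(list(sim$clone_set), params)
      }
      tab <- do.call(rbind, counts)
      p <- file.path(out_dir, "haplotype_counts.tsv")
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      stage_log(logf, stage,
                paste("haplotype counts:",
                      paste(tab$n_haplotypes, collapse = ", ")))
    }

    stage <- "characters"
    stats <- lapply(alns, site_stats)
    tab <- data.frame(marker = markers,
                      aligned_length = vapply(stats, `[[`, 0, "aligned_length"),
                      variable_sites = vapply(stats, `[[`, 0, "variable_sites"),
                      parsimony_informative_sites =
                        vapply(stats, `[[`, 0, "parsimony_informative_sites"),
                      indel_events = vapply(stats, `[[`, 0, "indel_events"),
                      min_len = vapply(stats, `[[`, 0, "min_len"),
                      max_len = vapply(stats, `[[`, 0, "max_len"))
    p <- file.path(out_dir, "site_stats.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    stage_log(logf, stage, "site statistics written")

    stage <- "trees"
    cms <- list()
    for (mk in markers) {
      cms[[mk]] <- build_matrix(alns[[mk]], simple_indel_coding(alns[[mk]]))
      res <- heuristic_search(cms[[mk]],
                              n_replicates = config$search$n_replicates,
                              seed = derive_seed(seed, paste0("search", mk)),
                              max_trees = config$search$max_trees)
      tree <- res$strict_consensus
      if (!is.null(config$bootstrap) && config$bootstrap$n_replicates > 0) {
        bs <- bootstrap_support(cms[[mk]],
                                n_replicates = config$bootstrap$n_replicates,
                                seed = derive_seed(seed, paste0("boot", mk)),
                                search_effort = config$bootstrap$search_effort,
                                full_search = res)
        tree <- bs$tree
      }
      p <- file.path(out_dir, paste0("tree_", mk, ".nwk"))
      write_newick(tree, p)
      emit(p)
      stage_log(logf, stage,
                sprintf("%s: length %d, %d tree(s), CI %.3f", mk,
                        res$best_length, length(res$best_trees), res$CI))
    }

    stage <- "ild"
    if (length(markers) >= 2 && !is.null(config$ild)) {
      res <- ild_test(cms[[1]], cms[[2]],
                      n_permutations = config$ild$n_permutations,
                      seed = derive_seed(seed, "ild"),
                      search_effort = config$ild$search_effort)
      p <- file.path(out_dir, "ild.tsv")
      write.table(data.frame(length_a = res$length_a,
                             length_b = res$length_b,
                             observed_sum = res$observed_sum,
                             n_permutations = res$n_permutations,
                             p_value = res$p_value,
                             seed = res$seed),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      stage_log(logf, stage, sprintf("p = %.4f", res$p_value))
    }

    stage <- "manifest"
    manifest <- data.frame(file = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)))
    write.table(manifest, file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log(logf, stage, paste(nrow(manifest), "artifact(s)"))
    invisible(out_dir)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
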