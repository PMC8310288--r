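#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' study conventions: 4 phage and 21 host profile clusters, all three null
#' models at 1200 replicates, 20 optimizer restarts, 5 curveball trades per
#' node, 9999 Mantel permutations.
#'
#' @param matrix_csv path to a binary infection-matrix CSV (header of phage
#'   ids, host ids in column 1), or `NULL`.
#' @param lysis_csv path to a raw lysis-score CSV (used when `matrix_csv`
#'   is `NULL`).
#' @param simulate when `TRUE` and no input path is given, analyse a
#'   [gen_salmonella_like()] matrix.
#' @param host_metadata_csv optional CSV with columns `host_id` and one
#'   attribute column per host category (e.g. serovar).
#' @param genetic_distance_csv optional named character vector of CSV paths
#'   to square phage-by-phage genetic distance matrices for the Mantel
#'   analysis.
#' @param k_phage_clusters,k_host_clusters profile-cluster counts.
#' @param null_models subset of `c("sim1", "sim8", "curveball")`.
#' @param n_replicates null-model replicates per ensemble.
#' @param restarts modularity optimizer restarts.
#' @param trade_multiplier curveball trades per (rows + columns).
#' @param mantel_permutations Mantel test permutations.
#' @param min_clique_hosts,min_clique_phages biclique size thresholds.
#' @param seed master seed for every stochastic stage.
#' @param outdir output directory (`NULL` = no files written).
#' @return A classed list (`pbin_config`).
#' @export
pbin_config <- function(matrix_csv = NULL, lysis_csv = NULL, simulate = FALSE,
                        host_metadata_csv = NULL, genetic_distance_csv = NULL,
                        k_phage_clusters = 4, k_host_clusters = 21,
                        null_models = c("sim1", "sim8", "curveball"),
                        n_replicates = 1200, restarts = 20,
                        trade_multiplier = 5, mantel_permutations = 9999,
                        min_clique_hosts = 2, min_clique_phages = 2,
                        seed = 1, outdir = NULL) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (!all(null_models %in% c("sim1", "sim8", "curveball")))
    stop("unknown null model")
  for (p in c(matrix_csv, lysis_csv, host_metadata_csv,
              unlist(genetic_distance_csv)))
    if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p))
  structure(as.list(environment()), class = "pbin_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pbin_config()] arguments.
#' @return A `pbin_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(pbin_config)))
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(pbin_config, vals)
}

#' Run the full infection-network analysis
#'
#' Executes the analysis sequence: ingest (binarize and filter), Jaccard
#' profile distances and complete-linkage clustering for phages and hosts,
#' group target-range summaries, cluster-overlap counts, NODF, Barber
#' modularity, null-model significance for both statistics, biclique
#' detection, and (when genetic distance matrices are supplied) Mantel
#' tests against the phage infection-profile distances. Results are
#' returned as a report list and, when `config$outdir` is set, written
#' under stable file names (`matrix_filtered.csv`, `clusters_phage.csv`,
#' `clusters_host.csv`, `nodf.json`, `modularity.json`,
#' `null_<stat>_<model>.json`, `cliques.tsv`, `report.json`, ...). The
#' report contains no timestamps, so identical config + seed reproduces
#' byte-identical output.
#'
#' @param config a [pbin_config()].
#' @return A list of class `pbin_report`; stage failures propagate with the
#'   stage name prepended.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pbin_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr),
                    error = function(e) stop(sprintf("[stage %s] %s", name,
                                                     conditionMessage(e)), call. = FALSE))
    message(sprintf("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  report <- list(package_version = as.character(utils::packageVersion("pbin")),
                 config = .config_echo(config))

  ingested <- stage("ingest", {
    if (!is.null(config$matrix_csv))
      list(matrix = read_infection_matrix(config$matrix_csv), sim = NULL)
    else if (!is.null(config$lysis_csv))
      list(matrix = binarize_lysis(read_lysis_table(config$lysis_csv)), sim = NULL)
    else if (isTRUE(config$simulate)) {
      sim <- gen_salmonella_like(seed = config$seed)
      list(matrix = sim$matrix, sim = sim)
    } else stop("no input: set matrix_csv, lysis_csv or simulate = TRUE")
  })
  raw <- ingested$matrix
  sim_meta <- ingested$sim
  flt <- stage("filter", filter_matrix(raw))
  mat <- flt$matrix
  report$filter_report <- unclass(flt$report)
  report$matrix_summary <- matrix_summary(mat)
  total_tested <- flt$report$retained + length(flt$report$dropped_zero)

  cl <- stage("cluster", {
    dp <- pairwise_jaccard(mat, "phages")
    dh <- pairwise_jaccard(mat, "hosts")
    list(phage = hclust_complete(dp, min(config$k_phage_clusters, ncol(mat))),
         host = hclust_complete(dh, min(config$k_host_clusters, nrow(mat))),
         d_phage = dp)
  })
  report$phage_clusters <- cl$phage$cluster
  report$host_clusters <- cl$host$cluster
  report$phage_pcoa_variance <-
    principal_coordinates(cl$d_phage, min(3, ncol(mat)))$variance_explained

  report$group_summary <- stage("summaries",
    group_target_summary(mat, cl$phage$cluster, total_tested))
  report$cluster_overlap <- cluster_overlap_counts(mat, cl$phage$cluster)

  report$nodf <- unclass(stage("nodf", nodf(mat)))
  mod <- stage("modularity",
    optimize_modularity(mat, restarts = config$restarts, seed = config$seed))
  report$modularity <- list(q = mod$q, n_modules = mod$partition$n_modules,
                            restarts_used = mod$restarts_used,
                            per_restart_q = mod$per_restart_q)

  ensembles <- list()
  for (st in c("nodf", "modularity")) for (mdl in config$null_models) {
    nm <- sprintf("%s_%s", st, mdl)
    ensembles[[nm]] <- stage(paste0("null_", nm),
      significance_test(mat, st, mdl, n_replicates = config$n_replicates,
                        seed = config$seed, restarts = config$restarts,
                        trade_multiplier = config$trade_multiplier))
  }
  report$null_tests <- lapply(ensembles, function(e)
    list(model = e$model, statistic = e$statistic_name,
         n_replicates = e$n_replicates, observed = e$observed,
         p_value = e$p_value, threshold_95 = e$threshold_95))

  cliq <- stage("cliques",
    find_cliques(mat, config$min_clique_hosts, config$min_clique_phages))
  report$cliques <- lapply(cliq$cliques, function(x)
    list(hosts = x$hosts, phages = x$phages))

  if (!is.null(config$genetic_distance_csv)) {
    report$mantel <- stage("mantel", {
      dp <- cl$d_phage
      lapply(config$genetic_distance_csv, function(path) {
        gd <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
        common <- intersect(rownames(dp), rownames(gd))
        if (length(common) < 3) stop("fewer than 3 shared phage labels for Mantel")
        unclass(mantel_test(gd[common, common], dp[common, common],
                            n_permutations = config$mantel_permutations,
                            seed = config$seed))
      })
    })
  }

  if (!is.null(config$outdir))
    stage("write", .write_outputs(config$outdir, mat, cl, mod, ensembles,
                                  cliq, report, sim_meta))
  structure(report, class = c("pbin_report", "list"))
}

.config_echo <- function(config) {
  e <- unclass(config)
  e[vapply(e, is.null, TRUE)] <- NULL
  e
}

.write_outputs <- function(outdir, mat, cl, mod, ensembles, cliq, report,
                           sim_meta) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_infection_matrix(mat, fp("matrix_filtered.csv"))
  write_infection_matrix(rearrange_matrix(mat), fp("matrix_rearranged.csv"))
  for (side in c("phage", "host")) {
    a <- cl[[side]]
    utils::write.csv(data.frame(node_id = a$labels, cluster = unname(a$cluster)),
                     fp(sprintf("clusters_%s.csv", side)), row.names = FALSE)
    linkage_newick(a, fp(sprintf("linkage_%s.nwk", side)))
  }
  jsonlite::write_json(report$nodf, fp("nodf.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(report$modularity, fp("modularity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  partition_table(mod$partition, fp("modules.csv"))
  for (nm in names(ensembles))
    write_null_ensemble(ensembles[[nm]], fp(sprintf("null_%s.json", nm)),
                        fp(sprintf("null_%s_scores.csv", nm)))
  cl_rows <- lapply(cliq$cliques, function(x)
    data.frame(hosts = paste(x$hosts, collapse = ","),
               phages = paste(x$phages, collapse = ",")))
  utils::write.table(if (length(cl_rows)) do.call(rbind, cl_rows)
                     else data.frame(hosts = character(), phages = character()),
                     fp("cliques.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  export_edgelist(build_graph(mat), fp("edges.tsv"))
  if (!is.null(sim_meta)) {
    utils::write.csv(sim_meta$phage_metadata, fp("phage_metadata.csv"), row.names = FALSE)
    utils::write.csv(sim_meta$host_metadata, fp("host_metadata.csv"), row.names = FALSE)
  }
  jsonlite::write_json(unclass(report), fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pbin_report <- function(x, ...) {
  s <- x$matrix_summary
  cat(sprintf("infection network report: %d hosts x %d phages, %d interactions (fill %.3f)\n",
              s$n_hosts, s$n_phages, s$n_ones, s$fill))
  cat(sprintf("  NODF = %.2f | Barber Q = %.4f (%d modules)\n",
              x$nodf$nodf_total, x$modularity$q, x$modularity$n_modules))
  for (nm in names(x$null_tests)) {
    nt <- x$null_tests[[nm]]
    cat(sprintf("  %-22s p = %.4g%s\n", nm, nt$p_value,
                if (nt$p_value < 0.05) " *" else ""))
  }
  cat(sprintf("  %d biclique(s) at >= %s hosts x >= %s phages\n",
              length(x$cliques), x$config$min_clique_hosts, x$config$min_clique_phages))
  invisible(x)
}
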