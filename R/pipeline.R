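#' Read a run configuration
#'
#' JSON or YAML (by extension) with fields: `events`, `meta` (input TSV
#' paths), optional `ppi` and `expression` paths, `scopes` (cancer types
#' and/or `"PAN"`; default all types plus PAN), `n_permutations` (default
#' 10000), `seed`, `fdr` (default 0.1), `min_frequency` (default 0.02),
#' `hyper_multiplier` (default 4.5), `hyper_scope`, `stages` (logical
#' toggles: `differential`, `enrichment`, `saturation`), `rank_regions`
#' (CNA ids to rank genes in) and `out_dir`.
#'
#' @param path config file path.
#' @return a validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg
}

.cfg_default <- function(cfg, field, default) {
  if (is.null(cfg[[field]])) default else cfg[[field]]
}

#' Run the full interaction-analysis pipeline
#'
#' Orchestrates all stages on one cohort: load events, exclude
#' hyper-altered samples, per-scope interaction detection, the
#' differential screen, PPI enrichment, optional saturation curves and
#' per-region gene ranking. All outputs (TSV, GraphML, JSON) are written
#' under `out_dir` along with a machine-readable provenance record;
#' identical config and seed give identical outputs.
#'
#' @param config a config list (see [read_config()]) or a path to one.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (f in c("events", "meta"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing input: ", f)
  for (f in c("ppi", "expression"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("missing input: ", f)
  out_dir <- .cfg_default(config, "out_dir", "oncoepi_results")
  seed <- .cfg_default(config, "seed", 1)
  n_perm <- .cfg_default(config, "n_permutations", 10000)
  fdr <- .cfg_default(config, "fdr", 0.1)
  min_freq <- .cfg_default(config, "min_frequency", 0.02)
  stages <- .cfg_default(config, "stages", list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- permutation_plan(n_permutations = n_perm, seed = seed)
  message("[load] ", config$events)
  mat <- load_events(config$events, config$meta)
  fh <- filter_hypermutated(mat, multiplier = .cfg_default(config, "hyper_multiplier", 4.5),
                            scope = .cfg_default(config, "hyper_scope", "global"))
  mat <- fh$matrix
  write.table(fh$report$excluded_hyper_samples,
              file.path(out_dir, "excluded_hyper_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scopes <- .cfg_default(config, "scopes", c(unique(mat$cancer_type), "PAN"))
  message("[detect] scopes: ", paste(scopes, collapse = ", "))
  networks <- list()
  for (sc in scopes) {
    net <- detect_interactions(mat, plan, scope = sc, fdr = fdr,
                               min_frequency = min_freq)
    networks[[sc]] <- net
    write.table(net$results,
                file.path(out_dir, paste0("interactions_", sc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    export_network(net, file.path(out_dir, paste0("network_", sc, ".graphml")),
                   format = "graphml")
    message("[detect] ", sc, ": ", nrow(net$edges), " interactions at FDR ", fdr)
  }
  results <- list(filter_report = fh$report, networks = networks)
  if (isTRUE(.cfg_default(stages, "differential", TRUE)) &&
      length(unique(mat$cancer_type)) > 1) {
    per_type <- networks[setdiff(names(networks), "PAN")]
    diff <- differential_screen(per_type, mat, plan, fdr = fdr,
                                min_frequency = min_freq)
    write.table(as.data.frame(diff), file.path(out_dir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("[differential] ", attr(diff, "n_comparisons"), " comparisons, ",
            sum(diff$call != "not_differential"), " differential")
    results$differential <- diff
  }
  if (!is.null(config$ppi) && isTRUE(.cfg_default(stages, "enrichment", TRUE))) {
    ppi <- read_ppi(config$ppi, min_score = config$ppi_min_score)
    pan_scope <- if ("PAN" %in% names(networks)) "PAN" else names(networks)[1]
    fm <- filter_recurrent(mat, min_frequency = min_freq, scope = pan_scope)
    enr <- enrichment_score(networks[[pan_scope]]$edges[c("a", "b")], fm, ppi,
                            n_resamples = .cfg_default(config, "n_resamples", 1000),
                            seed = seed)
    jsonlite::write_json(unclass(enr), file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    message(sprintf("[enrichment] fold %.2f (P %.4g)", enr$fold, enr$empirical_p))
    results$enrichment <- enr
  }
  if (isTRUE(.cfg_default(stages, "saturation", FALSE))) {
    sat <- saturation_pan_samples(mat, plan,
                                  step = .cfg_default(config, "saturation_step", 100),
                                  reps = .cfg_default(config, "saturation_reps", 10),
                                  fdr = fdr, min_frequency = min_freq)
    write.table(as.data.frame(sat), file.path(out_dir, "saturation_pan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$saturation <- sat
  }
  if (!is.null(config$expression) && length(config$rank_regions)) {
    expr <- read_expression(config$expression)
    for (reg in config$rank_regions) {
      rk <- rank_genes_in_region(mat, reg, expr,
                                 cancer_type = .cfg_default(config, "rank_scope", "PAN"))
      if (!is.null(rk))
        write.table(rk, file.path(out_dir, paste0("gene_ranking_", reg, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  provenance <- list(
    package = "oncoepi",
    version = as.character(utils::packageVersion("oncoepi")),
    seed = seed, n_permutations = n_perm, fdr = fdr,
    min_frequency = min_freq, scopes = scopes,
    n_samples = nrow(mat$incidence), n_alterations = ncol(mat$incidence))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
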