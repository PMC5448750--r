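#' Assemble a run configuration
#'
#' Defaults mirror the screen's published settings: k = 10 clusters, a
#' thousand k-means restarts, family-wise alpha 0.05, unannotated genes
#' excluded from enrichment, clusters of interest picked by the
#' surface-protein/guidance enrichment rule.
#'
#' @param expression path to the expression-density table (TSV/CSV).
#' @param evidence path to the predictor-evidence table (TSV).
#' @param keywords path to the functional-keyword table (TSV).
#' @param out_dir artifact directory (created if absent).
#' @param overrides,flags optional paths: localisation override table and
#'   visual-screen differential-expression flag table.
#' @param k clusters for the main analysis.
#' @param sweep logical: also sweep k over `k_min:k_max` and record
#'   adjacent-k stability.
#' @param k_min,k_max sweep range.
#' @param restarts,seed,alpha,impute_policy see the stage functions.
#' @param clusters_of_interest `"rule"` or explicit integer labels.
#' @return A `RunConfig` list.
#' @export
run_config <- function(expression, evidence, keywords, out_dir,
                       overrides = NULL, flags = NULL, k = 10,
                       sweep = FALSE, k_min = 6, k_max = 18,
                       restarts = 1000, seed = 0, alpha = 0.05,
                       impute_policy = "fill-with-one",
                       clusters_of_interest = "rule") {
  structure(as.list(environment()), class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Keys match the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("expression", "evidence", "keywords", "overrides",
                "flags", "out_dir")) {
    if (!is.null(raw[[key]]) && !grepl("^/", raw[[key]]))
      raw[[key]] <- file.path(base, raw[[key]])
  }
  do.call(run_config, raw)
}

# polynomial rolling hash of the configuration text, recorded in artifact
# headers so outputs can be traced to the exact settings that produced them
config_hash <- function(config) {
  txt <- yaml::as.yaml(config[order(names(config))])
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(config, stage) {
  sprintf("# connscreen %s | stage=%s | seed=%s | config=%s",
          as.character(utils::packageVersion("connscreen")), stage,
          config$seed, config_hash(config))
}

write_with_header <- function(obj, path, header) {
  writeLines(header, path)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_table(obj, tmp, format = if (grepl("\\.csv$", path)) "csv" else "tsv")
  file.append(path, tmp)
  invisible(path)
}

#' Run the full expression screen
#'
#' Executes the stages in order: gene filter, per-gene normalization,
#' k-means clustering (optionally a k sweep), localisation and functional
#' annotation, enrichment tests for both schemes, cluster-of-interest
#' selection and the candidate funnel. Every artifact written to
#' `config$out_dir` carries a provenance header (package version, seed,
#' configuration hash); `summary.json` aggregates gene counts, chi-square
#' results and funnel numbers. A stage failure aborts with a stage-named
#' error.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  for (key in c("expression", "evidence", "keywords"))
    if (!file.exists(config[[key]]))
      stop(sprintf("[%s] input not found: %s", key, config[[key]]))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  art <- function(name) file.path(config$out_dir, name)

  raw <- stage("filter", {
    tab <- read_expression_table(config$expression, quiet = TRUE)
    filter_all_missing(tab)
  })
  message(sprintf("[filter] retained %d genes, removed %d all-missing",
                  length(raw$table$gene_ids), length(raw$removed)))

  norm <- stage("normalize", normalize_per_gene(raw$table))
  dense <- stage("normalize",
                 impute_for_clustering(norm, config$impute_policy))
  write_with_header(norm, art("normalized.tsv"),
                    provenance_header(config, "normalize"))

  model <- stage("cluster",
                 kmeans_profiles(dense$matrix, config$k,
                                 restarts = config$restarts,
                                 seed = config$seed))
  summ <- stage("cluster", summarize_clusters(norm, model))
  assignments <- data.frame(gene_id = names(model$assignments),
                            k = config$k,
                            cluster = unname(model$assignments))
  write_with_header(assignments, art("assignments.tsv"),
                    provenance_header(config, "cluster"))
  write_with_header(
    data.frame(cluster = summ$labels, size = summ$size,
               peak_age = summ$peak_age, chron_rank = summ$chron_rank,
               summ$profiles, check.names = FALSE),
    art("cluster_summary.tsv"), provenance_header(config, "cluster"))

  sweep_stab <- NULL
  if (isTRUE(config$sweep)) {
    sw <- stage("sweep", sweep_k(dense$matrix, config$k_min, config$k_max,
                                 restarts = config$restarts,
                                 seed = config$seed))
    sweep_stab <- lapply(sw$transitions, function(tr)
      list(from = tr$from, to = tr$to, stability = tr$stability))
    write_table(sweep_stab, art("sweep_stability.json"), format = "json")
  }

  ann <- stage("annotate", {
    ev <- utils::read.delim(config$evidence, stringsAsFactors = FALSE,
                            comment.char = "#")
    kw <- utils::read.delim(config$keywords, stringsAsFactors = FALSE,
                            comment.char = "#")
    ov <- if (!is.null(config$overrides))
      utils::read.delim(config$overrides, stringsAsFactors = FALSE,
                        comment.char = "#") else NULL
    calls <- call_localisation(ev, overrides = ov)
    groups <- assign_group(kw)
    merge(calls, groups, by = "gene_id")
  })

  loc <- stats::setNames(ann$category, ann$gene_id)
  grp <- stats::setNames(as.character(ann$group), ann$gene_id)
  clus <- stats::setNames(assignments$cluster, assignments$gene_id)
  enr_loc <- stage("enrich",
                   enrichment_report(clus, loc[names(clus)],
                                     exclude = "unannotated",
                                     alpha = config$alpha))
  enr_fun <- stage("enrich",
                   enrichment_report(clus, grp[names(clus)],
                                     exclude = character(0),
                                     alpha = config$alpha))
  for (nm in c("localisation", "function")) {
    rep <- if (nm == "localisation") enr_loc else enr_fun
    write_table(enrichment_json(rep),
                art(sprintf("enrichment_%s.json", nm)), format = "json")
  }

  coi <- stage("funnel", {
    if (identical(config$clusters_of_interest, "rule"))
      select_clusters_of_interest(enr_loc$obs_exp, enr_fun$obs_exp)
    else as.integer(config$clusters_of_interest)
  })
  fr <- stage("funnel", {
    annot <- data.frame(gene_id = names(clus), cluster = unname(clus),
                        category = unname(loc[names(clus)]),
                        group = unname(grp[names(clus)]))
    funnel(annot, coi)
  })
  if (!is.null(config$flags)) {
    fl <- utils::read.delim(config$flags, stringsAsFactors = FALSE,
                            comment.char = "#")
    fr <- stage("funnel", apply_differential_flags(fr, fl))
  }
  write_with_header(fr$candidates, art("candidates.tsv"),
                    provenance_header(config, "funnel"))

  summary <- list(
    seed = config$seed, config = config_hash(config),
    n_genes_input = length(raw$table$gene_ids) + length(raw$removed),
    n_genes_retained = length(raw$table$gene_ids),
    removed_all_missing = raw$removed,
    zero_mean_excluded = norm$zero_mean_genes,
    k = config$k,
    cluster_sizes = summ$size,
    sweep_stability = sweep_stab,
    localisation = list(counts = as.list(tabulate_categories(loc)),
                        chi_square = enr_loc$overall$statistic,
                        df = enr_loc$overall$df,
                        p_value = enr_loc$overall$p_value,
                        bonferroni_threshold = enr_loc$threshold),
    functional = list(counts = as.list(tabulate_categories(grp)),
                      chi_square = enr_fun$overall$statistic,
                      df = enr_fun$overall$df,
                      p_value = enr_fun$overall$p_value,
                      bonferroni_threshold = enr_fun$threshold),
    funnel = list(clusters_of_interest = fr$clusters_of_interest,
                  n_in_clusters = fr$n_in_clusters,
                  n_extracellular = fr$n_extracellular,
                  n_candidates = nrow(fr$candidates),
                  candidates = fr$candidates$gene_id))
  write_table(summary, art("summary.json"), format = "json")
  invisible(summary)
}

# JSON-friendly view of an enrichment report
enrichment_json <- function(rep) {
  list(
    observed = apply(rep$table$observed, 1, as.list),
    overall = list(statistic = rep$overall$statistic,
                   df = rep$overall$df, p = rep$overall$p_value),
    per_category = lapply(rep$per_category, function(r)
      list(statistic = r$statistic, df = r$df, p = r$p_value,
           threshold = r$threshold, conclusion = r$conclusion)),
    obs_exp = apply(rep$obs_exp, 1, as.list),
    bonferroni_threshold = rep$threshold)
}
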