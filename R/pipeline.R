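#' Load a run configuration
#'
#' Configurations are JSON (see the package vignette for the schema):
#' dataset entries (file paths or synthetic specs with metadata and group
#' labels), per-sign error rates, binarization thresholds, the profile
#' correlation threshold tau, cross-validation settings, and an optional
#' annotation path.
#'
#' @param config a file path to a JSON config, or an already-built list.
#' @return the configuration list, validated.
#' @export
load_run_config <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  stopifnot(is.list(config), length(config$datasets) >= 1)
  groups <- vapply(config$datasets, function(d) d$group %||% "SYNTHETIC", "")
  if (sum(groups == "REFERENCE") > 1)
    stop("at most one dataset may be marked REFERENCE")
  config
}

# Materialize the configured datasets: read files or simulate, write the
# networks and (for synthetic runs) the GAF under out/networks/.
stage_simulate <- function(config, out, seed) {
  net_dir <- file.path(out, "networks")
  dir.create(net_dir, recursive = TRUE, showWarnings = FALSE)
  synth <- vapply(config$datasets, function(d) is.null(d$path), TRUE)
  networks <- list()
  annotations <- NULL
  truth <- NULL
  if (any(synth)) {
    tm_args <- config$truth %||% list()
    tm <- do.call(truth_model, tm_args)
    suite_cfg <- list(
      truth = tm,
      datasets = lapply(config$datasets[synth], function(d) {
        d$observation <- do.call(observation_model,
                                 d$synthetic %||% list())
        d
      }))
    suite <- generate_study_suite(suite_cfg, seed = seed)
    networks <- suite$networks
    annotations <- suite$annotations
    truth <- suite$truth
    write_gaf(annotations, file.path(net_dir, "annotations.gaf"))
  }
  for (d in config$datasets[!synth]) {
    networks[[d$dataset_id]] <- read_gi_table(
      d$path, dataset_id = d$dataset_id,
      readout = d$readout %||% NA_character_,
      condition = d$condition %||% NA_character_,
      laboratory = d$laboratory %||% NA_character_,
      group = d$group %||% "SYNTHETIC")
  }
  # preserve config order
  ids <- vapply(config$datasets, function(d) d$dataset_id, "")
  networks <- networks[ids]
  if (!is.null(config$annotations))
    annotations <- read_gaf(config$annotations,
                            config$evidence_codes %||%
                              experimental_evidence_codes())
  for (id in names(networks))
    write_edge_list(networks[[id]], file.path(net_dir, paste0(id, ".tsv")))
  list(networks = networks, annotations = annotations, truth = truth)
}

reference_id <- function(config) {
  for (d in config$datasets)
    if (identical(d$group %||% "", "REFERENCE")) return(d$dataset_id)
  NULL
}

# Comparison of every network to the reference, per sign filter.
stage_compare <- function(networks, config, out) {
  ref <- reference_id(config)
  if (is.null(ref)) stop("comparison stage requires a REFERENCE dataset")
  if (length(networks) < 2) stop("comparison stage needs >= 2 datasets")
  others <- setdiff(names(networks), ref)
  tabs <- lapply(others, function(id)
    compare_networks(networks[[ref]], networks[[id]]))
  tab <- do.call(rbind, tabs)
  write_tsv(tab, file.path(out, "comparisons.tsv"))
  tab
}

# Observed/expected overlap and uniqueness ratios per network pair and sign.
stage_expected <- function(comparisons, config, out) {
  rates <- run_rates(config)
  rows <- list()
  for (i in seq_len(nrow(comparisons))) {
    row <- comparisons[i, ]
    if (!(row$sign_filter %in% c("negative", "positive"))) next
    r <- rates[[row$sign_filter]]
    if (row$n_obs_a == 0 || row$n_obs_b == 0 || row$n_common_tested == 0)
      next
    exp_c <- tryCatch(
      expected_counts(row$n_common_tested, row$n_obs_a, row$n_obs_b, r),
      error = function(e) NULL)
    if (is.null(exp_c)) next
    ratios <- overlap_ratio(row, exp_c)
    rows[[length(rows) + 1]] <- data.frame(
      dataset_a = row$dataset_a, dataset_b = row$dataset_b,
      sign = row$sign_filter, N = row$n_common_tested,
      n_obs_a = row$n_obs_a, n_obs_b = row$n_obs_b,
      observed_both = row$n_both, expected_both = exp_c$E_both,
      observed_overlap = row$overlap,
      expected_overlap = exp_c$expected_overlap,
      ratio_overlap = ratios$ratio_overlap,
      ratio_overlap_inv = ratios$ratio_overlap_inv,
      observed_unique = row$unique,
      expected_unique = exp_c$expected_unique,
      ratio_unique = ratios$ratio_unique,
      ratio_unique_inv = ratios$ratio_unique_inv)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset_a = character(0))
  write_tsv(tab, file.path(out, "expected_ratios.tsv"))
  tab
}

run_rates <- function(config) {
  r <- config$rates
  if (is.null(r)) return(costanzo_rates())
  list(positive = error_rates(r$positive$sensitivity, r$positive$precision),
       negative = error_rates(r$negative$sensitivity, r$negative$precision))
}

# PHENO/MMS vs CONTROL group tests on each comparison measure.
stage_group_tests <- function(comparisons, config, out) {
  groups <- stats::setNames(
    vapply(config$datasets, function(d) d$group %||% "SYNTHETIC", ""),
    vapply(config$datasets, function(d) d$dataset_id, ""))
  cond_ids <- names(groups)[groups %in% c("PHENO", "MMS")]
  ctrl_ids <- names(groups)[groups == "CONTROL"]
  rows <- list()
  any_rows <- comparisons[comparisons$sign_filter == "any", ]
  for (measure in c("correlation", "overlap", "unique", "disagree")) {
    v1 <- any_rows[[measure]][any_rows$dataset_b %in% cond_ids]
    v2 <- any_rows[[measure]][any_rows$dataset_b %in% ctrl_ids]
    if (sum(!is.na(v1)) == 0 || sum(!is.na(v2)) == 0) next
    for (method in c("t", "wilcoxon")) {
      res <- group_difference_test(v1, v2, paired = FALSE, method = method)
      rows[[length(rows) + 1]] <- data.frame(
        measure = measure, method = method,
        n_condition = sum(!is.na(v1)), n_control = sum(!is.na(v2)),
        statistic = res$statistic, p_value = res$p_value)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(measure = character(0))
  write_tsv(tab, file.path(out, "group_tests.tsv"))
  tab
}

# Profile networks per dataset plus the max-combined network.
stage_combine <- function(networks, config, out) {
  tau <- config$tau %||% 0.1
  min_shared <- config$min_shared %||% 3
  pcns <- lapply(networks, profile_similarity_network, tau = tau,
                 min_shared = min_shared)
  combined <- combine_max(pcns)
  write_profile_network(combined, file.path(out, "combined_network.tsv"))
  write_profile_network(combined, file.path(out, "combined_network.sif"),
                        format = "sif")
  list(pcns = pcns, combined = combined)
}

# Per-term CV benchmark: reference vs each network vs their combination,
# with the improvement summary in the layout # terms / # positive /
# # negative / mean / p-value.
stage_predict <- function(pcns, annotations, config, out, seed) {
  ref <- reference_id(config)
  if (is.null(ref) || is.null(annotations)) return(NULL)
  k <- config$cv$k %||% 5
  min_genes <- config$cv$min_genes %||% 5
  others <- setdiff(names(pcns), ref)
  eval_tab <- list(); summary_rows <- list()
  for (id in others) {
    pcn_a <- pcns[[id]]; pcn_b <- pcns[[ref]]
    combined <- combine_max(list(pcn_a, pcn_b))
    terms <- Reduce(intersect, lapply(
      list(pcn_a, pcn_b, combined),
      function(p) eligible_terms(annotations, p$genes, min_genes)))
    if (length(terms) == 0) next
    impr <- numeric(0)
    for (term in terms) {
      evs <- lapply(list(A = pcn_a, B = pcn_b, C = combined),
                    function(p) cross_validate(p, term, annotations,
                                               k = k, seed = seed))
      impr[term] <- relative_improvement(evs$C$aupr, evs$A$aupr,
                                         evs$B$aupr)
      eval_tab[[length(eval_tab) + 1]] <- data.frame(
        network = id, term = term, n_pos = evs$C$n_positives,
        auroc_individual = evs$A$auroc, auroc_reference = evs$B$auroc,
        auroc_combined = evs$C$auroc,
        aupr_individual = evs$A$aupr, aupr_reference = evs$B$aupr,
        aupr_combined = evs$C$aupr,
        relative_improvement_aupr = impr[term])
    }
    impr_ok <- impr[!is.na(impr)]
    p_val <- if (length(impr_ok) >= 2 && any(impr_ok != 0))
      suppressWarnings(stats::wilcox.test(impr_ok)$p.value) else NA_real_
    summary_rows[[id]] <- data.frame(
      network = id, n_terms = length(impr_ok),
      n_positive = sum(impr_ok > 0), n_negative = sum(impr_ok < 0),
      mean = mean(impr_ok), p_value = p_val)
  }
  evals <- do.call(rbind, eval_tab)
  summary <- do.call(rbind, summary_rows)
  write_tsv(evals, file.path(out, "term_evaluations.tsv"))
  write_tsv(summary, file.path(out, "improvement_summary.tsv"))
  list(evaluations = evals, summary = summary)
}

# All-vs-all matrices + dendrograms for the four measures and the mean
# profile-correlation similarity.
stage_cluster <- function(networks, config, out) {
  if (length(networks) < 2) stop("cluster stage needs >= 2 datasets")
  linkage <- config$linkage %||% "average"
  for (measure in c("correlation", "overlap", "unique", "disagree")) {
    mat <- all_vs_all(networks, measure)
    if (anyNA(mat$values)) next
    dend <- hcluster(mat, linkage)
    export_comparison(mat, dend,
                      file.path(out, paste0("matrix_", measure, ".tsv")),
                      file.path(out, paste0("dendrogram_", measure,
                                            ".nwk")))
  }
  mat <- profile_similarity_matrix(networks,
                                   config$min_shared %||% 3)
  if (!anyNA(mat$values)) {
    dend <- hcluster(mat, linkage)
    export_comparison(mat, dend,
                      file.path(out, "matrix_profile_similarity.tsv"),
                      file.path(out, "dendrogram_profile_similarity.nwk"))
  }
  invisible(NULL)
}

write_tsv <- function(df, path) {
  if (is.null(df)) df <- data.frame()
  num <- vapply(df, is.double, TRUE)
  for (col in names(df)[num]) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full comparison/combination/prediction pipeline
#'
#' Executes, in order: dataset materialization (file or simulation),
#' comparison of every network to the reference, expected-overlap ratios
#' from the error model, PHENO-MMS-versus-CONTROL group tests, profile
#' network construction and maximum combination, the cross-validated gene
#' function prediction benchmark (skipped when no annotations are
#' available), and all-versus-all clustering. Results are tab-separated
#' tables plus Newick dendrograms under `out`; `manifest.json` records
#' the configuration hash, seed and package version. Deterministic given
#' (config, seed).
#'
#' @param config JSON path or configuration list (see
#'   [load_run_config()]).
#' @param out output directory (created).
#' @param seed master seed for all stochastic stages; overrides
#'   `config$seed`.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_gi_pipeline <- function(config, out, seed = NULL) {
  config <- load_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    message("[gicompare] stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- run_stage("simulate", stage_simulate(config, out, seed))
  comparisons <- run_stage("compare",
                           stage_compare(sim$networks, config, out))
  run_stage("expected", stage_expected(comparisons, config, out))
  run_stage("group_tests", stage_group_tests(comparisons, config, out))
  comb <- run_stage("combine", stage_combine(sim$networks, config, out))
  pred <- if (is.null(sim$annotations)) {
    message("[gicompare] stage predict skipped (no annotations)")
    NULL
  } else {
    run_stage("predict", stage_predict(comb$pcns, sim$annotations,
                                       config, out, seed))
  }
  run_stage("cluster", stage_cluster(sim$networks, config, out))
  manifest <- list(
    package = "gicompare",
    version = as.character(utils::packageVersion("gicompare")),
    seed = seed,
    config_hash = string_seed(jsonlite::toJSON(config, auto_unbox = TRUE,
                                               digits = NA)),
    datasets = vapply(config$datasets, function(d) d$dataset_id, ""))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(networks = sim$networks, annotations = sim$annotations,
                 truth = sim$truth, comparisons = comparisons,
                 combined = comb$combined, prediction = pred))
}

# Per-stage closures for the CLI: each stage re-materializes its inputs
# (deterministic given seed) and runs independently against `out`.
pipeline_stages <- function(config, out, seed) {
  config <- load_run_config(config)
  seed <- as.integer(seed)
  sim <- function() stage_simulate(config, out, seed)
  cmp <- function() stage_compare(sim()$networks, config, out)
  list(
    simulate = sim,
    compare = cmp,
    expected = function() stage_expected(cmp(), config, out),
    group_tests = function() stage_group_tests(cmp(), config, out),
    combine = function() stage_combine(sim()$networks, config, out),
    predict = function() {
      s <- sim()
      pc <- stage_combine(s$networks, config, out)
      stage_predict(pc$pcns, s$annotations, config, out, seed)
    },
    cluster = function() stage_cluster(sim()$networks, config, out))
}

#' A ready-made synthetic study configuration
#'
#' Six synthetic datasets observing one 300-gene, 10-module truth: one
#' REFERENCE, two CONTROL (same lab as each other), one MMS-like rewired
#' dataset and two PHENO-like rewired datasets, reproducing the study
#' design the pipeline expects. Useful for examples and end-to-end runs
#' without external data.
#'
#' @param n_genes,n_modules truth dimensions.
#' @return a configuration list for [run_gi_pipeline()].
#' @export
example_run_config <- function(n_genes = 120, n_modules = 6) {
  ds <- function(id, group, rewire = 0, batch = NA, share = 0)
    list(dataset_id = id, group = group,
         synthetic = list(rewire_fraction = rewire,
                          batch_id = batch, batch_fp_share = share))
  list(
    truth = list(n_genes = n_genes, n_modules = n_modules),
    datasets = list(
      ds("SGA", "REFERENCE"),
      ds("CTRL1", "CONTROL", batch = "labA", share = 0.5),
      ds("CTRL2", "CONTROL", batch = "labA", share = 0.5),
      ds("MMS1", "MMS", rewire = 0.5),
      ds("PHENO1", "PHENO", rewire = 0.6),
      ds("PHENO2", "PHENO", rewire = 0.6)),
    tau = 0.1, min_shared = 3,
    cv = list(k = 5, min_genes = 5),
    linkage = "average")
}
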