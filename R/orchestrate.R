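load_inputs <- function(expr_file, mapping_file, label_file, kgml_dir,
                        is_log = FALSE, noise_q = 0.05) {
  for (f in c(expr_file, mapping_file, label_file)) {
    if (!file.exists(f)) abort_input(paste0("Input file not found: ", f))
  }
  if (!dir.exists(kgml_dir)) abort_input(paste0("KGML directory not found: ", kgml_dir))
  m <- read_expression(expr_file, mapping_file, label_file, is_log = is_log)
  s <- scale_genes(filter_noise(m, q = noise_q))
  pws <- read_kgml_dir(kgml_dir)
  list(scaled = s, pathways = pws)
}

#' Run the scoring pipeline end to end and write its outputs
#'
#' Loads the expression matrix, mapping, labels and KGML directory, runs
#' noise filtering, scaling, pathway scoring and ranking, and writes
#' `scores.tsv` (pathway x sample matrix) and `ranking.tsv` to `out_dir`.
#'
#' @param expr_file,mapping_file,label_file,kgml_dir Input paths (see
#'   [read_expression()] and [read_kgml_dir()]).
#' @param out_dir Output directory (created if needed).
#' @param is_log Input expression is log2-scaled.
#' @param noise_q Noise-floor quantile (see [filter_noise()]).
#' @param min_nodes Minimum measured nodes per pathway.
#' @return List with the `pathway_scores` object, the ranking tibble and the
#'   written paths, invisibly.
#' @export
run_score <- function(expr_file, mapping_file, label_file, kgml_dir, out_dir,
                      is_log = FALSE, noise_q = 0.05, min_nodes = 5) {
  inp <- load_inputs(expr_file, mapping_file, label_file, kgml_dir,
                     is_log = is_log, noise_q = noise_q)
  ps <- score_pathways(inp$scaled, inp$pathways, min_nodes = min_nodes)
  ranking <- rank_pathways(ps)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(out_dir, "scores.tsv")
  readr::write_tsv(tibble::as_tibble(ps$scores, rownames = "pathway_id"),
                   scores_path, progress = FALSE)
  ranking_path <- file.path(out_dir, "ranking.tsv")
  readr::write_tsv(ranking, ranking_path, progress = FALSE)
  invisible(list(scores = ps, ranking = ranking,
                 paths = c(scores = scores_path, ranking = ranking_path)))
}

#' Run the FDR-ratio evaluation for both arms and write a report
#'
#' Computes the FDR-ratio experiment for the pathway arm and the gene-level
#' arm on the same data, writing `evaluation.tsv` (per-pathway p/FDR on real
#' labels), and `evaluation_summary.json` with both arms' mean FDRs, mock
#' FDR lists and ratios.
#'
#' @inheritParams run_score
#' @param n_mock Number of mock relabellings.
#' @param seed Master seed.
#' @return List with both `fdr_ratio_result` objects and written paths,
#'   invisibly.
#' @export
run_evaluate <- function(expr_file, mapping_file, label_file, kgml_dir, out_dir,
                         is_log = FALSE, noise_q = 0.05, min_nodes = 5,
                         n_mock = 10, seed = 1L) {
  inp <- load_inputs(expr_file, mapping_file, label_file, kgml_dir,
                     is_log = is_log, noise_q = noise_q)
  pw <- fdr_ratio_experiment(inp$scaled, inp$pathways, arm = "pathway",
                             n_mock = n_mock, seed = seed, min_nodes = min_nodes)
  gn <- fdr_ratio_experiment(inp$scaled, arm = "gene", n_mock = n_mock,
                             seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab_path <- file.path(out_dir, "evaluation.tsv")
  readr::write_tsv(pw$comparison, tab_path, progress = FALSE)
  summary_path <- file.path(out_dir, "evaluation_summary.json")
  jsonlite::write_json(
    list(
      pathway = list(fdr_real = pw$fdr_real, fdr_mock = pw$fdr_mock,
                     fdr_ratio = pw$ratio),
      gene = list(fdr_real = gn$fdr_real, fdr_mock = gn$fdr_mock,
                  fdr_ratio = gn$ratio),
      n_mock = n_mock, seed = seed
    ),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(list(pathway = pw, gene = gn,
                 paths = c(table = tab_path, summary = summary_path)))
}

#' Run the structural-uncertainty experiment and write detection rates
#'
#' @inheritParams run_score
#' @param target_pathway_id Pathway to perturb; defaults to the top-ranked
#'   pathway of the intact collection.
#' @param fractions,n_reps,top_k,seed See [uncertainty_experiment()].
#' @return List with the `uncertainty_result` tibble and the written path,
#'   invisibly.
#' @export
run_perturb <- function(expr_file, mapping_file, label_file, kgml_dir, out_dir,
                        target_pathway_id = NULL,
                        fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                        n_reps = 100, top_k = 25, seed = 1L,
                        is_log = FALSE, noise_q = 0.05, min_nodes = 5) {
  inp <- load_inputs(expr_file, mapping_file, label_file, kgml_dir,
                     is_log = is_log, noise_q = noise_q)
  if (is.null(target_pathway_id)) {
    ps <- score_pathways(inp$scaled, inp$pathways, min_nodes = min_nodes)
    target_pathway_id <- rank_pathways(ps)$pathway_id[1]
  }
  res <- uncertainty_experiment(inp$scaled, inp$pathways, target_pathway_id,
                                fractions = fractions, n_reps = n_reps,
                                top_k = top_k, seed = seed,
                                min_nodes = min_nodes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "detection_rates.tsv")
  readr::write_tsv(tibble::as_tibble(res), path, progress = FALSE)
  invisible(list(result = res, target_pathway_id = target_pathway_id,
                 paths = c(rates = path)))
}

#' Simulate a study and write it as an input fixture directory
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param effect_size,n_case,n_control,n_pathways See [simulate_study()].
#' @return The [simulate_study()] result with written paths attached,
#'   invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, effect_size = 1.5, n_case = 13,
                         n_control = 11, n_pathways = 250) {
  study <- simulate_study(seed = seed, effect_size = effect_size,
                          n_case = n_case, n_control = n_control,
                          n_pathways = n_pathways)
  paths <- write_simulation(study, out_dir)
  study$paths <- paths
  invisible(study)
}
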