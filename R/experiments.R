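#' Effect of sample size on the mean FDR
#'
#' Repeatedly subsamples one group to each requested size (the other group
#' kept intact), rescoring and retesting every time, and reports the mean
#' over replicates of the mean FDR at each size. A parallel mock arm draws
#' both artificial groups from the control pool only - the varied artificial
#' group gets the requested size and the remaining controls form its
#' counterpart - so that the mock curve shows how much apparent separation a
#' given group size produces when no real difference exists.
#'
#' @param s A [scale_genes()] result.
#' @param pathways List of [pathway()] objects.
#' @param sizes Integer vector of group sizes to test (default `5:30`).
#' @param which Which group is reduced: `"case"` or `"control"`.
#' @param n_reps Random subsets per size (default 10).
#' @param seed Master seed.
#' @param min_nodes Passed to the scorer.
#' @return Tibble of class `sample_size_curves` with columns `size`, `arm`
#'   (`"real"`/`"mock"`) and `mean_fdr`; per-replicate values are kept in
#'   the `"replicates"` attribute.
#' @export
sample_size_experiment <- function(s, pathways, sizes = 5:30,
                                   which = c("case", "control"),
                                   n_reps = 10, seed = 1L, min_nodes = 5) {
  stopifnot(inherits(s, "scaled_mat"))
  which <- match.arg(which)
  pr <- prep_scoring(rownames(s$values), pathways, min_nodes)
  if (length(pr$prep) == 0) abort_input("No scorable pathways.")
  idx_case <- base::which(s$labels == "case")
  idx_ctrl <- base::which(s$labels == "control")
  varied <- if (which == "case") idx_case else idx_ctrl
  fixed <- if (which == "case") idx_ctrl else idx_case
  if (max(sizes) > length(varied)) {
    abort_input(sprintf("Requested size %d exceeds available %s samples (%d).",
                        max(sizes), which, length(varied)))
  }
  if (max(sizes) + 2 > length(idx_ctrl)) {
    abort_input("Control pool too small for the mock arm at the largest size.")
  }

  eval_cols <- function(cols, lab) {
    m <- score_with_prep(s$values[, cols, drop = FALSE], lab, pr$prep)
    mean(group_comparison(m, lab)$fdr)
  }
  rep_rows <- list()
  counter <- 0L
  for (k in sizes) {
    for (r in seq_len(n_reps)) {
      counter <- counter + 1L
      sub_seed <- derive_seed(seed, counter)
      picks <- withr::with_seed(sub_seed, list(
        real = sample(varied, k),
        mock = sample(idx_ctrl, length(idx_ctrl))
      ))
      # real arm: reduced group + intact other group
      cols <- c(picks$real, fixed)
      lab <- factor(ifelse(cols %in% idx_case, "case", "control"),
                    levels = c("control", "case"))
      fdr_real <- eval_cols(cols, lab)
      # mock arm: two artificial groups from the control pool; the varied
      # role gets k samples, the remaining controls form the other group
      mock_varied <- picks$mock[seq_len(k)]
      mock_other <- picks$mock[-seq_len(k)]
      cols_m <- c(mock_varied, mock_other)
      lab_m <- factor(c(rep(if (which == "case") "case" else "control", k),
                        rep(if (which == "case") "control" else "case",
                            length(mock_other))),
                      levels = c("control", "case"))
      fdr_mock <- eval_cols(cols_m, lab_m)
      rep_rows[[counter]] <- tibble::tibble(
        size = k, rep = r,
        arm = c("real", "mock"), fdr_bar = c(fdr_real, fdr_mock))
    }
  }
  detail <- dplyr::bind_rows(rep_rows)
  out <- dplyr::summarise(
    dplyr::group_by(detail, .data$size, .data$arm),
    mean_fdr = mean(.data$fdr_bar), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$size, .data$arm)
  attr(out, "replicates") <- detail
  attr(out, "which") <- which
  class(out) <- c("sample_size_curves", class(out))
  out
}

#' Detection robustness under pathway-structure uncertainty
#'
#' Perturbs the target pathway by randomly removing a given fraction of its
#' nodes or relations ([remove_random()]), rescores it within the full
#' collection, and records whether it still ranks within the top `top_k`
#' pathways by case-control median score difference. The detection rate per
#' fraction and removal mode is the proportion of replicates where it does.
#' Scores of the unperturbed pathways are computed once and reused, since
#' perturbing one pathway leaves them unchanged.
#'
#' @param s A [scale_genes()] result.
#' @param pathways List of [pathway()] objects containing the target.
#' @param target_pathway_id Pathway whose structure is degraded.
#' @param fractions Removal proportions (default `c(.05, .1, .2, .3, .4, .5)`).
#' @param what Removal modes to run (default both `"nodes"` and
#'   `"relations"`).
#' @param n_reps Random reductions per fraction and mode (default 100).
#' @param top_k Detection cut-off rank (default 25).
#' @param seed Master seed.
#' @param min_nodes Passed to the scorer; a perturbed target falling below
#'   this measured-node count becomes unscorable and counts as undetected.
#' @return Tibble of class `uncertainty_result` with columns `what`,
#'   `fraction`, `detection_rate`, `n_detected`, `n_reps`; per-replicate
#'   ranks in the `"replicates"` attribute.
#' @export
uncertainty_experiment <- function(s, pathways, target_pathway_id,
                                   fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                                   what = c("nodes", "relations"),
                                   n_reps = 100, top_k = 25, seed = 1L,
                                   min_nodes = 5) {
  stopifnot(inherits(s, "scaled_mat"))
  what <- match.arg(what, several.ok = TRUE)
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (!target_pathway_id %in% ids) {
    abort_input(paste0("Target pathway not in collection: ", target_pathway_id))
  }
  target <- pathways[[match(target_pathway_id, ids)]]
  others <- pathways[ids != target_pathway_id]

  pr_others <- prep_scoring(rownames(s$values), others, min_nodes)
  pr_target <- prep_scoring(rownames(s$values), list(target), min_nodes)
  if (length(pr_target$prep) == 0) {
    abort_input("Target pathway is not scorable in this matrix.")
  }
  dev <- deviation_matrix(s$values, s$labels)
  case <- s$labels == "case"

  median_diff_rows <- function(m) {
    abs(apply(m[, case, drop = FALSE], 1, median) -
          apply(m[, !case, drop = FALSE], 1, median))
  }
  base_scores <- score_with_prep(s$values, s$labels, pr_others$prep)
  base_diff <- median_diff_rows(base_scores)
  base_ids <- rownames(base_scores)

  # rank of the target among the fixed competitors, ties broken by id
  target_rank <- function(d_target) {
    1L + sum(base_diff > d_target) +
      sum(base_diff == d_target & base_ids < target_pathway_id)
  }
  score_target <- function(p) {
    pr <- prep_scoring(rownames(s$values), list(p), min_nodes)
    if (length(pr$prep) == 0) return(NULL)
    pp <- pr$prep[[1]]
    nv <- vapply(pp$rows, function(rr) colMeans(dev[rr, , drop = FALSE]),
                 numeric(ncol(dev)))
    as.vector(nv %*% pp$weights) / sum(pp$weights)
  }

  rows <- list()
  detail <- list()
  counter <- 0L
  for (mode in what) {
    for (f in fractions) {
      detected <- logical(n_reps)
      ranks <- rep(NA_integer_, n_reps)
      for (r in seq_len(n_reps)) {
        counter <- counter + 1L
        pp <- remove_random(target, f, mode, seed = derive_seed(seed, counter))
        sc <- score_target(pp)
        if (!is.null(sc)) {
          d <- abs(median(sc[case]) - median(sc[!case]))
          ranks[r] <- target_rank(d)
          detected[r] <- ranks[r] <= top_k
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        what = mode, fraction = f,
        detection_rate = mean(detected),
        n_detected = sum(detected), n_reps = n_reps)
      detail[[length(detail) + 1L]] <- tibble::tibble(
        what = mode, fraction = f, rep = seq_len(n_reps), rank = ranks)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "replicates") <- dplyr::bind_rows(detail)
  attr(out, "target_pathway_id") <- target_pathway_id
  attr(out, "top_k") <- top_k
  class(out) <- c("uncertainty_result", class(out))
  out
}
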