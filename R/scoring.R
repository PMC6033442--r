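#' Per-gene deviation from the control reference
#'
#' The reference of a gene is the median of its scaled values over the
#' control samples; a sample's deviation is the absolute difference between
#' its scaled value and that reference. Two refinements keep case and
#' control deviations exchangeable under the null. First, each control's
#' reference is computed leave-one-out (median of the *other* controls), so
#' controls are not compared against a median they themselves pulled toward.
#' Second, each case sample's reference also omits one control - assigned by
#' deterministic rotation - so every sample, case or control, is compared
#' against a median of the same number of control values it did not
#' contribute to. Without the jackknife matching, the reference-group
#' deviations are systematically smaller (or differently dispersed) than
#' case deviations and the downstream group test is anti-conservative under
#' the null.
#'
#' @param x Scaled values matrix (genes x samples).
#' @param labels Factor of `"case"`/`"control"` over the columns.
#' @return Matrix of deviations in `[0, 1]`, same shape as `x`.
#' @keywords internal
#' @noRd
deviation_matrix <- function(x, labels) {
  ctrl <- base::which(labels == "control")
  if (length(ctrl) < 2) abort_input("Need at least 2 control samples for a reference.")
  xc <- x[, ctrl, drop = FALSE]
  loo <- loo_median(xc)
  dev <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  dev[, ctrl] <- abs(xc - loo)
  cases <- base::which(labels == "case")
  if (length(cases) > 0) {
    # rotation keyed on sorted sample names, so scores are invariant to
    # column order
    case_rank <- rank(colnames(x)[cases], ties.method = "first")
    ctrl_by_name <- order(colnames(x)[ctrl])
    omit <- ctrl_by_name[(case_rank - 1L) %% length(ctrl) + 1L]
    dev[, cases] <- abs(x[, cases, drop = FALSE] - loo[, omit, drop = FALSE])
  }
  dev
}

# leave-one-out medians per row: m[g, i] = median(x[g, -i]); vectorized via
# row-sorted values and ranks (ties broken by first occurrence, which only
# matters for exactly tied values where any break yields the same median)
loo_median <- function(x) {
  n <- ncol(x)
  if (n < 2) abort_input("Leave-one-out median needs >= 2 columns.")
  s <- t(apply(x, 1, sort))
  r <- t(apply(x, 1, rank, ties.method = "first"))
  g <- nrow(x)
  pick <- function(col) s[cbind(seq_len(g), col)]
  out <- matrix(0, g, n, dimnames = dimnames(x))
  if ((n - 1) %% 2 == 1) {
    # odd remainder: single middle element at position k of the n-1 survivors
    k <- n %/% 2
    for (i in seq_len(n)) {
      ri <- r[, i]
      out[, i] <- ifelse(ri <= k, pick(k + 1L), pick(k))
    }
  } else {
    # even remainder: mean of positions k, k+1 of the survivors
    k <- (n - 1L) %/% 2L
    for (i in seq_len(n)) {
      ri <- r[, i]
      lo <- ifelse(ri <= k, pick(k + 1L), pick(k))
      hi <- ifelse(ri >= k + 2L, pick(k + 1L), pick(k + 2L))
      out[, i] <- (lo + hi) / 2
    }
  }
  out
}

measured_nodes <- function(p, gene_ids) {
  rows <- lapply(p$nodes$members, function(m) {
    which(gene_ids %in% as.character(m))
  })
  keep <- p$nodes$kind %in% c("gene", "group") & lengths(rows) > 0
  list(node_ids = p$nodes$node_id[keep], rows = rows[keep])
}

#' Pathway node deviation values
#'
#' Transforms scaled gene values into per-node, per-sample deviations from
#' normal: each measured node's value is the mean deviation of its member
#' genes present in the matrix. Compound nodes and nodes without any
#' measured member gene are excluded.
#'
#' @param s A [scale_genes()] result.
#' @param p A [pathway()] object.
#' @return An object of class `node_values`: list with `pathway_id`,
#'   `node_ids`, `values` (node x sample matrix in `[0, 1]`) and `reference`
#'   (tibble of per-gene control medians for the genes used). A pathway with
#'   no measured node yields a zero-row matrix (flagged unscorable).
#' @export
node_values <- function(s, p) {
  stopifnot(inherits(s, "scaled_mat"), inherits(p, "pathway"))
  dev <- deviation_matrix(s$values, s$labels)
  mn <- measured_nodes(p, rownames(s$values))
  v <- matrix(NA_real_, length(mn$node_ids), ncol(s$values),
              dimnames = list(mn$node_ids, colnames(s$values)))
  for (i in seq_along(mn$rows)) {
    v[i, ] <- colMeans(dev[mn$rows[[i]], , drop = FALSE])
  }
  genes_used <- rownames(s$values)[sort(unique(unlist(mn$rows)))]
  ctrl <- s$labels == "control"
  ref <- tibble::tibble(
    gene_id = genes_used,
    reference = unname(apply(s$values[genes_used, ctrl, drop = FALSE], 1, median))
  )
  structure(
    list(pathway_id = p$pathway_id, node_ids = mn$node_ids, values = v,
         reference = ref, unscorable = length(mn$node_ids) == 0),
    class = "node_values"
  )
}

#' Topology-derived node importance weights
#'
#' A node's importance grows with its downstream reach over the *full*
#' pathway: `w = 1 + reach / max(reach)` (all weights 1 when no node reaches
#' anything). Weights are bounded in `[1, 2]` so topology modulates the
#' score without dominating it, and are reported for the measured nodes.
#'
#' @param p A [pathway()] object.
#' @param measured_node_ids Character vector of node ids to report weights
#'   for (must be non-empty).
#' @return Named numeric vector of weights in `[1, 2]`.
#' @export
node_importance <- function(p, measured_node_ids) {
  stopifnot(inherits(p, "pathway"))
  if (length(measured_node_ids) == 0) {
    abort_input("`measured_node_ids` must be non-empty.")
  }
  if (!all(measured_node_ids %in% p$nodes$node_id)) {
    abort_input("Unknown node ids in `measured_node_ids`.")
  }
  reach <- downstream_reach_all(p)
  rmax <- if (length(reach) > 0) max(reach) else 0L
  w <- if (rmax > 0) 1 + reach / rmax else stats::setNames(rep(1, length(reach)), names(reach))
  w[measured_node_ids]
}

#' Importance-weighted pathway deregulation score
#'
#' The per-sample score is the importance-weighted mean of the node
#' deviation values, hence bounded in `[0, 1]`: low means the pathway looks
#' like a typical control sample, high means deregulated.
#'
#' @param nv A [node_values()] result.
#' @param w Named weight vector covering `nv$node_ids` (see
#'   [node_importance()]).
#' @return Named numeric vector of per-sample scores; all-`NA` with
#'   attribute `unscorable = TRUE` when the node set is empty.
#' @export
pathway_score <- function(nv, w) {
  stopifnot(inherits(nv, "node_values"))
  if (length(nv$node_ids) == 0) {
    out <- stats::setNames(rep(NA_real_, ncol(nv$values)), colnames(nv$values))
    attr(out, "unscorable") <- TRUE
    return(out)
  }
  w <- w[nv$node_ids]
  if (anyNA(w)) abort_input("Weights do not cover all measured nodes.")
  colSums(nv$values * w) / sum(w)
}

# Precompute label-independent per-pathway scoring structure: member gene row
# indices per measured node and importance weights. Pathways with fewer than
# `min_nodes` measured nodes are dropped here (recorded in `skipped`).
prep_scoring <- function(gene_ids, pathways, min_nodes = 5) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  prep <- list()
  skipped <- character(0)
  for (p in pathways) {
    mn <- measured_nodes(p, gene_ids)
    if (length(mn$node_ids) < min_nodes) {
      skipped <- c(skipped, p$pathway_id)
      next
    }
    w <- node_importance(p, mn$node_ids)
    prep[[p$pathway_id]] <- list(name = p$name, rows = mn$rows,
                                 node_ids = mn$node_ids, weights = unname(w))
  }
  list(prep = prep, skipped = skipped)
}

# Score every prepared pathway for one labelling of the scaled matrix.
score_with_prep <- function(x, labels, prep) {
  dev <- deviation_matrix(x, labels)
  scores <- matrix(NA_real_, length(prep), ncol(x),
                   dimnames = list(names(prep), colnames(x)))
  for (j in seq_along(prep)) {
    pp <- prep[[j]]
    nv <- vapply(pp$rows, function(rr) colMeans(dev[rr, , drop = FALSE]),
                 numeric(ncol(x)))
    # vapply returns samples x nodes
    scores[j, ] <- as.vector(nv %*% pp$weights) / sum(pp$weights)
  }
  scores
}

#' Score a pathway collection for every sample
#'
#' Runs the full scoring pipeline over a list of pathways: node deviation
#' values, importance weights and weighted-mean scores. Pathways with fewer
#' than `min_nodes` measured nodes are skipped (logged), preventing one- or
#' two-gene pathways from producing noise-driven scores.
#'
#' @param s A [scale_genes()] result.
#' @param pathways A list of [pathway()] objects (or a single one).
#' @param min_nodes Minimum number of measured nodes for a pathway to be
#'   scored (default 5).
#' @return An object of class `pathway_scores`: list with `scores` (pathway x
#'   sample matrix in `[0, 1]`), `labels`, `info` (tibble: pathway_id, name,
#'   n_nodes) and `skipped` (ids of unscored pathways).
#' @export
score_pathways <- function(s, pathways, min_nodes = 5) {
  stopifnot(inherits(s, "scaled_mat"))
  pr <- prep_scoring(rownames(s$values), pathways, min_nodes)
  if (length(pr$skipped) > 0) {
    rlang::inform(sprintf("Skipped %d pathways with fewer than %d measured nodes.",
                          length(pr$skipped), min_nodes))
  }
  if (length(pr$prep) == 0) abort_input("No scorable pathways.")
  scores <- score_with_prep(s$values, s$labels, pr$prep)
  info <- tibble::tibble(
    pathway_id = names(pr$prep),
    name = vapply(pr$prep, function(p) p$name, character(1)),
    n_nodes = vapply(pr$prep, function(p) length(p$node_ids), integer(1))
  )
  structure(
    list(scores = scores, labels = s$labels, info = info, skipped = pr$skipped),
    class = "pathway_scores"
  )
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("<pathway_scores> %d pathways x %d samples (%d case, %d control)\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$labels == "case"), sum(x$labels == "control")))
  if (length(x$skipped) > 0) cat(sprintf("  %d pathways skipped\n", length(x$skipped)))
  invisible(x)
}

#' @export
tidy.pathway_scores <- function(x, ...) {
  tidy_matrix(x$scores, x$labels, value_col = "score", id_col = "pathway_id")
}

#' @export
glance.pathway_scores <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$scores),
    n_samples = ncol(x$scores),
    n_case = sum(x$labels == "case"),
    n_control = sum(x$labels == "control"),
    n_skipped = length(x$skipped)
  )
}

#' Rank pathways by case-control separation of their scores
#'
#' Pathways are ordered by the absolute difference between the median case
#' score and the median control score, largest first; ties are broken
#' lexicographically by pathway id. Rank 1 is the strongest detection.
#'
#' @param ps A [score_pathways()] result.
#' @return Tibble with columns `pathway_id`, `name`, `median_case`,
#'   `median_control`, `median_diff` (absolute difference) and `rank`.
#' @export
rank_pathways <- function(ps) {
  stopifnot(inherits(ps, "pathway_scores"))
  if (length(unique(ps$labels)) < 2) {
    abort_input("Both case and control samples are required for ranking.")
  }
  case <- ps$labels == "case"
  med_case <- unname(apply(ps$scores[, case, drop = FALSE], 1, median))
  med_ctrl <- unname(apply(ps$scores[, !case, drop = FALSE], 1, median))
  out <- tibble::tibble(
    pathway_id = rownames(ps$scores),
    median_case = med_case,
    median_control = med_ctrl,
    median_diff = abs(med_case - med_ctrl)
  )
  out <- dplyr::left_join(out, ps$info[, c("pathway_id", "name")], by = "pathway_id")
  out <- dplyr::arrange(out, dplyr::desc(.data$median_diff), .data$pathway_id)
  out$rank <- seq_len(nrow(out))
  dplyr::select(out, "pathway_id", "name", "median_case", "median_control",
                "median_diff", "rank")
}

#' @importFrom rlang .data
NULL
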