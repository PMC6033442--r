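#' Two-sided rank-sum p-value for one score vector
#'
#' Exact Wilcoxon rank-sum distribution when both groups have at most 25
#' samples and the pooled values are tie-free; tie-corrected normal
#' approximation with continuity correction otherwise. A fully tied vector
#' carries no evidence and returns 1.
#'
#' @keywords internal
#' @noRd
wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(x) <= 25 && length(y) <= 25
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  if (!is.finite(p)) return(1)
  min(p, 1)
}

#' Per-pathway rank-sum group tests
#'
#' Compares case and control scores within each pathway with a two-sided
#' two-sample Wilcoxon rank-sum test.
#'
#' @param ps A [score_pathways()] result, or a numeric matrix (rows = units,
#'   columns = samples) together with `labels`.
#' @param labels Required when `ps` is a plain matrix.
#' @return Tibble with columns `pathway_id` and `p_value`.
#' @export
wilcoxon_groups <- function(ps, labels = NULL) {
  if (inherits(ps, "pathway_scores")) {
    m <- ps$scores
    labels <- ps$labels
  } else {
    m <- ps
    if (is.null(labels)) abort_input("`labels` required for a plain matrix.")
    labels <- normalize_labels(labels, colnames(m))
  }
  check_group_sizes(labels)
  case <- labels == "case"
  p <- apply(m, 1, function(v) wilcox_p(v[case], v[!case]))
  tibble::tibble(pathway_id = rownames(m), p_value = unname(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Vector of BH step-up adjusted values, each at most 1.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) abort_input("Empty p-value vector.")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort_input("All p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

# shared machinery: rank-sum tests + BH over the rows of a matrix
group_comparison <- function(m, labels, id_col = "pathway_id") {
  tests <- wilcoxon_groups(m, labels)
  tests$fdr <- bh_fdr(tests$p_value)
  names(tests)[1] <- id_col
  tests
}

#' Mean BH-adjusted FDR of a group comparison
#'
#' @param comparison A tibble with an `fdr` column (as returned by
#'   [gene_level_arm()] or stored in an [fdr_ratio_experiment()] result).
#' @return The average FDR over all tested units.
#' @export
mean_fdr <- function(comparison) {
  mean(comparison$fdr)
}

#' Random mock relabelling of the pooled samples
#'
#' Pools the real case and control samples and splits them uniformly at
#' random into two artificial groups of (near-)equal size; with an odd pool
#' the first group gets the extra sample. The first artificial group plays
#' the control-reference role downstream, so the returned factor labels it
#' `"control"`.
#'
#' @param labels Real label factor/vector (used only for its length and
#'   sample names).
#' @param seed Integer seed; the split is reproducible.
#' @return Factor of mock labels, same length and names as `labels`.
#' @export
make_mock <- function(labels, seed = 1L) {
  n <- length(labels)
  if (n < 4) abort_input("Need at least 4 pooled samples for a mock split.")
  n_ctrl <- ceiling(n / 2)
  perm <- withr::with_seed(seed, sample.int(n))
  mock <- rep("case", n)
  mock[perm[seq_len(n_ctrl)]] <- "control"
  out <- factor(mock, levels = c("control", "case"))
  names(out) <- names(labels)
  out
}

#' Log-ratio of real to mock mean FDR
#'
#' `-log2(fdr_real / mean(fdr_mock))`: positive when the real labelling
#' separates groups better than random relabellings, zero when it does no
#' better. Base 2 is the convention throughout this package.
#'
#' @param fdr_real Mean FDR on the real labels (positive scalar).
#' @param fdr_mock Vector of mean FDRs, one per mock split (all positive).
#' @return The FDR ratio statistic.
#' @export
#' @examples
#' fdr_ratio(0.13, 0.71)
fdr_ratio <- function(fdr_real, fdr_mock) {
  if (length(fdr_real) != 1 || !is.finite(fdr_real) || fdr_real <= 0) {
    abort_input("`fdr_real` must be a single positive value.")
  }
  if (length(fdr_mock) == 0 || any(!is.finite(fdr_mock)) || any(fdr_mock <= 0)) {
    abort_input("`fdr_mock` must be positive values.")
  }
  -log2(fdr_real / mean(fdr_mock))
}

#' FDR-ratio experiment against mock relabellings
#'
#' Computes the mean FDR of the case-vs-control comparison on the real
#' labels, then repeats scoring and testing under `n_mock` seeded random
#' relabellings (for the pathway arm the control reference is recomputed
#' from each mock's control-role group), and assembles the FDR ratio.
#'
#' @param s A [scale_genes()] result.
#' @param pathways List of [pathway()] objects (pathway arm) or `NULL`
#'   (gene-level arm).
#' @param arm `"pathway"` scores pathways; `"gene"` applies the identical
#'   test machinery directly to the scaled gene rows.
#' @param n_mock Number of mock relabellings (default 10).
#' @param seed Master seed; mock split `i` uses `derive_seed(seed, i)`.
#' @param min_nodes Passed to the pathway scorer.
#' @return Object of class `fdr_ratio_result`: list with `arm`, `fdr_real`,
#'   `fdr_mock` (length `n_mock`), `ratio`, and `comparison` (per-unit
#'   p-value/FDR tibble on the real labels).
#' @export
fdr_ratio_experiment <- function(s, pathways = NULL,
                                 arm = c("pathway", "gene"),
                                 n_mock = 10, seed = 1L, min_nodes = 5) {
  stopifnot(inherits(s, "scaled_mat"))
  arm <- match.arg(arm)
  if (arm == "pathway") {
    if (is.null(pathways)) abort_input("Pathway arm requires `pathways`.")
    pr <- prep_scoring(rownames(s$values), pathways, min_nodes)
    if (length(pr$prep) == 0) abort_input("No scorable pathways.")
    eval_labels <- function(lab) {
      group_comparison(score_with_prep(s$values, lab, pr$prep), lab)
    }
  } else {
    eval_labels <- function(lab) {
      group_comparison(s$values, lab, id_col = "gene_id")
    }
  }
  real <- eval_labels(s$labels)
  fdr_real <- mean(real$fdr)
  fdr_mock <- vapply(seq_len(n_mock), function(i) {
    mock <- make_mock(s$labels, derive_seed(seed, i))
    mean(eval_labels(mock)$fdr)
  }, numeric(1))
  structure(
    list(arm = arm, fdr_real = fdr_real, fdr_mock = fdr_mock,
         ratio = fdr_ratio(fdr_real, fdr_mock), n_mock = n_mock,
         comparison = real),
    class = "fdr_ratio_result"
  )
}

#' @export
print.fdr_ratio_result <- function(x, ...) {
  cat(sprintf("<fdr_ratio_result> %s arm: FDR ratio %.3f (real %.3f vs mean mock %.3f, %d mocks)\n",
              x$arm, x$ratio, x$fdr_real, mean(x$fdr_mock), x$n_mock))
  invisible(x)
}

#' @export
tidy.fdr_ratio_result <- function(x, ...) {
  tibble::tibble(
    dataset = c("real", paste0("mock_", seq_along(x$fdr_mock))),
    fdr_bar = c(x$fdr_real, x$fdr_mock)
  )
}

#' @export
glance.fdr_ratio_result <- function(x, ...) {
  tibble::tibble(
    arm = x$arm,
    fdr_real = x$fdr_real,
    fdr_mock_mean = mean(x$fdr_mock),
    fdr_ratio = x$ratio,
    n_mock = x$n_mock
  )
}

#' Gene-level comparison arm
#'
#' Applies the identical Wilcoxon + BH machinery to the scaled per-gene
#' values instead of pathway scores - the baseline showing what the scaling
#' alone, without pathway information, detects.
#'
#' @param s A [scale_genes()] result.
#' @return Tibble with columns `gene_id`, `p_value`, `fdr`; the mean FDR is
#'   available via [mean_fdr()].
#' @export
gene_level_arm <- function(s) {
  stopifnot(inherits(s, "scaled_mat"))
  group_comparison(s$values, s$labels, id_col = "gene_id")
}
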