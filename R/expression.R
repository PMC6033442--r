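#' Expression matrix container
#'
#' Bundles a non-negative, linear-scale expression matrix (genes x samples,
#' Entrez gene ids as rownames) with case/control sample labels. This is the
#' raw substrate of the preprocessing step: values must be finite,
#' non-negative and on the original (non-log) intensity scale, and each group
#' must hold at least two samples.
#'
#' @param values Numeric matrix, genes in rows (rownames = Entrez ids),
#'   samples in columns (colnames = sample ids).
#' @param labels Per-sample labels, either a factor/character vector aligned
#'   to the columns or a named vector over the sample ids; values must be
#'   `"case"` or `"control"`.
#' @return An object of class `expr_mat`: a list with elements `values`,
#'   `labels` and `noise_threshold` (`NA` until [filter_noise()] is applied).
#' @export
#' @examples
#' x <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("10", "20"), c("s1", "s2")))
#' # two samples per group is the minimum, so duplicate the columns
#' x <- cbind(x, x + 1)
#' colnames(x) <- paste0("s", 1:4)
#' expr_matrix(x, c("case", "case", "control", "control"))
expr_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_input("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_input("`values` must have rownames (gene ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(values))) abort_input("Duplicated gene ids.")
  if (anyDuplicated(colnames(values))) abort_input("Duplicated sample ids.")
  if (!all(is.finite(values))) abort_input("All expression values must be finite.")
  if (any(values < 0)) abort_input("Expression values must be non-negative (linear scale).")
  labels <- normalize_labels(labels, colnames(values))
  check_group_sizes(labels)
  structure(
    list(values = values, labels = labels, noise_threshold = NA_real_),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  if (!is.na(x$noise_threshold)) {
    cat(sprintf("  noise threshold: %.4g\n", x$noise_threshold))
  }
  invisible(x)
}

#' Read an expression matrix and map probes to Entrez genes
#'
#' Loads a tab-separated expression table (first column probe/gene ids, header
#' row sample ids), maps probe ids to Entrez ids, collapses probes sharing an
#' Entrez id by their arithmetic mean, and drops unmapped probes with a
#' logged count. Values already on log2 scale are exponentiated back to
#' linear scale before anything else, matching the convention that downstream
#' steps see non-log intensities.
#'
#' @param path Path to the tab-separated expression table.
#' @param mapping Probe-to-Entrez mapping: either a two-column data frame
#'   (source id, Entrez id) or a path to a two-column tab-separated file
#'   (header auto-detected). Many probes may map to one Entrez id; each probe
#'   maps to at most one.
#' @param labels Sample labels (file path, data frame or named vector, see
#'   [expr_matrix()]).
#' @param is_log If `TRUE`, input values are log2 intensities and are
#'   converted to linear scale.
#' @return An [expr_matrix()] object with Entrez rownames.
#' @export
read_expression <- function(path, mapping, labels, is_log = FALSE) {
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort_format(paste0("Cannot parse expression table: ",
                                            conditionMessage(e)))
  )
  if (ncol(tab) < 3) abort_input("Expression table needs >= 2 sample columns.")
  num <- vapply(tab[-1], is.numeric, logical(1))
  if (!all(num)) {
    abort_format(paste0("Non-numeric sample columns in expression table: ",
                        paste(names(tab)[-1][!num], collapse = ", ")))
  }
  ids <- as.character(tab[[1]])
  x <- as.matrix(tab[-1])
  rownames(x) <- ids
  if (isTRUE(is_log)) x <- 2^x

  map <- read_gene_mapping(mapping)
  entrez <- map$entrez[match(ids, map$source_id)]
  dropped <- sum(is.na(entrez))
  if (dropped > 0) {
    rlang::inform(sprintf("Dropped %d of %d probes without an Entrez mapping.",
                          dropped, length(ids)))
  }
  keep <- !is.na(entrez)
  if (!any(keep)) abort_input("No expression row ids found in the mapping.")
  x <- x[keep, , drop = FALSE]
  entrez <- entrez[keep]

  # collapse probes sharing an Entrez id by arithmetic mean
  sums <- rowsum(x, group = entrez, reorder = TRUE)
  counts <- as.vector(table(entrez)[rownames(sums)])
  x <- sums / counts

  lab <- normalize_labels(labels, colnames(x))
  n_ctrl <- sum(lab == "control")
  if (n_ctrl < 15) {
    rlang::warn(sprintf(
      "Only %d control samples; at least 15 are recommended for a stable reference.",
      n_ctrl))
  }
  expr_matrix(x, lab)
}

#' Read a probe-to-Entrez mapping table
#'
#' @param mapping Two-column data frame or path to a two-column tab-separated
#'   file (source id, Entrez id); a header row is detected and skipped when
#'   the second field of the first row is not an integer.
#' @return A tibble with columns `source_id` (character) and `entrez`
#'   (integer); duplicate source ids keep their first mapping.
#' @export
read_gene_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    tab <- readr::read_tsv(mapping, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    if (ncol(tab) < 2) abort_format("Mapping file must have two columns.")
    if (nrow(tab) > 0 && is.na(suppressWarnings(as.integer(tab[[2]][1])))) {
      tab <- tab[-1, , drop = FALSE]   # header row
    }
    mapping <- tab
  }
  if (!is.data.frame(mapping) || ncol(mapping) < 2) {
    abort_input("`mapping` must be a two-column data frame or file path.")
  }
  out <- tibble::tibble(
    source_id = as.character(mapping[[1]]),
    entrez = suppressWarnings(as.integer(mapping[[2]]))
  )
  out <- out[!is.na(out$entrez), ]
  out[!duplicated(out$source_id), ]
}

#' Floor expression values at a noise threshold
#'
#' Values below the detection limit of the platform carry no signal, yet after
#' per-gene scaling they would contribute spurious deviation. The filter
#' computes a global nearest-rank quantile of all matrix values and floors
#' every value beneath it, keeping the matrix shape intact. The threshold is
#' recorded on the returned object for reporting.
#'
#' @param m An [expr_matrix()] object.
#' @param q Quantile in `[0, 1)` defining the noise floor; `q = 0` leaves the
#'   matrix unchanged. Default 0.05.
#' @return The filtered `expr_mat` with `noise_threshold` set.
#' @export
filter_noise <- function(m, q = 0.05) {
  stopifnot(inherits(m, "expr_mat"))
  if (!is.numeric(q) || length(q) != 1 || q < 0 || q >= 1) {
    abort_input("`q` must be a single value in [0, 1).")
  }
  t <- unname(quantile(m$values, probs = q, type = 1, names = FALSE))
  m$values[m$values < t] <- t
  m$noise_threshold <- t
  m
}

#' Scale each gene to the unit interval
#'
#' Per-gene min-max scaling across all samples (cases and controls together)
#' makes genes comparable regardless of their dynamic range and bounds all
#' downstream node and pathway values in `[0, 1]`. A gene with zero range
#' carries no information and maps to 0.5 for every sample.
#'
#' @param m An [expr_matrix()] object (typically after [filter_noise()]).
#' @return An object of class `scaled_mat`: list with `values` in `[0, 1]`,
#'   `labels`, and the `noise_threshold` carried forward.
#' @export
scale_genes <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  lo <- apply(m$values, 1, min)
  hi <- apply(m$values, 1, max)
  rng <- hi - lo
  scaled <- (m$values - lo) / ifelse(rng == 0, 1, rng)
  scaled[rng == 0, ] <- 0.5
  structure(
    list(values = scaled, labels = m$labels, noise_threshold = m$noise_threshold),
    class = "scaled_mat"
  )
}

#' @export
print.scaled_mat <- function(x, ...) {
  cat(sprintf("<scaled_mat> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
tidy.expr_mat <- function(x, ...) {
  tidy_matrix(x$values, x$labels, value_col = "value", id_col = "gene_id")
}

#' @export
tidy.scaled_mat <- function(x, ...) {
  tidy_matrix(x$values, x$labels, value_col = "scaled_value", id_col = "gene_id")
}

tidy_matrix <- function(values, labels, value_col, id_col) {
  out <- tibble::as_tibble(values, rownames = id_col)
  out <- tidyr::pivot_longer(out, -dplyr::all_of(id_col),
                             names_to = "sample_id", values_to = value_col)
  lab <- tibble::tibble(sample_id = colnames(values), label = labels)
  dplyr::left_join(out, lab, by = "sample_id")
}
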