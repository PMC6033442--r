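abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "pathdereg_input_error", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "pathdereg_format_error", ...)
}

#' Derive a replicate seed from a master seed
#'
#' Experiments that loop over replicates draw one sub-seed per replicate from
#' a single master seed, so runs are reproducible and replicates independent
#' of evaluation order. The derivation is a fixed affine step modulo the
#' largest 32-bit prime, keeping every derived seed a valid R integer.
#'
#' @param seed Master seed (single integer).
#' @param i Replicate counter (single non-negative integer).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, i) {
  stopifnot(length(seed) == 1, length(i) == 1)
  as.integer((abs(as.numeric(seed)) + 104729 * as.numeric(i)) %% 2147483647)
}

# labels come in as files, data frames, factors or named vectors; normalize to
# a case/control factor aligned to the given sample ids
normalize_labels <- function(labels, sample_ids) {
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    tab <- readr::read_tsv(labels, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(tab) < 2) abort_format("Label file must have two columns (sample_id, label).")
    labels <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  lv <- as.character(labels)
  if (!is.null(names(labels)) && all(nzchar(names(labels)))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0) {
      abort_input(paste0("Labels missing for samples: ",
                         paste(head(missing, 5), collapse = ", ")))
    }
    lv <- as.character(labels[sample_ids])
  } else if (length(lv) != length(sample_ids)) {
    abort_input("Unnamed label vector must match the number of samples.")
  }
  bad <- setdiff(unique(lv), c("case", "control"))
  if (length(bad) > 0) {
    abort_input(paste0("Labels must be 'case' or 'control'; found: ",
                       paste(bad, collapse = ", ")))
  }
  factor(lv, levels = c("control", "case"))
}

check_group_sizes <- function(labels, min_each = 2) {
  n_case <- sum(labels == "case")
  n_ctrl <- sum(labels == "control")
  if (n_case < min_each || n_ctrl < min_each) {
    abort_input(sprintf(
      "Need at least %d samples per group (found %d case, %d control).",
      min_each, n_case, n_ctrl))
  }
  invisible(c(case = n_case, control = n_ctrl))
}
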