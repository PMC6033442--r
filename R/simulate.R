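#' Configuration for the synthetic study generator
#'
#' Collects every knob of the toy-data generator: a collection of synthetic
#' pathway graphs plus an expression matrix whose group effect is restricted
#' to the genes of designated pathways and is modest compared to individual
#' variation. All randomness is multiplicative on the log scale, matching
#' how normalized microarray intensities behave.
#'
#' @param n_pathways Number of pathways to generate (default 250, so a
#'   top-25 detection window covers about 10% of the collection).
#' @param nodes_per_pathway Length-2 integer range of nodes per pathway
#'   (default `c(6, 20)`).
#' @param relation_density Expected relations per node (default 1.4).
#' @param inhibition_fraction Target fraction of inhibiting relations
#'   (default 0.12, the typical share in curated signaling pathways).
#' @param n_genes_background Genes outside every pathway (default 500).
#' @param n_case,n_control Group sizes (defaults 13 and 11).
#' @param effect_pathways Character vector of pathway ids whose member genes
#'   receive the group effect (must exist among the generated ids).
#' @param effect_size Multiplicative fold-change applied to effect genes in
#'   case samples (>= 1; default 1.5).
#' @param individual_sd Log-scale SD of the global per-sample factor applied
#'   to a sample's whole profile (default 0.1, a residual array effect after
#'   normalization).
#' @param gene_sd Log-scale SD of per-gene baseline levels across genes
#'   (default 1.0, spanning the usual intensity range).
#' @param residual_sd Log-scale SD of per-gene, per-sample variation - the
#'   natural individual variation that masks modest group effects (default
#'   0.5, exceeding the log effect of a 1.5-fold change).
#' @param p_shared Probability that a pathway gene is reused from another
#'   pathway rather than drawn fresh (default 0.1).
#' @param seed Master seed for the whole configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pathways = 250, nodes_per_pathway = c(6, 20),
                       relation_density = 1.4, inhibition_fraction = 0.12,
                       n_genes_background = 500, n_case = 13, n_control = 11,
                       effect_pathways = character(0), effect_size = 1.5,
                       individual_sd = 0.1, gene_sd = 1.0, residual_sd = 0.5,
                       p_shared = 0.1, seed = 1L) {
  cfg <- list(
    n_pathways = as.integer(n_pathways),
    nodes_per_pathway = as.integer(nodes_per_pathway),
    relation_density = relation_density,
    inhibition_fraction = inhibition_fraction,
    n_genes_background = as.integer(n_genes_background),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    effect_pathways = as.character(effect_pathways),
    effect_size = effect_size,
    individual_sd = individual_sd, gene_sd = gene_sd,
    residual_sd = residual_sd, p_shared = p_shared,
    seed = as.integer(seed)
  )
  if (cfg$n_pathways < 1 || cfg$n_case < 2 || cfg$n_control < 2 ||
      cfg$n_genes_background < 0) {
    abort_input("Counts must be positive (>= 2 samples per group).")
  }
  if (length(cfg$nodes_per_pathway) != 2 || cfg$nodes_per_pathway[1] < 2 ||
      diff(cfg$nodes_per_pathway) < 0) {
    abort_input("`nodes_per_pathway` must be an increasing range with min >= 2.")
  }
  if (cfg$effect_size < 1) abort_input("`effect_size` must be >= 1.")
  if (cfg$inhibition_fraction < 0 || cfg$inhibition_fraction > 1) {
    abort_input("`inhibition_fraction` must be in [0, 1].")
  }
  n_max <- cfg$nodes_per_pathway[1]
  if (round(cfg$relation_density * n_max) > n_max * (n_max - 1)) {
    abort_input("`relation_density` incompatible with the smallest node count.")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a collection of synthetic pathway graphs
#'
#' Each pathway draws its node count from the configured range, with roughly
#' 10% compound nodes (unmeasurable), 10% group nodes (complexes of two or
#' three of the pathway's gene nodes), and gene nodes carrying one or two
#' Entrez members. Members are mostly fresh ids, with probability `p_shared`
#' reused from earlier pathways so pathways overlap as real collections do.
#' Directed relations are drawn at the configured density with the target
#' share of inhibiting subtypes (exact up to rounding per pathway).
#'
#' @param cfg A [sim_config()].
#' @return Named list of [pathway()] objects with ids `syn0001`, `syn0002`, ...
#' @export
simulate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    next_gene <- 1000L
    used_genes <- integer(0)
    pws <- vector("list", cfg$n_pathways)
    for (j in seq_len(cfg$n_pathways)) {
      id <- sprintf("syn%04d", j)
      n_nodes <- sample(seq(cfg$nodes_per_pathway[1], cfg$nodes_per_pathway[2]), 1)
      n_comp <- round(0.1 * n_nodes)
      n_grp <- if (n_nodes - n_comp >= 4) round(0.1 * n_nodes) else 0L
      n_gene <- n_nodes - n_comp - n_grp

      draw_gene <- function() {
        if (length(used_genes) > 0 && stats::runif(1) < cfg$p_shared) {
          sample(used_genes, 1)
        } else {
          g <- next_gene
          next_gene <<- next_gene + 1L
          g
        }
      }
      gene_members <- lapply(seq_len(n_gene), function(i) {
        k <- sample(1:2, 1)
        sort(unique(vapply(seq_len(k), function(x) draw_gene(), integer(1))))
      })
      used_genes <- unique(c(used_genes, unlist(gene_members)))

      node_id <- as.character(seq_len(n_nodes))
      kind <- c(rep("gene", n_gene), rep("compound", n_comp), rep("group", n_grp))
      members <- c(gene_members, rep(list(integer(0)), n_comp), vector("list", n_grp))
      components <- rep(list(character(0)), n_nodes)
      if (n_grp > 0) {
        for (gidx in seq_len(n_grp)) {
          i <- n_gene + n_comp + gidx
          comp <- sample(seq_len(n_gene), sample(2:min(3, n_gene), 1))
          components[[i]] <- node_id[comp]
          members[[i]] <- sort(unique(unlist(gene_members[comp])))
        }
      }
      nodes <- tibble::tibble(node_id = node_id, kind = kind,
                              members = members, components = components)

      m <- round(cfg$relation_density * n_nodes)
      m <- min(m, n_nodes * (n_nodes - 1))
      if (m > 0) {
        pair_idx <- sample.int(n_nodes * (n_nodes - 1), m)
        src <- (pair_idx - 1) %/% (n_nodes - 1) + 1
        off <- (pair_idx - 1) %% (n_nodes - 1) + 1
        tgt <- ifelse(off >= src, off + 1L, off)
        n_inh <- round(cfg$inhibition_fraction * m)
        sign <- rep(1L, m)
        if (n_inh > 0) sign[sample.int(m, n_inh)] <- -1L
        relations <- tibble::tibble(
          source = node_id[src], target = node_id[tgt], sign = sign,
          subtypes = lapply(sign, function(sg) {
            if (sg == -1L) "inhibition" else "activation"
          })
        )
      } else {
        relations <- tibble::tibble(source = character(0), target = character(0),
                                    sign = integer(0), subtypes = list())
      }
      pws[[j]] <- pathway(id, paste("Synthetic pathway", j), nodes, relations)
    }
    stats::setNames(pws, vapply(pws, function(p) p$pathway_id, character(1)))
  })
}

#' Generate a synthetic expression matrix for a pathway collection
#'
#' Per-gene baselines are log-normal (`gene_sd`), each sample's whole profile
#' is multiplied by a global individual factor (`individual_sd`), and every
#' cell carries log-normal residual variation (`residual_sd`). Genes of the
#' configured effect pathways are additionally multiplied by `effect_size`
#' in case samples only. The effect is applied after all random draws, so
#' the same seed with different effect sizes yields matrices that differ
#' only in the effect - effect-size sweeps are paired by construction.
#'
#' @param cfg A [sim_config()].
#' @param pathways Result of [simulate_pathways()] on the same config.
#' @return An [expr_matrix()] object (rownames = Entrez ids, columns
#'   `case_01`, ..., `control_01`, ...).
#' @export
simulate_expression <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- names(pathways)
  missing <- setdiff(cfg$effect_pathways, ids)
  if (length(missing) > 0) {
    abort_input(paste0("Effect pathways not in collection: ",
                       paste(missing, collapse = ", ")))
  }
  pathway_genes <- sort(unique(unlist(lapply(pathways, function(p) unlist(p$nodes$members)))))
  bg_genes <- max(c(pathway_genes, 0L)) + seq_len(cfg$n_genes_background)
  genes <- c(pathway_genes, bg_genes)
  g <- length(genes)
  n <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                  sprintf("control_%02d", seq_len(cfg$n_control)))
  labels <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))

  x <- withr::with_seed(derive_seed(cfg$seed, 2L), {
    baseline <- stats::rnorm(g, mean = log(500), sd = cfg$gene_sd)
    indiv <- stats::rnorm(n, mean = 0, sd = cfg$individual_sd)
    resid <- matrix(stats::rnorm(g * n, 0, cfg$residual_sd), g, n)
    exp(outer(baseline, indiv, "+") + resid)
  })
  dimnames(x) <- list(as.character(genes), sample_ids)
  if (length(cfg$effect_pathways) > 0 && cfg$effect_size > 1) {
    eff_genes <- sort(unique(unlist(
      lapply(pathways[cfg$effect_pathways],
             function(p) unlist(p$nodes$members)))))
    case_cols <- labels == "case"
    x[as.character(eff_genes), case_cols] <-
      x[as.character(eff_genes), case_cols] * cfg$effect_size
  }
  expr_matrix(x, labels)
}

#' Standard synthetic case-control study
#'
#' The stock fixture for the evaluation experiments: a modestly sized
#' case-control cohort (13 cases, 11 controls by default, mirroring a small
#' type 1 diabetes expression study) over about 250 synthetic pathways, with
#' one designated deregulated pathway carrying a modest multiplicative
#' effect. The designated pathway is the one whose node count is closest to
#' the collection median (ties to the first), so perturbation experiments
#' act on a typical - not extreme - pathway.
#'
#' @param seed Master seed.
#' @param effect_size Fold-change on the effect pathway's genes in cases
#'   (default 1.5; set to 1 for a null study).
#' @param n_case,n_control,n_pathways See [sim_config()].
#' @param ... Further arguments forwarded to [sim_config()].
#' @return List of class `sim_study`: `expression` ([expr_matrix()]),
#'   `pathways` (named list), `effect_pathway` (id, `NA` for a null study)
#'   and `config`.
#' @export
simulate_study <- function(seed = 1L, effect_size = 1.5, n_case = 13,
                           n_control = 11, n_pathways = 250, ...) {
  cfg <- sim_config(seed = seed, effect_size = effect_size, n_case = n_case,
                    n_control = n_control, n_pathways = n_pathways, ...)
  pws <- simulate_pathways(cfg)
  sizes <- vapply(pws, function(p) nrow(p$nodes), integer(1))
  target <- names(pws)[which.min(abs(sizes - median(sizes)))]
  cfg$effect_pathways <- target
  expr <- simulate_expression(cfg, pws)
  structure(
    list(expression = expr, pathways = pws,
         effect_pathway = if (effect_size > 1) target else NA_character_,
         designated_pathway = target, config = cfg),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d pathways, %d genes x %d samples; effect %gx on %s\n",
              length(x$pathways), nrow(x$expression$values),
              ncol(x$expression$values), x$config$effect_size,
              x$designated_pathway))
  invisible(x)
}

#' Write a simulated study as analysis-ready input files
#'
#' Emits the exact on-disk formats the loaders consume: `expression.tsv`
#' (probe column + sample columns), `mapping.tsv` (identity probe-to-Entrez
#' mapping), `labels.tsv`, and a `kgml/` directory with one KGML file per
#' pathway.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kgml_dir <- file.path(dir, "kgml")
  dir.create(kgml_dir, showWarnings = FALSE)
  x <- study$expression$values
  expr_tab <- tibble::as_tibble(x, rownames = "probe_id")
  expr_path <- file.path(dir, "expression.tsv")
  readr::write_tsv(expr_tab, expr_path, progress = FALSE)
  map_path <- file.path(dir, "mapping.tsv")
  readr::write_tsv(tibble::tibble(probe_id = rownames(x), entrez = rownames(x)),
                   map_path, progress = FALSE)
  lab_path <- file.path(dir, "labels.tsv")
  readr::write_tsv(tibble::tibble(sample_id = colnames(x),
                                  label = as.character(study$expression$labels)),
                   lab_path, col_names = FALSE, progress = FALSE)
  for (p in study$pathways) {
    write_kgml(p, file.path(kgml_dir, paste0(p$pathway_id, ".xml")))
  }
  invisible(list(expression = expr_path, mapping = map_path,
                 labels = lab_path, kgml_dir = kgml_dir))
}
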