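#' Pathway graph container
#'
#' A pathway is a signed directed graph over nodes that are functional units
#' (gene products, gene-product groups, or compounds) connected by directional
#' relations. Gene and group nodes carry one or more Entrez gene members;
#' group nodes may additionally record the node ids of their components.
#'
#' @param pathway_id Pathway identifier, e.g. `"hsa04010"`.
#' @param name Human-readable pathway title.
#' @param nodes Tibble with columns `node_id` (character, unique), `kind`
#'   (`"gene"`, `"group"` or `"compound"`), `members` (list of integer Entrez
#'   vectors; empty only for compounds) and optionally `components` (list of
#'   character node-id vectors for groups).
#' @param relations Tibble with columns `source`, `target` (node ids), `sign`
#'   (integer in `{-1, 0, 1}`) and `subtypes` (list of character vectors).
#' @return An object of class `pathway`.
#' @export
pathway <- function(pathway_id, name, nodes, relations) {
  if (!is.character(pathway_id) || length(pathway_id) != 1 || !nzchar(pathway_id)) {
    abort_input("`pathway_id` must be a non-empty string.")
  }
  nodes <- tibble::as_tibble(nodes)
  relations <- tibble::as_tibble(relations)
  if (nrow(nodes) > 0) {
    if (anyDuplicated(nodes$node_id)) abort_input("Duplicated node ids.")
    bad_kind <- setdiff(unique(nodes$kind), c("gene", "group", "compound"))
    if (length(bad_kind) > 0) {
      abort_input(paste0("Unknown node kind: ", paste(bad_kind, collapse = ", ")))
    }
    n_mem <- lengths(nodes$members)
    if (any(nodes$kind %in% c("gene", "group") & n_mem == 0)) {
      abort_input("Gene and group nodes must have at least one Entrez member.")
    }
  }
  if (!"components" %in% names(nodes)) {
    nodes$components <- rep(list(character(0)), nrow(nodes))
  }
  if (nrow(relations) > 0) {
    known <- c(relations$source, relations$target) %in% nodes$node_id
    if (!all(known)) abort_input("Relation endpoint references a missing node.")
    if (!"subtypes" %in% names(relations)) {
      relations$subtypes <- rep(list(character(0)), nrow(relations))
    }
  } else {
    relations <- tibble::tibble(source = character(0), target = character(0),
                                sign = integer(0), subtypes = list())
  }
  structure(
    list(pathway_id = pathway_id, name = name %||% pathway_id,
         nodes = nodes, relations = relations),
    class = "pathway"
  )
}

#' @export
print.pathway <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = c("gene", "group", "compound")))
  cat(sprintf("<pathway> %s: %s\n", x$pathway_id, x$name))
  cat(sprintf("  %d nodes (%d gene, %d group, %d compound), %d relations (%d inhibiting)\n",
              nrow(x$nodes), kinds[["gene"]], kinds[["group"]], kinds[["compound"]],
              nrow(x$relations), sum(x$relations$sign == -1L)))
  invisible(x)
}

#' Sign of a relation from its KGML subtypes
#'
#' Inhibiting subtypes dominate activating ones when several are listed,
#' because a missed inhibition is the costlier annotation error; anything
#' else (binding, phosphorylation, ...) is neutral.
#'
#' @param subtypes Character vector of KGML subtype names.
#' @return `-1L` if any of inhibition/repression is present, else `+1L` if
#'   any of activation/expression is present, else `0L`.
#' @export
#' @examples
#' relation_sign(c("phosphorylation", "activation"))
#' relation_sign("inhibition")
relation_sign <- function(subtypes) {
  s <- tolower(as.character(subtypes))
  if (any(s %in% c("inhibition", "repression"))) return(-1L)
  if (any(s %in% c("activation", "expression"))) return(1L)
  0L
}

parse_entrez_tokens <- function(name) {
  toks <- strsplit(trimws(name %||% ""), "\\s+")[[1]]
  ids <- sub("^[a-zA-Z]{2,4}:", "", toks)
  ids <- suppressWarnings(as.integer(ids))
  sort(unique(ids[!is.na(ids)]))
}

#' Parse a KEGG KGML file into a pathway graph
#'
#' Entries of type `gene` become gene nodes holding all listed Entrez ids;
#' `group` entries become group nodes whose members are the union of their
#' components' members; `compound` entries become compound nodes; `map`
#' entries (links to other pathways) carry no measurable content and are
#' dropped, as are entries of any other type. Relations referencing a dropped
#' or missing entry are discarded with a message, and duplicate relations
#' (same source, target and sign) are deduplicated.
#'
#' @param file Path to a KGML (XML) file.
#' @return A [pathway()] object.
#' @export
read_kgml <- function(file) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) abort_format(
                    paste0("Cannot parse KGML file '", file, "': ",
                           conditionMessage(e))))
  name_attr <- xml2::xml_attr(doc, "name")
  pathway_id <- if (is.na(name_attr)) "unknown" else sub("^path:", "", name_attr)
  title <- xml2::xml_attr(doc, "title")
  if (is.na(title)) title <- pathway_id

  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")

  n_map <- sum(types == "map")
  if (n_map > 0) {
    rlang::inform(sprintf("%s: dropped %d map-type entries.", pathway_id, n_map))
  }

  members <- vector("list", length(entries))
  comps <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    if (types[i] == "gene") {
      members[[i]] <- parse_entrez_tokens(names_attr[i])
    } else if (types[i] == "group") {
      comps[[i]] <- xml2::xml_attr(
        xml2::xml_find_all(entries[[i]], "./component"), "id")
    } else {
      members[[i]] <- integer(0)
    }
  }
  # resolve group members as the union of their components' members
  gene_lookup <- stats::setNames(members, ids)
  for (i in which(types == "group")) {
    kept <- intersect(comps[[i]], ids[types %in% c("gene", "group")])
    members[[i]] <- sort(unique(unlist(gene_lookup[kept])))
    comps[[i]] <- kept
  }

  keep <- (types == "gene" & lengths(members) > 0) |
    (types == "group" & lengths(members) > 0) |
    types == "compound"
  n_empty <- sum(types %in% c("gene", "group") & lengths(members) == 0)
  if (n_empty > 0) {
    rlang::inform(sprintf("%s: dropped %d gene/group entries without Entrez members.",
                          pathway_id, n_empty))
  }
  nodes <- tibble::tibble(
    node_id = ids[keep],
    kind = types[keep],
    members = members[keep],
    components = lapply(comps[keep], function(x) x %||% character(0))
  )

  rels <- xml2::xml_find_all(doc, ".//relation")
  src <- xml2::xml_attr(rels, "entry1")
  tgt <- xml2::xml_attr(rels, "entry2")
  subtypes <- lapply(rels, function(r) {
    xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
  })
  ok <- src %in% nodes$node_id & tgt %in% nodes$node_id
  if (any(!ok)) {
    rlang::inform(sprintf("%s: dropped %d relations with missing endpoints.",
                          pathway_id, sum(!ok)))
  }
  relations <- tibble::tibble(
    source = src[ok], target = tgt[ok],
    sign = vapply(subtypes[ok], relation_sign, integer(1)),
    subtypes = subtypes[ok]
  )
  relations <- relations[!duplicated(relations[c("source", "target", "sign")]), ]

  pathway(pathway_id, title, nodes, relations)
}

#' Read all KGML files in a directory
#'
#' @param dir Directory containing `.xml`/`.kgml` files.
#' @return Named list of [pathway()] objects (names = pathway ids).
#' @export
read_kgml_dir <- function(dir) {
  if (!dir.exists(dir)) abort_input(paste0("KGML directory not found: ", dir))
  files <- sort(list.files(dir, pattern = "\\.(xml|kgml)$", full.names = TRUE))
  if (length(files) == 0) abort_input(paste0("No KGML files in: ", dir))
  pws <- lapply(files, read_kgml)
  stats::setNames(pws, vapply(pws, function(p) p$pathway_id, character(1)))
}

#' Write a pathway graph as minimal KGML
#'
#' Emits well-formed KGML that [read_kgml()] round-trips to an equal pathway
#' model. Group nodes are written with their recorded component entries; a
#' group whose components have all been pruned away falls back to a gene-type
#' entry carrying the member union (its kind changes on re-parse).
#'
#' @param p A [pathway()] object.
#' @param file Output file path.
#' @return `file`, invisibly.
#' @export
write_kgml <- function(p, file) {
  stopifnot(inherits(p, "pathway"))
  doc <- xml2::xml_new_root("pathway",
                            name = paste0("path:", p$pathway_id),
                            org = substr(p$pathway_id, 1, 3),
                            title = p$name)
  for (i in seq_len(nrow(p$nodes))) {
    nd <- p$nodes[i, ]
    kind <- nd$kind
    comp <- nd$components[[1]]
    if (kind == "group" && length(comp) == 0) kind <- "gene"
    if (kind == "gene") {
      e <- xml2::xml_add_child(doc, "entry", id = nd$node_id, type = "gene",
                               name = paste(paste0("hsa:", nd$members[[1]]),
                                            collapse = " "))
    } else if (kind == "compound") {
      e <- xml2::xml_add_child(doc, "entry", id = nd$node_id, type = "compound",
                               name = paste0("cpd:", nd$node_id))
    } else {
      e <- xml2::xml_add_child(doc, "entry", id = nd$node_id, type = "group",
                               name = "undefined")
      for (cid in comp) xml2::xml_add_child(e, "component", id = cid)
    }
  }
  for (i in seq_len(nrow(p$relations))) {
    r <- p$relations[i, ]
    rel <- xml2::xml_add_child(doc, "relation", entry1 = r$source,
                               entry2 = r$target, type = "PPrel")
    sts <- r$subtypes[[1]]
    if (length(sts) == 0) {
      sts <- switch(as.character(r$sign), "-1" = "inhibition",
                    "1" = "activation", character(0))
    }
    for (st in sts) xml2::xml_add_child(rel, "subtype", name = st, value = "--")
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

pathway_graph <- function(p) {
  igraph::graph_from_data_frame(
    d = as.data.frame(p$relations[, c("source", "target")]),
    directed = TRUE,
    vertices = data.frame(name = p$nodes$node_id)
  )
}

#' Number of nodes downstream of a node
#'
#' Counts the distinct nodes (excluding the start node itself) reachable by
#' following relations in their direction, ignoring relation signs. This
#' "rough" use of topology feeds the node importance weights: nodes with
#' wide downstream reach exert feedback over more of the pathway.
#'
#' @param p A [pathway()] object.
#' @param node_id Node to start from.
#' @return Integer count of reachable nodes.
#' @export
downstream_reach <- function(p, node_id) {
  stopifnot(inherits(p, "pathway"))
  if (!node_id %in% p$nodes$node_id) {
    abort_input(paste0("Unknown node id: ", node_id))
  }
  unname(downstream_reach_all(p)[node_id])
}

downstream_reach_all <- function(p) {
  n <- nrow(p$nodes)
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  if (nrow(p$relations) == 0) {
    return(stats::setNames(integer(n), p$nodes$node_id))
  }
  g <- pathway_graph(p)
  d <- igraph::distances(g, mode = "out")
  reach <- as.integer(rowSums(is.finite(d)) - 1L)  # excludes the start node
  stats::setNames(reach, rownames(d))[p$nodes$node_id]
}

#' Fraction of inhibiting relations in a pathway
#'
#' @param p A [pathway()] object.
#' @return Proportion of relations with sign `-1`, or `NA_real_` (with a
#'   warning) when the pathway has no relations.
#' @export
inhibition_fraction <- function(p) {
  stopifnot(inherits(p, "pathway"))
  if (nrow(p$relations) == 0) {
    rlang::warn(paste0(p$pathway_id, ": no relations; inhibition fraction undefined."))
    return(NA_real_)
  }
  mean(p$relations$sign == -1L)
}

#' Randomly remove nodes or relations from a pathway
#'
#' Structural-uncertainty perturbation: removes `floor(fraction * N)` items
#' uniformly at random under the given seed. Removing a node also removes
#' every relation incident to it, and group components referencing removed
#' nodes are pruned (member genes are kept). The result is always a valid
#' pathway.
#'
#' @param p A [pathway()] object.
#' @param fraction Proportion to remove, in `[0, 0.5]`.
#' @param what `"nodes"` or `"relations"`.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return The reduced [pathway()].
#' @export
remove_random <- function(p, fraction, what = c("nodes", "relations"), seed = 1L) {
  stopifnot(inherits(p, "pathway"))
  what <- match.arg(what)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 0.5) {
    abort_input("`fraction` must be a single value in [0, 0.5].")
  }
  n_items <- if (what == "nodes") nrow(p$nodes) else nrow(p$relations)
  k <- floor(fraction * n_items)
  if (k == 0) return(p)
  idx <- withr::with_seed(seed, sample.int(n_items, k))
  if (what == "relations") {
    relations <- p$relations[-idx, , drop = FALSE]
    return(pathway(p$pathway_id, p$name, p$nodes, relations))
  }
  nodes <- p$nodes[-idx, , drop = FALSE]
  kept <- nodes$node_id
  rel <- p$relations
  rel <- rel[rel$source %in% kept & rel$target %in% kept, , drop = FALSE]
  nodes$components <- lapply(nodes$components, intersect, y = kept)
  pathway(p$pathway_id, p$name, nodes, rel)
}
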