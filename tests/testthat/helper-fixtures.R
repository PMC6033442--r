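# Fixture builders shared across test files; everything is generated in code.

# scaled matrix with explicit values; labels default to 2 case + 2 control
make_scaled <- function(values, labels = NULL, noise_threshold = NA_real_) {
  if (is.null(labels)) {
    labels <- rep(c("case", "control"), each = ncol(values) / 2)
  }
  structure(
    list(values = values,
         labels = factor(labels, levels = c("control", "case")),
         noise_threshold = noise_threshold),
    class = "scaled_mat"
  )
}

# simple gene-node pathway: one single-member gene node per entry of `genes`,
# relations given as a data frame with source/target (+ optional sign)
make_gene_pathway <- function(id, genes, rel = NULL) {
  nodes <- tibble::tibble(
    node_id = names(genes) %||% as.character(seq_along(genes)),
    kind = "gene",
    members = unname(lapply(genes, function(g) as.integer(g)))
  )
  if (is.null(rel)) {
    rel <- tibble::tibble(source = character(0), target = character(0),
                          sign = integer(0))
  } else {
    rel <- tibble::as_tibble(rel)
    if (!"sign" %in% names(rel)) rel$sign <- 1L
  }
  pathway(id, paste("Test pathway", id), nodes, rel)
}

chain_pathway <- function(id = "test01") {
  make_gene_pathway(id, stats::setNames(as.list(1:3), c("A", "B", "C")),
                    data.frame(source = c("A", "B"), target = c("B", "C")))
}

# a small simulated study used where a full synthetic cohort is overkill
small_study <- function(seed = 1, effect_size = 1.5, n_pathways = 40,
                        n_case = 8, n_control = 8) {
  simulate_study(seed = seed, effect_size = effect_size,
                 n_pathways = n_pathways, n_case = n_case,
                 n_control = n_control, n_genes_background = 100)
}

# hand-written KGML exercising genes, a group, a compound, a map entry,
# duplicate relations and a relation with a missing endpoint
write_fixture_kgml <- function(file) {
  txt <- paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:tst00001" org="tst" title="Fixture pathway">\n',
    '  <entry id="1" type="gene" name="hsa:10 hsa:20"/>\n',
    '  <entry id="2" type="gene" name="hsa:30"/>\n',
    '  <entry id="3" type="gene" name="hsa:40"/>\n',
    '  <entry id="4" type="map" name="path:tst00002"/>\n',
    '  <entry id="5" type="compound" name="cpd:C00165"/>\n',
    '  <entry id="6" type="group" name="undefined">\n',
    '    <component id="1"/>\n',
    '    <component id="2"/>\n',
    '  </entry>\n',
    '  <relation entry1="1" entry2="2" type="PPrel">\n',
    '    <subtype name="activation" value="--&gt;"/>\n',
    '  </relation>\n',
    '  <relation entry1="1" entry2="2" type="PPrel">\n',
    '    <subtype name="activation" value="--&gt;"/>\n',
    '  </relation>\n',
    '  <relation entry1="2" entry2="3" type="PPrel">\n',
    '    <subtype name="inhibition" value="--|"/>\n',
    '  </relation>\n',
    '  <relation entry1="3" entry2="4" type="maplink">\n',
    '    <subtype name="binding/association" value="---"/>\n',
    '  </relation>\n',
    '</pathway>\n')
  writeLines(txt, file)
  file
}
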