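test_that("KGML entries and relations parse into the expected graph", {
  f <- write_fixture_kgml(withr::local_tempfile(fileext = ".xml"))
  p <- suppressMessages(read_kgml(f))
  expect_s3_class(p, "pathway")
  expect_equal(p$pathway_id, "tst00001")
  # map entry dropped; 3 genes + 1 compound + 1 group remain
  expect_equal(nrow(p$nodes), 5)
  expect_equal(sum(p$nodes$kind == "gene"), 3)
  expect_equal(sum(p$nodes$kind == "compound"), 1)
  expect_equal(sum(p$nodes$kind == "group"), 1)
  # group members = union of its components' members
  grp <- p$nodes[p$nodes$kind == "group", ]
  expect_equal(grp$members[[1]], c(10L, 20L, 30L))
  # duplicate relation deduplicated, maplink to dropped entry removed
  expect_equal(nrow(p$relations), 2)
  expect_equal(p$relations$sign[p$relations$target == "3"], -1L)
  expect_equal(p$relations$sign[p$relations$target == "2"], 1L)
})

test_that("relation signs follow the inhibition > activation > neutral precedence", {
  expect_equal(relation_sign("activation"), 1L)
  expect_equal(relation_sign("expression"), 1L)
  expect_equal(relation_sign("inhibition"), -1L)
  expect_equal(relation_sign("repression"), -1L)
  expect_equal(relation_sign("binding/association"), 0L)
  expect_equal(relation_sign(character(0)), 0L)
  expect_equal(relation_sign(c("activation", "inhibition")), -1L)
  expect_equal(relation_sign(c("phosphorylation", "activation")), 1L)
})

test_that("downstream reach counts distinct reachable nodes, self excluded", {
  chain <- chain_pathway()
  expect_equal(downstream_reach(chain, "A"), 2L)
  expect_equal(downstream_reach(chain, "B"), 1L)
  expect_equal(downstream_reach(chain, "C"), 0L)

  cyc <- make_gene_pathway("cyc", list(A = 1, B = 2),
                           data.frame(source = c("A", "B"), target = c("B", "A")))
  expect_equal(downstream_reach(cyc, "A"), 1L)

  iso <- make_gene_pathway("iso", list(A = 1, B = 2),
                           data.frame(source = "A", target = "B"))
  expect_equal(downstream_reach(iso, "B"), 0L)
  expect_error(downstream_reach(iso, "Z"), class = "pathdereg_input_error")
})

test_that("downstream reach matches the transitive-closure oracle", {
  cfg <- sim_config(n_pathways = 60, nodes_per_pathway = c(3, 12),
                    relation_density = 1.6, seed = 404)
  pws <- simulate_pathways(cfg)
  for (p in pws) {
    got <- pathdereg:::downstream_reach_all(p)
    want <- vapply(p$nodes$node_id, function(nid) reach_brute(p, nid), numeric(1))
    expect_equal(unname(got), unname(want[names(got)]))
  }
})

test_that("inhibition fraction is the share of negative relations", {
  p <- make_gene_pathway("mix", as.list(stats::setNames(1:4, LETTERS[1:4])),
                         data.frame(source = c("A", "B", "C", "D"),
                                    target = c("B", "C", "D", "A"),
                                    sign = c(1L, 1L, -1L, -1L)))
  expect_equal(inhibition_fraction(p), 0.5)
  allact <- make_gene_pathway("act", list(A = 1, B = 2),
                              data.frame(source = "A", target = "B"))
  expect_equal(inhibition_fraction(allact), 0)
  none <- make_gene_pathway("none", list(A = 1))
  expect_warning(expect_true(is.na(inhibition_fraction(none))))
})

test_that("random removal respects counts, endpoints and determinism", {
  cfg <- sim_config(n_pathways = 1, nodes_per_pathway = c(10, 10),
                    relation_density = 2, seed = 17)
  p <- simulate_pathways(cfg)[[1]]

  expect_pathway_equal(remove_random(p, 0, "nodes", seed = 5), p)

  half <- remove_random(p, 0.5, "nodes", seed = 5)
  expect_equal(nrow(half$nodes), 5)
  expect_true(all(half$relations$source %in% half$nodes$node_id))
  expect_true(all(half$relations$target %in% half$nodes$node_id))

  again <- remove_random(p, 0.5, "nodes", seed = 5)
  expect_pathway_equal(half, again)

  # relation removal never increases any surviving node's reach
  r0 <- pathdereg:::downstream_reach_all(p)
  pr <- remove_random(p, 0.4, "relations", seed = 9)
  r1 <- pathdereg:::downstream_reach_all(pr)
  expect_true(all(r1 <= r0[names(r1)]))

  expect_error(remove_random(p, 0.6, "nodes"), class = "pathdereg_input_error")
})

test_that("write + parse round-trips the pathway model", {
  cfg <- sim_config(n_pathways = 12, nodes_per_pathway = c(5, 15), seed = 23)
  pws <- simulate_pathways(cfg)
  for (p in pws[1:6]) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_kgml(p, f)
    expect_pathway_equal(suppressMessages(read_kgml(f)), p)
  }
  # empty-relation pathway round-trips
  empty <- make_gene_pathway("tst00009", list(A = 5, B = 6))
  f <- withr::local_tempfile(fileext = ".xml")
  write_kgml(empty, f)
  expect_pathway_equal(suppressMessages(read_kgml(f)), empty)
})

test_that("malformed KGML raises a format error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry", f)
  expect_error(read_kgml(f), class = "pathdereg_format_error")
})
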