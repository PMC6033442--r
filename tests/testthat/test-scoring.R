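# scaled fixture with constant controls, so every reference (leave-one-out
# or not) equals the control value and hand arithmetic is exact
constant_control_scaled <- function(case_values, control_value = 0.5,
                                    genes = paste0("g", seq_len(nrow(case_values)))) {
  n_ctrl <- 3
  vals <- cbind(case_values,
                matrix(control_value, nrow(case_values), n_ctrl))
  dimnames(vals) <- list(genes,
                         c(paste0("case_", seq_len(ncol(case_values))),
                           paste0("ctrl_", seq_len(n_ctrl))))
  make_scaled(vals, c(rep("case", ncol(case_values)), rep("control", n_ctrl)))
}

test_that("node values are mean member-gene deviations from the control reference", {
  # node {g1, g2}: case scaled values (0.8, 0.6), references (0.5, 0.5)
  s <- constant_control_scaled(cbind(c(0.8, 0.6)))
  p <- make_gene_pathway("np", list(n1 = c(1, 2)))
  p$nodes$members[[1]] <- c(1L, 2L)
  rownames(s$values) <- c("1", "2")
  nv <- node_values(s, p)
  expect_equal(unname(nv$values["n1", "case_1"]), 0.2)
  # control samples sit exactly at every reference -> deviation 0
  expect_equal(unname(nv$values["n1", c("ctrl_1", "ctrl_2", "ctrl_3")]),
               rep(0, 3))
  expect_equal(nv$reference$reference, c(0.5, 0.5))
})

test_that("unmeasured and compound nodes are excluded from node values", {
  s <- constant_control_scaled(cbind(c(0.9, 0.1)), genes = c("1", "2"))
  nodes <- tibble::tibble(
    node_id = c("a", "b", "c"),
    kind = c("gene", "gene", "compound"),
    members = list(1L, 99L, integer(0)))   # 99 absent from the matrix
  p <- pathway("ex", "exclusion", nodes,
               tibble::tibble(source = character(0), target = character(0),
                              sign = integer(0)))
  nv <- node_values(s, p)
  expect_equal(nv$node_ids, "a")

  # no measured node at all -> flagged unscorable
  p2 <- pathway("ex2", "none", nodes[2:3, ],
                tibble::tibble(source = character(0), target = character(0),
                               sign = integer(0)))
  nv2 <- node_values(s, p2)
  expect_true(nv2$unscorable)
  expect_equal(nrow(nv2$values), 0)
})

test_that("importance weights are 1 + normalized downstream reach", {
  chain <- chain_pathway()
  w <- node_importance(chain, c("A", "B", "C"))
  expect_equal(unname(w), c(2, 1.5, 1))

  star <- make_gene_pathway("star", as.list(stats::setNames(1:4, c("H", "L1", "L2", "L3"))),
                            data.frame(source = "H", target = c("L1", "L2", "L3")))
  w2 <- node_importance(star, c("H", "L1", "L2", "L3"))
  expect_equal(unname(w2), c(2, 1, 1, 1))

  norel <- make_gene_pathway("flat", list(A = 1, B = 2))
  expect_equal(unname(node_importance(norel, c("A", "B"))), c(1, 1))
  expect_error(node_importance(chain, character(0)),
               class = "pathdereg_input_error")
})

test_that("pathway scores are weighted means of node values", {
  nv <- structure(list(
    pathway_id = "x", node_ids = c("a", "b", "c"),
    values = matrix(c(0.2, 0.4, 0.6), 3, 1,
                    dimnames = list(c("a", "b", "c"), "s1")),
    unscorable = FALSE), class = "node_values")
  w <- c(a = 2, b = 1.5, c = 1)
  expect_equal(unname(pathway_score(nv, w)), (0.4 + 0.6 + 0.6) / 4.5)

  # all zero -> 0; uniform node values -> that value regardless of weights
  nv$values[] <- 0
  expect_equal(unname(pathway_score(nv, w)), 0)
  nv$values[] <- 0.37
  expect_equal(unname(pathway_score(nv, w)), 0.37)
  expect_equal(unname(pathway_score(nv, c(a = 1, b = 1, c = 1))), 0.37)
})

test_that("score_pathways filters small pathways and keeps sample shape", {
  st <- small_study(seed = 31)
  s <- scale_genes(filter_noise(st$expression))
  small <- make_gene_pathway("tiny01", list(A = 1000, B = 1001))
  pws <- c(st$pathways[1:3], list(tiny01 = small))
  expect_message(ps <- score_pathways(s, pws, min_nodes = 5), "Skipped")
  expect_false("tiny01" %in% rownames(ps$scores))
  expect_equal(ncol(ps$scores), ncol(s$values))
  expect_true(all(ps$scores >= 0 & ps$scores <= 1))

  # duplicated pathway gives identical score rows
  dup <- st$pathways[[1]]
  dup$pathway_id <- "dup0001"
  ps2 <- suppressMessages(score_pathways(s, c(st$pathways[1:3], list(dup0001 = dup))))
  expect_equal(unname(ps2$scores["dup0001", ]),
               unname(ps2$scores[st$pathways[[1]]$pathway_id, ]))

  expect_error(suppressMessages(score_pathways(s, list(small), min_nodes = 5)),
               class = "pathdereg_input_error")
})

test_that("a sample equal to the control reference scores zero everywhere", {
  # constant controls; one case pinned to the control value, one deviating
  vals <- cbind(case_1 = rep(0.4, 6), case_2 = runif(6),
                ctrl_1 = rep(0.4, 6), ctrl_2 = rep(0.4, 6), ctrl_3 = rep(0.4, 6))
  rownames(vals) <- as.character(1:6)
  s <- make_scaled(vals, c("case", "case", "control", "control", "control"))
  p <- make_gene_pathway("ref0", as.list(stats::setNames(1:6, paste0("n", 1:6))))
  ps <- score_pathways(s, list(p), min_nodes = 5)
  expect_equal(unname(ps$scores[, "case_1"]), 0)
  expect_equal(unname(ps$scores[, "ctrl_1"]), 0)
})

test_that("scores are invariant to sample order and pathway order", {
  st <- small_study(seed = 8, n_pathways = 12)
  s <- scale_genes(filter_noise(st$expression))
  ps <- suppressMessages(score_pathways(s, st$pathways))

  perm <- sample(ncol(s$values))
  s_perm <- make_scaled(s$values[, perm], as.character(s$labels)[perm])
  ps_perm <- suppressMessages(score_pathways(s_perm, st$pathways))
  expect_equal(ps_perm$scores, ps$scores[, perm])

  ps_shuffled <- suppressMessages(score_pathways(s, rev(st$pathways)))
  expect_equal(ps_shuffled$scores[rownames(ps$scores), ], ps$scores)
})

test_that("pathways are ranked by absolute median score difference", {
  scores <- rbind(
    pwA = c(0.6, 0.6, 0.6, 0.2, 0.2, 0.2),
    pwB = c(0.3, 0.3, 0.3, 0.2, 0.2, 0.2),
    pwC = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25))
  colnames(scores) <- paste0("s", 1:6)
  ps <- structure(list(
    scores = scores,
    labels = factor(rep(c("case", "control"), each = 3),
                    levels = c("control", "case")),
    info = tibble::tibble(pathway_id = c("pwA", "pwB", "pwC"),
                          name = c("A", "B", "C"), n_nodes = c(5L, 5L, 5L)),
    skipped = character(0)), class = "pathway_scores")
  rk <- rank_pathways(ps)
  expect_equal(rk$pathway_id, c("pwA", "pwB", "pwC"))
  expect_equal(rk$median_diff, c(0.4, 0.1, 0))
  expect_equal(rk$rank, 1:3)

  # identical distributions -> all diffs 0, lexicographic order
  ps$scores[] <- 0.5
  rk0 <- rank_pathways(ps)
  expect_equal(rk0$pathway_id, sort(rk0$pathway_id))
  expect_equal(rk0$median_diff, rep(0, 3))

  ps$labels <- factor(rep("case", 6), levels = c("control", "case"))
  expect_error(rank_pathways(ps), class = "pathdereg_input_error")
})

test_that("tidy and glance summarise score objects", {
  st <- small_study(seed = 5, n_pathways = 10)
  s <- scale_genes(filter_noise(st$expression))
  ps <- suppressMessages(score_pathways(s, st$pathways))
  td <- tidy(ps)
  expect_equal(nrow(td), nrow(ps$scores) * ncol(ps$scores))
  expect_setequal(names(td), c("pathway_id", "sample_id", "score", "label"))
  gl <- glance(ps)
  expect_equal(gl$n_pathways, nrow(ps$scores))
  expect_equal(gl$n_case + gl$n_control, ncol(ps$scores))
})
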