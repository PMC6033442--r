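# Independent oracles used to cross-check the implementation.

# exhaustive enumeration of the two-sided rank-sum p-value over all
# C(m+n, m) group assignments (tie-free inputs)
enum_wilcox_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p <- if (u_obs > m * n / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# brute-force Benjamini-Hochberg step-up: adj_(i) = min over j >= i of
# p_(j) * m / j, clipped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# transitive closure by the Floyd-Warshall scheme; self excluded
reach_brute <- function(p, node_id) {
  ids <- p$nodes$node_id
  k_n <- length(ids)
  adj <- matrix(FALSE, k_n, k_n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(p$relations))) {
    adj[p$relations$source[k], p$relations$target[k]] <- TRUE
  }
  for (k in ids) {
    hits <- adj[, k]
    if (any(hits)) adj[hits, ] <- adj[hits, , drop = FALSE] | rep(adj[k, ], each = sum(hits))
  }
  sum(adj[node_id, setdiff(ids, node_id)])
}

expect_pathway_equal <- function(a, b) {
  expect_equal(a$pathway_id, b$pathway_id)
  oa <- order(a$nodes$node_id)
  ob <- order(b$nodes$node_id)
  expect_equal(a$nodes$node_id[oa], b$nodes$node_id[ob])
  expect_equal(a$nodes$kind[oa], b$nodes$kind[ob])
  expect_equal(lapply(a$nodes$members[oa], as.integer),
               lapply(b$nodes$members[ob], as.integer))
  ra <- a$relations[order(a$relations$source, a$relations$target, a$relations$sign),
                    c("source", "target", "sign")]
  rb <- b$relations[order(b$relations$source, b$relations$target, b$relations$sign),
                    c("source", "target", "sign")]
  expect_equal(as.data.frame(ra), as.data.frame(rb))
}
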