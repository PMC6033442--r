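write_expr_fixture <- function(dir, values, probes, samples) {
  tab <- data.frame(probe_id = probes, values, check.names = FALSE)
  colnames(tab) <- c("probe_id", samples)
  path <- file.path(dir, "expr.tsv")
  readr::write_tsv(tab, path, progress = FALSE)
  path
}

test_that("probes mapping to one gene are collapsed by their mean", {
  dir <- withr::local_tempdir()
  # two probes for Entrez 100 with values 10 and 20 -> 15; one probe for 200
  vals <- rbind(c(10, 10, 10, 10), c(20, 20, 20, 20), c(5, 6, 7, 8))
  path <- write_expr_fixture(dir, vals, c("p1", "p2", "p3"),
                             c("s1", "s2", "s3", "s4"))
  mapping <- data.frame(source_id = c("p1", "p2", "p3"),
                        entrez = c(100, 100, 200))
  labels <- c(s1 = "case", s2 = "case", s3 = "control", s4 = "control")
  m <- suppressWarnings(read_expression(path, mapping, labels))
  expect_setequal(rownames(m$values), c("100", "200"))
  expect_equal(unname(m$values["100", ]), rep(15, 4))
  expect_equal(unname(m$values["200", ]), c(5, 6, 7, 8))
})

test_that("log2 input is converted back to linear scale", {
  dir <- withr::local_tempdir()
  path <- write_expr_fixture(dir, rbind(c(1, 2, 3, 4)), "p1",
                             paste0("s", 1:4))
  mapping <- data.frame(source_id = "p1", entrez = 1)
  labels <- stats::setNames(c("case", "case", "control", "control"),
                            paste0("s", 1:4))
  m <- suppressWarnings(read_expression(path, mapping, labels, is_log = TRUE))
  expect_equal(unname(m$values["1", ]), c(2, 4, 8, 16))
})

test_that("a small cohort loads with all samples and warns about few controls", {
  dir <- withr::local_tempdir()
  set.seed(7)
  n <- 24  # 13 cases + 11 controls
  vals <- matrix(runif(10 * n, 1, 100), 10, n)
  probes <- paste0("p", 1:10)
  samples <- paste0("s", 1:n)
  path <- write_expr_fixture(dir, vals, probes, samples)
  mapping <- data.frame(source_id = probes, entrez = 1:10)
  labels <- stats::setNames(rep(c("case", "control"), c(13, 11)), samples)
  expect_warning(m <- read_expression(path, mapping, labels),
                 "control samples")
  expect_equal(ncol(m$values), 24)
  expect_equal(sum(m$labels == "case"), 13)
})

test_that("unmapped probes are dropped and degenerate inputs error", {
  dir <- withr::local_tempdir()
  vals <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  path <- write_expr_fixture(dir, vals, c("p1", "px"), paste0("s", 1:4))
  mapping <- data.frame(source_id = "p1", entrez = 1)
  labels <- stats::setNames(c("case", "case", "control", "control"),
                            paste0("s", 1:4))
  expect_message(
    suppressWarnings(m <- read_expression(path, mapping, labels)),
    "Dropped 1")
  expect_equal(rownames(m$values), "1")

  # no overlap between matrix ids and mapping
  mapping_bad <- data.frame(source_id = "nope", entrez = 9)
  expect_error(suppressWarnings(read_expression(path, mapping_bad, labels)),
               class = "pathdereg_input_error")

  # fewer than 2 samples in a group
  labels_bad <- stats::setNames(c("case", "control", "control", "control"),
                                paste0("s", 1:4))
  expect_error(suppressWarnings(read_expression(path, mapping, labels_bad)),
               class = "pathdereg_input_error")

  # malformed (non-numeric) table
  bad_path <- file.path(dir, "bad.tsv")
  writeLines(c("probe_id\ts1\ts2\ts3", "p1\t1\tx\t3"), bad_path)
  expect_error(read_expression(bad_path, mapping, labels),
               class = "pathdereg_format_error")
})

test_that("noise filtering floors values at the nearest-rank quantile", {
  vals <- matrix(sample(1:100), 25, 4,
                 dimnames = list(paste0("g", 1:25), paste0("s", 1:4)))
  m <- expr_matrix(vals, c("case", "case", "control", "control"))
  f <- filter_noise(m, q = 0.05)
  expect_equal(f$noise_threshold, 5)       # 5th smallest of 1..100
  expect_equal(min(f$values), 5)
  expect_true(all(f$values[vals >= 5] == vals[vals >= 5]))

  # q = 0 leaves the matrix unchanged; constant matrices always unchanged
  expect_equal(filter_noise(m, q = 0)$values, vals)
  const <- expr_matrix(
    matrix(7, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
    c("case", "case", "control", "control"))
  expect_equal(filter_noise(const, 0.3)$values, const$values)

  # idempotence
  expect_equal(filter_noise(f, q = 0.05)$values, f$values)
  expect_error(filter_noise(m, q = 1), class = "pathdereg_input_error")
})

test_that("per-gene scaling maps to [0,1] with the degenerate-range rule", {
  vals <- rbind(g1 = c(10, 20, 30, 40),
                g2 = c(7, 7, 7, 7),
                g3 = c(2, 4, 4, 10))
  colnames(vals) <- paste0("s", 1:4)
  m <- expr_matrix(vals, c("case", "case", "control", "control"))
  s <- scale_genes(m)
  expect_equal(unname(s$values["g1", ]), c(0, 1/3, 2/3, 1))
  expect_equal(unname(s$values["g2", ]), rep(0.5, 4))
  expect_equal(unname(s$values["g3", ]), c(0, 0.25, 0.25, 1))
  expect_true(all(s$values >= 0 & s$values <= 1))
})

test_that("scaling is invariant to positive affine transforms and column order", {
  set.seed(11)
  vals <- matrix(runif(40, 1, 50), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  labels <- c("case", "case", "control", "control")
  s0 <- scale_genes(expr_matrix(vals, labels))
  s1 <- scale_genes(expr_matrix(3.7 * vals + 2, labels))
  expect_equal(s0$values, s1$values)

  perm <- c(3, 1, 4, 2)
  sp <- scale_genes(expr_matrix(vals[, perm], labels[perm]))
  expect_equal(sp$values, s0$values[, perm])
})

test_that("the prep pipeline preserves index sets apart from logged drops", {
  dir <- withr::local_tempdir()
  set.seed(3)
  vals <- matrix(runif(20, 1, 100), 5, 4)
  path <- write_expr_fixture(dir, vals, paste0("p", 1:5), paste0("s", 1:4))
  mapping <- data.frame(source_id = paste0("p", 1:5), entrez = 11:15)
  labels <- stats::setNames(c("case", "case", "control", "control"),
                            paste0("s", 1:4))
  m <- suppressWarnings(read_expression(path, mapping, labels))
  s <- scale_genes(filter_noise(m, 0.05))
  expect_setequal(rownames(s$values), as.character(11:15))
  expect_equal(colnames(s$values), paste0("s", 1:4))
})
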