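test_that("expression files round-trip through write and read in both orientations", {
  vals <- matrix(c(1.5, 0, 2.25, 3, 4.125, 5), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  M <- expression_matrix(vals, stage = "log")
  f <- tempfile(fileext = ".tsv")
  write_expression(M, f)
  back <- read_expression(f, stage = "log")
  expect_identical(rownames(back), rownames(M))
  expect_identical(colnames(back), colnames(M))
  expect_identical(unclass(back)[, ], unclass(M)[, ])

  # transposed storage with the orientation flag recovers the same matrix
  ft <- tempfile(fileext = ".tsv")
  dft <- data.frame(gene_id = colnames(M), t(unclass(M)), check.names = FALSE)
  write.table(dft, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_expression(ft, orientation = "genes_by_samples", stage = "log")
  expect_equal(unclass(back_t)[, ], unclass(M)[, ])
})

test_that("malformed expression files are rejected with informative errors", {
  f <- tempfile()
  writeLines(c("id\tgA\tgA", "s1\t1\t2", "s2\t3\t4"), f)
  expect_error(read_expression(f), "gA")
  writeLines(c("id\tgA\tgB", "s1\t1\toops", "s2\t3\t4"), f)
  expect_error(read_expression(f), "row 1, column 2")
  writeLines(c("id\tgA\tgB", "s1\t1", "s2\t3\t4"), f)
  expect_error(read_expression(f), "ragged")
  writeLines(c("id\tgA\tgB", "s1\t1\t2", "s1\t3\t4"), f)
  expect_error(read_expression(f), "s1")
})

test_that("TPM normalization matches hand-computed rates and forces row totals", {
  # single gene: whatever the count, the one gene holds the full million
  one <- expression_matrix(matrix(7, 1, 1, dimnames = list("s", "g")), stage = "counts")
  expect_equal(as.numeric(normalize_tpm(one, c(g = 500))), 1e6)

  # counts (10, 10), lengths (1000, 2000): rates 0.01 and 0.005 -> 2:1 split
  two <- expression_matrix(matrix(c(10, 10), 1, 2,
                                  dimnames = list("s", c("g1", "g2"))),
                           stage = "counts")
  tpm <- normalize_tpm(two, c(g1 = 1000, g2 = 2000))
  expect_equal(as.numeric(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  # all-zero sample stays all-zero, warned, no NaN
  z <- expression_matrix(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE,
                                dimnames = list(c("s1", "s2"), c("g1", "g2"))),
                         stage = "counts")
  expect_warning(ztpm <- normalize_tpm(z, c(g1 = 100, g2 = 100)), "all-zero")
  expect_equal(as.numeric(unclass(ztpm)["s1", ]), c(0, 0))
  expect_false(any(is.nan(ztpm)))

  expect_error(normalize_tpm(two, c(g1 = 1000)), "g2")
})

test_that("TPM rows sum to 1e6 for random count matrices across seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6; d <- 40
    counts <- matrix(rpois(n * d, lambda = 30), n, d,
                     dimnames = list(paste0("s", 1:n), paste0("g", 1:d)))
    lens <- runif(d, 200, 5000); names(lens) <- colnames(counts)
    tpm <- normalize_tpm(expression_matrix(counts, stage = "counts"), lens)
    expect_equal(rowSums(tpm), setNames(rep(1e6, n), rownames(counts)),
                 tolerance = 1e-6)
  }
})

test_that("log transform applies log2(x+1) and preserves within-sample ordering", {
  tpm_vals <- matrix(c(0, 1, 3, 999996), 1, 4,
                     dimnames = list("s", paste0("g", 1:4)))
  tpm <- expression_matrix(tpm_vals, stage = "tpm")
  lg <- log_transform(tpm)
  expect_equal(as.numeric(lg)[1:3], c(0, 1, 2))
  expect_identical(attr(lg, "stage"), "log")

  set.seed(1)
  v <- runif(50)
  v <- v / sum(v) * 1e6
  row <- expression_matrix(matrix(v, 1, dimnames = list("s", paste0("g", seq_along(v)))),
                           stage = "tpm")
  expect_identical(order(as.numeric(log_transform(row))), order(v))

  expect_error(log_transform(lg), "stage 'tpm'")
})

test_that("label vectors validate membership and designate a positive class", {
  y <- label_vector(c("a", "b", "a"), positive_class = "b")
  expect_identical(levels(y), c("a", "b"))
  expect_identical(attr(y, "positive_class"), "b")
  expect_error(label_vector(c("a", "b"), label_set = c("a", "b"), positive_class = "c"), "positive_class")
  expect_error(label_vector(c("a", "x"), label_set = c("a", "b")), "x")
  expect_error(label_vector(c("a", "a")), "at least 2")
})
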