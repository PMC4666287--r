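test_that("count matrices round-trip through files in both dialects", {
  for (seed in 1:10) {
    for (dialect in c("tsv", "csv")) {
      cm <- make_counts(m = sample(1:8, 1), n = sample(2:6, 1), seed = seed)
      f <- withr::local_tempfile(fileext = paste0(".", dialect))
      write_counts(cm, f, dialect)
      back <- read_counts(f, dialect)
      expect_identical(back, cm)
    }
  }
})

test_that("malformed count files are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "g1\t2.5\t3", "g2\t1\t1"), f)
  expect_error(read_counts(f), "non-negative integers.*g1.*s1")
  writeLines(c("gene\ts1\ts2", "g1\t-2\t3", "g2\t1\t1"), f)
  expect_error(read_counts(f), "non-negative integers")
  writeLines(c("gene\ts1\ts2", "g1\t2\t3", "g1\t1\t1"), f)
  expect_error(read_counts(f), "duplicate gene ids")
  writeLines(c("gene\ts1\ts1", "g1\t2\t3", "g2\t1\t1"), f)
  expect_error(read_counts(f), "duplicate sample ids")
})

test_that("covariate reading types variables, realigns rows, rejects degenerate columns", {
  csv <- withr::local_tempfile(fileext = ".csv")
  cfgf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("id,Line,Block,RIN",
               "s3,L,b2,7.1", "s1,H,b1,6.5", "s2,L,b1,8.0", "s4,H,b2,7.7"),
             csv)
  writeLines(c("primary: Line",
               "variables:",
               "  - {name: Line, type: categorical, levels: [H, L]}",
               "  - {name: Block, type: categorical}",
               "  - {name: RIN, type: continuous}"), cfgf)
  ct <- read_covariates(csv, cfgf, sample_ids = c("s1", "s2", "s3", "s4"))
  expect_s3_class(ct, "covariate_table")
  expect_identical(ct$sample_ids, c("s1", "s2", "s3", "s4"))
  expect_identical(ct$var_names[1], "Line")          # primary first
  expect_identical(levels(ct$data$Line), c("H", "L")) # declared order
  expect_identical(as.character(ct$data$Line),
                   c("H", "L", "L", "H"))             # realigned by id
  expect_identical(ct$var_types, c("categorical", "categorical", "continuous"))

  # missing sample
  expect_error(read_covariates(csv, cfgf, sample_ids = c("s1", "s9")),
               "missing samples.*s9")
  # constant column
  writeLines(c("id,Line,Flat", "s1,H,1", "s2,L,1", "s3,L,1"), csv)
  expect_error(read_covariates(csv, list(primary = "Line")), "constant")
  # one observed level in a categorical
  df <- data.frame(grp = c("A", "A", "A", "B"), b = c("x", "x", "x", "x"),
                   row.names = paste0("s", 1:4))
  expect_error(covariate_table(df, "grp"), "fewer than 2 observed levels")
})

test_that("undeclared numeric variables default to continuous with a message", {
  df <- data.frame(grp = rep(c("A", "B"), 3), v = rnorm(6),
                   row.names = paste0("s", 1:6))
  expect_message(covariate_table(df, "grp"), "no declared type")
})

test_that("gene filtering applies both predicates, preserves order, is idempotent", {
  # means (0, 7.9, 8, 100, 8); zero fractions (1, 0, 0, 0, 0.9)
  n <- 10
  cm <- rbind(g1 = rep(0L, n),
              g2 = c(7L, rep(8L, 9)),  # mean 7.9
              g3 = rep(8L, n),
              g4 = rep(100L, n),
              g5 = c(rep(0L, 9), 80L))
  colnames(cm) <- paste0("s", 1:n)
  stopifnot(rowMeans(cm) == c(0, 7.9, 8, 100, 8))
  kept <- filter_genes(cm, min_mean = 8, max_zero_frac = 0.87)
  expect_identical(rownames(kept), c("g3", "g4"))
  expect_identical(filter_genes(kept, 8, 0.87), kept)  # idempotent
  # all-zero gene removed for any positive mean threshold
  expect_false("g1" %in% rownames(filter_genes(cm, 1e-9, 1)))
  expect_error(filter_genes(cm, min_mean = 1000), "all genes removed")
})

test_that("offsets are log upper quantiles, permutation invariant, match a direct order-statistic computation", {
  cm <- matrix(8L, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(compute_offsets(cm)), rep(log(8), 2))

  # permuted columns give equal offsets
  x <- rpois(50, 30) + 1L
  cm2 <- cbind(a = x, b = sample(x))
  rownames(cm2) <- paste0("g", 1:50)
  o <- compute_offsets(cm2)
  expect_equal(o[["a"]], o[["b"]])

  # type-7 oracle on 1..100: position 1 + 0.75 * 99 = 75.25
  cm3 <- cbind(a = sample(1:100), b = rep(10L, 100))
  rownames(cm3) <- paste0("g", 1:100)
  s <- sort(cm3[, "a"])
  oracle <- unname(s[75] + 0.25 * (s[76] - s[75]))
  expect_equal(compute_offsets(cm3)[["a"]], log(oracle))

  # zero quantile errors
  cm4 <- matrix(c(0L, 0L, 0L, 1L, 5L, 6L), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_error(compute_offsets(cm4), "stronger gene filtering")
})

test_that("design matrices code variables independently of companions", {
  ct <- make_ct(12)
  dm_full <- design_matrix(ct, 1:4)
  expect_equal(ncol(dm_full$matrix), 1 + 1 + 1 + 2 + 1)
  expect_equal(length(dm_full$blocks[["3"]]), 2)  # 3-level blk
  expect_equal(unname(dm_full$matrix[, dm_full$blocks[["1"]]]),
               as.numeric(ct$data$grp == "B"))     # reference coding

  dm_min <- design_matrix(ct, 1)
  expect_equal(ncol(dm_min$matrix), 2)
  # variable 1's columns identical whatever else is present
  expect_equal(dm_full$matrix[, dm_full$blocks[["1"]]],
               dm_min$matrix[, dm_min$blocks[["1"]]])
  for (S in list(c(1, 2), c(1, 2, 3), c(1, 3, 4))) {
    dm <- design_matrix(ct, S)
    expect_equal(dm$matrix[, dm$blocks[["1"]]],
                 dm_min$matrix[, dm_min$blocks[["1"]]])
  }
  expect_error(design_matrix(ct, 2:3), "primary")

  # rank deficiency names the dependent columns
  df <- data.frame(grp = rep(c("A", "B"), 4), x = 1:8, y = 2 * (1:8),
                   row.names = paste0("s", 1:8))
  ct2 <- covariate_table(df, "grp",
                         types = c(x = "continuous", y = "continuous"))
  expect_error(design_matrix(ct2, 1:3), "rank deficient.*y")
})
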