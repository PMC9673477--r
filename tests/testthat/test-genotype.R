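test_that("minor allele frequency matches hand computations", {
  G <- gs_genotypes(cbind(c(0, 0, 0, 2), c(0, 0, 0, 0), c(1, 2, 0, 1)))
  expect_equal(unname(compute_maf(G)), c(0.25, 0, 0.5))
  expect_true(all(compute_maf(G) >= 0 & compute_maf(G) <= 0.5))
})

test_that("MAF filter keeps the boundary, preserves order, and is idempotent", {
  # columns with MAF 0.05, 0.10, 0.25 at n = 10 (homozygous counts 1/2/5... use allele sums)
  V <- cbind(c(1, rep(0, 9)),                 # p = 1/20 = 0.05
             c(2, rep(0, 9)),                 # p = 0.10
             c(2, 2, 1, rep(0, 7)))           # p = 5/20 = 0.25
  G <- gs_genotypes(V)
  kept <- filter_maf(G, 0.10)
  expect_equal(kept$marker_ids, G$marker_ids[2:3])
  expect_identical(filter_maf(G, 0)$values, G$values)
  expect_identical(filter_maf(kept, 0.10)$values, kept$values)
  expect_error(filter_maf(G, 0.49), "removed all markers")
})

test_that("MAF filter agrees with a brute-force per-column oracle", {
  G <- toy_genotypes(30, 50, seed = 7)
  thr <- 0.2
  oracle_keep <- vapply(seq_len(50), function(j) {
    p <- sum(G$values[, j]) / (2 * 30)
    min(p, 1 - p) >= thr
  }, TRUE)
  expect_equal(filter_maf(G, thr)$marker_ids, G$marker_ids[oracle_keep])
})

test_that("duplicate-marker filter keeps first occurrences, matches O(m^2) oracle", {
  set.seed(3)
  base <- matrix(sample(0:2, 18 * 10, replace = TRUE), 18, 10)
  # plant duplicate triples: columns 11-13 copy 1, 14-15 copy 5
  V <- cbind(base, base[, 1], base[, 1], base[, 1], base[, 5], base[, 5])
  G <- gs_genotypes(V)
  out <- filter_duplicates(G)
  # oracle: pairwise comparison, keep first of each identical set
  m <- ncol(V)
  keep <- rep(TRUE, m)
  for (j in 2:m) for (i in 1:(j - 1))
    if (keep[j] && all(V[, i] == V[, j])) keep[j] <- FALSE
  expect_equal(out$marker_ids, G$marker_ids[keep])
  # identity on a duplicate-free matrix
  G2 <- out
  expect_identical(filter_duplicates(G2)$values, G2$values)
})

test_that("encodings satisfy their invariants and round-trip", {
  G <- toy_genotypes(12, 6, seed = 9)
  e0 <- encode_genotypes(G, "additive012")
  expect_equal(e0$values, G$values + 0.0, ignore_attr = TRUE)
  ec <- encode_genotypes(G, "additive_centered")
  expect_equal(ec$values, G$values - 1.0, ignore_attr = TRUE)
  expect_equal(encode_genotypes(
    gs_genotypes(matrix(c(0, 1, 2), 3, 1)), "additive_centered")$values[, 1],
    c(-1, 0, 1), ignore_attr = TRUE)
  oh <- encode_genotypes(G, "onehot")
  expect_true(all(rowSums(oh$values) == ncol(G$values)))
  # single marker with two observed states -> two indicator columns
  oh1 <- encode_genotypes(gs_genotypes(matrix(c(0, 2, 0), 3, 1)), "onehot")
  expect_equal(ncol(oh1$values), 2)
  # round trip
  back <- decode_onehot(oh)
  expect_equal(back$values, G$values, ignore_attr = TRUE)
  expect_error(encode_genotypes(G, "dosage"), "arg")
  # row counts preserved by all schemes
  for (s in c("additive012", "additive_centered", "onehot"))
    expect_equal(nrow(encode_genotypes(G, s)$values), 12)
})

test_that("synthetic panels respect the MAF window and are seed-reproducible", {
  G1 <- generate_genotypes(200, 300, maf_low = 0.10, seed = 1)
  G2 <- generate_genotypes(200, 300, maf_low = 0.10, seed = 1)
  G3 <- generate_genotypes(200, 300, maf_low = 0.10, seed = 2)
  expect_identical(G1$values, G2$values)
  expect_false(identical(G1$values, G3$values))
  expect_true(all(compute_maf(G1) > 0.10))
  expect_true(all(G1$values %in% c(0L, 2L)))      # inbred-like default
  expect_equal(dim(G1), c(200, 300))
  # no duplicated columns by construction
  expect_equal(ncol(filter_duplicates(G1)$values), 300)
  # heterozygous calls appear when homozygous_only is off
  Gh <- generate_genotypes(200, 50, homozygous_only = FALSE, seed = 4)
  expect_true(any(Gh$values == 1L))
  expect_true(all(compute_maf(Gh) > 0.10))
})

test_that("a tight MAF window at tiny n forces the single representable count", {
  # homozygous, n = 4: MAF in (0.2, 0.25] admits exactly one minor homozygote
  G <- generate_genotypes(4, 1, maf_low = 0.2, maf_high = 0.25, seed = 1)
  expect_equal(sum(G$values == 2L), 1)
  expect_equal(sum(G$values == 0L), 3)
  # infeasible: smallest nonzero MAF (1/4) above maf_high
  expect_error(generate_genotypes(4, 1, maf_low = 0.1, maf_high = 0.2),
               "representable")
})

test_that("LD blocks raise within-block correlation above between-block", {
  G <- generate_genotypes(500, 50, ld_block_size = 10, ld_rho = 0.8, seed = 7)
  C <- abs(stats::cor(G$values))
  blk <- rep(1:5, each = 10)
  within <- C[outer(blk, blk, `==`) & upper.tri(C)]
  between <- C[outer(blk, blk, `!=`) & upper.tri(C)]
  expect_gt(mean(within), mean(between) + 0.2)
})

test_that("genotype tables round-trip and malformed cells are located", {
  G <- toy_genotypes(5, 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(G, path)
  back <- read_genotype_table(path)
  expect_identical(back$values, G$values)
  expect_identical(back$sample_ids, G$sample_ids)

  # corrupt one cell -> error cites sample and marker
  lines <- readLines(path)
  lines[3] <- sub("[0-2]$", "3", lines[3])
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_genotype_table(bad), "invalid genotype value '3'.*S2")

  # duplicated marker id in the header
  lines <- readLines(path)
  lines[1] <- sub("M2", "M1", lines[1])
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, dup)
  expect_error(read_genotype_table(dup), "duplicated marker id.*M1")
})

test_that("phenotype tables round-trip", {
  y <- stats::setNames(rnorm(6), paste0("S", 1:6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(y, path)
  expect_equal(read_phenotype_table(path), y)
})

test_that("the container rejects malformed input", {
  expect_error(gs_genotypes(matrix(c(0, 3), 2, 1)), "not in \\{0,1,2\\}")
  expect_error(gs_genotypes(matrix(0L, 2, 2), sample_ids = c("a", "a")),
               "duplicate sample id")
  expect_error(gs_genotypes(matrix(0L, 2, 2), marker_ids = c("m", "m")),
               "duplicate marker id")
  expect_error(gs_genotypes(matrix(c(0L, NA), 2, 1)), "missing")
})
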