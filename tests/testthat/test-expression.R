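# Count normalization, DE-table logic, ddCt and ortholog concordance.

counts_fixture <- function(n = 200, libs = 4, seed = 5) {
  set.seed(seed)
  m <- matrix(rnbinom(n * libs, mu = 80, size = 3), n, libs,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("L%d", 1:libs)))
  m
}

test_that("CPM matches hand arithmetic and columns sum to 1e6", {
  m <- matrix(c(5, 1e6 - 5, 12, 4e6 - 12), 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  x <- cpm(m)
  expect_equal(x["a", "L1"], 5)
  expect_equal(x["a", "L2"], 3)
  expect_equal(unname(colSums(cpm(counts_fixture()))), rep(1e6, 4))
  # log2 with prior on a zero count
  z <- matrix(c(0, 1e6), 2, 1, dimnames = list(c("a", "b"), "L1"))
  expect_equal(cpm(z, log2 = TRUE, prior = 0.5)["a", 1], -1)
  expect_error(cpm(matrix(0, 2, 1)), "zero size")
})

test_that("expression filter applies the CPM >= 0.5 in >= 2 libraries rule", {
  # library sizes of 1e6 make CPM equal the count scaled by 1
  base <- matrix(1e6 / 4, 4, 4, dimnames = list(paste0("f", 1:4), paste0("L", 1:4)))
  m <- rbind(base,
             zero = c(0, 0, 0, 0),
             two_libs = c(0.6, 0.6, 0, 0),
             one_lib = c(0.6, 0, 0, 0))
  kept <- rownames(filter_expressed(m, 0.5, 2))
  expect_false("zero" %in% kept)
  expect_true("two_libs" %in% kept)
  expect_false("one_lib" %in% kept)
})

test_that("expression filter is idempotent and preserves library order", {
  m <- counts_fixture()
  m[1:20, ] <- 0
  f1 <- filter_expressed(m)
  f2 <- filter_expressed(f1)
  expect_identical(f1, f2)
  expect_identical(colnames(f1), colnames(m))
})

test_that("TMM factors are exactly 1 for entrywise-proportional libraries", {
  x <- counts_fixture(300, 1)[, 1]
  m <- cbind(L1 = x, L2 = 2L * x, L3 = 3L * x, L4 = 7L * x)
  f <- tmm_factors(m)
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)
})

test_that("TMM factors have geometric mean 1 and are label-invariant", {
  set.seed(42)
  for (i in 1:5) {
    m <- counts_fixture(250, 5, seed = i)
    m[, 2] <- m[, 2] * rbinom(250, 1, 0.9) * 3  # perturb one library
    f <- tmm_factors(m)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    perm <- sample(5)
    expect_equal(unname(tmm_factors(m[, perm])), unname(f[perm]), tolerance = 1e-10)
  }
})

test_that("TMM estimator agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(99)
  for (i in 1:3) {
    m <- counts_fixture(400, 4, seed = 100 + i)
    m[sample(400, 60), 2] <- 0
    ours <- tmm_factors(m)
    ref <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(ours), unname(ref), tolerance = 0.02)
  }
})

test_that("RPKM matches hand arithmetic and halves when length doubles", {
  m <- matrix(c(10, 1e6 - 10), 2, 1, dimnames = list(c("a", "b"), "L1"))
  attr(m, "lengths") <- c(a = 1000, b = 2000)
  expect_equal(rpkm(m)["a", 1], 10)
  attr(m, "lengths") <- c(a = 2000, b = 2000)
  expect_equal(rpkm(m)["a", 1], 5)
  m2 <- matrix(c(8, 2e6 - 8), 2, 1, dimnames = list(c("a", "b"), "L1"))
  attr(m2, "lengths") <- c(a = 500, b = 1000)
  expect_equal(rpkm(m2)["a", 1], 8)
  attr(m2, "lengths") <- NULL
  expect_error(rpkm(m2), "lengths")
})

test_that("DE calls use the inclusive FDR threshold and logFC sign", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   logfc = c(-1.2, -1.2, 2, 0, -3),
                   fdr = c(0.01, 0.06, 0.05, 0.01, 0.05))
  calls <- call_de(de)
  expect_setequal(calls$down, c("a", "e"))
  expect_setequal(calls$up, "c")
  expect_true(all(c("b", "d") %in% calls$unchanged))
  expect_error(call_de(rbind(de, de[1, ])), "duplicate")
})

test_that("Venn partition is disjoint and covers all DE genes", {
  a <- list(up = c("u1", "u2", "x"), down = c("d1", "d2", "y"), unchanged = "z")
  b <- list(up = c("u1", "y"), down = c("d1", "x", "q"), unchanged = "z")
  v <- venn_partition(a, b)
  expect_setequal(v$down_both, "d1")
  expect_setequal(v$up_both, "u1")
  expect_setequal(v$discordant, c("x", "y"))
  all_cats <- unlist(v[setdiff(names(v), "sizes")])
  expect_false(any(duplicated(all_cats)))
  expect_setequal(all_cats, union(union(a$up, a$down), union(b$up, b$down)))
  # disjoint down sets give an empty intersection
  expect_length(venn_partition(list(up = NULL, down = "d1", unchanged = NULL),
                               list(up = NULL, down = "d2", unchanged = NULL))$down_both, 0)
})

test_that("ddct reproduces the closed forms and is monotone in each CT", {
  expect_equal(ddct(20, 20, 20, 20), 1.0)
  expect_equal(ddct(21, 20, 20, 20), 0.5)
  expect_equal(ddct(25, 20, 23, 20), 0.25)
  set.seed(7)
  ct <- matrix(runif(40, 15, 35), 10)
  base <- ddct(ct[, 1], ct[, 2], ct[, 3], ct[, 4])
  expect_true(all(ddct(ct[, 1] + 0.5, ct[, 2], ct[, 3], ct[, 4]) < base))
  expect_true(all(ddct(ct[, 1], ct[, 2] + 0.5, ct[, 3], ct[, 4]) > base))
  expect_error(ddct(Inf, 20, 20, 20), "finite")
})

test_that("ortholog concordance joins, counts quadrants and correlates", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   logfc = c(1, -2, 3, 0), fdr = c(0.01, 0.01, 0.2, 0.5))
  map <- data.frame(m = c("a", "b", "c", "d"), h = c("A", "B", "C", "D"))
  de2 <- de; de2$gene_id <- c("A", "B", "C", "D")
  r <- ortholog_concordance(de, de2, map)
  expect_equal(r$spearman, 1)
  expect_equal(unname(r$quadrants[c("up_up", "down_down")]), c(2L, 1L))
  expect_equal(sum(r$quadrants), 3L)  # the logFC = 0 gene is excluded
  # one-to-many errors unless collapsed by best combined FDR
  map2 <- rbind(map, data.frame(m = "a", h = "B"))
  expect_error(ortholog_concordance(de, de2, map2), "one-to-many")
  r2 <- ortholog_concordance(de, de2, map2, collapse = "best_fdr")
  expect_false(any(duplicated(r2$pairs$id1)))
  # empty intersection: no pairs, correlation absent
  r3 <- ortholog_concordance(de[0, ], de2, map)
  expect_equal(nrow(r3$pairs), 0L)
  expect_true(is.na(r3$spearman))
})
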