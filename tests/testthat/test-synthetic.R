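# Generators: determinism, planted ground truth, and self-validation
# against the downstream modules.

test_that("genome generation is seed-deterministic and non-overlapping", {
  expect_error(generate_genome(0), ">= 1")
  g1 <- generate_genome(200, 2, seed = 91)
  g2 <- generate_genome(200, 2, seed = 91)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(200, 2, seed = 92)))
  expect_equal(nrow(g1), 200L)
  # all-pairs overlap check within each chromosome
  for (ch in unique(g1$chrom)) {
    g <- g1[g1$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("planted peaks classify to their intended class for their gene", {
  genes <- generate_genome(100, 2, seed = 93)
  pk <- generate_peaks(genes, noise_peaks = 20, seed = 93)
  ann <- annotate_peaks(rbind(pk$peaks_a, pk$peaks_b), genes)
  planted <- pk$ground_truth$planted_classes
  hit <- merge(planted, ann, by = c("peak_id", "tf", "gene_id"))
  expect_equal(nrow(hit), nrow(planted))  # every planted pair is recovered
  expect_equal(hit$target_class, hit$class)
  # bound sets recovered exactly
  expect_setequal(genes_bound(ann, "TF_A"), pk$ground_truth$bound_a)
  expect_setequal(genes_bound(ann, "TF_B"), pk$ground_truth$bound_b)
})

test_that("all-promoter class mix puts every planted peak on its TSS", {
  genes <- generate_genome(40, 1, seed = 95)
  pk <- generate_peaks(genes, class_mix = c(promoter = 1, proximal = 0,
                                            putative_promoter = 0,
                                            putative_distal = 0), seed = 95)
  ann <- annotate_peaks(rbind(pk$peaks_a, pk$peaks_b), genes)
  planted <- ann[ann$gene_id %in% c(pk$ground_truth$bound_a, pk$ground_truth$bound_b), ]
  m <- merge(pk$ground_truth$planted_classes, ann, by = c("peak_id", "gene_id"))
  expect_true(all(m$target_class == "promoter"))
})

test_that("noise peaks receive no gene assignment downstream", {
  genes <- generate_genome(60, 2, seed = 97)
  pk <- generate_peaks(genes, noise_peaks = 50, seed = 97)
  ann <- annotate_peaks(rbind(pk$peaks_a, pk$peaks_b), genes)
  expect_length(pk$ground_truth$noise_peaks, 50L)
  expect_false(any(pk$ground_truth$noise_peaks %in% ann$peak_id))
})

test_that("zero co-bound fraction plants disjoint bound sets", {
  genes <- generate_genome(80, 2, seed = 99)
  pk <- generate_peaks(genes, fraction_cobound = 0, seed = 99)
  expect_length(intersect(pk$ground_truth$bound_a, pk$ground_truth$bound_b), 0)
})

test_that("DE tables plant dual-down and single-contrast genes cleanly", {
  genes <- generate_genome(150, 2, seed = 101)
  pk <- generate_peaks(genes, seed = 101)
  de <- generate_de_tables(genes, pk$ground_truth, n_down_a_only = 12,
                           n_down_b_only = 9, seed = 101)
  gt <- de$ground_truth
  calls_a <- call_de(de$de_a)
  calls_b <- call_de(de$de_b)
  expect_true(all(gt$down_both %in% calls_a$down))
  expect_true(all(gt$down_both %in% calls_b$down))
  v <- venn_partition(calls_a, calls_b)
  expect_setequal(v$down_both, gt$down_both)
  expect_equal(unname(v$sizes[c("down_a_only", "down_b_only")]), c(12L, 9L))
  # a gene planted down in A only is never a co-regulated candidate
  expect_length(intersect(gt$down_a_only, v$down_both), 0)
  expect_error(generate_de_tables(genes, pk$ground_truth, effect_logfc = 1),
               "negative")
})

test_that("coverage is background plus a plateau over each peak", {
  genes <- generate_genome(20, 1, seed = 103)
  pk <- generate_peaks(genes, seed = 103)
  cov <- generate_coverage(pk$peaks_a, genes, peak_height = 8, background = 0.5)
  track <- cov$TF_A
  p1 <- pk$peaks_a[1, ]
  inside <- track$start >= p1$start & track$end <= p1$end & track$chrom == p1$chrom
  expect_true(all(track$value[inside] >= 8.5))
  expect_setequal(round(unique(track$value[track$value < 8]), 6), 0.5)
  # degenerate: zero background and no peaks -> identically zero (empty track)
  none <- generate_coverage(pk$peaks_a[0, ], genes, peak_height = 1, background = 0)
  expect_length(none, 0)
})

test_that("clonotype generator plants the dominant clone exactly", {
  cl <- generate_clonotypes(n_clones = 50, dominant_fraction = 0.6,
                            n_samples = 2, seed = 105)
  for (s in names(cl$ground_truth$dominant))
    expect_equal(dominance_index(cl$table, s), 0.6)
  mono <- generate_clonotypes(n_clones = 10, dominant_fraction = 1, seed = 105)
  expect_equal(nrow(mono$table), 1L)
  expect_equal(top_clone_frequencies(mono$table)$frequency, 1)
})

test_that("the planted gene set is the most enriched downstream", {
  genes <- generate_genome(200, 2, seed = 107)
  co <- sample(genes$gene_id, 30)
  gs <- generate_gene_sets(genes, co, n_sets = 20, seed = 107)
  res <- gene_set_enrichment(co, genes$gene_id, gs$sets)
  expect_equal(res$set[1], gs$ground_truth$planted_set)
  expect_equal(length(gs$sets), 20L)
})

test_that("count generator silences genes the expression filter removes", {
  genes <- generate_genome(100, 2, seed = 109)
  keep <- genes$gene_id[1:10]
  m <- generate_counts(genes, keep_expressed = keep, seed = 109)
  silent <- attr(m, "silent")
  expect_length(intersect(silent, keep), 0)
  kept <- rownames(filter_expressed(m))
  expect_setequal(setdiff(rownames(m), kept), silent)
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_genome(20, 1, seed = 7))
  invisible(generate_clonotypes(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("simulated datasets are written completely and reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(d1, n_genes = 60, noise_peaks = 10, seed = 111)
  s2 <- simulate_dataset(d2, n_genes = 60, noise_peaks = 10, seed = 111)
  for (k in names(s1$paths)) {
    expect_true(file.exists(s1$paths[[k]]))
    expect_identical(readLines(s1$paths[[k]]), readLines(s2$paths[[k]]))
  }
  expect_equal(s1$ground_truth$cobound, s2$ground_truth$cobound)
})
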