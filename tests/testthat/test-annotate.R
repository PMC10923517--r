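# The four-class peak-to-TSS annotation.

mk_peak <- function(summit, id = "p", width = 400L, chrom = "chr1", tf = "TF_A") {
  peak_table(data.frame(peak_id = id, tf = tf, chrom = chrom,
                        start = summit - width %/% 2L,
                        end = summit + width %/% 2L, summit = summit,
                        score = NA, stringsAsFactors = FALSE))
}

test_that("TSS index window queries equal a brute-force scan", {
  fx <- random_fixture(200, 0, seed = 31)
  idx <- tss_index(fx$genes)
  set.seed(32)
  for (i in 1:200) {
    chrom <- sample(c("chr1", "chr2", "chr9"), 1)
    lo <- sample.int(2e6, 1); hi <- lo + sample.int(30000, 1)
    got <- sort(tfcoreg:::tss_in_window(idx, chrom, lo, hi))
    want <- which(fx$genes$chrom == chrom & fx$genes$tss >= lo & fx$genes$tss <= hi)
    expect_identical(got, want)
    got_b <- sort(tfcoreg:::body_overlap(idx, chrom, lo, hi))
    want_b <- which(fx$genes$chrom == chrom & fx$genes$start < hi & fx$genes$end > lo)
    expect_identical(got_b, want_b)
  }
  # closed-window boundary: a window ending exactly on a TSS returns the gene
  g1 <- fx$genes[1, ]
  expect_true(1L %in% tfcoreg:::tss_in_window(idx, g1$chrom, g1$tss - 100, g1$tss))
  # empty catalog
  empty <- tss_index(fx$genes[0, ])
  expect_length(tfcoreg:::tss_in_window(empty, "chr1", 0, 1e6), 0)
})

test_that("crafted boundary peaks classify exactly as documented", {
  gene <- boundary_gene("+")  # TSS at 100000
  tss <- gene$tss
  cases <- list(
    list(summit = tss + 100, class = "promoter"),       # interval covers the TSS
    list(summit = tss + 1200, class = "proximal"),      # inside the gene body
    list(summit = tss - 2999, class = "putative_promoter"),
    list(summit = tss - 3000, class = "putative_promoter"),  # inclusive 3 kb
    list(summit = tss - 3001, class = "putative_distal"),
    list(summit = tss - 9999, class = "putative_distal"),
    list(summit = tss - 10000, class = "putative_distal"),   # inclusive 10 kb
    list(summit = tss - 10001, class = NA))                  # out of range
  for (cs in cases) {
    ann <- annotate_peaks(mk_peak(cs$summit), gene)
    if (is.na(cs$class)) expect_equal(nrow(ann), 0L)
    else expect_equal(ann$target_class, cs$class)
  }
})

test_that("signed distance is negative upstream in gene orientation", {
  for (strand in c("+", "-")) {
    gene <- boundary_gene(strand)
    up <- if (strand == "+") gene$tss - 5000L else gene$tss + 5000L
    ann <- annotate_peaks(mk_peak(up), gene)
    expect_equal(ann$signed_distance, -5000L)
  }
})

test_that("indexed annotation equals the brute-force classifier exactly", {
  fx <- random_fixture(120, 300, seed = 41)
  got <- sort_ann(annotate_peaks(fx$peaks, fx$genes))
  want <- sort_ann(oracle_annotate(fx$peaks, fx$genes))
  expect_equal(got, want)
})

test_that("annotation classes are invariant under coordinate mirroring", {
  fx <- random_fixture(60, 150, seed = 51)
  L <- 4e6
  mirror_genes <- fx$genes
  mirror_genes$start <- L - fx$genes$end
  mirror_genes$end <- L - fx$genes$start
  mirror_genes$strand <- ifelse(fx$genes$strand == "+", "-", "+")
  mirror_genes <- gene_catalog(mirror_genes[c("gene_id", "chrom", "start", "end", "strand")])
  mirror_peaks <- fx$peaks
  mirror_peaks$start <- L - fx$peaks$end
  mirror_peaks$end <- L - fx$peaks$start
  mirror_peaks$summit <- ifelse(is.na(fx$peaks$summit), NA, L - 1L - fx$peaks$summit)
  mirror_peaks <- peak_table(mirror_peaks)

  a1 <- annotate_peaks(fx$peaks, fx$genes)
  a2 <- annotate_peaks(mirror_peaks, mirror_genes)
  # midpoint anchors can shift by 1 bp under mirroring (integer division),
  # flipping assignments exactly on a window boundary; compare summit-anchored
  has_summit <- !is.na(fx$peaks$summit)
  s1 <- a1[a1$peak_id %in% fx$peaks$peak_id[has_summit], ]
  s2 <- a2[a2$peak_id %in% fx$peaks$peak_id[has_summit], ]
  expect_identical(sort(paste(s1$peak_id, s1$gene_id, s1$target_class)),
                   sort(paste(s2$peak_id, s2$gene_id, s2$target_class)))
})

test_that("enlarging the TSS window never removes an assignment", {
  fx <- random_fixture(80, 200, seed = 61)
  small <- annotate_peaks(fx$peaks, fx$genes, tss_window = 5000L)
  big <- annotate_peaks(fx$peaks, fx$genes, tss_window = 15000L)
  expect_true(all(paste(small$peak_id, small$gene_id) %in%
                  paste(big$peak_id, big$gene_id)))
})

test_that("genes_bound collects per-TF gene sets with class filters", {
  expect_length(genes_bound(tfcoreg:::empty_annotation(), "TF_A"), 0)
  gene2 <- gene_catalog(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                                   start = c(100000L, 200000L),
                                   end = c(105000L, 204000L), strand = "+"))
  pk <- rbind(mk_peak(100100L, "pa", tf = "TF_A"),
              mk_peak(100150L, "pb", tf = "TF_B"),
              mk_peak(201000L, "pc", tf = "TF_A"))
  ann <- annotate_peaks(pk, gene2)
  expect_setequal(genes_bound(ann, "TF_A"), c("g1", "g2"))
  expect_setequal(genes_bound(ann, "TF_B"), "g1")
  expect_setequal(genes_bound(ann, "TF_A", classes = "promoter"), "g1")
  expect_setequal(genes_bound(ann, "TF_A", classes = "proximal"), "g2")
  expect_error(genes_bound(ann, "TF_A", classes = "enhancer"), "unknown target class")
})

test_that("nearest-only mode keeps the minimal-distance gene", {
  genes <- gene_catalog(data.frame(gene_id = c("near", "far"), chrom = "chr1",
                                   start = c(100000L, 108000L),
                                   end = c(101000L, 109000L), strand = "+"))
  ann <- annotate_peaks(mk_peak(102000L), genes)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$gene_id[ann$is_nearest_gene], "near")
  ann1 <- annotate_peaks(mk_peak(102000L), genes, nearest_only = TRUE)
  expect_equal(ann1$gene_id, "near")
})
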