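# TSS-centered coverage matrices and motif-window scanning.

test_that("TSS matrix handles zero, constant and plateau tracks", {
  genes <- gene_catalog(data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                                   start = c(50000L, 200000L),
                                   end = c(60000L, 210000L),
                                   strand = c("+", "-")))
  zero <- coverage_track(data.frame(chrom = character(), start = integer(),
                                    end = integer(), value = numeric()))
  expect_true(all(tss_matrix(zero, genes) == 0))

  const <- coverage_track(data.frame(chrom = "chr1", start = 0L, end = 500000L, value = 3))
  m <- tss_matrix(const, genes)
  expect_true(all(m == 3))
  expect_equal(dim(m), c(2L, 100L))

  # plateau of height 7 covering bins 48-52 of the plus-strand gene
  tss <- genes$tss[1]
  plat <- coverage_track(data.frame(chrom = "chr1",
                                    start = tss + (-300L), end = tss + 200L, value = 7))
  mp <- tss_matrix(plat, genes)
  expect_equal(unname(mp["gp", 48:52]), rep(7, 5))
  expect_true(all(mp["gp", -(48:52)] == 0))
})

test_that("binned means conserve the integrated window coverage", {
  genes <- generate_genome(20, 1, seed = 13)
  pk <- generate_peaks(genes, seed = 13)
  cov <- generate_coverage(rbind(pk$peaks_a, pk$peaks_b), genes, seed = 13)
  track <- cov$TF_A
  m <- tss_matrix(track, genes, half_width = 5000L, bin = 100L)
  for (i in seq_len(nrow(genes))) {
    lo <- genes$tss[i] - 5000; hi <- genes$tss[i] + 5000
    runs <- track[track$chrom == genes$chrom[i], ]
    ov <- pmin(runs$end, hi) - pmax(runs$start, lo)
    integral <- sum(runs$value[ov > 0] * ov[ov > 0])
    expect_equal(sum(m[i, ]) * 100, integral, tolerance = 1e-9)
  }
})

test_that("flipping a gene's strand reverses its row exactly", {
  genes <- generate_genome(10, 1, seed = 17)
  pk <- generate_peaks(genes, seed = 17)
  cov <- generate_coverage(rbind(pk$peaks_a, pk$peaks_b), genes, seed = 17)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  # keep the same TSS base so the window itself is unchanged
  flipped$start <- genes$tss
  flipped$end <- genes$tss + 1L
  flipped <- gene_catalog(flipped[c("gene_id", "chrom", "start", "end", "strand")])
  anchored <- genes
  anchored$start <- genes$tss
  anchored$end <- genes$tss + 1L
  anchored <- gene_catalog(anchored[c("gene_id", "chrom", "start", "end", "strand")])
  m1 <- tss_matrix(cov$TF_A, anchored)
  m2 <- tss_matrix(cov$TF_A, flipped)
  for (i in seq_len(nrow(genes)))
    expect_equal(unname(m2[i, ]), unname(rev(m1[i, ])))
})

test_that("log2 comparison is antisymmetric and summarizes per gene", {
  genes <- generate_genome(15, 1, seed = 19)
  pk <- generate_peaks(genes, fraction_cobound = 0.3, seed = 19)
  cov <- generate_coverage(rbind(pk$peaks_a, pk$peaks_b), genes, seed = 19)
  ma <- tss_matrix(cov$TF_A, genes)
  mb <- tss_matrix(cov$TF_B, genes)
  cmp <- tss_log2_comparison(ma, mb)
  cmp_rev <- tss_log2_comparison(mb, ma)
  expect_equal(cmp$log2_ratio, -cmp_rev$log2_ratio)
  expect_equal(tss_log2_comparison(ma, ma)$log2_ratio, ma * 0)
  # closed form: A = 3, B = 1, pc = 1 -> log2(4/2) = 1
  one <- matrix(3, 1, 2, dimnames = list("g", c("-100", "0")))
  two <- matrix(1, 1, 2, dimnames = list("g", c("-100", "0")))
  attr(one, "half_width") <- attr(two, "half_width") <- 100L
  attr(one, "bin") <- attr(two, "bin") <- 100L
  expect_true(all(tss_log2_comparison(one, two)$log2_ratio == 1))
  expect_error(tss_log2_comparison(ma, mb[, 1:10]), "grid")
})

test_that("consensus scanning hits exact IUPAC matches on either strand", {
  m <- motif_model("ets", consensus = "GGAA")
  r <- scan_motif(c(w1 = "TTGGAATT", w2 = "TTTTCCTT", w3 = "TTTTTTTT"), m)
  expect_equal(r$hit, c(TRUE, TRUE, FALSE))  # w2 carries it on the minus strand
  # ambiguity codes expand; N in the window never matches
  amb <- motif_model("amb", consensus = "GGAW")
  expect_true(scan_motif("CCGGATCC", amb)$hit)
  expect_false(scan_motif("CCGGNTCC", amb)$hit)
  # windows shorter than the motif are flagged, never hit
  short <- scan_motif("GG", m)
  expect_true(short$too_short && !short$hit)
})

test_that("PWM best scores equal exhaustive position-and-strand enumeration", {
  set.seed(23)
  pwm <- matrix(rnorm(24), 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  mm <- motif_model("rand", pwm = pwm, threshold = 0)
  seqs <- vapply(1:50, function(i) random_seq(101), "")
  seqs[7] <- sub("^.{40}", paste0(substr(seqs[7], 1, 34), "NNNNNN"), seqs[7])
  got <- scan_motif(seqs, mm)$best_score
  want <- vapply(seqs, function(s) oracle_pwm_best(s, pwm), 0)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("a reverse-complement-only PWM plant is detected", {
  # strongly favor ACGTAC; plant only its reverse complement GTACGT
  pwm <- matrix(-5, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  hit <- c("A", "C", "G", "T", "A", "C")
  for (p in 1:6) pwm[hit[p], p] <- 2
  mm <- motif_model("fwd", pwm = pwm, threshold = 12)
  win <- paste0(strrep("C", 40), "GTACGT", strrep("C", 40))
  expect_true(scan_motif(win, mm)$hit)
})

test_that("motif enrichment ratio and binomial tail follow the closed forms", {
  e <- motif_enrichment(5, 10, 50, 100)
  expect_equal(e$ratio, 1)
  expect_equal(motif_enrichment(10, 10, 50, 100)$p_value, 2^-10)
  # exact tail summation oracle for (k = 7, n = 10, rate = 0.2)
  p <- motif_enrichment(7, 10, 20, 100)$p_value
  want <- sum(choose(10, 7:10) * 0.2^(7:10) * 0.8^(10 - (7:10)))
  expect_equal(p, want, tolerance = 1e-12)
  z <- motif_enrichment(3, 10, 0, 100)
  expect_true(is.infinite(z$ratio) && z$zero_background && z$p_value < 1)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(29)
  seqs <- vapply(1:10, function(i) random_seq(80), "")
  shuf <- shuffle_windows(seqs, times = 3, seed = 31)
  expect_length(shuf, 30)
  for (i in seq_along(seqs)) {
    for (j in 1:3) {
      s <- shuf[(i - 1) * 3 + j]
      expect_equal(dinuc_counts(s), dinuc_counts(seqs[i]))
    }
  }
  # shuffling is seed-deterministic
  expect_identical(shuffle_windows(seqs, 3, seed = 31), shuf)
})
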